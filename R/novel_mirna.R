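#' Fold an RNA/DNA sequence into a secondary structure
#'
#' Built-in folding backend: a Nussinov-style dynamic program maximizing a
#' simple stacking-aware stability score (G:C 3, A:U 2, G:U 1, +1 per
#' stacked pair; minimum hairpin loop 3 nt). Deterministic and
#' dependency-free; an external thermodynamic folder with the same
#' contract (`function(seq) -> list(structure, mfe)`) can be supplied
#' wherever a `folder` argument is accepted.
#'
#' @param seq nucleotide sequence (A/C/G/T/U).
#' @return list with `structure` (dot-bracket string of the same length)
#'   and `mfe` (pseudo free energy, negative of the total stability).
#' @export
fold_hairpin <- function(seq) {
  s <- normalize_seq(seq)
  res <- .fold_stack_cpp(seq_to_int(s), min_loop = 3L, stack_bonus = 1.0)
  list(structure = res$structure, mfe = res$energy)
}

#' Fold with the external RNAfold program
#'
#' Shells out to the ViennaRNA `RNAfold` binary when it is on the PATH;
#' useful as an independent thermodynamic backend or oracle.
#'
#' @param seq nucleotide sequence.
#' @return list with `structure` and `mfe` (kcal/mol).
#' @export
fold_rnafold <- function(seq) {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold binary not found on PATH", call. = FALSE)
  }
  rna <- chartr("T", "U", normalize_seq(seq))
  out <- system2("RNAfold", args = "--noPS", input = rna, stdout = TRUE)
  line <- out[2L]
  structure <- sub("\\s.*$", "", line)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = structure, mfe = mfe)
}

# partner index (1-based) for each position of a dot-bracket string,
# NA when unpaired; errors on unbalanced brackets
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure", call. = FALSE)
  partner
}

#' Filter abundant tags down to novel-miRNA candidates
#'
#' The pre-structure cascade: (1) keep tags with combined read count
#' >= `min_reads`; (2) map each tag to the genome by exact match on both
#' strands, dropping tags with zero hits or more than `max_genome_hits`
#' hits, or any hit overlapping the repeat annotation; (3) drop tags
#' within Hamming distance <= `known_max_mm` of any known miRNA or other
#' ncRNA (equal-length windows of the longer sequence). Every removed tag
#' is attributed to the first stage that rejects it.
#'
#' @param tags tag table (columns `seq`, `count_treatment`,
#'   `count_control`).
#' @param genome named character vector of contig sequences.
#' @param repeat_annotation data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or NULL.
#' @param known_mirnas,other_ncrnas character vectors of reference
#'   sequences.
#' @param min_reads abundance threshold on combined counts (default 100).
#' @param max_genome_hits maximum allowed genomic hits (default 20).
#' @param known_max_mm Hamming radius for known-sequence removal
#'   (default 2).
#' @return list with `candidates` (tag rows plus a `hits` list-column of
#'   genomic loci) and `report` (named stage counts, non-increasing).
#' @export
filter_candidates <- function(tags, genome, repeat_annotation = NULL,
                              known_mirnas = character(0),
                              other_ncrnas = character(0),
                              min_reads = 100L, max_genome_hits = 20L,
                              known_max_mm = 2L) {
  if (length(genome) == 0L || all(nchar(genome) == 0L)) {
    stop("empty genome", call. = FALSE)
  }
  if (is.null(names(genome))) {
    stop("genome contigs must be named", call. = FALSE)
  }
  combined <- tags$count_treatment + tags$count_control
  report <- c(input_unique = nrow(tags))
  tags <- tags[combined >= min_reads, , drop = FALSE]
  report["abundance_pass"] <- nrow(tags)

  genome <- normalize_seq(genome, "genome")
  hits <- lapply(tags$seq, function(s) map_tag_to_genome(s, genome))
  n_hits <- vapply(hits, nrow, integer(1L))
  keep <- n_hits >= 1L & n_hits <= max_genome_hits
  tags <- tags[keep, , drop = FALSE]; hits <- hits[keep]
  report["genome_mapped"] <- nrow(tags)

  if (!is.null(repeat_annotation) && nrow(repeat_annotation) > 0L) {
    overlaps_repeat <- vapply(hits, function(h) {
      any(vapply(seq_len(nrow(h)), function(i) {
        r <- repeat_annotation[repeat_annotation$chrom == h$chrom[i], ,
                               drop = FALSE]
        any(r$start < h$end[i] & r$end > h$start[i])
      }, logical(1L)))
    }, logical(1L))
    tags <- tags[!overlaps_repeat, , drop = FALSE]
    hits <- hits[!overlaps_repeat]
  }
  report["repeat_filtered"] <- nrow(tags)

  refs <- normalize_seq(c(known_mirnas, other_ncrnas), "reference")
  if (length(refs) > 0L && nrow(tags) > 0L) {
    near_known <- vapply(tags$seq, function(s) {
      any(vapply(refs, function(r) min_window_hamming(s, r) <= known_max_mm,
                 logical(1L)))
    }, logical(1L))
    tags <- tags[!near_known, , drop = FALSE]
    hits <- hits[!near_known]
  }
  report["known_filtered"] <- nrow(tags)

  tags$hits <- hits
  list(candidates = tags, report = report)
}

map_tag_to_genome <- function(tag, genome) {
  tag <- normalize_seq(tag)
  rc <- revcomp(tag)
  rows <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else rc
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = IRanges::start(m) - 1L,
          end = IRanges::end(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Excise candidate precursor windows around a mapped tag and fold them
#'
#' Two windows are generated per flank setting, with the mature tag placed
#' toward either end of the precursor (`flank = c(up, dn)` and its
#' reverse). Minus-strand loci are excised as the reverse complement, so
#' the precursor always carries the mature tag in its own orientation.
#' Windows that would run past a contig edge are clipped and flagged.
#'
#' @param genome named character vector of contigs.
#' @param locus one-row data.frame (`chrom`, `start`, `end`, `strand`) of
#'   the mature tag's genomic hit.
#' @param flanks length-2 integer vector of flank sizes (default
#'   `c(20, 160)`).
#' @param folder folding backend, default [fold_hairpin()].
#' @return list of unevaluated hairpin candidates: `precursor_seq`,
#'   `structure`, `mfe`, `mature_start`/`mature_end` (0-based within the
#'   precursor), `locus`, `clipped`.
#' @export
excise_and_fold <- function(genome, locus, flanks = c(20L, 160L),
                            folder = fold_hairpin) {
  stopifnot(all(flanks >= 0L))
  chrom_seq <- unname(genome[locus$chrom])
  if (length(chrom_seq) != 1L || is.na(chrom_seq)) {
    stop("unknown chromosome: ", locus$chrom, call. = FALSE)
  }
  clen <- nchar(chrom_seq)
  flank_sets <- unique(list(as.integer(flanks), rev(as.integer(flanks))))
  lapply(flank_sets, function(fl) {
    # fl is (upstream, downstream) in the mature strand's orientation
    if (locus$strand == "+") {
      ws <- locus$start - fl[1L]; we <- locus$end + fl[2L]
    } else {
      ws <- locus$start - fl[2L]; we <- locus$end + fl[1L]
    }
    clipped <- ws < 0L || we > clen
    ws_c <- max(ws, 0L); we_c <- min(we, clen)
    win <- substr(chrom_seq, ws_c + 1L, we_c)
    if (locus$strand == "+") {
      precursor <- win
      mstart <- locus$start - ws_c
    } else {
      precursor <- revcomp(win)
      mstart <- we_c - locus$end
    }
    fold <- folder(precursor)
    if (nchar(fold$structure) != nchar(precursor)) {
      stop("folder returned a structure of the wrong length", call. = FALSE)
    }
    list(precursor_seq = normalize_seq(precursor),
         structure = fold$structure, mfe = fold$mfe,
         mature_start = mstart,
         mature_end = mstart + (locus$end - locus$start),
         locus = locus, clipped = clipped, criteria = NULL, passed = NA)
  })
}

#' Evaluate a folded precursor window against hairpin criteria
#'
#' Criteria (all must hold): (a) the mature span lies entirely in one arm
#' of a single stem-loop (no bracket-direction change inside the span, and
#' partner positions run monotonically); (b) at most `max_unpaired_mature`
#' mature bases are unpaired in the mature:star duplex; (c) no asymmetric
#' bulge larger than `max_bulge` nt within the duplex; (d) folding energy
#' at most `mfe_max`; (e) the mature span does not overlap a terminal
#' (hairpin) loop.
#'
#' @param candidate an element of the [excise_and_fold()] output.
#' @param mfe_max energy ceiling, default -18.
#' @param max_unpaired_mature default 4.
#' @param max_bulge default 2.
#' @return the candidate with `criteria` (named logicals), `passed`,
#'   `arm` (`"5p"`/`"3p"`) and `star_interval` filled in.
#' @export
evaluate_hairpin <- function(candidate, mfe_max = -18,
                             max_unpaired_mature = 4L, max_bulge = 2L) {
  if (is.null(candidate$structure)) {
    stop("candidate has not been folded", call. = FALSE)
  }
  partner <- pair_table(candidate$structure)
  ch <- strsplit(candidate$structure, "")[[1L]]
  span <- (candidate$mature_start + 1L):candidate$mature_end # 1-based
  span_ch <- ch[span]
  span_partner <- partner[span]

  open_in <- any(span_ch == "(")
  close_in <- any(span_ch == ")")
  paired_idx <- span[!is.na(span_partner)]
  partners <- partner[paired_idx]
  monotone <- if (length(partners) >= 2L) {
    all(diff(partners) < 0L)
  } else TRUE
  single_arm <- !(open_in && close_in) && monotone &&
    length(paired_idx) > 0L

  unpaired <- sum(is.na(span_partner))
  duplex_unpaired_ok <- unpaired <= max_unpaired_mature

  bulge_ok <- TRUE
  if (single_arm && length(paired_idx) >= 2L) {
    for (k in seq_len(length(paired_idx) - 1L)) {
      gap_m <- paired_idx[k + 1L] - paired_idx[k] - 1L
      gap_s <- abs(partners[k] - partners[k + 1L]) - 1L
      if (abs(gap_m - gap_s) > max_bulge) { bulge_ok <- FALSE; break }
    }
  } else if (!single_arm) {
    bulge_ok <- FALSE
  }

  mfe_ok <- candidate$mfe <= mfe_max

  # terminal (hairpin) loops: unpaired stretches directly enclosed by a pair
  loop_positions <- integer(0)
  pair_open <- which(!is.na(partner) & partner > seq_along(partner))
  for (i in pair_open) {
    j <- partner[i]
    if (j - i > 1L && all(is.na(partner[(i + 1L):(j - 1L)]))) {
      loop_positions <- c(loop_positions, (i + 1L):(j - 1L))
    }
  }
  outside_loop <- !any(span %in% loop_positions)

  criteria <- c(single_arm = single_arm,
                duplex_unpaired = duplex_unpaired_ok,
                bulge = bulge_ok,
                mfe = mfe_ok,
                outside_terminal_loop = outside_loop)
  candidate$criteria <- criteria
  candidate$passed <- all(criteria)
  if (length(paired_idx) > 0L) {
    candidate$arm <- if (ch[paired_idx[1L]] == "(") "5p" else "3p"
    candidate$star_interval <- c(min(partners) - 1L, max(partners))
  } else {
    candidate$arm <- NA_character_
    candidate$star_interval <- c(NA_integer_, NA_integer_)
  }
  candidate
}

#' Discover novel miRNAs from collapsed tags
#'
#' Composes [filter_candidates()], [excise_and_fold()] and
#' [evaluate_hairpin()]: a tag is called a novel miRNA iff at least one of
#' its precursor windows passes all hairpin criteria. For each call the
#' best-energy passing window is reported.
#'
#' @param tags tag table with per-library counts.
#' @param genome named character vector of contigs.
#' @param annotations list with elements `repeats` (data.frame or NULL),
#'   `known_mirnas`, `other_ncrnas` (character vectors).
#' @param config list of knobs: `min_reads` (100), `max_genome_hits` (20),
#'   `known_max_mm` (2), `flanks` (c(20, 160)), `mfe_max` (-18),
#'   `max_unpaired_mature` (4), `max_bulge` (2), `folder`.
#' @return list with `novel` (table of calls: tag, locus, precursor,
#'   structure, energy, arm) and `report` (cascade counts including
#'   `structure_pass`).
#' @export
discover_novel <- function(tags, genome, annotations = list(),
                           config = list()) {
  cfg <- modifyList(list(min_reads = 100L, max_genome_hits = 20L,
                         known_max_mm = 2L, flanks = c(20L, 160L),
                         mfe_max = -18, max_unpaired_mature = 4L,
                         max_bulge = 2L, folder = fold_hairpin), config)
  fc <- filter_candidates(
    tags, genome,
    repeat_annotation = annotations$repeats,
    known_mirnas = annotations$known_mirnas %||% character(0),
    other_ncrnas = annotations$other_ncrnas %||% character(0),
    min_reads = cfg$min_reads, max_genome_hits = cfg$max_genome_hits,
    known_max_mm = cfg$known_max_mm)
  cands <- fc$candidates
  rows <- list()
  n_pass <- 0L
  if (nrow(cands) > 0L) {
    for (i in seq_len(nrow(cands))) {
      best <- NULL
      for (h in seq_len(nrow(cands$hits[[i]]))) {
        locus <- cands$hits[[i]][h, , drop = FALSE]
        wins <- excise_and_fold(genome, locus, flanks = cfg$flanks,
                                folder = cfg$folder)
        for (w in wins) {
          ev <- evaluate_hairpin(w, mfe_max = cfg$mfe_max,
                                 max_unpaired_mature = cfg$max_unpaired_mature,
                                 max_bulge = cfg$max_bulge)
          if (isTRUE(ev$passed) &&
              (is.null(best) || ev$mfe < best$mfe)) best <- ev
        }
      }
      if (!is.null(best)) {
        n_pass <- n_pass + 1L
        rows[[n_pass]] <- data.frame(
          tag_seq = cands$seq[i],
          count_treatment = cands$count_treatment[i],
          count_control = cands$count_control[i],
          chrom = best$locus$chrom, start = best$locus$start,
          end = best$locus$end, strand = best$locus$strand,
          precursor_seq = best$precursor_seq,
          structure = best$structure, mfe = best$mfe, arm = best$arm,
          stringsAsFactors = FALSE)
      }
    }
  }
  novel <- if (n_pass > 0L) do.call(rbind, rows) else
    data.frame(tag_seq = character(0), count_treatment = integer(0),
               count_control = integer(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               precursor_seq = character(0), structure = character(0),
               mfe = numeric(0), arm = character(0),
               stringsAsFactors = FALSE)
  report <- c(fc$report, structure_pass = n_pass)
  list(novel = novel, report = report)
}
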