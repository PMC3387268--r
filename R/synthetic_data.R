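random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) random_seq(len), character(1L))
}

#' Default desk-scale simulation parameters
#'
#' Two 500-kb contigs, 20 known miRNA signatures (two of them with a
#' second locus), 5 novel hairpins, 10 repeat blocks, 10 ncRNAs, 10 PWMs
#' (5 planted), promoters for the 10 differentially expressed miRNA
#' genes. The full pipeline runs in minutes at this scale.
#'
#' @param ... overrides for individual parameters.
#' @return named list of generator parameters.
#' @export
desk_params <- function(...) {
  modifyList(list(
    contig_lengths = c(chr1 = 500000L, chr2 = 500000L),
    n_known = 20L, n_multi_locus = 2L, n_de_known = 10L,
    n_hairpins = 5L, n_repeats = 10L, n_ncrnas = 10L,
    n_pwms = 10L, n_pwms_planted = 5L,
    mature_len = 21L, pwm_width = 8L, motif_occurrences = 3L,
    de_fold_up = 3.0, de_fold_down = 1 / 3,
    max_attempts = 1000L), list(...))
}

# non-overlapping placement registry (buffered intervals per chrom)
new_registry <- function(contig_lengths) {
  env <- new.env(parent = emptyenv())
  env$occupied <- lapply(contig_lengths, function(x) {
    data.frame(start = integer(0), end = integer(0))
  })
  env$lengths <- contig_lengths
  env
}

reserve_interval <- function(reg, len, buffer = 50L,
                            max_attempts = 1000L, chrom = NULL) {
  for (i in seq_len(max_attempts)) {
    ch <- chrom %||% sample(names(reg$lengths), 1L)
    clen <- reg$lengths[[ch]]
    if (clen < len + 2L * buffer) next
    start <- sample.int(clen - len - 2L * buffer, 1L) + buffer
    occ <- reg$occupied[[ch]]
    if (nrow(occ) == 0L ||
        !any(occ$start < start + len + buffer &
             occ$end + buffer > start)) {
      reg$occupied[[ch]] <- rbind(occ, data.frame(start = start,
                                                  end = start + len))
      return(list(chrom = ch, start = start, end = start + len))
    }
  }
  stop("generation error: could not place a feature of length ", len,
       " after ", max_attempts, " attempts", call. = FALSE)
}

plant_seq <- function(contigs, chrom, start, seq) {
  substr(contigs[[chrom]], start + 1L, start + nchar(seq)) <- seq
  contigs
}

# a designed precursor: 5-nt extension + mature + 5-nt extension form the
# 5' arm; an 8-nt loop; the 3' arm is the arm's reverse complement
design_precursor <- function(mature) {
  arm <- paste0(random_seq(5L), mature, random_seq(5L))
  loop <- random_seq(8L)
  list(precursor = paste0(arm, loop, revcomp(arm)),
       mature_offset = 5L) # 0-based offset of the mature within the arm
}

#' Simulate a genome with planted regulatory features
#'
#' Generates i.i.d.-uniform background contigs and plants, without
#' overlap: novel miRNA hairpin precursors (designed complementary arms),
#' known mature miRNA loci, tandem repeat blocks, and pri-miRNA promoters
#' (for the differentially expressed miRNA genes) carrying planted PWM
#' consensus occurrences. All coordinates, sequences, PWMs and the true
#' fold-change assignment are recorded in the truth manifest. A fixed
#' seed gives byte-identical output.
#'
#' @param params list from [desk_params()].
#' @param seed integer RNG seed.
#' @return list: `genome` (named character), `tss_table`,
#'   `repeat_annotation`, `known_catalog`, `ncrnas`, `pwms`, `manifest`.
#' @export
simulate_genome <- function(params = desk_params(), seed = 1L) {
  set.seed(seed)
  p <- params
  contigs <- vapply(p$contig_lengths, random_seq, character(1L))
  names(contigs) <- names(p$contig_lengths)
  reg <- new_registry(p$contig_lengths)

  # distinct mature sequences for known + novel miRNAs (pairwise Hamming
  # distance > 4 so the known-removal radius of 2 cannot confuse them)
  n_mature <- p$n_known + p$n_hairpins
  matures <- character(0)
  while (length(matures) < n_mature) {
    cand <- random_seq(p$mature_len)
    ok <- all(vapply(matures, function(m)
      min_window_hamming(cand, m) > 4L, logical(1L)))
    if (ok) matures <- c(matures, cand)
  }
  known_mature <- matures[seq_len(p$n_known)]
  novel_mature <- matures[p$n_known + seq_len(p$n_hairpins)]

  # known miRNA loci: signature ids miR101a..; the first n_multi_locus
  # signatures get a second genomic locus
  sig_ids <- paste0("miR", 100L + seq_len(p$n_known), "a")
  known_rows <- list()
  for (i in seq_len(p$n_known)) {
    n_loci <- if (i <= p$n_multi_locus) 2L else 1L
    for (l in seq_len(n_loci)) {
      strand <- sample(c("+", "-"), 1L)
      loc <- reserve_interval(reg, p$mature_len,
                              max_attempts = p$max_attempts)
      planted <- if (strand == "+") known_mature[i] else
        revcomp(known_mature[i])
      contigs <- plant_seq(contigs, loc$chrom, loc$start, planted)
      known_rows[[length(known_rows) + 1L]] <- data.frame(
        signature_id = sig_ids[i], mature_seq = known_mature[i],
        locus_id = paste0(sig_ids[i], "-", l), chrom = loc$chrom,
        start = loc$start, end = loc$end, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  known_catalog <- do.call(rbind, known_rows)

  # novel hairpins
  hairpin_rows <- list()
  for (i in seq_len(p$n_hairpins)) {
    d <- design_precursor(novel_mature[i])
    strand <- if (i %% 2L == 0L) "-" else "+"
    plen <- nchar(d$precursor)
    loc <- reserve_interval(reg, plen, max_attempts = p$max_attempts)
    planted <- if (strand == "+") d$precursor else revcomp(d$precursor)
    contigs <- plant_seq(contigs, loc$chrom, loc$start, planted)
    # genomic coordinates of the mature tag within the planted precursor
    if (strand == "+") {
      m_start <- loc$start + d$mature_offset
    } else {
      m_start <- loc$end - d$mature_offset - p$mature_len
    }
    hairpin_rows[[i]] <- data.frame(
      hairpin_id = paste0("miRn", i), mature_seq = novel_mature[i],
      precursor_seq = d$precursor, chrom = loc$chrom,
      precursor_start = loc$start, precursor_end = loc$end,
      mature_start = m_start, mature_end = m_start + p$mature_len,
      strand = strand, arm = "5p", stringsAsFactors = FALSE)
  }
  hairpins <- do.call(rbind, hairpin_rows)

  # tandem repeat blocks
  repeat_rows <- list()
  for (i in seq_len(p$n_repeats)) {
    unit <- random_seq(10L)
    block <- paste(rep(unit, 30L), collapse = "")
    loc <- reserve_interval(reg, nchar(block),
                            max_attempts = p$max_attempts)
    contigs <- plant_seq(contigs, loc$chrom, loc$start, block)
    repeat_rows[[i]] <- data.frame(chrom = loc$chrom, start = loc$start,
                                   end = loc$end, unit = unit,
                                   stringsAsFactors = FALSE)
  }
  repeat_annotation <- if (p$n_repeats > 0L) do.call(rbind, repeat_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               unit = character(0), stringsAsFactors = FALSE)

  ncrnas <- data.frame(
    id = paste0("ncRNA", seq_len(p$n_ncrnas)),
    seq = random_seqs(p$n_ncrnas, 100L), stringsAsFactors = FALSE)

  # true fold-change assignment: the first n_de_known signatures are
  # differentially expressed, alternating induced / repressed; novel
  # hairpins 1 and 2 are DE as well
  fold_truth <- data.frame(
    entity_id = c(sig_ids, hairpins$hairpin_id),
    kind = c(rep("known", p$n_known), rep("novel", p$n_hairpins)),
    mature_seq = c(known_mature, novel_mature),
    fold = 1.0, stringsAsFactors = FALSE)
  de_idx <- seq_len(p$n_de_known)
  fold_truth$fold[de_idx] <- ifelse(de_idx %% 2L == 1L,
                                    p$de_fold_up, p$de_fold_down)
  if (p$n_hairpins >= 2L) {
    fold_truth$fold[p$n_known + 1L] <- 2.5
    fold_truth$fold[p$n_known + 2L] <- 0.4
  }

  # promoters (TSS) for the DE known miRNA genes
  de_sigs <- sig_ids[de_idx]
  tss_rows <- list()
  for (i in seq_along(de_sigs)) {
    strand <- sample(c("+", "-"), 1L)
    # reserve [tss-1000, tss+500) plus slack, strand-oriented
    loc <- reserve_interval(reg, 1700L, max_attempts = p$max_attempts)
    tss <- if (strand == "+") loc$start + 1000L else loc$start + 700L
    tss_rows[[i]] <- data.frame(chrom = loc$chrom, tss_pos = tss,
                                strand = strand, gene_id = de_sigs[i],
                                stringsAsFactors = FALSE)
  }
  tss_table <- do.call(rbind, tss_rows)

  # PWMs: width-8 count matrices with an 85/5/5/5 consensus column profile
  consensus <- character(0)
  while (length(consensus) < p$n_pwms) {
    cand <- random_seq(p$pwm_width)
    if (!cand %in% consensus) consensus <- c(consensus, cand)
  }
  family_pool <- c("MYB", "bZIP", "HMG", "AP2/ERF", "bHLH", "HD-Zip",
                   "DOF", "MADS", "NAC", "SBP", "TCP", "ARF")
  families <- sample(family_pool, p$n_pwms)
  pwms <- vector("list", p$n_pwms)
  for (i in seq_len(p$n_pwms)) {
    mat <- matrix(5, nrow = 4L, ncol = p$pwm_width,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- strsplit(consensus[i], "")[[1L]]
    for (j in seq_len(p$pwm_width)) mat[cons[j], j] <- 85
    pwms[[i]] <- new_pwm(sprintf("PWM%03d", i), paste0("TF_", families[i]),
                         families[i], mat)
  }
  pwm_meta <- data.frame(
    motif_id = vapply(pwms, `[[`, "", "motif_id"),
    tf_name = vapply(pwms, `[[`, "", "tf_name"),
    tf_family = families, consensus = consensus,
    planted = seq_len(p$n_pwms) <= p$n_pwms_planted,
    stringsAsFactors = FALSE)

  # plant consensus occurrences of each planted PWM in 2-4 promoters
  planted_rows <- list()
  prom_occupied <- lapply(seq_len(nrow(tss_table)), function(i) integer(0))
  for (i in which(pwm_meta$planted)) {
    target_proms <- sort(sample(seq_len(nrow(tss_table)),
                                sample(2:4, 1L)))
    for (pr in target_proms) {
      offsets <- integer(0)
      attempts <- 0L
      while (length(offsets) < p$motif_occurrences) {
        attempts <- attempts + 1L
        if (attempts > p$max_attempts) {
          stop("generation error: could not place motif occurrences",
               call. = FALSE)
        }
        o <- sample.int(1500L - p$pwm_width, 1L) - 1L
        taken <- c(prom_occupied[[pr]], offsets)
        if (any(abs(taken - o) < p$pwm_width)) next
        offsets <- c(offsets, o)
      }
      prom_occupied[[pr]] <- c(prom_occupied[[pr]], offsets)
      tss <- tss_table$tss_pos[pr]; strand <- tss_table$strand[pr]
      for (o in offsets) {
        if (strand == "+") {
          gstart <- tss - 1000L + o
          contigs <- plant_seq(contigs, tss_table$chrom[pr], gstart,
                               consensus[i])
        } else {
          gstart <- tss + 1000L - o - p$pwm_width
          contigs <- plant_seq(contigs, tss_table$chrom[pr], gstart,
                               revcomp(consensus[i]))
        }
      }
      planted_rows[[length(planted_rows) + 1L]] <- data.frame(
        motif_id = pwm_meta$motif_id[i], tf_family = pwm_meta$tf_family[i],
        gene_id = tss_table$gene_id[pr],
        offsets = paste(sort(offsets), collapse = ","),
        n = p$motif_occurrences, stringsAsFactors = FALSE)
    }
  }
  planted_motifs <- do.call(rbind, planted_rows)

  # self-check: every novel mature sequence maps only within its own
  # precursor (both strands hit the perfectly complementary arms, so up
  # to two hits are legitimate)
  for (i in seq_len(p$n_hairpins)) {
    hits <- map_tag_to_genome(novel_mature[i], contigs)
    h <- hairpins[i, ]
    inside <- hits$chrom == h$chrom & hits$start >= h$precursor_start &
      hits$end <= h$precursor_end
    if (nrow(hits) < 1L || !all(inside)) {
      stop("generation error: novel mature sequence ", i,
           " maps outside its precursor", call. = FALSE)
    }
  }

  manifest <- list(
    seed = seed, params = p,
    contigs = data.frame(chrom = names(contigs),
                         length = unname(nchar(contigs)),
                         stringsAsFactors = FALSE),
    known_catalog = known_catalog, hairpins = hairpins,
    repeat_annotation = repeat_annotation, ncrnas = ncrnas,
    tss_table = tss_table, pwm_meta = pwm_meta,
    planted_motifs = planted_motifs, fold_truth = fold_truth)
  list(genome = contigs, tss_table = tss_table,
       repeat_annotation = repeat_annotation,
       known_catalog = known_catalog, ncrnas = ncrnas, pwms = pwms,
       manifest = manifest)
}

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Simulate the two small-RNA sequencing libraries
#'
#' Reads are mature sequence plus 3' adapter, truncated to the read
#' length. Per-entity counts honour the fold map exactly in expectation:
#' control weights are a seeded lognormal profile, treatment weights are
#' control times fold, and a random-background filler keeps the two
#' libraries' usable totals equal so observed RPM ratios match the true
#' folds. Adapter-only and too-short reads are mixed in at the configured
#' fractions. `sampling = "expected"` uses deterministic rounded counts
#' (the zero-noise regime); `"multinomial"` draws them.
#'
#' @param manifest truth manifest from [simulate_genome()].
#' @param depth_treatment,depth_control library depths (default 2e5).
#' @param fold_map named treatment/control ratios per entity id; defaults
#'   to the manifest's fold truth.
#' @param adapter 3' adapter sequence.
#' @param noise list: `background_frac` (0.15), `adapter_only_frac`
#'   (0.03), `short_frac` (0.02), `sampling` (`"multinomial"` or
#'   `"expected"`).
#' @param seed RNG seed.
#' @param read_length raw read length (default 36).
#' @return list: `reads_treatment`, `reads_control` (character vectors),
#'   `counts` (true per-entity counts), and the updated `manifest`.
#' @export
simulate_libraries <- function(manifest, depth_treatment = 200000L,
                               depth_control = 200000L, fold_map = NULL,
                               adapter = DEFAULT_ADAPTER,
                               noise = list(), seed = 1L,
                               read_length = 36L) {
  set.seed(seed)
  nz <- modifyList(list(background_frac = 0.15, adapter_only_frac = 0.03,
                        short_frac = 0.02, sampling = "multinomial"),
                   noise)
  ft <- manifest$fold_truth
  if (is.null(fold_map)) {
    fold_map <- setNames(ft$fold, ft$entity_id)
  }
  unknown <- setdiff(names(fold_map), ft$entity_id)
  if (length(unknown) > 0L) {
    stop("fold_map references unknown miRNA(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  folds <- setNames(rep(1.0, nrow(ft)), ft$entity_id)
  folds[names(fold_map)] <- fold_map
  n_ent <- nrow(ft)

  base <- rlnorm(n_ent, meanlog = 0, sdlog = 0.5)
  budget <- 1 - nz$background_frac - nz$adapter_only_frac - nz$short_frac
  if (budget <= 0) stop("noise fractions exhaust the library", call. = FALSE)
  scale <- budget / max(sum(base), sum(base * folds))
  w_ctl <- base * scale
  w_trt <- base * folds * scale

  make_library <- function(weights, depth) {
    if (depth == 0L) {
      return(list(reads = character(0),
                  counts = setNames(integer(n_ent), ft$entity_id)))
    }
    probs <- c(weights, nz$adapter_only_frac, nz$short_frac,
               1 - sum(weights) - nz$adapter_only_frac - nz$short_frac)
    if (probs[length(probs)] < 0) {
      stop("fold map pushes miRNA mass above the library budget",
           call. = FALSE)
    }
    counts <- if (nz$sampling == "expected") {
      k <- floor(probs * depth)
      rem <- depth - sum(k)
      if (rem > 0L) { # assign the remainder to the largest fractions
        frac <- probs * depth - k
        k[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
          k[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
      }
      k
    } else {
      as.integer(rmultinom(1L, depth, probs))
    }
    n_cat <- length(counts)
    ent_counts <- counts[seq_len(n_ent)]
    reads <- rep(substr(paste0(ft$mature_seq, adapter), 1L, read_length),
                 ent_counts)
    n_ao <- counts[n_ent + 1L]
    if (n_ao > 0L) {
      ao <- substr(paste0(adapter, adapter, adapter), 1L, read_length)
      reads <- c(reads, rep(ao, n_ao))
    }
    n_short <- counts[n_ent + 2L]
    if (n_short > 0L) {
      lens <- sample(8:17, n_short, replace = TRUE)
      shorts <- vapply(lens, function(l)
        substr(paste0(random_seq(l), adapter, adapter), 1L, read_length),
        character(1L))
      reads <- c(reads, shorts)
    }
    n_bg <- counts[n_cat]
    if (n_bg > 0L) {
      lens <- sample(18:26, n_bg, replace = TRUE)
      shorts <- vapply(lens, function(l)
        substr(paste0(random_seq(l), adapter, adapter), 1L, read_length),
        character(1L))
      reads <- c(reads, shorts)
    }
    list(reads = reads,
         counts = setNames(as.integer(ent_counts), ft$entity_id))
  }

  trt <- make_library(w_trt, depth_treatment)
  ctl <- make_library(w_ctl, depth_control)
  counts <- data.frame(entity_id = ft$entity_id, kind = ft$kind,
                       fold = unname(folds),
                       count_treatment = unname(trt$counts),
                       count_control = unname(ctl$counts),
                       stringsAsFactors = FALSE)
  manifest$library_truth <- list(
    depth_treatment = depth_treatment, depth_control = depth_control,
    adapter = adapter, noise = nz, counts = counts)
  list(reads_treatment = trt$reads, reads_control = ctl$reads,
       counts = counts, manifest = manifest)
}

# replace the site base pairing miRNA position `pos` (1-based from the
# miRNA 5' end) with a base that is neither Watson-Crick nor wobble
inject_mismatch <- function(site, mirna, pos) {
  L <- nchar(mirna)
  idx <- L - pos + 1L # 1-based index into the site
  m <- substr(mirna, pos, pos)
  comp <- chartr("ACGT", "TGCA", m)
  wob <- switch(m, G = "T", T = "G", NA_character_)
  choices <- setdiff(c("A", "C", "G", "T"), c(comp, wob))
  repl <- choices[1L]
  substr(site, idx, idx) <- repl
  site
}

TARGET_SITE_CLASSES <- c("all_pass", "violate_seed", "violate_10_11",
                         "violate_consec", "violate_total", "distance7")

make_site <- function(mirna, class) {
  site <- revcomp(mirna)
  pos <- switch(class,
                all_pass = integer(0),
                violate_seed = c(3L, 8L),
                violate_10_11 = 10L,
                violate_consec = c(13L, 14L, 15L),
                violate_total = c(1L, 13L, 15L, 17L, 19L),
                distance7 = c(1L, 3L, 5L, 13L, 15L, 17L, 19L),
                stop("unknown site class: ", class, call. = FALSE))
  for (p_ in pos) site <- inject_mismatch(site, mirna, p_)
  site
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' For each differentially expressed miRNA an all-pass site is embedded
#' in two transcripts - one designated a true (anti-correlated) target
#' with a TF-family annotation, one a non-regulated decoy - and, for the
#' first two DE miRNAs, one site of each rule-violation class plus a
#' Hamming-distance-7 decoy. Every planted site's rule profile is
#' verified against [score_duplex()] at generation time.
#'
#' @param manifest truth manifest (after [simulate_genome()]).
#' @param n_transcripts number of transcripts (default 100).
#' @param transcript_len transcript length in nt (default 500).
#' @param seed RNG seed.
#' @return list: `transcripts` (named character),
#'   `transcript_annotation` (id -> TF family), and the updated
#'   `manifest` (with a `targets` table).
#' @export
simulate_transcript_targets <- function(manifest, n_transcripts = 100L,
                                        transcript_len = 500L, seed = 1L) {
  set.seed(seed)
  ft <- manifest$fold_truth
  de <- ft[ft$fold != 1, , drop = FALSE]
  transcripts <- setNames(random_seqs(n_transcripts, transcript_len),
                          sprintf("t%03d", seq_len(n_transcripts)))
  target_family_pool <- c("MYB", "ARF", "GRF", "AP2/ERF", "SBP", "TCP",
                          "NAC", "CBF")
  free <- names(transcripts)
  rows <- list()
  annotation <- data.frame(transcript_id = names(transcripts),
                           tf_family = NA_character_,
                           stringsAsFactors = FALSE)
  plant_site <- function(tid, mirna_entity, class, regulated, family) {
    site <- make_site(mirna_entity$mature_seq, class)
    dup <- score_duplex(mirna_entity$mature_seq, site)
    n_mm <- sum(dup$states != "match")
    if (class == "all_pass" && !dup$accepted) {
      stop("generation error: all-pass site rejected", call. = FALSE)
    }
    if (class %in% c("violate_seed", "violate_10_11", "violate_consec",
                     "violate_total")) {
      rule <- c(violate_seed = "r_seed_le1", violate_10_11 = "r_no_mm_10_11",
                violate_consec = "r_consec_le2_after12",
                violate_total = "r_total_le4")[[class]]
      others <- setdiff(names(dup$rule_verdicts), rule)
      if (dup$rule_verdicts[[rule]] || !all(dup$rule_verdicts[others])) {
        stop("generation error: site class ", class,
             " does not violate exactly its rule", call. = FALSE)
      }
    }
    if (class == "distance7" && n_mm <= 6L) {
      stop("generation error: distance7 decoy too close", call. = FALSE)
    }
    L <- nchar(site)
    offset <- sample.int(transcript_len - L, 1L) - 1L
    tr <- transcripts[[tid]]
    substr(tr, offset + 1L, offset + L) <- site
    transcripts[[tid]] <<- tr
    data.frame(mirna_id = mirna_entity$entity_id, transcript_id = tid,
               offset = offset, class = class,
               accepted_expected = class == "all_pass",
               tf_family = family, regulated = regulated,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(de))) {
    ent <- de[i, , drop = FALSE]
    fam <- sample(target_family_pool, 1L)
    # regulated target transcript
    tid <- free[1L]; free <- free[-1L]
    annotation$tf_family[annotation$transcript_id == tid] <- fam
    rows[[length(rows) + 1L]] <- plant_site(tid, ent, "all_pass", TRUE, fam)
    # non-regulated decoy target
    tid <- free[1L]; free <- free[-1L]
    fam2 <- sample(target_family_pool, 1L)
    annotation$tf_family[annotation$transcript_id == tid] <- fam2
    rows[[length(rows) + 1L]] <- plant_site(tid, ent, "all_pass", FALSE,
                                            fam2)
    if (i <= 2L) {
      for (cls in setdiff(TARGET_SITE_CLASSES, "all_pass")) {
        tid <- free[1L]; free <- free[-1L]
        rows[[length(rows) + 1L]] <- plant_site(tid, ent, cls, FALSE,
                                                NA_character_)
      }
    }
  }
  targets <- do.call(rbind, rows)
  manifest$targets <- targets
  manifest$transcript_annotation <- annotation
  list(transcripts = transcripts, transcript_annotation = annotation,
       manifest = manifest)
}

#' Simulate qPCR Ct tables and phenotype trait tables
#'
#' The design is 3 inbred lines (tolerant, mid, sensitive) x 3 treatment
#' durations (1h, 2h, 4h) x 3 replicates. True relative expression for a
#' DE miRNA with fold f ramps over time (f^0.5, f^0.75, f) with a
#' line-specific exponent (tolerant 1, mid 0.6, sensitive -0.8, i.e. the
#' sensitive line responds in the opposite direction). Regulated targets
#' follow the reciprocal profile (exact negative log2 correlation);
#' non-regulated targets are flat. Ct values are reference Ct + offset -
#' log2(rel) + Normal(0, qpcr_noise_sd) per replicate. Trait replicates
#' are control mean x line effect multiplier x lognormal noise, with
#' total dry weight = leaf + root dry weight.
#'
#' @param manifest truth manifest (after targets are planted).
#' @param qpcr_noise_sd replicate Ct noise (default 0.2; 0 = exact).
#' @param trait_noise_sd lognormal sigma for traits (default 0.1).
#' @param seed RNG seed.
#' @return list: `ct_table`, `trait_table`, updated `manifest` (with
#'   `qpcr_truth` and `phenotype_truth`).
#' @export
simulate_expression_tables <- function(manifest, qpcr_noise_sd = 0.2,
                                       trait_noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  lines <- c(tolerant = 1.0, mid = 0.6, sensitive = -0.8)
  times <- c("1h" = 0.5, "2h" = 0.75, "4h" = 1.0)
  ft <- manifest$fold_truth
  de <- ft[ft$fold != 1, , drop = FALSE]
  targets <- manifest$targets
  if (is.null(targets)) stop("targets must be simulated first",
                             call. = FALSE)
  truth_rows <- list()
  add_truth <- function(entity_id, kind, rel_fun) {
    for (ln in names(lines)) for (tm in names(times)) {
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        entity_id = entity_id, kind = kind, line = ln, time = tm,
        rel_expr = rel_fun(lines[[ln]], times[[tm]]),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(de))) {
    f <- de$fold[i]
    add_truth(de$entity_id[i], "miRNA",
              function(s, a) f^(s * a))
  }
  tgt <- targets[targets$accepted_expected, , drop = FALSE]
  for (i in seq_len(nrow(tgt))) {
    f <- ft$fold[match(tgt$mirna_id[i], ft$entity_id)]
    if (tgt$regulated[i]) {
      add_truth(tgt$transcript_id[i], "target",
                function(s, a) f^(-s * a))
    } else {
      add_truth(tgt$transcript_id[i], "target", function(s, a) 1.0)
    }
  }
  qpcr_truth <- do.call(rbind, truth_rows)
  qpcr_truth <- qpcr_truth[!duplicated(
    qpcr_truth[, c("entity_id", "line", "time")]), , drop = FALSE]
  if (any(qpcr_truth$rel_expr <= 0)) {
    stop("non-positive relative expression in truth", call. = FALSE)
  }

  ct_ref <- 15; offset <- 8; n_rep <- 3L
  ct_rows <- list()
  for (i in seq_len(nrow(qpcr_truth))) {
    q <- qpcr_truth[i, ]
    for (cond in c("treated", "control")) {
      mu <- ct_ref + offset -
        if (cond == "treated") log2(q$rel_expr) else 0
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        entity_id = q$entity_id, kind = q$kind, line = q$line,
        time = q$time, condition = cond, replicate = seq_len(n_rep),
        ct = mu + rnorm(n_rep, 0, qpcr_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  # reference (18S-like) rows, constant Ct
  for (ln in names(lines)) for (tm in names(times)) {
    for (cond in c("treated", "control")) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        entity_id = "18S", kind = "reference", line = ln, time = tm,
        condition = cond, replicate = seq_len(n_rep), ct = ct_ref,
        stringsAsFactors = FALSE)
    }
  }
  ct_table <- do.call(rbind, ct_rows)
  rownames(ct_table) <- NULL

  control_means <- c(RL = 12, LL = 20, RW = 1.5, LW = 2.5)
  multipliers <- c(tolerant = 0.9, mid = 0.7, sensitive = 0.45)
  trait_rows <- list()
  for (ln in names(multipliers)) {
    for (rep_ in seq_len(n_rep)) {
      noise_c <- rlnorm(length(control_means), 0, trait_noise_sd)
      noise_t <- rlnorm(length(control_means), 0, trait_noise_sd)
      vals_c <- control_means * noise_c
      vals_t <- control_means * multipliers[[ln]] * noise_t
      for (tr in names(control_means)) {
        trait_rows[[length(trait_rows) + 1L]] <- data.frame(
          line = ln, condition = c("treated", "control"), trait = tr,
          replicate = rep_, value = c(vals_t[[tr]], vals_c[[tr]]),
          stringsAsFactors = FALSE)
      }
      trait_rows[[length(trait_rows) + 1L]] <- data.frame(
        line = ln, condition = c("treated", "control"), trait = "TW",
        replicate = rep_,
        value = c(vals_t[["LW"]] + vals_t[["RW"]],
                  vals_c[["LW"]] + vals_c[["RW"]]),
        stringsAsFactors = FALSE)
    }
  }
  trait_table <- do.call(rbind, trait_rows)
  rownames(trait_table) <- NULL

  # what a real assay design records: each assayed entity and, for
  # miRNAs, the mature sequence its stem-loop primer was built from
  assay_catalog <- rbind(
    data.frame(entity_id = de$entity_id, kind = "miRNA",
               mature_seq = de$mature_seq, stringsAsFactors = FALSE),
    data.frame(entity_id = unique(tgt$transcript_id), kind = "target",
               mature_seq = NA_character_, stringsAsFactors = FALSE))

  manifest$qpcr_truth <- qpcr_truth
  manifest$phenotype_truth <- data.frame(
    line = names(multipliers), multiplier = unname(multipliers),
    stringsAsFactors = FALSE)
  list(ct_table = ct_table, trait_table = trait_table,
       assay_catalog = assay_catalog, manifest = manifest)
}

#' Run the full synthetic study generator
#'
#' Chains [simulate_genome()], [simulate_libraries()],
#' [simulate_transcript_targets()] and [simulate_expression_tables()]
#' under a single master seed (each stage gets a fixed offset of it) and
#' optionally writes every artifact to `dir` in its standard format.
#'
#' @param params generator parameters, see [desk_params()].
#' @param seed master seed.
#' @param dir optional output directory.
#' @param depth_treatment,depth_control library depths.
#' @param noise noise settings for [simulate_libraries()].
#' @param qpcr_noise_sd,trait_noise_sd expression noise settings.
#' @param n_transcripts transcriptome size.
#' @return list bundling all generated data and the final manifest.
#' @export
simulate_study <- function(params = desk_params(), seed = 1L, dir = NULL,
                           depth_treatment = 200000L,
                           depth_control = 200000L, noise = list(),
                           qpcr_noise_sd = 0.2, trait_noise_sd = 0.1,
                           n_transcripts = 100L) {
  gen <- simulate_genome(params, seed = seed)
  lib <- simulate_libraries(gen$manifest,
                            depth_treatment = depth_treatment,
                            depth_control = depth_control,
                            noise = noise, seed = seed + 1000L)
  tx <- simulate_transcript_targets(lib$manifest,
                                    n_transcripts = n_transcripts,
                                    seed = seed + 2000L)
  expr <- simulate_expression_tables(tx$manifest,
                                     qpcr_noise_sd = qpcr_noise_sd,
                                     trait_noise_sd = trait_noise_sd,
                                     seed = seed + 3000L)
  study <- list(genome = gen$genome, tss_table = gen$tss_table,
                repeat_annotation = gen$repeat_annotation,
                known_catalog = gen$known_catalog, ncrnas = gen$ncrnas,
                pwms = gen$pwms,
                reads_treatment = lib$reads_treatment,
                reads_control = lib$reads_control,
                adapter = lib$manifest$library_truth$adapter,
                transcripts = tx$transcripts,
                transcript_annotation = tx$transcript_annotation,
                ct_table = expr$ct_table, trait_table = expr$trait_table,
                assay_catalog = expr$assay_catalog,
                manifest = expr$manifest)
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a simulated study to disk in standard formats
#'
#' FASTA genome/transcripts/catalogs, FASTQ libraries, TSV tables,
#' JASPAR-style PFM text and a JSON truth manifest.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_sequences(study$genome, fp("genome.fasta"))
  write_sequences(study$transcripts, fp("transcripts.fasta"))
  write_sequences(setNames(study$known_catalog$mature_seq,
                           study$known_catalog$locus_id),
                  fp("known_mirnas.fasta"))
  write_sequences(setNames(study$ncrnas$seq, study$ncrnas$id),
                  fp("ncrnas.fasta"))
  write_fastq <- function(reads, path) {
    if (length(reads) == 0L) { file.create(path); return(invisible()) }
    ids <- sprintf("@read%07d", seq_along(reads))
    qual <- strrep("I", nchar(reads))
    writeLines(paste(ids, reads, "+", qual, sep = "\n"), path)
  }
  write_fastq(study$reads_treatment, fp("treatment.fastq"))
  write_fastq(study$reads_control, fp("control.fastq"))
  write_tsv_table(study$tss_table, fp("tss.tsv"))
  write_tsv_table(study$repeat_annotation, fp("repeats.tsv"))
  write_tsv_table(study$known_catalog, fp("known_catalog.tsv"))
  write_tsv_table(study$transcript_annotation,
                  fp("transcript_annotation.tsv"))
  write_tsv_table(study$ct_table, fp("ct_table.tsv"))
  write_tsv_table(study$trait_table, fp("trait_table.tsv"))
  pfm_lines <- unlist(lapply(study$pwms, function(p) {
    c(paste0(">", p$motif_id, " ", p$tf_name),
      vapply(c("A", "C", "G", "T"), function(b)
        paste0(b, " [ ", paste(p$matrix[b, ], collapse = " "), " ]"),
        character(1L)))
  }))
  writeLines(pfm_lines, fp("pwms.pfm"))
  write_manifest(study$manifest, fp("truth_manifest.json"))
  invisible(dir)
}

#' Write / read the truth manifest
#'
#' JSON serialization of the manifest; data frames are stored by column
#' so a round trip restores identical content.
#'
#' @param manifest truth manifest list.
#' @param path JSON file path.
#' @return `read_manifest` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  json <- jsonlite::toJSON(manifest, dataframe = "columns", digits = NA,
                           auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("contigs", "known_catalog", "hairpins", "repeat_annotation",
               "ncrnas", "tss_table", "pwm_meta", "planted_motifs",
               "fold_truth", "targets", "transcript_annotation",
               "qpcr_truth", "phenotype_truth")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.data.frame(raw[[nm]])
  }
  if (!is.null(raw$library_truth$counts)) {
    raw$library_truth$counts <- as.data.frame(raw$library_truth$counts)
  }
  raw
}
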