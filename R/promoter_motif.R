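#' Extract a promoter window around a pri-miRNA TSS
#'
#' Plus strand: `[tss - up, tss + down)`; minus strand: the mirrored
#' interval `[tss - down, tss + up)` reverse-complemented, so the returned
#' sequence always reads 5'->3' relative to transcription. Intervals are
#' clipped at contig edges and flagged.
#'
#' @param genome named character vector of contigs.
#' @param tss_record list/one-row data.frame with `chrom`, `tss_pos`
#'   (0-based), `strand`, `gene_id`.
#' @param up,down window extents in nt (defaults 1000 and 500).
#' @return list: `gene_id`, `chrom`, `tss`, `strand`, `seq`, `clipped`.
#' @export
extract_promoter <- function(genome, tss_record, up = 1000L, down = 500L) {
  chrom_seq <- unname(genome[tss_record$chrom])
  if (length(chrom_seq) != 1L || is.na(chrom_seq)) {
    stop("unknown chromosome: ", tss_record$chrom, call. = FALSE)
  }
  clen <- nchar(chrom_seq)
  tss <- as.integer(tss_record$tss_pos)
  if (tss < 0L || tss > clen) stop("TSS outside chromosome", call. = FALSE)
  if (tss_record$strand == "+") {
    ws <- tss - up; we <- tss + down
  } else {
    ws <- tss - down; we <- tss + up
  }
  clipped <- ws < 0L || we > clen
  ws <- max(ws, 0L); we <- min(we, clen)
  seq <- substr(chrom_seq, ws + 1L, we)
  if (tss_record$strand == "-") seq <- revcomp(seq)
  list(gene_id = tss_record$gene_id, chrom = tss_record$chrom, tss = tss,
       strand = tss_record$strand, seq = seq, clipped = clipped)
}

#' Extract promoters for a whole TSS table
#'
#' @param genome named character vector of contigs.
#' @param tss_table data.frame as from [read_tss()].
#' @param up,down window extents.
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `tss`,
#'   `strand`, `seq`, `clipped`.
#' @export
extract_promoters <- function(genome, tss_table, up = 1000L, down = 500L) {
  rows <- lapply(seq_len(nrow(tss_table)), function(i) {
    p <- extract_promoter(genome, tss_table[i, , drop = FALSE], up, down)
    data.frame(gene_id = p$gene_id, chrom = p$chrom, tss = p$tss,
               strand = p$strand, seq = p$seq, clipped = p$clipped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pwm_log_odds <- function(pwm, background_freqs, pseudocount = 0.1) {
  probs <- normalize_pwm(pwm, pseudocount = pseudocount)
  log2(probs / background_freqs)
}

#' Scan a promoter with a PWM on both strands
#'
#' Standard log-odds scanning: at every offset the score is
#' `sum log2(p_base,i / q_base)`; a hit requires score at or above
#' `score_threshold_frac` times the PWM's maximum attainable score.
#' Overlapping hits are allowed; N positions contribute 0 (background).
#'
#' @param promoter a single promoter sequence, or a named character vector
#'   of promoters.
#' @param pwm `hypoxamir_pwm` object.
#' @param background_freqs length-4 numeric (A, C, G, T), summing to 1.
#' @param score_threshold_frac fraction of the maximum log-odds score
#'   (default 0.8).
#' @param pseudocount PWM pseudocount per cell (default 0.1).
#' @return data.frame of hits: `motif_id`, `gene_id`, `offset` (0-based,
#'   forward-strand coordinates of the hit's left edge), `strand`,
#'   `score`.
#' @export
scan_pwm <- function(promoter, pwm, background_freqs = rep(0.25, 4),
                     score_threshold_frac = 0.8, pseudocount = 0.1) {
  stopifnot(abs(sum(background_freqs) - 1) < 1e-6)
  lods <- pwm_log_odds(pwm, background_freqs, pseudocount)
  max_score <- sum(apply(lods, 2L, max))
  threshold <- score_threshold_frac * max_score
  L <- ncol(lods)
  ids <- names(promoter) %||% rep(NA_character_, length(promoter))
  rows <- list()
  for (i in seq_along(promoter)) {
    seq <- normalize_seq(promoter[[i]], "promoter")
    plen <- nchar(seq)
    if (plen < L) next
    fwd_int <- seq_to_int(seq)
    rev_int <- seq_to_int(revcomp(seq))
    for (strand in c("+", "-")) {
      sc <- .pwm_score_cpp(if (strand == "+") fwd_int else rev_int, lods)
      hit <- which(sc >= threshold)
      if (length(hit) == 0L) next
      offset <- if (strand == "+") hit - 1L else plen - L - (hit - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = pwm$motif_id, gene_id = ids[i], offset = offset,
        strand = strand, score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif_id = character(0), gene_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif over-representation in promoters versus background
#'
#' For each PWM the per-position background hit rate is estimated from the
#' background promoter set (both strands); the raw p-value is the
#' upper-tail binomial probability of at least the observed foreground hit
#' total in the foreground's scanned positions at that rate. Bonferroni
#' multiplies by `n_motifs_tested`. A motif is selected iff the corrected
#' p-value is below `p_max` and at least `min_promoters_ge3` promoters
#' carry `min_occ` or more occurrences.
#'
#' @param promoters named character vector of foreground promoters.
#' @param pwms list of `hypoxamir_pwm` objects.
#' @param background_promoters character vector of length-matched
#'   background sequences (e.g. sampled uniformly from the genome).
#' @param n_motifs_tested Bonferroni multiplier (default: number of PWMs).
#' @param p_max corrected p-value threshold (default 0.001).
#' @param min_occ per-promoter occurrence threshold (default 3).
#' @param min_promoters_ge3 number of promoters that must reach `min_occ`
#'   (default 1).
#' @param background_freqs,score_threshold_frac,pseudocount scanning
#'   parameters, see [scan_pwm()].
#' @return data.frame with one row per motif: hit counts, `promoters_ge3`,
#'   `background_rate`, `rate_floored`, `p_raw`, `p_bonferroni`,
#'   `selected`; per-promoter counts in `attr(, "per_promoter")`.
#' @export
motif_enrichment <- function(promoters, pwms, background_promoters,
                             n_motifs_tested = length(pwms),
                             p_max = 0.001, min_occ = 3L,
                             min_promoters_ge3 = 1L,
                             background_freqs = rep(0.25, 4),
                             score_threshold_frac = 0.8,
                             pseudocount = 0.1) {
  if (n_motifs_tested < length(pwms)) {
    stop("n_motifs_tested must be at least the number of PWMs",
         call. = FALSE)
  }
  if (is.null(names(promoters))) {
    names(promoters) <- paste0("promoter_", seq_along(promoters))
  }
  per_prom <- list()
  rows <- lapply(pwms, function(pwm) {
    L <- ncol(pwm$matrix)
    fg <- scan_pwm(promoters, pwm, background_freqs,
                   score_threshold_frac, pseudocount)
    bg <- scan_pwm(setNames(background_promoters,
                            seq_along(background_promoters)),
                   pwm, background_freqs, score_threshold_frac, pseudocount)
    fg_pos <- sum(pmax(nchar(promoters) - L + 1L, 0L)) * 2L
    bg_pos <- sum(pmax(nchar(background_promoters) - L + 1L, 0L)) * 2L
    if (bg_pos == 0L) stop("background promoters shorter than the motif",
                           call. = FALSE)
    floored <- nrow(bg) == 0L
    rate <- if (floored) 0.5 / bg_pos else nrow(bg) / bg_pos
    observed <- nrow(fg)
    counts <- table(factor(fg$gene_id, levels = names(promoters)))
    per_prom[[pwm$motif_id]] <<- as.integer(counts)
    p_raw <- pbinom(observed - 1L, fg_pos, rate, lower.tail = FALSE)
    p_bonf <- min(1, p_raw * n_motifs_tested)
    data.frame(motif_id = pwm$motif_id, tf_name = pwm$tf_name,
               tf_family = pwm$tf_family, observed_hits = observed,
               promoters_ge3 = sum(counts >= min_occ),
               background_hits = nrow(bg), background_rate = rate,
               rate_floored = floored, p_raw = p_raw,
               p_bonferroni = p_bonf,
               selected = p_bonf < p_max &&
                 sum(counts >= min_occ) >= min_promoters_ge3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pp <- do.call(rbind, per_prom)
  if (!is.null(pp)) colnames(pp) <- names(promoters)
  attr(out, "per_promoter") <- pp
  out
}
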