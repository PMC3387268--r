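# shared fixtures and independent oracles

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reduced-size generator parameters for unit tests
small_params <- function(...) {
  base <- list(contig_lengths = c(chr1 = 30000L, chr2 = 30000L),
               n_known = 6L, n_multi_locus = 1L, n_de_known = 4L,
               n_hairpins = 2L, n_repeats = 2L, n_ncrnas = 3L,
               n_pwms = 6L, n_pwms_planted = 3L)
  do.call(desk_params, modifyList(base, list(...)))
}

small_study <- function(seed = 7L, ...) {
  simulate_study(params = small_params(), seed = seed,
                 depth_treatment = 20000L, depth_control = 20000L,
                 n_transcripts = 30L, ...)
}

# brute-force duplex scan: score every window of every transcript with
# score_duplex, no candidate pre-filter (independent of the scanner's
# Hamming short cut)
brute_force_scan <- function(mirna, transcripts, max_mm = 6L) {
  L <- nchar(mirna)
  rows <- list()
  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    if (nchar(tx) < L) next
    for (s in seq_len(nchar(tx) - L + 1L)) {
      win <- substr(tx, s, s + L - 1L)
      mm <- sum(strsplit(win, "")[[1L]] !=
                  strsplit(revcomp(mirna), "")[[1L]])
      if (mm > max_mm) next
      dup <- score_duplex(mirna, win)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid, site_start = s - 1L, n_mismatch = mm,
        score = dup$score, accepted = dup$accepted,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(target_id = character(0), site_start = integer(0),
                      n_mismatch = integer(0), score = numeric(0),
                      accepted = logical(0)))
  }
  out[order(out$target_id, out$site_start), , drop = FALSE]
}

# brute-force per-offset log-odds scoring of one strand, plain R
brute_force_pwm_scores <- function(seq, pwm, bg = rep(0.25, 4),
                                   pseudocount = 0.1) {
  probs <- normalize_pwm(pwm, pseudocount)
  lods <- log2(probs / bg)
  ch <- strsplit(seq, "")[[1L]]
  L <- ncol(lods)
  n <- length(ch) - L + 1L
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n), function(o) {
    sum(vapply(seq_len(L), function(k) {
      b <- ch[o + k - 1L]
      if (b %in% rownames(lods)) lods[b, k] else 0
    }, numeric(1L)))
  }, numeric(1L))
}

# chunk-permutation dinucleotide shuffle (preserves dinucleotide content)
dinuc_shuffle <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  pairs <- split(ch, ceiling(seq_along(ch) / 2))
  paste(unlist(pairs[sample(length(pairs))]), collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
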