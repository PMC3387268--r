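#' Score a miRNA:target duplex with positional mismatch rules
#'
#' The target site (sense strand, same length as the miRNA) is compared
#' against the reverse complement of the miRNA. Position i is counted
#' 1-based from the miRNA 5' end; it is a `match` if the bases are
#' Watson-Crick complementary, a `wobble` if they form a G:U pair, and a
#' `mismatch` otherwise. A match scores 0; wobbles and mismatches score
#' `wobble_score` and 1 respectively (default: wobbles count as full
#' mismatches; set `wobble_score = 0.5` for the softer convention).
#'
#' Acceptance rules on the per-position scores:
#' * `r_seed_le1` - summed score over positions 2..12 at most 1;
#' * `r_no_mm_10_11` - zero score at positions 10 and 11;
#' * `r_consec_le2_after12` - no run of 3+ consecutive scored positions
#'   lying wholly after position 12;
#' * `r_total_le4` - total score at most 4.
#'
#' @param mirna_seq mature miRNA, 5'->3'.
#' @param site_seq target transcript window, 5'->3'.
#' @param wobble_score score assigned to a G:U pair (default 1).
#' @param mirna_id,target_id,site_start optional bookkeeping fields.
#' @return a `duplex_alignment` list: `states`, `position_scores`,
#'   `score`, `rule_verdicts`, `accepted`, plus coordinates when given.
#' @export
score_duplex <- function(mirna_seq, site_seq, wobble_score = 1,
                         mirna_id = NA_character_,
                         target_id = NA_character_,
                         site_start = NA_integer_) {
  if (grepl("-", mirna_seq, fixed = TRUE) ||
      grepl("-", site_seq, fixed = TRUE)) {
    stop("gapped duplexes are not supported", call. = FALSE)
  }
  m <- strsplit(normalize_seq(mirna_seq, "miRNA"), "")[[1L]]
  t_ <- strsplit(normalize_seq(site_seq, "site"), "")[[1L]]
  L <- length(m)
  if (length(t_) != L) {
    stop("site length (", length(t_), ") must equal miRNA length (", L, ")",
         call. = FALSE)
  }
  # miRNA position i pairs the site base at index L + 1 - i
  tb <- t_[L:1L]
  wc <- (m == "A" & tb == "T") | (m == "T" & tb == "A") |
        (m == "G" & tb == "C") | (m == "C" & tb == "G")
  wob <- (m == "G" & tb == "T") | (m == "T" & tb == "G")
  states <- ifelse(wc, "match", ifelse(wob, "wobble", "mismatch"))
  scores <- ifelse(wc, 0, ifelse(wob, wobble_score, 1))

  seed_idx <- 2:min(12L, L)
  r_seed <- sum(scores[seed_idx]) <= 1
  r_1011 <- if (L >= 11L) sum(scores[c(10L, 11L)]) == 0 else TRUE
  r_total <- sum(scores) <= 4

  r_consec <- TRUE
  run <- rle(scores > 0)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  bad <- run$values & run$lengths >= 3L & starts > 12L
  if (any(bad)) r_consec <- FALSE

  verdicts <- c(r_seed_le1 = r_seed, r_no_mm_10_11 = r_1011,
                r_consec_le2_after12 = r_consec, r_total_le4 = r_total)
  structure(list(
    mirna_id = mirna_id, mirna_seq = paste(m, collapse = ""),
    target_id = target_id,
    site_start = site_start,
    site_end = if (is.na(site_start)) NA_integer_ else site_start + L,
    states = states, position_scores = scores, score = sum(scores),
    rule_verdicts = verdicts, accepted = all(verdicts)),
    class = "duplex_alignment")
}

#' Scan transcripts for candidate miRNA target sites
#'
#' Every window with Hamming distance at most `candidate_max_mm` to the
#' reverse-complemented miRNA is scored with [score_duplex()]; all
#' candidates are returned with their rule verdicts, the accepted subset
#' flagged. Transcripts shorter than the miRNA are skipped.
#'
#' @param mirna_seq mature miRNA sequence.
#' @param transcripts named character vector of sense-strand transcript
#'   sequences.
#' @param candidate_max_mm Hamming pre-filter radius (default 6).
#' @param wobble_score passed to [score_duplex()].
#' @param mirna_id label for the output.
#' @return data.frame sorted by (`target_id`, `site_start`): coordinates
#'   (0-based half-open), `n_mismatch` (Hamming), `score`, the four rule
#'   verdict columns and `accepted`.
#' @export
scan_transcriptome <- function(mirna_seq, transcripts,
                               candidate_max_mm = 6L, wobble_score = 1,
                               mirna_id = "miRNA") {
  if (is.null(names(transcripts))) {
    stop("transcripts must be named", call. = FALSE)
  }
  mirna <- normalize_seq(mirna_seq, "miRNA")
  rc <- revcomp(mirna)
  rc_int <- seq_to_int(rc)
  L <- nchar(mirna)
  rows <- list()
  for (tid in names(transcripts)) {
    tseq <- normalize_seq(transcripts[[tid]], "transcript")
    if (nchar(tseq) < L) next
    d <- .hamming_scan_cpp(seq_to_int(tseq), rc_int)
    offs <- which(d <= candidate_max_mm) # 1-based offsets
    for (o in offs) {
      site <- substr(tseq, o, o + L - 1L)
      dup <- score_duplex(mirna, site, wobble_score = wobble_score,
                          mirna_id = mirna_id, target_id = tid,
                          site_start = o - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirna_id, target_id = tid,
        site_start = o - 1L, site_end = o - 1L + L,
        site_seq = site, n_mismatch = d[o], score = dup$score,
        r_seed_le1 = dup$rule_verdicts[["r_seed_le1"]],
        r_no_mm_10_11 = dup$rule_verdicts[["r_no_mm_10_11"]],
        r_consec_le2_after12 = dup$rule_verdicts[["r_consec_le2_after12"]],
        r_total_le4 = dup$rule_verdicts[["r_total_le4"]],
        accepted = dup$accepted, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      site_seq = character(0), n_mismatch = integer(0),
                      score = numeric(0), r_seed_le1 = logical(0),
                      r_no_mm_10_11 = logical(0),
                      r_consec_le2_after12 = logical(0),
                      r_total_le4 = logical(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$target_id, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify RACE cleavage clones around a predicted target site
#'
#' Counts cloned 5' ends within a `window`-nt window centered on the
#' complementary site, and those exactly at the canonical slicing
#' position, i.e. the transcript coordinate pairing miRNA position 10
#' (cleavage falls between positions 10 and 11).
#'
#' @param site one-row data.frame or list with `site_start`, `site_end`
#'   (0-based half-open transcript coordinates).
#' @param clone_positions integer transcript coordinates of cloned 5'
#'   ends.
#' @param window window width in nt (default 100).
#' @return list: `n_clones`, `n_in_window`, `n_canonical`,
#'   `canonical_position`, `window_start`, `window_end`.
#' @export
classify_cleavage <- function(site, clone_positions, window = 100L) {
  start <- site$site_start; end <- site$site_end
  L <- end - start
  center <- (start + end) / 2
  w0 <- center - window / 2; w1 <- center + window / 2
  in_window <- clone_positions >= w0 & clone_positions < w1
  canonical <- start + L - 10L
  list(n_clones = length(clone_positions),
       n_in_window = sum(in_window),
       n_canonical = sum(clone_positions == canonical),
       canonical_position = canonical,
       window_start = w0, window_end = w1)
}
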