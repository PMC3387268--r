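#' Trim the 3' adapter from small-RNA reads
#'
#' Exact prefix search: the first occurrence of the adapter's first
#' `min_overlap` bases marks the insert/adapter boundary and everything
#' from it onward is removed. A read whose adapter starts at position 1 is
#' adapter-only; a read with no occurrence is returned untrimmed (its full
#' sequence is kept so that it falls into the size filter downstream).
#'
#' @param reads character vector of raw read sequences.
#' @param adapter3 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length that must match
#'   (default 6).
#' @return data.frame with columns `read`, `insert`, `status`
#'   (`"trimmed"`, `"adapter_only"`, `"untrimmed"`).
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 6L) {
  if (length(adapter3) != 1L || nchar(adapter3) == 0L) {
    stop("adapter must be a single non-empty sequence", call. = FALSE)
  }
  if (min_overlap < 1L || min_overlap > nchar(adapter3)) {
    stop("min_overlap must be in [1, nchar(adapter)]", call. = FALSE)
  }
  reads <- toupper(as.character(reads))
  if (any(nchar(reads) == 0L)) stop("empty read sequence", call. = FALSE)
  prefix <- toupper(substr(adapter3, 1L, min_overlap))
  pos <- regexpr(prefix, reads, fixed = TRUE)
  status <- ifelse(pos == 1L, "adapter_only",
                   ifelse(pos > 1L, "trimmed", "untrimmed"))
  insert <- ifelse(pos >= 1L, substr(reads, 1L, pmax(pos - 1L, 0L)), reads)
  data.frame(read = reads, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

count_classify_inserts <- function(inserts, library_id,
                                   min_len = 18L, max_len = 26L) {
  n <- length(inserts)
  len <- nchar(inserts)
  adapter_only <- inserts == ""
  has_n <- !adapter_only & grepl("N", inserts, fixed = TRUE)
  too_short <- !adapter_only & !has_n & len < min_len
  too_long <- !adapter_only & !has_n & len > max_len
  keep <- !adapter_only & !has_n & !too_short & !too_long
  hist_counts <- table(factor(len[keep], levels = min_len:max_len))
  filtered <- sum(keep)
  frac_20_24 <- if (filtered > 0L) {
    sum(len[keep] >= 20L & len[keep] <= 24L) / filtered
  } else NA_real_
  list(keep = keep,
       stats = list(library_id = library_id,
                    total_reads = n,
                    adapter_only = sum(adapter_only),
                    with_n = sum(has_n),
                    too_short = sum(too_short),
                    too_long = sum(too_long),
                    filtered_reads = filtered,
                    size_histogram = as.integer(hist_counts),
                    size_histogram_lengths = min_len:max_len,
                    frac_20_24 = frac_20_24))
}

#' Collapse trimmed inserts into unique tags with per-library counts
#'
#' Inserts shorter than `min_len` or longer than `max_len` are excluded and
#' counted (`too_short`/`too_long`; untrimmed full-length reads fall into
#' `too_long`); empty inserts are adapter-only; inserts containing N are
#' discarded and counted separately. Survivors are deduplicated by exact
#' sequence (U normalized to T). RPM uses each library's filtered read
#' total as denominator.
#'
#' @param inserts_treatment,inserts_control character vectors of trimmed
#'   inserts (the `insert` column of [trim_adapter()] output).
#' @param min_len,max_len insert size bounds, defaults 18 and 26 nt.
#' @return list with `tags` (data.frame: `seq`, `count_treatment`,
#'   `count_control`, `rpm_treatment`, `rpm_control`) and `stats` (list of
#'   two per-library summaries). The tag table carries the library totals
#'   in `attr(, "library_totals")`.
#' @export
collapse_tags <- function(inserts_treatment, inserts_control,
                          min_len = 18L, max_len = 26L) {
  up_t <- toupper(inserts_treatment)
  up_c <- toupper(inserts_control)
  trt <- count_classify_inserts(up_t, "treatment", min_len, max_len)
  ctl <- count_classify_inserts(up_c, "control", min_len, max_len)
  s_trt <- chartr("U", "T", up_t[trt$keep])
  s_ctl <- chartr("U", "T", up_c[ctl$keep])
  seqs <- sort(unique(c(s_trt, s_ctl)))
  ct_t <- table(factor(s_trt, levels = seqs))
  ct_c <- table(factor(s_ctl, levels = seqs))
  tot_t <- trt$stats$filtered_reads
  tot_c <- ctl$stats$filtered_reads
  tags <- data.frame(
    seq = seqs,
    count_treatment = as.integer(ct_t),
    count_control = as.integer(ct_c),
    rpm_treatment = if (tot_t > 0) as.integer(ct_t) / tot_t * 1e6 else 0,
    rpm_control = if (tot_c > 0) as.integer(ct_c) / tot_c * 1e6 else 0,
    stringsAsFactors = FALSE)
  attr(tags, "library_totals") <- c(treatment = tot_t, control = tot_c)
  list(tags = tags, stats = list(treatment = trt$stats, control = ctl$stats))
}

#' Library statistics as a one-row-per-library table
#'
#' @param stats the `stats` element returned by [collapse_tags()].
#' @param tags optionally the tag table, to fill `unique_tags`.
#' @return data.frame mirroring a sequencing summary table.
#' @export
library_stats_table <- function(stats, tags = NULL) {
  rows <- lapply(stats, function(s) {
    data.frame(library_id = s$library_id, total_reads = s$total_reads,
               reads_with_n = s$with_n, adapter_only = s$adapter_only,
               too_short = s$too_short, too_long = s$too_long,
               filtered_reads = s$filtered_reads,
               frac_20_24 = s$frac_20_24, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(tags)) {
    out$unique_tags <- c(sum(tags$count_treatment > 0L),
                         sum(tags$count_control > 0L))[
                           match(out$library_id, c("treatment", "control"))]
  }
  out
}

#' Pearson chi-square test on two library counts
#'
#' Tests whether a tag's frequency differs between two libraries using the
#' 2x2 contingency table `{count_a, total_a - count_a; count_b,
#' total_b - count_b}` (df = 1, no continuity correction by default). The
#' result is flagged when any expected cell is below 1; the statistic is
#' still computed.
#'
#' @param count_a,count_b per-library counts (vectorized).
#' @param total_a,total_b library totals.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return data.frame with `chi2`, `p_value`, `low_expectation`.
#' @export
chi_square_de <- function(count_a, total_a, count_b, total_b,
                          correct = FALSE) {
  if (any(total_a <= 0) || any(total_b <= 0)) {
    stop("library totals must be positive", call. = FALSE)
  }
  if (any(count_a > total_a) || any(count_b > total_b) ||
      any(count_a < 0) || any(count_b < 0)) {
    stop("counts must satisfy 0 <= count <= total", call. = FALSE)
  }
  a <- as.numeric(count_a); b <- as.numeric(total_a) - a
  c_ <- as.numeric(count_b); d <- as.numeric(total_b) - c_
  n <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(num - n / 2, 0)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom == 0, 0, n * num^2 / denom)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  # expected cells under the margins
  e_min <- pmin((a + b) * (a + c_), (a + b) * (b + d),
                (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n
  data.frame(chi2 = chi2, p_value = p,
             low_expectation = denom == 0 | e_min < 1)
}

fold_change_rpm <- function(count_t, count_c, total_t, total_c,
                            pseudocount = 0.5) {
  # pseudocount on the count scale, used for the fold only
  rt <- (count_t + pseudocount) / total_t * 1e6
  rc <- (count_c + pseudocount) / total_c * 1e6
  rt / rc
}

#' Quantify known mature miRNA signatures from collapsed tags
#'
#' A tag contributes to a signature iff its sequence is identical to the
#' catalog mature sequence (T/U-insensitive). Catalog entries with the same
#' mature sequence (different loci) are merged into one signature listing
#' all loci. Signatures with zero reads in both libraries are omitted.
#'
#' @param tags tag table from [collapse_tags()].
#' @param mature_catalog data.frame with one row per locus: columns
#'   `signature_id`, `mature_seq`, `locus_id`.
#' @param library_totals named numeric `c(treatment=, control=)`; defaults
#'   to the totals attached to `tags`.
#' @return data.frame of signature expression: ids, loci, counts, RPM,
#'   fold change (pseudocount-protected), chi-square statistic, p-value.
#' @export
quantify_known <- function(tags, mature_catalog, library_totals = NULL) {
  library_totals <- library_totals %||% attr(tags, "library_totals")
  if (is.null(library_totals)) {
    stop("library totals are required for RPM and chi-square", call. = FALSE)
  }
  cat_seq <- normalize_seq(mature_catalog$mature_seq, "catalog sequence")
  # a signature_id must map to a single sequence
  by_id <- split(cat_seq, mature_catalog$signature_id)
  dup <- names(by_id)[vapply(by_id, function(x) length(unique(x)) > 1L,
                             logical(1L))]
  if (length(dup) > 0L) {
    stop("catalog error: signature '", dup[1L],
         "' maps to multiple mature sequences", call. = FALSE)
  }
  # merge identical sequences into one signature
  groups <- split(seq_len(nrow(mature_catalog)), cat_seq)
  sig <- lapply(names(groups), function(s) {
    idx <- groups[[s]]
    ids <- sort(unique(mature_catalog$signature_id[idx]))
    list(signature_id = paste(ids, collapse = "/"),
         mature_seq = s,
         locus_ids = paste(sort(unique(mature_catalog$locus_id[idx])),
                           collapse = ","))
  })
  hit <- match(vapply(sig, `[[`, "", "mature_seq"), tags$seq)
  keep <- !is.na(hit)
  sig <- sig[keep]; hit <- hit[keep]
  if (length(sig) == 0L) {
    return(data.frame(signature_id = character(0), mature_seq = character(0),
                      locus_ids = character(0), count_treatment = integer(0),
                      count_control = integer(0), rpm_treatment = numeric(0),
                      rpm_control = numeric(0), fold_change = numeric(0),
                      chi2 = numeric(0), p_value = numeric(0),
                      low_expectation = logical(0),
                      stringsAsFactors = FALSE))
  }
  ct <- tags$count_treatment[hit]
  cc <- tags$count_control[hit]
  nonzero <- (ct + cc) >= 1L
  sig <- sig[nonzero]; ct <- ct[nonzero]; cc <- cc[nonzero]
  tt <- library_totals[["treatment"]]
  tc <- library_totals[["control"]]
  test <- chi_square_de(ct, tt, cc, tc)
  out <- data.frame(
    signature_id = vapply(sig, `[[`, "", "signature_id"),
    mature_seq = vapply(sig, `[[`, "", "mature_seq"),
    locus_ids = vapply(sig, `[[`, "", "locus_ids"),
    count_treatment = ct, count_control = cc,
    rpm_treatment = ct / tt * 1e6, rpm_control = cc / tc * 1e6,
    fold_change = fold_change_rpm(ct, cc, tt, tc),
    chi2 = test$chi2, p_value = test$p_value,
    low_expectation = test$low_expectation,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$signature_id), , drop = FALSE]
}

#' Differential-expression filter on signature expression
#'
#' A signature passes iff p < `p_max`, the RPM fold change is at least
#' `fold_min` in either direction (>= fold_min or <= 1/fold_min), and the
#' larger of the two library RPM values exceeds `rpm_min`.
#'
#' @param signatures output of [quantify_known()].
#' @param p_max chi-square p-value ceiling (default 0.01).
#' @param fold_min symmetric fold-change threshold (default 1.5).
#' @param rpm_min abundance floor on `max(rpm_treatment, rpm_control)`
#'   (default 50).
#' @return the input with a `passes_filter` column, subset to the passing
#'   rows, sorted by |log2 fold change| descending.
#' @export
de_filter <- function(signatures, p_max = 0.01, fold_min = 1.5,
                      rpm_min = 50) {
  if (nrow(signatures) == 0L) {
    signatures$passes_filter <- logical(0)
    return(signatures)
  }
  fc <- signatures$fold_change
  pass <- (signatures$p_value < p_max) &
    (fc >= fold_min | fc <= 1 / fold_min) &
    (pmax(signatures$rpm_treatment, signatures$rpm_control) > rpm_min)
  signatures$passes_filter <- pass
  out <- signatures[pass, , drop = FALSE]
  out[order(abs(log2(out$fold_change)), decreasing = TRUE), , drop = FALSE]
}
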