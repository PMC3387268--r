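#' Waterlogging tolerance coefficient
#'
#' WTC = mean of the treated replicate values divided by the mean of the
#' control replicate values, computed per trait.
#'
#' @param treated,control numeric replicate vectors for the same line and
#'   trait.
#' @return scalar WTC.
#' @export
compute_wtc <- function(treated, control) {
  if (length(control) == 0L || mean(control) <= 0) {
    stop("control mean must be positive", call. = FALSE)
  }
  mean(treated) / mean(control)
}

#' WTC table from a long trait table
#'
#' @param trait_table data.frame with columns `line`, `condition`
#'   (`"treated"`/`"control"`), `trait`, `value` (one row per replicate).
#' @return data.frame with one row per (line, trait) and its WTC.
#' @export
wtc_table <- function(trait_table) {
  need <- c("line", "condition", "trait", "value")
  stopifnot(all(need %in% names(trait_table)))
  combos <- unique(trait_table[, c("line", "trait")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- trait_table$line == combos$line[i] &
      trait_table$trait == combos$trait[i]
    tr <- trait_table$value[sel & trait_table$condition == "treated"]
    ct <- trait_table$value[sel & trait_table$condition == "control"]
    data.frame(line = combos$line[i], trait = combos$trait[i],
               wtc = compute_wtc(tr, ct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the invariant 44-nt selfed stem-loop body of the RT primer
STEMLOOP_BODY <- "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGAC"

#' Stem-loop RT primer for a mature miRNA
#'
#' The primer is the constant 44-nt selfed stem-loop body extended at its
#' 3' end by six nucleotides complementary (DNA) to the last six
#' nucleotides of the mature miRNA's 3' end. miRNAs sharing their last six
#' nucleotides yield identical primers; a warning reports such collisions.
#'
#' @param mature_seq character vector of mature miRNA sequences (RNA or
#'   DNA alphabet), each at least 6 nt.
#' @return character vector of 50-nt primer sequences (DNA).
#' @export
stemloop_primer <- function(mature_seq) {
  mature <- normalize_seq(mature_seq, "mature miRNA")
  if (any(nchar(mature) < 6L)) {
    stop("mature miRNA must be at least 6 nt", call. = FALSE)
  }
  last6 <- substr(mature, nchar(mature) - 5L, nchar(mature))
  ext <- revcomp(last6)
  if (anyDuplicated(ext) && length(unique(mature)) > 1L) {
    warning("identical primers for miRNAs sharing their 3'-terminal 6 nt",
            call. = FALSE)
  }
  paste0(STEMLOOP_BODY, ext)
}

#' Relative expression by the comparative (delta-delta-Ct) method
#'
#' Replicate Ct values are averaged before differencing;
#' `rel = 2^-((Ct_target,trt - Ct_ref,trt) - (Ct_target,ctl -
#' Ct_ref,ctl))`. Expression is normalized to the reference (18S-like)
#' transcript.
#'
#' @param ct_target_trt,ct_ref_trt,ct_target_ctl,ct_ref_ctl numeric Ct
#'   replicate vectors.
#' @return scalar relative expression (treatment/control).
#' @export
relative_expression <- function(ct_target_trt, ct_ref_trt,
                                ct_target_ctl, ct_ref_ctl) {
  vals <- c(ct_target_trt, ct_ref_trt, ct_target_ctl, ct_ref_ctl)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (mean(ct_target_trt) - mean(ct_ref_trt)) -
    (mean(ct_target_ctl) - mean(ct_ref_ctl))
  2^(-ddct)
}

#' Hierarchical clustering of log2 expression-ratio profiles
#'
#' Agglomerative clustering with Euclidean distance and average linkage;
#' the tree is cut into `k` groups and a heatmap-ready row order is
#' returned. Ties in the distance matrix are resolved deterministically by
#' row index (the behaviour of [stats::hclust()]).
#'
#' @param log2_matrix numeric matrix, rows = entities, columns = line x
#'   time log2(treatment/control) ratios. Missing values are an error.
#' @param k number of clusters (default 4).
#' @return list: `tree` (hclust), `labels` (named cluster assignment),
#'   `order` (row indices in dendrogram order).
#' @export
cluster_profiles <- function(log2_matrix, k = 4L) {
  log2_matrix <- as.matrix(log2_matrix)
  if (anyNA(log2_matrix)) {
    idx <- which(is.na(log2_matrix), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", rownames(log2_matrix)[idx[1L]] %||%
           idx[1L], ", column ", idx[2L], call. = FALSE)
  }
  if (k > nrow(log2_matrix)) stop("k exceeds the number of rows",
                                  call. = FALSE)
  tree <- hclust(dist(log2_matrix, method = "euclidean"),
                 method = "average")
  labels <- cutree(tree, k = k)
  list(tree = tree, labels = labels, order = tree$order)
}

#' Negative-correlation call between a miRNA and a candidate target
#'
#' Per inbred line, the Pearson correlation of log2 expression ratios over
#' the time points is computed; the pair is called negatively correlated
#' iff r < 0 in every line. A line with zero variance in either profile
#' has an undefined correlation: the call is FALSE and the line flagged.
#'
#' @param mirna_profile,target_profile numeric matrices with identical
#'   dimnames: rows = lines, columns = time points, values = log2 ratios.
#' @return list: `call` (logical), `r_by_line` (named numeric, NA where
#'   undefined), `flagged_lines`.
#' @export
call_negative_correlation <- function(mirna_profile, target_profile) {
  m <- as.matrix(mirna_profile); t_ <- as.matrix(target_profile)
  if (!identical(dim(m), dim(t_))) {
    stop("profiles must share the line x time design", call. = FALSE)
  }
  lines <- rownames(m) %||% paste0("line_", seq_len(nrow(m)))
  r <- vapply(seq_len(nrow(m)), function(i) {
    if (stats::sd(m[i, ]) == 0 || stats::sd(t_[i, ]) == 0) {
      return(NA_real_)
    }
    cor(m[i, ], t_[i, ])
  }, numeric(1L))
  names(r) <- lines
  flagged <- lines[is.na(r)]
  call <- length(r) > 0L && all(!is.na(r)) && all(r < 0)
  list(call = call, r_by_line = r, flagged_lines = flagged)
}

#' Two-sample Welch t-test helper
#'
#' Convenience wrapper used when annotating trait or expression
#' comparisons between lines; not a package contribution.
#'
#' @param x,y numeric replicate vectors.
#' @return list with `statistic` and `p_value`.
#' @export
two_sample_t <- function(x, y) {
  fit <- stats::t.test(x, y)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}
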