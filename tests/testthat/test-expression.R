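test_that("WTC is the ratio of treated to control means and scale-invariant", {
  expect_equal(compute_wtc(c(2, 2, 2), c(4, 4, 4)), 0.5)
  expect_equal(compute_wtc(c(3, 4, 5), c(3, 4, 5)), 1.0)
  x <- c(1.2, 1.5, 1.8); y <- c(2.0, 2.4, 2.1)
  expect_equal(compute_wtc(3.7 * x, 3.7 * y), compute_wtc(x, y))
  expect_equal(compute_wtc(x, y), mean(x) / mean(y)) # direct formula
  expect_error(compute_wtc(c(1, 2), c(0, 0)), "positive")

  tab <- data.frame(line = "tolerant",
                    condition = rep(c("treated", "control"), each = 3L),
                    trait = "TW", value = c(2, 2, 2, 4, 4, 4),
                    stringsAsFactors = FALSE)
  expect_equal(wtc_table(tab)$wtc, 0.5)
})

test_that("stem-loop primers append the reverse complement of the 3' hexamer", {
  p <- stemloop_primer("UGAAUUGAAGUCUGGAGA")
  expect_equal(nchar(p), 50L)
  expect_equal(substr(p, 1L, 44L),
               "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGAC")
  expect_equal(substr(p, 45L, 50L), "TCTCCA") # revcomp of TGGAGA
  expect_equal(substr(stemloop_primer("ACGTACAAAAAA"), 45L, 50L),
               "TTTTTT")
  expect_error(stemloop_primer("ACGTA"), "6 nt")
  expect_warning(stemloop_primer(c("ACGTACGTTGGAGA", "CCCCCCCCTGGAGA")),
                 "identical")
})

test_that("delta-delta-Ct relative quantification", {
  expect_equal(relative_expression(20, 15, 20, 15), 1.0)
  expect_equal(relative_expression(20, 15, 22, 15), 4.0)
  expect_equal(relative_expression(21, 15, 20, 15), 0.5)
  # replicate averaging before differencing
  expect_equal(relative_expression(c(19, 21), c(15, 15), c(22, 22),
                                   c(15, 15)), 4.0)
  # normalization identity: rel(x, x, y, y) = 1
  for (x in c(10, 20.5, 33)) {
    expect_equal(relative_expression(x, x, 25, 25), 1.0)
  }
  expect_error(relative_expression(NA, 15, 20, 15), "finite")
})

test_that("profile clustering recovers well-separated blocks", {
  set.seed(61)
  centers <- matrix(c(5, 5, 5, -5, -5, -5, 5, -5, 5, -5, 5, -5),
                    nrow = 4L, byrow = TRUE)
  mat <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(15L, sd = 0.2), nrow = 5L), 2L, centers[k, ], "+")
  }))
  rownames(mat) <- paste0("e", 1:20)
  res <- cluster_profiles(mat, k = 4L)
  truth <- rep(1:4, each = 5L)
  # same partition up to label renaming
  expect_equal(length(unique(res$labels)), 4L)
  for (k in 1:4) {
    expect_equal(length(unique(res$labels[truth == k])), 1L)
  }
  # identical rows merge at height zero with the same label
  mat2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  res2 <- cluster_profiles(mat2, k = 2L)
  expect_equal(res2$labels[["a"]], res2$labels[["b"]])
  expect_equal(min(res2$tree$height), 0)
  # merge heights non-decreasing
  expect_true(all(diff(res$tree$height) >= -1e-12))

  # permutation safety: shuffled rows give the same partition
  perm <- sample(nrow(mat))
  res_p <- cluster_profiles(mat[perm, ], k = 4L)
  relabel <- function(l) as.integer(factor(l, levels = unique(l)))
  expect_equal(relabel(res_p$labels[rownames(mat)]),
               relabel(res$labels))

  bad <- mat; bad[2L, 3L] <- NA
  expect_error(cluster_profiles(bad), "missing")
})

test_that("negative-correlation calls require r < 0 in every line", {
  p <- matrix(c(1, 2, 3, 0.5, 1, 1.5, -1, -2, -3), nrow = 3L,
              byrow = TRUE, dimnames = list(c("tolerant", "mid",
                                              "sensitive"),
                                            c("1h", "2h", "4h")))
  res <- call_negative_correlation(p, -p)
  expect_true(res$call)
  expect_equal(unname(res$r_by_line), rep(-1, 3L))

  expect_false(call_negative_correlation(p, p)$call)

  mixed <- -p; mixed["mid", ] <- p["mid", ]
  expect_false(call_negative_correlation(p, mixed)$call)

  flat <- p; flat[] <- 1
  res_flat <- call_negative_correlation(p, flat)
  expect_false(res_flat$call)
  expect_length(res_flat$flagged_lines, 3L)
  expect_error(call_negative_correlation(p, p[1:2, ]), "design")
})

test_that("expression profiles invert the Ct model exactly at zero noise", {
  study <- small_study(seed = 17L, qpcr_noise_sd = 0, trait_noise_sd = 0)
  profs <- expression_profiles(study$ct_table)
  truth <- study$manifest$qpcr_truth
  for (ent in unique(truth$entity_id)[1:4]) {
    tr <- truth[truth$entity_id == ent, ]
    for (i in seq_len(nrow(tr))) {
      expect_equal(profs[[ent]][tr$line[i], tr$time[i]],
                   log2(tr$rel_expr[i]), tolerance = 1e-9)
    }
  }
  # designated anti-correlated pairs are called, flat decoys are not
  tgt <- study$manifest$targets
  tgt <- tgt[tgt$accepted_expected, ]
  for (i in seq_len(nrow(tgt))) {
    res <- call_negative_correlation(profs[[tgt$mirna_id[i]]],
                                     profs[[tgt$transcript_id[i]]])
    expect_equal(res$call, tgt$regulated[i])
  }
  # phenotype: WTC equals the planted line multiplier at zero noise
  wtc <- wtc_table(study$trait_table)
  truth_ph <- study$manifest$phenotype_truth
  for (i in seq_len(nrow(truth_ph))) {
    tw <- wtc$wtc[wtc$line == truth_ph$line[i] & wtc$trait == "TW"]
    expect_equal(tw, truth_ph$multiplier[i], tolerance = 1e-9)
  }
})
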