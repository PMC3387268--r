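ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming classifies reads by prefix occurrence", {
  insert <- rand_dna(21L)
  read <- substr(paste0(insert, ADAPTER), 1L, 36L)
  res <- trim_adapter(read, ADAPTER)
  expect_equal(res$status, "trimmed")
  expect_equal(res$insert, insert)

  ao <- substr(paste0(ADAPTER, ADAPTER), 1L, 36L)
  expect_equal(trim_adapter(ao, ADAPTER)$status, "adapter_only")

  plain <- strrep("AC", 18L)
  res3 <- trim_adapter(plain, ADAPTER)
  expect_equal(res3$status, "untrimmed")
  expect_equal(res3$insert, plain) # full read kept for the size filter

  expect_error(trim_adapter(read, ADAPTER, min_overlap = 0L))
  expect_error(trim_adapter(read, ""))
})

test_that("tag collapsing filters by size, counts stages and conserves reads", {
  tag <- rand_dna(21L)
  trt <- c(rep(tag, 3L), rand_dna(17L), rand_dna(27L), "",
           paste0("N", rand_dna(20L)))
  ctl <- c(tag, rand_dna(20L))
  col <- collapse_tags(trt, ctl)
  tr <- col$tags[col$tags$seq == tag, ]
  expect_equal(c(tr$count_treatment, tr$count_control), c(3L, 1L))
  s <- col$stats$treatment
  expect_equal(s$too_short, 1L)
  expect_equal(s$too_long, 1L)
  expect_equal(s$adapter_only, 1L)
  expect_equal(s$with_n, 1L)
  expect_equal(s$filtered_reads, 3L)
  expect_equal(s$total_reads, s$adapter_only + s$too_short + s$too_long +
                 s$filtered_reads + s$with_n)
  expect_equal(sum(s$size_histogram), s$filtered_reads)
  # count conservation into the tag table
  expect_equal(sum(col$tags$count_treatment), s$filtered_reads)
  expect_equal(sum(col$tags$count_control),
               col$stats$control$filtered_reads)
})

test_that("RPM sums to one million per library", {
  set.seed(11)
  trt <- replicate(200L, rand_dna(sample(18:26, 1L)))
  ctl <- replicate(150L, rand_dna(sample(18:26, 1L)))
  col <- collapse_tags(trt, ctl)
  expect_equal(sum(col$tags$rpm_treatment), 1e6, tolerance = 1e-9)
  expect_equal(sum(col$tags$rpm_control), 1e6, tolerance = 1e-9)
})

test_that("known-signature quantification requires perfect matches and merges shared sequences", {
  mature <- rand_dna(21L)
  mismatched <- mature
  substr(mismatched, 5L, 5L) <- setdiff(c("A", "C", "G", "T"),
                                        substr(mature, 5L, 5L))[1L]
  tags <- data.frame(seq = c(mature, mismatched),
                     count_treatment = c(120L, 50L),
                     count_control = c(40L, 50L),
                     stringsAsFactors = FALSE)
  attr(tags, "library_totals") <- c(treatment = 1e6, control = 1e6)
  catalog <- data.frame(
    signature_id = c("miR1a", "miR1b", "miR2a"),
    mature_seq = c(mature, mature, rand_dna(21L)),
    locus_id = c("locA", "locB", "locC"), stringsAsFactors = FALSE)
  sig <- quantify_known(tags, catalog)
  # one signature: shared mature sequence, both loci listed; the
  # 1-mismatch tag contributes nowhere; the unseen catalog entry is absent
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$signature_id, "miR1a/miR1b")
  expect_equal(sig$locus_ids, "locA,locB")
  expect_equal(c(sig$count_treatment, sig$count_control), c(120L, 40L))

  bad <- data.frame(signature_id = c("miR1a", "miR1a"),
                    mature_seq = c(mature, mismatched),
                    locus_id = c("locA", "locB"), stringsAsFactors = FALSE)
  expect_error(quantify_known(tags, bad), "catalog")

  # U/T-insensitive matching
  catalog_u <- data.frame(signature_id = "miR9",
                          mature_seq = chartr("T", "U", mature),
                          locus_id = "locU", stringsAsFactors = FALSE)
  sig_u <- quantify_known(tags, catalog_u)
  expect_equal(sig_u$count_treatment, 120L)
})

test_that("chi-square matches the closed-form oracle and handles degeneracy", {
  # frozen oracle value: Pearson chi-square of {200, 999800; 100, 999900}
  res <- chi_square_de(200, 1e6, 100, 1e6)
  expect_equal(res$chi2, 33.33833, tolerance = 1e-5)
  expect_equal(res$p_value, 7.744097e-09, tolerance = 1e-4)
  expect_false(res$low_expectation)

  sym <- chi_square_de(50, 1e6, 50, 1e6)
  expect_equal(sym$chi2, 0)
  expect_equal(sym$p_value, 1)

  degen <- chi_square_de(0, 1e6, 0, 1e6)
  expect_equal(degen$chi2, 0)
  expect_true(degen$low_expectation)

  expect_error(chi_square_de(10, 5, 1, 10), "count")

  # cross-check against stats::chisq.test on random tables
  set.seed(21)
  for (i in 1:20) {
    a <- rpois(1, 500); b <- rpois(1, 300)
    ours <- chi_square_de(a, 1e5, b, 1e5)
    ref <- suppressWarnings(chisq.test(
      matrix(c(a, 1e5 - a, b, 1e5 - b), 2L, byrow = TRUE),
      correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("DE filter applies p, symmetric fold and RPM thresholds", {
  mk <- function(rpm_t, rpm_c, p) {
    data.frame(signature_id = "s", rpm_treatment = rpm_t,
               rpm_control = rpm_c, fold_change = rpm_t / rpm_c,
               p_value = p, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(de_filter(mk(80, 40, 1e-5))), 1L)  # fold 2, rpm ok
  expect_equal(nrow(de_filter(mk(60, 50, 1e-5))), 0L)  # fold 1.2
  expect_equal(nrow(de_filter(mk(45, 10, 1e-5))), 0L)  # max rpm <= 50
  expect_equal(nrow(de_filter(mk(40, 80, 1e-5))), 1L)  # repressed side
  expect_equal(nrow(de_filter(mk(80, 40, 0.02))), 0L)  # p too large
})

test_that("DE filter is monotone in its thresholds", {
  set.seed(31)
  n <- 200L
  sig <- data.frame(
    signature_id = paste0("s", seq_len(n)),
    rpm_treatment = runif(n, 1, 400), rpm_control = runif(n, 1, 400),
    p_value = runif(n), stringsAsFactors = FALSE)
  sig$fold_change <- sig$rpm_treatment / sig$rpm_control
  base <- de_filter(sig)$signature_id
  expect_true(all(de_filter(sig, fold_min = 2)$signature_id %in% base))
  expect_true(all(de_filter(sig, rpm_min = 100)$signature_id %in% base))
  expect_true(all(de_filter(sig, p_max = 0.001)$signature_id %in% base))
})
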