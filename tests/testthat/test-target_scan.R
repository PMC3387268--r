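test_that("duplex scoring implements the positional rules", {
  set.seed(41)
  m <- rand_dna(21L)
  perfect <- revcomp(m)
  d <- score_duplex(m, perfect)
  expect_equal(d$score, 0)
  expect_true(d$accepted)
  expect_true(all(d$states == "match"))

  inj <- function(pos) {
    s <- perfect
    for (p in pos) s <- hypoxamir:::inject_mismatch(s, m, p)
    score_duplex(m, s)
  }
  d10 <- inj(10L)
  expect_false(d10$accepted)
  expect_false(d10$rule_verdicts[["r_no_mm_10_11"]])
  expect_true(d10$rule_verdicts[["r_seed_le1"]]) # one mismatch in 2..12 ok

  d_consec <- inj(c(13L, 14L, 15L))
  expect_false(d_consec$accepted)
  expect_false(d_consec$rule_verdicts[["r_consec_le2_after12"]])
  expect_true(all(d_consec$rule_verdicts[c("r_seed_le1", "r_no_mm_10_11",
                                           "r_total_le4")]))

  d_seed <- inj(c(3L, 8L))
  expect_false(d_seed$accepted)
  expect_false(d_seed$rule_verdicts[["r_seed_le1"]])
  expect_true(all(d_seed$rule_verdicts[c("r_no_mm_10_11",
                                         "r_consec_le2_after12",
                                         "r_total_le4")]))

  d_total <- inj(c(1L, 13L, 15L, 17L, 19L))
  expect_false(d_total$accepted)
  expect_false(d_total$rule_verdicts[["r_total_le4"]])
  expect_true(all(d_total$rule_verdicts[c("r_seed_le1", "r_no_mm_10_11",
                                          "r_consec_le2_after12")]))

  expect_error(score_duplex(m, substr(perfect, 1L, 20L)), "length")
  expect_error(score_duplex(m, paste0(substr(perfect, 1L, 20L), "-")),
               "gap")
})

test_that("G:U wobbles score as mismatches by default, configurable to 0.5", {
  # miRNA G against target T is a wobble
  m <- "GGGGGGGGGGGGGGGGGGGGG"
  site <- revcomp(m) # CCCC...
  substr(site, 21L, 21L) <- "T" # pairs miRNA position 1 -> G:T wobble
  d <- score_duplex(m, site)
  expect_equal(d$states[1L], "wobble")
  expect_equal(d$score, 1)
  d_half <- score_duplex(m, site, wobble_score = 0.5)
  expect_equal(d_half$score, 0.5)
})

test_that("transcriptome scanning equals the brute-force window oracle", {
  set.seed(42)
  transcripts <- setNames(replicate(10L, rand_dna(300L)),
                          paste0("t", 1:10))
  for (rep_ in 1:5) {
    m <- rand_dna(21L)
    # plant a perfect site and a near-miss in random transcripts
    tid <- sample(names(transcripts), 2L)
    tx <- transcripts[[tid[1L]]]
    off <- sample.int(250L, 1L)
    substr(tx, off, off + 20L) <- revcomp(m)
    transcripts[[tid[1L]]] <- tx
    tx2 <- transcripts[[tid[2L]]]
    site2 <- hypoxamir:::make_site(m, "violate_seed")
    off2 <- sample.int(250L, 1L)
    substr(tx2, off2, off2 + 20L) <- site2
    transcripts[[tid[2L]]] <- tx2

    hits <- scan_transcriptome(m, transcripts)
    oracle <- brute_force_scan(m, transcripts)
    expect_equal(nrow(hits), nrow(oracle))
    expect_equal(hits$target_id, oracle$target_id)
    expect_equal(hits$site_start, oracle$site_start)
    expect_equal(hits$n_mismatch, oracle$n_mismatch)
    expect_equal(hits$accepted, oracle$accepted)
    # the planted perfect site is an accepted hit at its coordinates
    expect_true(any(hits$accepted & hits$target_id == tid[1L] &
                      hits$site_start == off - 1L))
    # the seed-violating site is a candidate but not accepted
    seedhit <- hits[hits$target_id == tid[2L] &
                      hits$site_start == off2 - 1L, ]
    expect_equal(nrow(seedhit), 1L)
    expect_false(seedhit$accepted)
  }
})

test_that("relaxing the candidate radius never removes an accepted hit", {
  set.seed(43)
  transcripts <- setNames(replicate(5L, rand_dna(300L)), paste0("t", 1:5))
  m <- rand_dna(21L)
  tx <- transcripts[["t1"]]
  substr(tx, 50L, 70L) <- revcomp(m)
  transcripts[["t1"]] <- tx
  strict <- scan_transcriptome(m, transcripts, candidate_max_mm = 3L)
  relaxed <- scan_transcriptome(m, transcripts, candidate_max_mm = 6L)
  key <- function(df) paste(df$target_id, df$site_start)[df$accepted]
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("candidate windows mirror under reverse complementation", {
  set.seed(44)
  tx <- rand_dna(200L)
  m <- rand_dna(21L)
  substr(tx, 100L, 120L) <- revcomp(m)
  fwd <- hypoxamir:::.hamming_scan_cpp(hypoxamir:::seq_to_int(tx),
                                       hypoxamir:::seq_to_int(revcomp(m)))
  rev_ <- hypoxamir:::.hamming_scan_cpp(
    hypoxamir:::seq_to_int(revcomp(tx)),
    hypoxamir:::seq_to_int(m))
  expect_equal(fwd, rev(rev_))
})

test_that("cleavage clones are windowed and the canonical site located", {
  site <- list(site_start = 100L, site_end = 121L)
  # canonical position pairs miRNA position 10: 100 + 21 - 10 = 111
  res <- classify_cleavage(site, clone_positions = rep(111L, 4L))
  expect_equal(res$canonical_position, 111L)
  expect_equal(res$n_canonical, 4L)
  expect_equal(res$n_in_window, 4L)

  # center 110.5; a clone 60 nt downstream is outside [60.5, 160.5)
  res2 <- classify_cleavage(site, clone_positions = c(111L, 171L))
  expect_equal(res2$n_in_window, 1L)
  expect_equal(res2$n_clones, 2L)
  expect_lte(res2$n_canonical, res2$n_in_window)
})
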