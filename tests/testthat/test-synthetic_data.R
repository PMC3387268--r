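test_that("genome simulation is deterministic and self-consistent", {
  g1 <- simulate_genome(small_params(), seed = 7L)
  g2 <- simulate_genome(small_params(), seed = 7L)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$manifest$known_catalog, g2$manifest$known_catalog)
  g3 <- simulate_genome(small_params(), seed = 8L)
  expect_false(identical(g1$genome, g3$genome))

  # every planted hairpin locus passes structural evaluation
  m <- g1$manifest
  for (i in seq_len(nrow(m$hairpins))) {
    h <- m$hairpins[i, ]
    locus <- data.frame(chrom = h$chrom, start = h$mature_start,
                        end = h$mature_end, strand = h$strand,
                        stringsAsFactors = FALSE)
    wins <- excise_and_fold(g1$genome, locus)
    expect_true(any(vapply(wins, function(w)
      isTRUE(evaluate_hairpin(w)$passed), logical(1L))))
    # planted coordinates carry the planted sequences
    expect_equal(nrow(hypoxamir:::map_tag_to_genome(h$mature_seq,
                                                    g1$genome)) >= 1L,
                 TRUE)
  }
  # every known locus carries its mature sequence
  kc <- m$known_catalog
  for (i in seq_len(nrow(kc))) {
    seg <- substr(g1$genome[[kc$chrom[i]]], kc$start[i] + 1L, kc$end[i])
    expected <- if (kc$strand[i] == "+") kc$mature_seq[i] else
      revcomp(kc$mature_seq[i])
    expect_equal(seg, expected)
  }
  # planted motif occurrences sit in the extracted promoters
  proms <- extract_promoters(g1$genome, g1$tss_table)
  pm <- m$planted_motifs
  for (i in seq_len(nrow(pm))) {
    cons <- m$pwm_meta$consensus[m$pwm_meta$motif_id == pm$motif_id[i]]
    pseq <- proms$seq[proms$gene_id == pm$gene_id[i]]
    for (off in as.integer(strsplit(pm$offsets[i], ",")[[1L]])) {
      expect_equal(substr(pseq, off + 1L, off + nchar(cons)), cons)
    }
  }

  # no repeats requested: empty annotation
  g0 <- simulate_genome(small_params(n_repeats = 0L), seed = 7L)
  expect_equal(nrow(g0$repeat_annotation), 0L)
})

test_that("library simulation honours fold changes and noise fractions", {
  gen <- simulate_genome(small_params(), seed = 7L)
  lib <- simulate_libraries(gen$manifest, depth_treatment = 100000L,
                            depth_control = 100000L, seed = 9L)
  counts <- lib$counts
  # observed count ratios sit inside a generous binomial envelope of the
  # true fold (equal depths, equal filler fractions)
  for (i in seq_len(nrow(counts))) {
    f <- counts$fold[i]
    obs <- counts$count_treatment[i] / counts$count_control[i]
    se <- sqrt(1 / counts$count_treatment[i] + 1 / counts$count_control[i])
    expect_lt(abs(log(obs) - log(f)), 5 * se)
  }
  # adapter-only fraction recovered by the trimming stats
  trim <- trim_adapter(lib$reads_treatment,
                       hypoxamir:::DEFAULT_ADAPTER)
  n_ao <- sum(trim$status == "adapter_only")
  expect_lt(abs(n_ao - 0.03 * 100000L), 5 * sqrt(100000L * 0.03 * 0.97))

  # depth zero gives an empty library
  lib0 <- simulate_libraries(gen$manifest, depth_treatment = 0L,
                             depth_control = 0L, seed = 9L)
  expect_length(lib0$reads_treatment, 0L)

  expect_error(simulate_libraries(gen$manifest, fold_map = c(miRZZ = 2),
                                  seed = 9L), "unknown")
})

test_that("expected-count sampling reproduces fold changes exactly", {
  gen <- simulate_genome(small_params(), seed = 7L)
  lib <- simulate_libraries(gen$manifest, seed = 9L,
                            noise = list(sampling = "expected"),
                            depth_treatment = 50000L,
                            depth_control = 50000L)
  counts <- lib$counts
  ratio <- counts$count_treatment / counts$count_control
  expect_equal(ratio, counts$fold, tolerance = 0.01)
})

test_that("planted target site classes behave as designed", {
  gen <- simulate_genome(small_params(), seed = 7L)
  lib <- simulate_libraries(gen$manifest, seed = 9L,
                            depth_treatment = 20000L,
                            depth_control = 20000L)
  tx <- simulate_transcript_targets(lib$manifest, n_transcripts = 30L,
                                    seed = 10L)
  tgt <- tx$manifest$targets
  expect_true(all(hypoxamir:::TARGET_SITE_CLASSES %in% tgt$class))
  for (i in seq_len(nrow(tgt))) {
    mirna <- tx$manifest$fold_truth$mature_seq[
      match(tgt$mirna_id[i], tx$manifest$fold_truth$entity_id)]
    hits <- scan_transcriptome(
      mirna, tx$transcripts[tgt$transcript_id[i]],
      mirna_id = tgt$mirna_id[i])
    planted <- hits[hits$site_start == tgt$offset[i], ]
    if (tgt$class[i] == "distance7") {
      expect_equal(nrow(planted), 0L) # beyond the candidate radius
    } else {
      expect_equal(nrow(planted), 1L)
      expect_equal(planted$accepted, tgt$class[i] == "all_pass")
    }
  }
})

test_that("study generation is byte-identical across runs with one seed", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(params = small_params(), seed = 19L, dir = d1,
                 depth_treatment = 20000L, depth_control = 20000L,
                 n_transcripts = 30L)
  simulate_study(params = small_params(), seed = 19L, dir = d2,
                 depth_treatment = 20000L, depth_control = 20000L,
                 n_transcripts = 30L)
  files <- list.files(d1)
  expect_true(length(files) >= 10L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("the truth manifest round-trips through JSON", {
  gen <- simulate_genome(small_params(), seed = 7L)
  path <- tempfile(fileext = ".json")
  write_manifest(gen$manifest, path)
  back <- read_manifest(path)
  for (nm in c("known_catalog", "hairpins", "tss_table", "pwm_meta",
               "planted_motifs", "fold_truth")) {
    expect_equal(back[[nm]], gen$manifest[[nm]], info = nm)
  }
  expect_equal(back$seed, gen$manifest$seed)
})

test_that("fold-change estimates track truth under sampling noise", {
  # parameter recovery: estimated RPM fold within 20% of truth for the
  # vast majority of planted miRNAs across seeds
  gen <- simulate_genome(small_params(), seed = 7L)
  ok <- 0L; total <- 0L
  for (s in 1:5) {
    lib <- simulate_libraries(gen$manifest, seed = 100L + s,
                              depth_treatment = 100000L,
                              depth_control = 100000L)
    counts <- lib$counts
    est <- counts$count_treatment / counts$count_control
    ok <- ok + sum(abs(log(est / counts$fold)) < log(1.2))
    total <- total + nrow(counts)
  }
  expect_gte(ok / total, 0.95)
})
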