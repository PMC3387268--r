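# a tiny genome with one planted hairpin, used by several blocks
make_hairpin_genome <- function(seed = 5L, strand = "+") {
  set.seed(seed)
  mature <- rand_dna(21L)
  pre <- hypoxamir:::design_precursor(mature)
  left <- rand_dna(400L); right <- rand_dna(400L)
  planted <- if (strand == "+") pre$precursor else revcomp(pre$precursor)
  genome <- c(chr1 = paste0(left, planted, right))
  m_off <- if (strand == "+") 400L + pre$mature_offset else
    400L + nchar(pre$precursor) - pre$mature_offset - 21L
  list(genome = genome, mature = mature,
       locus = data.frame(chrom = "chr1", start = m_off,
                          end = m_off + 21L, strand = strand,
                          stringsAsFactors = FALSE))
}

test_that("candidate cascade stages remove tags for the stated reasons", {
  hp <- make_hairpin_genome()
  known <- rand_dna(21L)
  near_known <- known
  substr(near_known, 3L, 3L) <- setdiff(c("A", "C", "G", "T"),
                                        substr(known, 3L, 3L))[1L]
  substr(near_known, 9L, 9L) <- setdiff(c("A", "C", "G", "T"),
                                        substr(known, 9L, 9L))[1L]
  far_known <- known
  for (p in c(3L, 9L, 15L)) {
    substr(far_known, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(known, p, p))[1L]
  }
  genome <- hp$genome
  # plant the distance-2 and distance-3 tags so they survive mapping
  genome[["chr1"]] <- paste0(genome[["chr1"]], near_known,
                             strrep("T", 30L), far_known, rand_dna(100L))
  tags <- data.frame(
    seq = c(hp$mature, rand_dna(21L), known, near_known, far_known),
    count_treatment = c(300L, 60L, 200L, 200L, 200L),
    count_control = c(300L, 39L, 200L, 200L, 200L),
    stringsAsFactors = FALSE)
  res <- filter_candidates(tags, genome, known_mirnas = known,
                           min_reads = 100L)
  # tag 2: combined 99 reads -> abundance stage; tag 3 identical to a
  # known miRNA and tag 4 at Hamming 2 -> known stage; tag 5 at Hamming 3
  # kept; note tag 3 is unmapped (not planted) so it already fails mapping
  expect_equal(unname(res$report["input_unique"]), 5L)
  expect_equal(unname(res$report["abundance_pass"]), 4L)
  expect_equal(unname(res$report["genome_mapped"]), 3L)
  expect_equal(unname(res$report["known_filtered"]), 2L)
  expect_setequal(res$candidates$seq, c(hp$mature, far_known))
  expect_true(all(diff(res$report) <= 0))

  # repeat overlap removal
  rep_ann <- data.frame(chrom = "chr1", start = hp$locus$start - 5L,
                        end = hp$locus$end + 5L, stringsAsFactors = FALSE)
  res2 <- filter_candidates(tags[1L, , drop = FALSE], genome,
                            repeat_annotation = rep_ann)
  expect_equal(unname(res2$report["repeat_filtered"]), 0L)

  expect_error(filter_candidates(tags, character(0)), "genome")
})

test_that("window excision arithmetic and clipping behave", {
  hp <- make_hairpin_genome()
  wins <- excise_and_fold(hp$genome, hp$locus, flanks = c(20L, 120L))
  expect_length(wins, 2L)
  for (w in wins) {
    expect_equal(nchar(w$precursor_seq), 21L + 20L + 120L)
    expect_equal(substr(w$precursor_seq, w$mature_start + 1L,
                        w$mature_end), hp$mature)
    expect_equal(nchar(w$structure), nchar(w$precursor_seq))
    expect_false(w$clipped)
  }
  # clipping at the contig edge
  edge_locus <- data.frame(chrom = "chr1", start = 5L, end = 26L,
                           strand = "+", stringsAsFactors = FALSE)
  we <- excise_and_fold(hp$genome, edge_locus, flanks = c(50L, 50L))
  expect_true(any(vapply(we, `[[`, TRUE, "clipped")))
})

test_that("minus-strand loci are excised as the reverse complement", {
  hp <- make_hairpin_genome(seed = 6L, strand = "-")
  wins <- excise_and_fold(hp$genome, hp$locus)
  for (w in wins) {
    expect_equal(substr(w$precursor_seq, w$mature_start + 1L,
                        w$mature_end), hp$mature)
  }
})

test_that("the built-in folder agrees with RNAfold on a designed hairpin", {
  set.seed(8)
  arm <- rand_dna(30L)
  hairpin <- paste0(arm, "GCAAAAGC", revcomp(arm))
  f <- fold_hairpin(hairpin)
  expect_gte(sum(strsplit(f$structure, "")[[1L]] == "("), 30L)
  expect_lt(f$mfe, 0)
  # independent thermodynamic implementation on the same perfect hairpin
  f2 <- fold_rnafold(hairpin)
  expect_gte(sum(strsplit(f2$structure, "")[[1L]] == "("), 30L)
  expect_lt(f2$mfe, 0)
  # homopolymer: no base pairs at all
  fa <- fold_hairpin(strrep("A", 80L))
  expect_equal(fa$structure, strrep(".", 80L))
  # determinism
  expect_identical(fold_hairpin(hairpin), fold_hairpin(hairpin))
})

test_that("hairpin evaluation criteria discriminate designed cases", {
  set.seed(9)
  mature <- rand_dna(21L)
  pre <- hypoxamir:::design_precursor(mature)
  f <- fold_hairpin(pre$precursor)
  cand <- list(precursor_seq = pre$precursor, structure = f$structure,
               mfe = f$mfe, mature_start = 5L, mature_end = 26L)
  ev <- evaluate_hairpin(cand)
  expect_true(ev$passed)
  expect_true(all(ev$criteria))
  expect_equal(ev$arm, "5p")
  # star interval falls on the 3' arm
  expect_gt(ev$star_interval[1L], 35L)

  # mature span straddling the terminal loop
  straddle <- cand
  straddle$mature_start <- 25L; straddle$mature_end <- 46L
  ev2 <- evaluate_hairpin(straddle)
  expect_false(ev2$passed)
  expect_false(ev2$criteria[["single_arm"]] &&
                 ev2$criteria[["outside_terminal_loop"]])

  # five unpaired mature bases violate the duplex criterion: force an
  # artificial structure with a 5-nt interior hole in the mature span
  hole <- f$structure
  # find 5 consecutive '(' inside the mature span and their partners
  part <- hypoxamir:::pair_table(f$structure)
  span <- 6:26
  paired <- span[!is.na(part[span])][1:5]
  ch <- strsplit(hole, "")[[1L]]
  ch[paired] <- "."; ch[part[paired]] <- "."
  cand3 <- cand; cand3$structure <- paste(ch, collapse = "")
  ev3 <- evaluate_hairpin(cand3)
  expect_false(ev3$criteria[["duplex_unpaired"]])

  expect_error(evaluate_hairpin(list(structure = NULL)), "folded")
})

test_that("unbalanced dot-bracket strings are rejected", {
  expect_error(hypoxamir:::pair_table("((..)"), "unbalanced")
  expect_error(hypoxamir:::pair_table("(..))"), "unbalanced")
})

test_that("novel discovery recovers planted hairpins and rejects decoys", {
  set.seed(10)
  hp1 <- make_hairpin_genome(seed = 11L, strand = "+")
  hp2 <- make_hairpin_genome(seed = 12L, strand = "-")
  genome <- c(chr1 = hp1$genome[["chr1"]], chr2 = hp2$genome[["chr1"]])
  nonhairpin <- rand_dna(21L)
  genome[["chr1"]] <- paste0(genome[["chr1"]], rand_dna(50L), nonhairpin,
                             rand_dna(50L))
  tags <- data.frame(seq = c(hp1$mature, hp2$mature, nonhairpin),
                     count_treatment = c(200L, 200L, 200L),
                     count_control = c(100L, 100L, 100L),
                     stringsAsFactors = FALSE)
  res <- discover_novel(tags, genome)
  expect_setequal(res$novel$tag_seq, c(hp1$mature, hp2$mature))
  expect_equal(unname(res$report["structure_pass"]), 2L)

  # abundance below threshold: no calls
  low <- tags; low$count_treatment <- 50L; low$count_control <- 40L
  expect_equal(nrow(discover_novel(low, genome)$novel), 0L)

  # a planted hairpin whose tag matches a known miRNA is filtered out
  res3 <- discover_novel(tags, genome,
                         annotations = list(known_mirnas = hp1$mature))
  expect_false(hp1$mature %in% res3$novel$tag_seq)
})

test_that("dinucleotide-shuffled precursors rarely pass evaluation", {
  set.seed(13)
  mature <- rand_dna(21L)
  pre <- hypoxamir:::design_precursor(mature)
  passes <- 0L
  for (i in 1:200) {
    shuf <- dinuc_shuffle(pre$precursor)
    f <- fold_hairpin(shuf)
    cand <- list(precursor_seq = shuf, structure = f$structure,
                 mfe = f$mfe, mature_start = 5L, mature_end = 26L)
    if (isTRUE(evaluate_hairpin(cand)$passed)) passes <- passes + 1L
  }
  expect_lte(passes / 200, 0.05)
})
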