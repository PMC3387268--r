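#' Expression profiles (log2 treatment/control) from a Ct table
#'
#' Applies [relative_expression()] per entity x line x time against the
#' reference entity, returning one line x time matrix of log2 ratios per
#' entity.
#'
#' @param ct_table long Ct table (columns `entity_id`, `kind`, `line`,
#'   `time`, `condition`, `replicate`, `ct`).
#' @param reference_id entity id of the normalisation reference
#'   (default `"18S"`).
#' @return named list of matrices (rows = lines, columns = times).
#' @export
expression_profiles <- function(ct_table, reference_id = "18S") {
  ref <- ct_table[ct_table$entity_id == reference_id, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference entity '", reference_id,
                            "' absent from the Ct table", call. = FALSE)
  entities <- setdiff(unique(ct_table$entity_id), reference_id)
  lines <- unique(ct_table$line)
  times <- unique(ct_table$time)
  lapply(setNames(entities, entities), function(ent) {
    m <- matrix(NA_real_, nrow = length(lines), ncol = length(times),
                dimnames = list(lines, times))
    for (ln in lines) for (tm in times) {
      sel <- ct_table$entity_id == ent & ct_table$line == ln &
        ct_table$time == tm
      rsel <- ref$line == ln & ref$time == tm
      rel <- relative_expression(
        ct_table$ct[sel & ct_table$condition == "treated"],
        ref$ct[rsel & ref$condition == "treated"],
        ct_table$ct[sel & ct_table$condition == "control"],
        ref$ct[rsel & ref$condition == "control"])
      m[ln, tm] <- log2(rel)
    }
    m
  })
}

#' Run the full analysis pipeline on a (simulated or real) study
#'
#' Executes every stage end to end: adapter trimming and tag collapsing
#' of the two libraries; known-signature quantification and the
#' chi-square / fold / RPM differential-expression filter; novel miRNA
#' discovery; target scanning of the DE miRNAs against the
#' transcriptome; delta-delta-Ct expression profiles and
#' negative-correlation target calls; promoter extraction and PWM
#' over-representation; and regulatory network assembly.
#'
#' @param study list as produced by [simulate_study()] (fields: `genome`,
#'   `reads_treatment`, `reads_control`, `adapter`, `known_catalog`,
#'   `ncrnas`, `repeat_annotation`, `transcripts`,
#'   `transcript_annotation`, `ct_table`, `tss_table`, `pwms`).
#' @param config list of knobs: `p_max` (0.01), `fold_min` (1.5),
#'   `rpm_min` (50), `min_reads` (100), `candidate_max_mm` (6),
#'   `wobble_score` (1), `enrich_p_max` (0.001), `min_occ` (3),
#'   `n_background` (200), `background_len` (1500), plus any
#'   [discover_novel()] keys.
#' @return list with `tags`, `library_stats`, `signatures`, `de_table`,
#'   `novel`, `cascade`, `target_hits`, `profiles`, `negcor_table`,
#'   `enrichment`, `tf_mirna_table`, `mirna_target_table`, `network`,
#'   `network_summary`, `wtc`.
#' @export
run_pipeline <- function(study, config = list()) {
  cfg <- modifyList(list(p_max = 0.01, fold_min = 1.5, rpm_min = 50,
                         min_reads = 100L, candidate_max_mm = 6L,
                         wobble_score = 1, enrich_p_max = 0.001,
                         min_occ = 3L, n_background = 200L,
                         background_len = 1500L), config)

  trim_t <- trim_adapter(study$reads_treatment, study$adapter)
  trim_c <- trim_adapter(study$reads_control, study$adapter)
  col <- collapse_tags(trim_t$insert, trim_c$insert)
  tags <- col$tags

  signatures <- quantify_known(
    tags, study$known_catalog[, c("signature_id", "mature_seq", "locus_id")])
  de_table <- de_filter(signatures, p_max = cfg$p_max,
                        fold_min = cfg$fold_min, rpm_min = cfg$rpm_min)

  disc <- discover_novel(
    tags, study$genome,
    annotations = list(repeats = study$repeat_annotation,
                       known_mirnas = study$known_catalog$mature_seq,
                       other_ncrnas = study$ncrnas$seq),
    config = cfg[intersect(names(cfg),
                           c("min_reads", "max_genome_hits", "known_max_mm",
                             "flanks", "mfe_max", "max_unpaired_mature",
                             "max_bulge", "folder"))])

  # novel calls get the DE statistics of their tags too; names come from
  # the assay catalog when one exists (mature-sequence lookup), otherwise
  # novel_1, novel_2, ...
  novel <- disc$novel
  if (nrow(novel) > 0L) {
    totals <- attr(tags, "library_totals")
    test <- chi_square_de(novel$count_treatment, totals[["treatment"]],
                          novel$count_control, totals[["control"]])
    novel$rpm_treatment <- novel$count_treatment /
      totals[["treatment"]] * 1e6
    novel$rpm_control <- novel$count_control / totals[["control"]] * 1e6
    novel$fold_change <- fold_change_rpm(
      novel$count_treatment, novel$count_control,
      totals[["treatment"]], totals[["control"]])
    novel$p_value <- test$p_value
    novel$chi2 <- test$chi2
    lab <- rep(NA_character_, nrow(novel))
    if (!is.null(study$assay_catalog)) {
      lab <- study$assay_catalog$entity_id[
        match(novel$tag_seq, study$assay_catalog$mature_seq)]
    }
    lab[is.na(lab)] <- paste0("novel_", which(is.na(lab)))
    novel$novel_id <- lab
  }

  de_entities <- data.frame(mirna_id = de_table$signature_id,
                            mature_seq = de_table$mature_seq,
                            fold_change = de_table$fold_change,
                            stringsAsFactors = FALSE)
  if (nrow(novel) > 0L) {
    fc <- novel$fold_change
    novel_de <- (novel$p_value < cfg$p_max) &
      (fc >= cfg$fold_min | fc <= 1 / cfg$fold_min) &
      (pmax(novel$rpm_treatment, novel$rpm_control) > cfg$rpm_min)
    if (any(novel_de)) {
      de_entities <- rbind(de_entities, data.frame(
        mirna_id = novel$novel_id[novel_de],
        mature_seq = novel$tag_seq[novel_de],
        fold_change = novel$fold_change[novel_de],
        stringsAsFactors = FALSE))
    }
  }

  target_hits <- do.call(rbind, lapply(seq_len(nrow(de_entities)),
                                       function(i) {
    scan_transcriptome(de_entities$mature_seq[i], study$transcripts,
                       candidate_max_mm = cfg$candidate_max_mm,
                       wobble_score = cfg$wobble_score,
                       mirna_id = de_entities$mirna_id[i])
  }))
  if (is.null(target_hits)) {
    target_hits <- data.frame(mirna_id = character(0),
                              target_id = character(0),
                              site_start = integer(0),
                              site_end = integer(0),
                              site_seq = character(0),
                              n_mismatch = integer(0), score = numeric(0),
                              r_seed_le1 = logical(0),
                              r_no_mm_10_11 = logical(0),
                              r_consec_le2_after12 = logical(0),
                              r_total_le4 = logical(0),
                              accepted = logical(0),
                              stringsAsFactors = FALSE)
  }

  profiles <- expression_profiles(study$ct_table)
  accepted <- target_hits[target_hits$accepted, , drop = FALSE]
  pair_keys <- unique(accepted[, c("mirna_id", "target_id")])
  negcor_rows <- lapply(seq_len(nrow(pair_keys)), function(i) {
    m_id <- pair_keys$mirna_id[i]; t_id <- pair_keys$target_id[i]
    if (is.null(profiles[[m_id]]) || is.null(profiles[[t_id]])) {
      return(NULL)
    }
    res <- call_negative_correlation(profiles[[m_id]], profiles[[t_id]])
    data.frame(mirna_id = m_id, target_id = t_id, call = res$call,
               r_min = suppressWarnings(min(res$r_by_line)),
               r_max = suppressWarnings(max(res$r_by_line)),
               stringsAsFactors = FALSE)
  })
  negcor_table <- do.call(rbind, negcor_rows)
  if (is.null(negcor_table)) {
    negcor_table <- data.frame(mirna_id = character(0),
                               target_id = character(0), call = logical(0),
                               r_min = numeric(0), r_max = numeric(0),
                               stringsAsFactors = FALSE)
  }

  promoters_df <- extract_promoters(study$genome, study$tss_table)
  promoters <- setNames(promoters_df$seq, promoters_df$gene_id)
  background <- sample_background_promoters(
    study$genome, n = cfg$n_background, len = cfg$background_len,
    exclude = promoter_intervals(study$tss_table))
  enrichment <- motif_enrichment(promoters, study$pwms, background,
                                 p_max = cfg$enrich_p_max,
                                 min_occ = cfg$min_occ)
  per_prom <- attr(enrichment, "per_promoter")
  sel <- which(enrichment$selected)
  tf_rows <- lapply(sel, function(i) {
    genes <- colnames(per_prom)[per_prom[enrichment$motif_id[i], ] >=
                                  cfg$min_occ]
    if (length(genes) == 0L) return(NULL)
    data.frame(mirna_id = genes, tf_name = enrichment$tf_name[i],
               tf_family = enrichment$tf_family[i],
               motif_id = enrichment$motif_id[i], stringsAsFactors = FALSE)
  })
  tf_mirna_table <- do.call(rbind, tf_rows)
  if (is.null(tf_mirna_table)) {
    tf_mirna_table <- data.frame(mirna_id = character(0),
                                 tf_name = character(0),
                                 tf_family = character(0),
                                 motif_id = character(0),
                                 stringsAsFactors = FALSE)
  }

  ann <- study$transcript_annotation
  called <- negcor_table[negcor_table$call, , drop = FALSE]
  fam <- ann$tf_family[match(called$target_id, ann$transcript_id)]
  mirna_target_table <- data.frame(mirna_id = called$mirna_id,
                                   tf_family = fam,
                                   stringsAsFactors = FALSE)
  mirna_target_table <- mirna_target_table[!is.na(
    mirna_target_table$tf_family), , drop = FALSE]

  regulation <- data.frame(
    mirna_id = unique(c(tf_mirna_table$mirna_id,
                        mirna_target_table$mirna_id)),
    stringsAsFactors = FALSE)
  regulation$regulation <- ifelse(
    de_entities$fold_change[match(regulation$mirna_id,
                                  de_entities$mirna_id)] >= 1,
    "up", "down")
  regulation$regulation[is.na(regulation$regulation)] <- "up"
  network <- build_network(tf_mirna_table, mirna_target_table, regulation)

  wtc <- if (!is.null(study$trait_table)) wtc_table(study$trait_table) else
    NULL

  list(tags = tags, library_stats = col$stats, signatures = signatures,
       de_table = de_table, de_entities = de_entities, novel = novel,
       cascade = disc$report,
       target_hits = target_hits, profiles = profiles,
       negcor_table = negcor_table, enrichment = enrichment,
       tf_mirna_table = tf_mirna_table,
       mirna_target_table = mirna_target_table, network = network,
       network_summary = summarize_network(network), wtc = wtc)
}

#' Sample length-matched background sequences from a genome
#'
#' Windows are drawn uniformly (length-weighted across contigs). The
#' foreground promoter intervals should be passed as `exclude`: windows
#' overlapping them are rejected, so the background rate is not
#' contaminated by the very sequences being tested for enrichment.
#'
#' @param genome named character vector of contigs.
#' @param n number of sequences.
#' @param len sequence length.
#' @param exclude optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) of intervals background windows must not overlap.
#' @return character vector of background sequences.
#' @export
sample_background_promoters <- function(genome, n = 1000L, len = 1500L,
                                        exclude = NULL) {
  lens <- nchar(genome)
  ok <- lens >= len
  if (!any(ok)) stop("no contig is long enough for the background length",
                     call. = FALSE)
  genome <- genome[ok]; lens <- lens[ok]
  out <- character(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(1000L)) {
      ci <- sample(seq_along(genome), 1L, prob = lens / sum(lens))
      start <- sample.int(lens[ci] - len + 1L, 1L) # 1-based
      if (!is.null(exclude) && nrow(exclude) > 0L) {
        ex <- exclude[exclude$chrom == names(genome)[ci], , drop = FALSE]
        if (nrow(ex) > 0L &&
            any(ex$start < start - 1L + len & ex$end > start - 1L)) next
      }
      out[i] <- substr(genome[[ci]], start, start + len - 1L)
      break
    }
    if (out[i] == "") {
      stop("could not sample a background window avoiding the excluded ",
           "intervals", call. = FALSE)
    }
  }
  out
}

# promoter genomic intervals implied by a TSS table (for background
# exclusion)
promoter_intervals <- function(tss_table, up = 1000L, down = 500L) {
  w_up <- ifelse(tss_table$strand == "+", up, down)
  w_dn <- ifelse(tss_table$strand == "+", down, up)
  data.frame(chrom = tss_table$chrom,
             start = pmax(tss_table$tss_pos - w_up, 0L),
             end = tss_table$tss_pos + w_dn,
             stringsAsFactors = FALSE)
}

prf <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  c(tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Compare pipeline output against the truth manifest
#'
#' Computes precision and recall for the recoverable feature classes:
#' differentially expressed signatures, novel hairpin calls, accepted
#' miRNA-transcript target sites, miRNA-to-target-family edges, and
#' TF-family-to-miRNA promoter edges.
#'
#' @param results output of [run_pipeline()].
#' @param manifest the study's truth manifest.
#' @return data.frame with one row per feature class: tp, fp, fn,
#'   precision, recall.
#' @export
evaluate_against_truth <- function(results, manifest) {
  ft <- manifest$fold_truth
  truth_de <- ft$entity_id[ft$kind == "known" & ft$fold != 1]
  pred_de <- results$de_table$signature_id

  truth_novel <- manifest$hairpins$mature_seq
  pred_novel <- results$novel$tag_seq

  tgt <- manifest$targets
  truth_sites <- with(tgt[tgt$accepted_expected, , drop = FALSE],
                      paste(mirna_id, transcript_id))
  acc <- results$target_hits[results$target_hits$accepted, , drop = FALSE]
  pred_sites <- unique(paste(acc$mirna_id, acc$target_id))

  truth_tedge <- unique(with(
    tgt[tgt$accepted_expected & tgt$regulated, , drop = FALSE],
    paste(mirna_id, tf_family)))
  pred_tedge <- unique(paste(results$mirna_target_table$mirna_id,
                             results$mirna_target_table$tf_family))

  pm <- manifest$planted_motifs
  truth_uedge <- unique(paste(pm$tf_family, pm$gene_id))
  pred_uedge <- unique(paste(results$tf_mirna_table$tf_family,
                             results$tf_mirna_table$mirna_id))

  rows <- rbind(
    de_signatures = prf(pred_de, truth_de),
    novel_hairpins = prf(pred_novel, truth_novel),
    target_sites = prf(pred_sites, truth_sites),
    mirna_target_edges = prf(pred_tedge, truth_tedge),
    tf_mirna_edges = prf(pred_uedge, truth_uedge))
  out <- data.frame(feature = rownames(rows), rows,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
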