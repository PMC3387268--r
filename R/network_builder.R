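#' Assemble the TF -> miRNA -> target-family regulatory network
#'
#' Nodes are the distinct miRNA genes and TF families; edges come from
#' the two input tables and are deduplicated. `TF_to_miRNA` edges run TF
#' family -> miRNA (promoter binding sites); `miRNA_to_target` edges run
#' miRNA -> TF family (negative-correlation target calls). The builder
#' reports whatever the inputs imply and never reconciles counts to any
#' external figure.
#'
#' @param tf_mirna_table data.frame with columns `mirna_id`, `tf_family`
#'   (one row per predicted promoter binding interaction).
#' @param mirna_target_table data.frame with columns `mirna_id`,
#'   `tf_family` (one row per negatively correlated target family).
#' @param mirna_regulation_table data.frame with columns `mirna_id`,
#'   `regulation` (`"up"`/`"down"`); every miRNA appearing in an edge must
#'   be listed.
#' @return directed igraph with vertex attributes `kind`
#'   (`"miRNA"`/`"TF_family"`), `regulation` (miRNA nodes), `tf_role`
#'   (`"upstream_only"`/`"target_only"`/`"both"` for TF nodes) and edge
#'   attribute `kind`.
#' @export
build_network <- function(tf_mirna_table, mirna_target_table,
                          mirna_regulation_table) {
  up <- unique(data.frame(
    source = tf_mirna_table$tf_family,
    dest = tf_mirna_table$mirna_id,
    kind = rep("TF_to_miRNA", nrow(tf_mirna_table)),
    stringsAsFactors = FALSE))
  dn <- unique(data.frame(
    source = mirna_target_table$mirna_id,
    dest = mirna_target_table$tf_family,
    kind = rep("miRNA_to_target", nrow(mirna_target_table)),
    stringsAsFactors = FALSE))
  mirnas <- sort(unique(c(up$dest, dn$source)))
  families <- sort(unique(c(up$source, dn$dest)))
  if (length(intersect(mirnas, families)) > 0L) {
    stop("a node cannot be both a miRNA and a TF family: ",
         paste(intersect(mirnas, families), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(mirnas, mirna_regulation_table$mirna_id)
  if (length(missing) > 0L) {
    stop("miRNA(s) absent from the regulation table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  edges <- rbind(up, dn)
  tf_role <- vapply(families, function(f) {
    is_up <- f %in% up$source
    is_dn <- f %in% dn$dest
    if (is_up && is_dn) "both" else if (is_up) "upstream_only"
    else "target_only"
  }, character(1L))
  vertices <- data.frame(
    name = c(mirnas, families),
    kind = c(rep("miRNA", length(mirnas)),
             rep("TF_family", length(families))),
    regulation = c(mirna_regulation_table$regulation[
      match(mirnas, mirna_regulation_table$mirna_id)],
      rep(NA_character_, length(families))),
    tf_role = c(rep(NA_character_, length(mirnas)), tf_role),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  assert_bipartite_kinds(g)
  g
}

assert_bipartite_kinds <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(e) == 0L) return(invisible(TRUE))
  kind <- igraph::V(graph)$kind
  names(kind) <- igraph::V(graph)$name
  bad_up <- e$kind == "TF_to_miRNA" &
    !(kind[e$from] == "TF_family" & kind[e$to] == "miRNA")
  bad_dn <- e$kind == "miRNA_to_target" &
    !(kind[e$from] == "miRNA" & kind[e$to] == "TF_family")
  if (any(bad_up) || any(bad_dn)) {
    stop("edge-kind bipartiteness violated", call. = FALSE)
  }
  invisible(TRUE)
}

#' Family-level feedback loops
#'
#' Returns every (TF family, miRNA) pair connected in both directions: the
#' family has a binding site in the miRNA's promoter and is itself
#' targeted by that miRNA (a directed 2-cycle), sorted lexicographically.
#'
#' @param graph network built by [build_network()].
#' @return data.frame with columns `tf_family`, `mirna_id`.
#' @export
find_feedback_loops <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  up <- e[e$kind == "TF_to_miRNA", c("from", "to")]
  dn <- e[e$kind == "miRNA_to_target", c("from", "to")]
  key_up <- paste(up$from, up$to, sep = "\r")
  key_dn <- paste(dn$to, dn$from, sep = "\r")
  both <- intersect(key_up, key_dn)
  if (length(both) == 0L) {
    return(data.frame(tf_family = character(0), mirna_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(both, "\r", fixed = TRUE)
  out <- data.frame(tf_family = vapply(parts, `[`, "", 1L),
                    mirna_id = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tf_family, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a regulatory network
#'
#' miRNA families are derived from node names by the maximal
#' `miR<number>` prefix rule (see [mirna_family()]).
#'
#' @param graph network built by [build_network()].
#' @return named list of counts: nodes, edges, miRNA nodes, miRNA
#'   families, TF families (total and by role), feedback loops.
#' @export
summarize_network <- function(graph) {
  v <- igraph::as_data_frame(graph, what = "vertices")
  e <- igraph::as_data_frame(graph, what = "edges")
  mirnas <- v$name[v$kind == "miRNA"]
  tfs <- v[v$kind == "TF_family", , drop = FALSE]
  list(n_nodes = nrow(v),
       n_edges = nrow(e),
       n_mirna_nodes = length(mirnas),
       n_mirna_families = length(unique(mirna_family(mirnas))),
       n_tf_families = nrow(tfs),
       n_tf_upstream_only = sum(tfs$tf_role == "upstream_only"),
       n_tf_target_only = sum(tfs$tf_role == "target_only"),
       n_tf_both = sum(tfs$tf_role == "both"),
       n_feedback_loops = nrow(find_feedback_loops(graph)))
}
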