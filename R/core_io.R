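#' Read sequence records from FASTA or FASTQ
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Sequences
#' are returned exactly as written (U and T both accepted and preserved);
#' downstream matching normalizes to DNA space. Records must have a
#' non-empty id and a sequence drawn from A/C/G/T/U/N (case-insensitive);
#' FASTQ qualities must match the sequence length.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return data.frame with columns `id`, `seq`, `quality` (NA for FASTA).
#'   An empty file yields a zero-row data.frame.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    blank_id <- which(grepl("^>\\s*$", lines))
    if (length(blank_id) > 0L) {
      stop("parse error at line ", blank_id[1L],
           ": FASTA header with blank id", call. = FALSE)
    }
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    out <- data.frame(id = as.character(names(set)),
                      seq = as.character(set),
                      quality = rep(NA_character_, length(set)),
                      stringsAsFactors = FALSE)
  } else {
    out <- tryCatch({
      set <- Biostrings::readBStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      qual <- as.character(S4Vectors::mcols(set)$qualities)
      data.frame(id = as.character(names(set)),
                 seq = as.character(set),
                 quality = if (length(set)) qual else character(0),
                 stringsAsFactors = FALSE)
    }, error = function(e) stop("parse error in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    badq <- which(nchar(out$quality) != nchar(out$seq))
    if (length(badq) > 0L) {
      stop("parse error: quality length differs from sequence length for ",
           "record ", badq[1L], " (", out$id[badq[1L]], ")", call. = FALSE)
    }
  }
  rownames(out) <- NULL
  if (nrow(out) == 0L) return(out)
  # keep only the first whitespace-delimited token of the description
  out$id <- sub("\\s.*$", "", out$id)
  if (any(out$id == "")) {
    stop("parse error: record with empty id", call. = FALSE)
  }
  bad <- grepl("[^ACGTUNacgtun]", out$seq)
  if (any(bad)) {
    stop("parse error: record '", out$id[bad][1L],
         "' contains characters outside {A,C,G,T,U,N}", call. = FALSE)
  }
  out
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id` and `seq` columns, or a named
#'   character vector.
#' @param path output path.
#' @export
write_sequences <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  writeLines(paste0(">", records$id, "\n", records$seq), path)
  invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Accepts the JASPAR PFM text dialect: a `>motif_id name` header followed
#' by four rows in A, C, G, T order, either bare numbers or the bracketed
#' `A [ 3 1 0 ... ]` style. For count matrices all column sums must agree
#' within integer tolerance. TF families are attached from a metadata table
#' (columns `motif_id`, `tf_family`).
#'
#' @param path PFM text file.
#' @param metadata optional data.frame (or TSV path) mapping `motif_id` to
#'   `tf_family` (and optionally `tf_name`).
#' @return list of PWM objects: `motif_id`, `tf_name`, `tf_family`,
#'   `matrix` (4 x L, rows A/C/G/T).
#' @export
read_pwms <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(metadata)) metadata <- read_tsv_table(metadata)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L && length(lines) > 0L) {
    stop("parse error: no '>' motif headers found in ", path, call. = FALSE)
  }
  pwms <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    rows <- lines[from:to]
    if (length(rows) != 4L) {
      stop("parse error: motif ", lines[hdr[i]], " has ", length(rows),
           " matrix rows (expected 4: A, C, G, T)", call. = FALSE)
    }
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    if (anyNA(unlist(vals))) {
      stop("parse error: non-numeric matrix cell in motif ",
           lines[hdr[i]], call. = FALSE)
    }
    widths <- lengths(vals)
    if (length(unique(widths)) != 1L) {
      stop("parse error: rows of unequal width in motif ",
           lines[hdr[i]], call. = FALSE)
    }
    mat <- do.call(rbind, vals)
    rownames(mat) <- c("A", "C", "G", "T")
    if (any(mat < 0)) {
      stop("parse error: negative cell in motif ", lines[hdr[i]],
           call. = FALSE)
    }
    if (ncol(mat) < 4L) {
      stop("motif ", lines[hdr[i]], " is too narrow (width < 4)",
           call. = FALSE)
    }
    sums <- colSums(mat)
    if (all(mat == round(mat)) && max(sums) - min(sums) > 1 + 1e-9) {
      stop("parse error: count matrix with unequal column sums in motif ",
           lines[hdr[i]], call. = FALSE)
    }
    toks <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1L]]
    motif_id <- toks[1L]
    tf_name <- if (length(toks) > 1L) toks[2L] else motif_id
    tf_family <- NA_character_
    if (!is.null(metadata)) {
      hit <- match(motif_id, metadata$motif_id)
      if (!is.na(hit)) {
        tf_family <- metadata$tf_family[hit]
        if ("tf_name" %in% names(metadata)) tf_name <- metadata$tf_name[hit]
      }
    }
    pwms[[i]] <- new_pwm(motif_id, tf_name, tf_family, mat)
  }
  pwms
}

#' Construct a position weight matrix object
#'
#' @param motif_id,tf_name,tf_family identifiers.
#' @param matrix 4 x L non-negative matrix, rows A/C/G/T.
#' @return a `hypoxamir_pwm` list.
#' @export
new_pwm <- function(motif_id, tf_name, tf_family, matrix) {
  stopifnot(nrow(matrix) == 4L, ncol(matrix) >= 4L, all(matrix >= 0))
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_name = tf_name,
                 tf_family = tf_family, matrix = matrix),
            class = "hypoxamir_pwm")
}

#' Normalize a PFM into per-column probabilities
#'
#' Adds a pseudocount to every cell and rescales each column to sum to 1.
#'
#' @param pwm a `hypoxamir_pwm` (or bare 4 x L matrix).
#' @param pseudocount added to each cell before normalization.
#' @return matrix of column-stochastic probabilities.
#' @export
normalize_pwm <- function(pwm, pseudocount = 0) {
  mat <- if (inherits(pwm, "hypoxamir_pwm")) pwm$matrix else pwm
  mat <- mat + pseudocount
  sweep(mat, 2L, colSums(mat), "/")
}

#' Write a tab-separated result table
#'
#' Canonical table dialect: tab-separated, single '#'-prefixed header line,
#' UTF-8, '.' decimal separator.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- strsplit(sub("^#", "", first), "\t")[[1L]]
  df <- read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "",
                   quote = "", encoding = "UTF-8",
                   col.names = header,
                   check.names = FALSE)
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                 header), check.names = FALSE)
  }
  df
}

#' Read a BED-like TSS table
#'
#' Columns: `chrom`, `tss_pos` (0-based), `strand`, `gene_id`.
#'
#' @param path input TSV.
#' @return data.frame with the four columns above.
#' @export
read_tss <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "tss_pos", "strand", "gene_id")
  if (!all(need %in% names(df))) {
    stop("TSS table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  }
  df$tss_pos <- as.integer(df$tss_pos)
  df
}

network_edge_table <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(e) == 0L) {
    return(data.frame(source = character(0), kind = character(0),
                      dest = character(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(source = e$from, kind = e$kind, dest = e$to,
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Write a regulatory network to disk
#'
#' Supported interchange formats: SIF (`source<TAB>kind<TAB>dest`), a
#' minimal GraphML-style XML, and a headed TSV edge list. Duplicate edges
#' are written once; node and edge kinds survive a round trip through
#' [read_network()].
#'
#' @param graph igraph object with vertex attribute `kind` and edge
#'   attribute `kind`.
#' @param path output path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  edges <- network_edge_table(graph)
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", edges$source, edges$kind, edges$dest),
               path)
  } else if (format == "tsv") {
    write_tsv_table(edges, path)
  } else {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml>',
               '  <graph edgedefault="directed">')
    kinds <- if (nrow(nodes) > 0L && "kind" %in% names(nodes)) {
      nodes$kind
    } else rep(NA_character_, nrow(nodes))
    lines <- c(lines, sprintf('    <node id="%s" kind="%s"/>',
                              esc(nodes$name), esc(kinds)))
    lines <- c(lines, sprintf(
      '    <edge source="%s" target="%s" kind="%s"/>',
      esc(edges$source), esc(edges$dest), esc(edges$kind)))
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a regulatory network written by [write_network()]
#'
#' @param path input path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return igraph object; edge attribute `kind` is restored (and vertex
#'   `kind` for GraphML input).
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    edges <- data.frame(source = vapply(parts, `[`, "", 1L),
                        kind = vapply(parts, `[`, "", 2L),
                        dest = vapply(parts, `[`, "", 3L),
                        stringsAsFactors = FALSE)
  } else if (format == "tsv") {
    edges <- read_tsv_table(path)
  } else {
    doc <- xml2::read_xml(path)
    enodes <- xml2::xml_find_all(doc, ".//edge")
    edges <- data.frame(
      source = xml2::xml_attr(enodes, "source"),
      kind = xml2::xml_attr(enodes, "kind"),
      dest = xml2::xml_attr(enodes, "target"),
      stringsAsFactors = FALSE)
    vnodes <- xml2::xml_find_all(doc, ".//node")
    vdf <- data.frame(name = xml2::xml_attr(vnodes, "id"),
                      kind = xml2::xml_attr(vnodes, "kind"),
                      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "dest", "kind")], directed = TRUE, vertices = vdf)
    return(g)
  }
  igraph::graph_from_data_frame(edges[, c("source", "dest", "kind")],
                                directed = TRUE)
}
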