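SEQ_ALPHABET <- c("A", "C", "G", "T", "U", "N")

#' Normalize a nucleotide sequence to DNA space
#'
#' Upper-cases and converts U to T so that reads, genome and catalog
#' sequences can be compared in a single alphabet. Characters outside
#' A/C/G/T/U/N are rejected.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector in the A/C/G/T/N alphabet.
#' @export
normalize_seq <- function(x, what = "sequence") {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  bad <- grepl("[^ACGTUN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,U,N}: ",
         x[bad][1L], call. = FALSE)
  }
  chartr("U", "T", x)
}

#' Reverse complement in DNA space
#'
#' @param x character vector (A/C/G/T/U/N; U is treated as T).
#' @return reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  x <- normalize_seq(x)
  vapply(x, function(s) {
    rc <- rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]])
    paste(rc, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# integer coding A=0 C=1 G=2 T=3, N (or anything else) = 4
seq_to_int <- function(s) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  ch <- strsplit(s, "")[[1L]]
  out <- unname(code[ch])
  out[is.na(out)] <- 4L
  out
}

# minimum Hamming distance between the shorter of (a, b) and all
# equal-length windows of the longer; Inf when either is empty
min_window_hamming <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(a) == 0L) return(Inf)
  d <- .hamming_scan_cpp(seq_to_int(b), seq_to_int(a))
  if (length(d) == 0L) return(Inf)
  min(d)
}

#' miRNA family from a gene or signature name
#'
#' The family is the maximal `miR<number>` (or `miRn<number>` for novel
#' candidates) prefix of the name after stripping a species prefix such as
#' `zma-`; names without such a prefix are their own family.
#'
#' @param x character vector of miRNA names, e.g. `"zma-miR159h"`.
#' @return character vector of family names.
#' @export
mirna_family <- function(x) {
  x <- sub("^[a-z]{3}-", "", as.character(x))
  m <- regmatches(x, regexpr("^miRn?[0-9]+", x))
  out <- x
  has <- grepl("^miRn?[0-9]+", x)
  out[has] <- m
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
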