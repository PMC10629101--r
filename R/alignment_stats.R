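## Per-marker sequence characteristics: site classification and GC content.

# Integer coding of unambiguous bases; everything else (gaps, IUPAC
# ambiguity codes) becomes NA and is excluded from site classification
# and distance computation.
.code_alignment <- function(aln) {
  mat <- if (inherits(aln, "labeled_alignment")) aln$seq else aln
  code <- matrix(NA_integer_, nrow = nrow(mat), ncol = ncol(mat),
                 dimnames = list(rownames(mat), NULL))
  code[mat == "A"] <- 1L
  code[mat == "C"] <- 2L
  code[mat == "G"] <- 3L
  code[mat == "T"] <- 4L
  code
}

# 4 x L matrix of per-column base counts over unambiguous bases.
.base_counts <- function(code) {
  vapply(1:4, function(b) colSums(code == b, na.rm = TRUE),
         numeric(ncol(code)))
}

#' Classify alignment columns and summarise sequence characteristics
#'
#' Computes the per-marker summary used to compare candidate barcodes:
#' numbers of conserved, variable, parsimony-informative and singleton
#' sites, plus pooled GC content. Only unambiguous bases (`A`, `C`, `G`,
#' `T`) enter the classification; gap and ambiguity characters are ignored,
#' and a column with fewer than two usable rows is counted neither as
#' conserved nor as variable.
#'
#' Definitions, per column over the usable rows:
#' * conserved: exactly one state present (in at least two rows);
#' * variable: at least two states present;
#' * parsimony-informative: at least two states each present in at least two
#'   sequences;
#' * singleton: variable but not parsimony-informative.
#'
#' @param aln A [labeled_alignment()] with at least two sequences.
#' @return A list of class `site_stats`: `n_sequences`, `aligned_length`,
#'   `n_conserved`, `n_variable`, `n_informative`, `n_singleton`,
#'   `gc_ratio` (percent).
#' @export
classify_sites <- function(aln) {
  code <- .code_alignment(aln)
  if (nrow(code) < 2L)
    stop("site classification needs at least 2 sequences", call. = FALSE)
  counts <- .base_counts(code)          # L x 4 after vapply
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  usable <- rowSums(counts)
  n_states <- rowSums(counts > 0)
  n_states_ge2 <- rowSums(counts >= 2)

  scored <- usable >= 2
  conserved <- scored & n_states == 1
  variable <- scored & n_states >= 2
  informative <- variable & n_states_ge2 >= 2
  singleton <- variable & !informative

  structure(list(
    n_sequences = nrow(code),
    aligned_length = ncol(code),
    n_conserved = sum(conserved),
    n_variable = sum(variable),
    n_informative = sum(informative),
    n_singleton = sum(singleton),
    gc_ratio = gc_ratio(aln)
  ), class = "site_stats")
}

#' @export
print.site_stats <- function(x, ...) {
  cat(sprintf(
    "<site_stats> n=%d length=%d conserved=%d variable=%d informative=%d singleton=%d GC=%.2f%%\n",
    x$n_sequences, x$aligned_length, x$n_conserved, x$n_variable,
    x$n_informative, x$n_singleton, x$gc_ratio))
  invisible(x)
}

#' GC content of an alignment
#'
#' Percentage of G+C among unambiguous bases pooled over the whole matrix
#' (not averaged per sequence); gaps and ambiguity codes are excluded.
#'
#' @param aln A [labeled_alignment()] or character matrix.
#' @return GC percentage in `[0, 100]`.
#' @export
gc_ratio <- function(aln) {
  code <- .code_alignment(aln)
  n_base <- sum(!is.na(code))
  if (n_base == 0L)
    stop("no unambiguous bases; GC undefined", call. = FALSE)
  100 * sum(code == 2L | code == 3L, na.rm = TRUE) / n_base
}
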