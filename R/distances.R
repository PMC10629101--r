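## Kimura two-parameter distances, group summaries and barcoding-gap
## assessment.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Compares only columns where both sequences carry an unambiguous base
#' (pairwise deletion of gaps and ambiguity codes). With `P` the proportion
#' of transitions and `Q` the proportion of transversions over the compared
#' sites, the distance is
#' \deqn{d = -\tfrac{1}{2}\,\ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).}
#' The pair is flagged invalid when fewer than `min_overlap` sites are
#' comparable or when a log argument is non-positive (substitution
#' saturation); invalid pairs carry `NA` as distance.
#'
#' @param seq1,seq2 Character strings or single-character vectors of equal
#'   length (aligned).
#' @param min_overlap Minimum number of comparable sites for a valid
#'   distance (default 50).
#' @return A list with `distance` (substitutions/site or `NA`), `valid`
#'   (logical), and `n_sites` (comparable sites).
#' @export
k2p_distance <- function(seq1, seq2, min_overlap = 50) {
  to_chars <- function(s) {
    if (length(s) == 1L && nchar(s) > 1L) strsplit(toupper(s), "")[[1L]]
    else toupper(s)
  }
  a <- to_chars(seq1); b <- to_chars(seq2)
  if (length(a) != length(b))
    stop("sequences must have equal length", call. = FALSE)
  code <- .code_alignment(rbind(a, b))
  ok <- !is.na(code[1L, ]) & !is.na(code[2L, ])
  x <- code[1L, ok]; y <- code[2L, ok]
  n <- length(x)
  if (n < min_overlap)
    return(list(distance = NA_real_, valid = FALSE, n_sites = n))
  # transitions: A<->G (1,3), C<->T (2,4); purines odd codes, pyrimidines even
  diff <- x != y
  ts <- diff & (x %% 2L == y %% 2L)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(distance = NA_real_, valid = FALSE, n_sites = n))
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), valid = TRUE, n_sites = n)
}

#' Pairwise K2P distance matrix for a labeled alignment
#'
#' Evaluates [k2p_distance()] for every unordered sample pair, using matrix
#' cross-products over base-indicator matrices so large alignments and
#' bootstrap replicates stay fast.
#'
#' @param aln A [labeled_alignment()] with at least two samples, or a
#'   character matrix of aligned sequences.
#' @param min_overlap Minimum comparable sites per pair (default 50).
#' @return An object of class `k2p_matrix`: list with `sample_ids`,
#'   `d` (symmetric numeric matrix, `NA` where invalid), `valid`
#'   (symmetric logical), and `n_invalid_pairs`.
#' @export
pairwise_matrix <- function(aln, min_overlap = 50) {
  code <- .code_alignment(aln)
  n <- nrow(code)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  ids <- rownames(code)

  ind <- lapply(1:4, function(b) {
    m <- (code == b); m[is.na(m)] <- FALSE; m * 1
  })
  usable <- Reduce(`+`, ind)
  comparable <- usable %*% t(usable)
  matches <- Reduce(`+`, lapply(ind, function(m) m %*% t(m)))
  transitions <- ind[[1]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[1]]) +
    ind[[2]] %*% t(ind[[4]]) + ind[[4]] %*% t(ind[[2]])

  P <- transitions / comparable
  Q <- (comparable - matches - transitions) / comparable
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  valid <- comparable >= min_overlap & w1 > 0 & w2 > 0
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  d[valid] <- -0.5 * log(w1[valid]) - 0.25 * log(w2[valid])
  diag(d) <- 0
  diag(valid) <- TRUE
  dimnames(valid) <- dimnames(d)

  structure(list(
    sample_ids = ids, d = d, valid = valid,
    n_invalid_pairs = sum(!valid[upper.tri(valid)])
  ), class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat("<k2p_matrix>", length(x$sample_ids), "samples;",
      x$n_invalid_pairs, "invalid pairs\n")
  invisible(x)
}

# Valid unordered pairs split into intra-/interspecific sets.
.pair_sets <- function(dm, labels) {
  ids <- dm$sample_ids
  labels <- labels[ids]
  if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  ut <- upper.tri(dm$d)
  i <- row(dm$d)[ut]; j <- col(dm$d)[ut]
  ok <- dm$valid[ut]
  same <- labels[i] == labels[j]
  list(
    intra = data.frame(i = i[ok & same], j = j[ok & same],
                       d = dm$d[ut][ok & same],
                       species = labels[i[ok & same]],
                       stringsAsFactors = FALSE),
    inter = data.frame(i = i[ok & !same], j = j[ok & !same],
                       d = dm$d[ut][ok & !same], stringsAsFactors = FALSE),
    n_invalid = sum(!ok)
  )
}

.se <- function(x) if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else 0

#' Group distance summary for one marker
#'
#' Summarises a K2P distance matrix into the usual barcoding quantities:
#' * `mean_inter`: mean over valid between-species pairs (+- SE over pairs);
#' * `mean_intra`: mean over valid within-species pairs, pooled;
#' * `theta`: per-species mean intraspecific distance, averaged across
#'   species (+- SE over species means);
#' * `coalescence_depth`: per-species maximum intraspecific distance,
#'   averaged across species (+- SE over species maxima).
#'
#' Species with fewer than two sampled sequences contribute nothing to the
#' intraspecific quantities. Standard errors are analytic over the pair (or
#' species) sets; pairwise distances are not independent, so these SEs are
#' an approximation in the style of the usual reporting convention.
#'
#' @param dm A `k2p_matrix` from [pairwise_matrix()].
#' @param labels Named character vector of species per sample id, e.g.
#'   [species_labels()].
#' @return A list of class `group_distance_summary` with entries
#'   `mean_inter`, `mean_intra`, `theta`, `coalescence_depth` (each a
#'   `c(estimate, se)` vector), `per_species` (data frame of species means
#'   and maxima), and pair counts.
#' @export
group_distance_summary <- function(dm, labels) {
  ps <- .pair_sets(dm, labels)
  if (nrow(ps$inter) == 0L)
    stop("no valid interspecific pairs; summary undefined", call. = FALSE)

  intra <- ps$intra
  sp_means <- sp_max <- numeric(0)
  if (nrow(intra)) {
    sp_means <- tapply(intra$d, intra$species, mean)
    sp_max <- tapply(intra$d, intra$species, max)
  }
  est <- function(x, se) c(estimate = x, se = se)
  structure(list(
    mean_inter = est(mean(ps$inter$d), .se(ps$inter$d)),
    mean_intra = if (nrow(intra)) est(mean(intra$d), .se(intra$d))
                 else est(NA_real_, NA_real_),
    theta = if (length(sp_means)) est(mean(sp_means), .se(as.numeric(sp_means)))
            else est(NA_real_, NA_real_),
    coalescence_depth = if (length(sp_max))
      est(mean(sp_max), .se(as.numeric(sp_max))) else est(NA_real_, NA_real_),
    per_species = if (length(sp_means))
      data.frame(species = names(sp_means),
                 mean_intra = as.numeric(sp_means),
                 max_intra = as.numeric(sp_max), stringsAsFactors = FALSE)
    else data.frame(species = character(0), mean_intra = numeric(0),
                    max_intra = numeric(0)),
    n_inter_pairs = nrow(ps$inter),
    n_intra_pairs = nrow(intra),
    n_invalid_pairs = ps$n_invalid
  ), class = "group_distance_summary")
}

#' @export
print.group_distance_summary <- function(x, ...) {
  f <- function(v) sprintf("%.4f +- %.4f", v[1], v[2])
  cat("<group_distance_summary>\n",
      " inter:", f(x$mean_inter), sprintf("(%d pairs)\n", x$n_inter_pairs),
      " intra:", f(x$mean_intra), sprintf("(%d pairs)\n", x$n_intra_pairs),
      " theta:", f(x$theta), "\n",
      " depth:", f(x$coalescence_depth), "\n")
  invisible(x)
}

#' Barcoding-gap assessment
#'
#' Builds fixed-width histograms of the intra- and interspecific distance
#' distributions and reports whether a barcoding gap is present, defined as
#' the minimum interspecific distance exceeding the maximum intraspecific
#' distance. When the distributions overlap, the overlap interval
#' `[min_inter, max_intra]` is reported.
#'
#' @param dm A `k2p_matrix`.
#' @param labels Named species vector per sample id.
#' @param bin_width Histogram bin width (substitutions/site); left-closed
#'   bins starting at 0. Default 0.005.
#' @return A list of class `gap_assessment`: `intra_histogram` and
#'   `inter_histogram` (data frames of `bin_left`, `count`), `max_intra`,
#'   `min_inter`, `gap_present`, `overlap_interval` (or `NULL`).
#' @export
barcoding_gap <- function(dm, labels, bin_width = 0.005) {
  ps <- .pair_sets(dm, labels)
  if (nrow(ps$intra) == 0L)
    stop("no valid intraspecific pairs; barcoding gap undefined",
         call. = FALSE)
  if (nrow(ps$inter) == 0L)
    stop("no valid interspecific pairs; barcoding gap undefined",
         call. = FALSE)
  histo <- function(x) {
    upper <- max(x, bin_width)
    breaks <- seq(0, (floor(upper / bin_width) + 1) * bin_width,
                  by = bin_width)
    idx <- pmin(floor(x / bin_width) + 1L, length(breaks) - 1L)
    data.frame(bin_left = breaks[-length(breaks)],
               count = tabulate(idx, nbins = length(breaks) - 1L))
  }
  max_intra <- max(ps$intra$d)
  min_inter <- min(ps$inter$d)
  gap <- min_inter > max_intra
  structure(list(
    intra_histogram = histo(ps$intra$d),
    inter_histogram = histo(ps$inter$d),
    max_intra = max_intra, min_inter = min_inter,
    gap_present = gap,
    overlap_interval = if (gap) NULL else c(min_inter, max_intra)
  ), class = "gap_assessment")
}

#' @export
print.gap_assessment <- function(x, ...) {
  cat("<gap_assessment> max_intra =", format(x$max_intra, digits = 4),
      "min_inter =", format(x$min_inter, digits = 4),
      "gap:", x$gap_present, "\n")
  invisible(x)
}
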