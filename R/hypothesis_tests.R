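## Wilcoxon signed-rank comparison of interspecific distance vectors
## between markers.

#' Pair interspecific distances of two markers by sample-pair identity
#'
#' The paired observation unit is an interspecific sample pair (i, j): the
#' pair contributes one observation per marker, namely its K2P distance in
#' that marker. Only pairs present and valid in both matrices are used.
#'
#' @param dmA,dmB `k2p_matrix` objects for the two markers.
#' @param labels Named species vector covering the samples of both matrices.
#' @return List with numeric vectors `x` (marker A), `y` (marker B),
#'   `pair_ids` (character `"id1|id2"`), and `n`.
#' @export
pair_marker_distances <- function(dmA, dmB, labels) {
  shared <- intersect(dmA$sample_ids, dmB$sample_ids)
  if (length(shared) < 2L)
    stop("no shared samples between markers", call. = FALSE)
  sp <- labels[shared]
  if (anyNA(sp)) stop("labels missing for some shared samples", call. = FALSE)
  pairs <- utils::combn(shared, 2L)
  inter <- sp[pairs[1L, ]] != sp[pairs[2L, ]]
  pairs <- pairs[, inter, drop = FALSE]
  if (ncol(pairs) == 0L)
    stop("no shared interspecific pairs", call. = FALSE)
  ok <- dmA$valid[cbind(pairs[1L, ], pairs[2L, ])] &
        dmB$valid[cbind(pairs[1L, ], pairs[2L, ])]
  pairs <- pairs[, ok, drop = FALSE]
  if (ncol(pairs) == 0L)
    stop("no shared valid interspecific pairs", call. = FALSE)
  idx <- cbind(pairs[1L, ], pairs[2L, ])
  list(x = dmA$d[idx], y = dmB$d[idx],
       pair_ids = paste(pairs[1L, ], pairs[2L, ], sep = "|"),
       n = ncol(pairs))
}

#' Wilcoxon signed-rank test
#'
#' Tests whether the paired vectors `x` and `y` differ in location.
#' Differences `d = x - y` equal to zero are dropped (their count is
#' reported); absolute differences are ranked with midranks for ties. When
#' the number of non-zero differences is at most 25 and the absolute
#' differences are tie-free, the two-sided p-value is exact (from the full
#' null distribution of the positive-rank sum); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param exact_max Largest `n` for which the exact distribution is used
#'   (default 25).
#' @return A list of class `wilcoxon_result`: `w_plus`, `w_minus`, `n`
#'   (non-zero differences), `n_zero_dropped`, `p_value` (two-sided),
#'   `method` (`"exact"` or `"normal-approximation"`), `direction`
#'   (`"x > y"`, `"x < y"` or `"x == y"`).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero; test undefined", call. = FALSE)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])

  has_ties <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max && !has_ties) {
    method <- "exact"
    # psignrank is the exact null CDF of W+ for tie-free ranks
    p <- 2 * min(stats::psignrank(w_plus, n),
                 1 - stats::psignrank(w_plus - 1, n))
    p <- min(p, 1)
  } else {
    method <- "normal-approximation"
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(w_plus - mu) * 0.5
    z <- (w_plus - mu - cc) / sqrt(sigma2)
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  structure(list(
    w_plus = w_plus, w_minus = w_minus, n = n, n_zero_dropped = n_zero,
    p_value = p, method = method,
    direction = if (w_plus > w_minus) "x > y"
                else if (w_plus < w_minus) "x < y" else "x == y"
  ), class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W+=%.2f W-=%.2f n=%d p=%.4g (%s) %s\n",
              x$w_plus, x$w_minus, x$n, x$p_value, x$method, x$direction))
  invisible(x)
}

#' Compare interspecific distances of two markers
#'
#' Convenience wrapper: pairs the interspecific distances of two markers by
#' sample-pair identity ([pair_marker_distances()]) and runs
#' [wilcoxon_signed_rank()]. An alternative `pairing = "sorted"` mode pairs
#' the sorted distance vectors instead (truncated to the shorter length),
#' for sensitivity analysis when the matched-pair rule is questioned.
#'
#' @param dmA,dmB `k2p_matrix` objects.
#' @param labels Named species vector.
#' @param markerA,markerB Names used in the verdict string.
#' @param pairing `"matched"` (default) or `"sorted"`.
#' @return A `wilcoxon_result` with an added `verdict` field like
#'   `"A > B"`.
#' @export
compare_marker_distances <- function(dmA, dmB, labels,
                                     markerA = "A", markerB = "B",
                                     pairing = c("matched", "sorted")) {
  pairing <- match.arg(pairing)
  if (pairing == "matched") {
    pv <- pair_marker_distances(dmA, dmB, labels)
    x <- pv$x; y <- pv$y
  } else {
    get_inter <- function(dm) sort(.pair_sets(dm, labels)$inter$d)
    x <- get_inter(dmA); y <- get_inter(dmB)
    m <- min(length(x), length(y))
    x <- x[seq_len(m)]; y <- y[seq_len(m)]
  }
  res <- wilcoxon_signed_rank(x, y)
  res$pairing <- pairing
  res$verdict <- if (res$direction == "x > y")
    paste(markerA, ">", markerB)
  else if (res$direction == "x < y") paste(markerA, "<", markerB)
  else paste(markerA, "~", markerB)
  res
}
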