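## Neighbor-joining, column-resampling bootstrap, and the species-monophyly
## success criterion.

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei agglomeration using the Studier-Keppler criterion
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j`. Ties on the minimum of `Q` are
#' broken deterministically on the lowest `(i, j)` index pair in the current
#' taxon ordering. Negative branch lengths are clamped to zero with the
#' excess transferred to the adjacent (sibling) branch, preserving the
#' distance between the joined taxa. The result is an unrooted tree.
#'
#' @param dm A `k2p_matrix` from [pairwise_matrix()] (all pairs must be
#'   valid), or a plain symmetric numeric matrix with dimnames.
#' @return An [ape::phylo] object with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "k2p_matrix")) {
    if (any(!dm$valid))
      stop("distance matrix has invalid pairs; prune those samples first",
           call. = FALSE)
    d <- dm$d
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 samples for a tree", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active cluster carried as a Newick fragment
  frags <- labels
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (i, j) among ties, scanning column-major upper triangle
    Q[lower.tri(Q)] <- Inf
    idx <- which(Q == min(Q))
    sel <- idx[1L]
    i <- (sel - 1L) %% n + 1L
    j <- (sel - 1L) %/% n + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }

    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }

    new_frag <- paste0("(", frags[i], ":", fmt(vi), ",",
                       frags[j], ":", fmt(vj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    frags <- c(frags[keep], new_frag)
    rownames(d_new) <- colnames(d_new) <- NULL
    d <- d_new
    n <- n - 1L
  }
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", frags[1], ":", fmt(va), ",", frags[2], ":", fmt(vb),
                ",", frags[3], ":", fmt(vc), ");")
  ape::read.tree(text = txt)
}

# Canonical non-trivial bipartitions of an unrooted tree, keyed by the tip
# set on the side NOT containing the lexicographically smallest tip label.
tree_bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1L]
  parts <- ape::prop.part(phy)
  keys <- character(0)
  for (p in parts) {
    side <- phy$tip.label[p]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P matrix
#' and NJ tree per replicate, and scores each internal edge of the original
#' tree by the percentage of replicates whose tree contains the same
#' bipartition. Replicates whose distance matrix contains an invalid pair
#' are dropped (and counted); support is over the retained replicates.
#'
#' @param aln A [labeled_alignment()] valid for distance computation.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param min_overlap Passed to [pairwise_matrix()].
#' @return A list of class `bootstrap_tree`: `tree` (the original NJ tree
#'   with integer percent supports in `node.label`; the root label is
#'   empty), `support` (named vector keyed by bipartition), `n_used`,
#'   `n_dropped`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000, seed = 1,
                              min_overlap = 50) {
  dm <- pairwise_matrix(aln, min_overlap = min_overlap)
  if (any(!dm$valid))
    stop("original alignment yields invalid pairs; prune samples first",
         call. = FALSE)
  tree <- neighbor_joining(dm)
  keys <- tree_bipartition_keys(tree)
  counts <- stats::setNames(numeric(length(keys)), keys)

  set.seed(seed)
  n_used <- 0L
  L <- aln$length
  for (rep in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- aln
    boot$seq <- aln$seq[, cols, drop = FALSE]
    bdm <- pairwise_matrix(boot, min_overlap = min(min_overlap, L))
    if (any(!bdm$valid)) next
    btree <- neighbor_joining(bdm)
    bkeys <- tree_bipartition_keys(btree)
    hit <- keys %in% bkeys
    counts[hit] <- counts[hit] + 1
    n_used <- n_used + 1L
  }
  support <- if (n_used > 0L) 100 * counts / n_used else counts * NA_real_

  # attach supports as internal node labels
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  tips_sorted <- sort(tree$tip.label)
  ref <- tips_sorted[1L]
  labs <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- tree$tip.label[parts[[k]]]
    if (ref %in% side) side <- setdiff(tips_sorted, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) labs[k] <- sprintf("%d", round(support[key]))
  }
  tree$node.label <- labs

  structure(list(tree = tree, support = support,
                 n_used = n_used, n_dropped = n_replicates - n_used),
            class = "bootstrap_tree")
}

#' @export
print.bootstrap_tree <- function(x, ...) {
  cat("<bootstrap_tree>", length(x$tree$tip.label), "tips;",
      x$n_used, "replicates used,", x$n_dropped, "dropped\n")
  invisible(x)
}

#' Is a species monophyletic on an unrooted tree?
#'
#' True when some bipartition of the unrooted tree places exactly the
#' species' samples on one side. A species with a single sample (or with all
#' but one of the tree's leaves) is trivially monophyletic.
#'
#' @param tree An [ape::phylo] object or a `bootstrap_tree`.
#' @param labels Named species vector per sample id.
#' @param species The species to test.
#' @return Logical.
#' @export
is_species_monophyletic <- function(tree, labels, species) {
  if (inherits(tree, "bootstrap_tree")) tree <- tree$tree
  tips <- tree$tip.label
  mine <- tips[labels[tips] == species]
  if (length(mine) == 0L)
    stop("species ", species, " absent from tree", call. = FALSE)
  if (length(mine) <= 1L || length(mine) >= length(tips) - 1L) return(TRUE)
  ref <- sort(tips)[1L]
  side <- if (ref %in% mine) setdiff(tips, mine) else mine
  key <- paste(sort(side), collapse = "|")
  key %in% tree_bipartition_keys(tree)
}
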