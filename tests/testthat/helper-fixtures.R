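# Shared fixtures and independent oracles, built in code.

# Quick two-species labeled alignment from sequence strings.
toy_aln <- function(seqs, species, ids = NULL, genus = "Genus",
                    marker = "toy") {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  meta <- data.frame(sample_id = ids, species = species, genus = genus,
                     origin = "test", stringsAsFactors = FALSE)
  labeled_alignment(setNames(seqs, ids), meta, marker = marker)
}

# Independent K2P oracle: direct per-site loop, no shared code with the
# package's matrix implementation.
k2p_oracle <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  pur <- c("A", "G"); pyr <- c("C", "T")
  n <- ts <- tv <- 0
  for (k in seq_along(a)) {
    if (!a[k] %in% c(pur, pyr) || !b[k] %in% c(pur, pyr)) next
    n <- n + 1
    if (a[k] == b[k]) next
    same_class <- (a[k] %in% pur && b[k] %in% pur) ||
      (a[k] %in% pyr && b[k] %in% pyr)
    if (same_class) ts <- ts + 1 else tv <- tv + 1
  }
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Exact Wilcoxon signed-rank oracle: full enumeration of the 2^n sign
# assignments of the ranked absolute differences.
wsr_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  list(w_plus = w_obs, p = min(p, 1))
}

# Random aligned sequence with optional gap/ambiguity characters.
random_seq <- function(len, gap_frac = 0, seed_chars = c("A", "C", "G", "T")) {
  chars <- sample(seed_chars, len, replace = TRUE)
  if (gap_frac > 0) {
    k <- rbinom(1, len, gap_frac)
    if (k > 0) chars[sample(len, k)] <- sample(c("-", "N"), k, replace = TRUE)
  }
  paste(chars, collapse = "")
}
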