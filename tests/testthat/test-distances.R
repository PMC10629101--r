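test_that("k2p_distance matches the closed form and flags saturation", {
  # P = 0.25, Q = 0: d = -0.5 ln(0.5)
  r <- k2p_distance("AAAA", "AAAG", min_overlap = 1)
  expect_equal(r$distance, -0.5 * log(0.5), tolerance = 1e-12)
  expect_true(r$valid)

  # 100 sites with 10 transitions, 5 transversions: P=0.1, Q=0.05
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  r2 <- k2p_distance(s1, s2, min_overlap = 50)
  expect_equal(r2$distance, -0.5 * log(0.75) - 0.25 * log(0.9),
               tolerance = 1e-12)
  expect_equal(r2$distance, 0.170181, tolerance = 1e-6)

  # saturation: P = 0.5, Q = 0 -> log argument <= 0
  s3 <- paste0(strrep("G", 50), strrep("A", 50))
  r3 <- k2p_distance(s1, s3, min_overlap = 50)
  expect_false(r3$valid)
  expect_true(is.na(r3$distance))

  # pairwise deletion and the min_overlap rule
  r4 <- k2p_distance("ACGT-N", "ACGAN-", min_overlap = 3)
  expect_equal(r4$n_sites, 4L)
  r5 <- k2p_distance("ACGT-N", "ACGAN-", min_overlap = 5)
  expect_false(r5$valid)

  expect_error(k2p_distance("ACGT", "ACG"), "equal length")
})

test_that("pairwise_matrix agrees with per-pair oracle and is symmetric", {
  set.seed(21)
  seqs <- replicate(8, random_seq(120, gap_frac = 0.05))
  aln <- toy_aln(seqs, rep(c("sp1", "sp2"), each = 4))
  dm <- pairwise_matrix(aln, min_overlap = 50)
  expect_identical(dm$d, t(dm$d))
  expect_identical(dm$valid, t(dm$valid))
  expect_equal(unname(diag(dm$d)), rep(0, 8))
  for (i in 1:7) for (j in (i + 1):8) {
    oracle <- k2p_oracle(seqs[i], seqs[j])
    if (is.na(oracle)) expect_false(dm$valid[i, j])
    else expect_equal(unname(dm$d[i, j]), oracle, tolerance = 1e-12)
  }
  # identical sequences give a zero matrix
  dm0 <- pairwise_matrix(toy_aln(rep(strrep("ACGT", 30), 3),
                                 c("a", "a", "b")), min_overlap = 10)
  expect_true(all(dm0$d == 0))
})

test_that("pairwise_matrix matches ape::dist.dna on gap-free data", {
  set.seed(22)
  ds <- simulate_dataset(marker_spec("m", 400, 0.03, 0.01), 5, seed = 9)
  aln <- ds$alignments$m
  dm <- pairwise_matrix(aln)
  bin <- ape::as.DNAbin(lapply(
    setNames(seq_len(nrow(aln$seq)), sample_ids(aln)),
    function(i) tolower(aln$seq[i, ])))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[sample_ids(aln), sample_ids(aln)]),
               tolerance = 1e-10)
})

test_that("group summaries follow the stated definitions", {
  # two species, intra 0 within, inter constant
  aln <- toy_aln(c(strrep("A", 60), strrep("A", 60),
                   paste0(strrep("G", 3), strrep("A", 57)),
                   paste0(strrep("G", 3), strrep("A", 57))),
                 c("sp1", "sp1", "sp2", "sp2"))
  dm <- pairwise_matrix(aln, min_overlap = 10)
  gs <- group_distance_summary(dm, species_labels(aln))
  expect_equal(unname(gs$mean_intra["estimate"]), 0)
  expect_gt(unname(gs$mean_inter["estimate"]), 0)
  expect_equal(unname(gs$theta["estimate"]), 0)
  expect_equal(unname(gs$coalescence_depth["estimate"]), 0)
  expect_equal(gs$n_inter_pairs, 4L)
  expect_equal(gs$n_intra_pairs, 2L)

  # theta/depth ignore species without intraspecific pairs
  d <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  intra <- c(0.01, 0.02, 0.03)  # pairs ab, ac, bc of species A
  d["a", "b"] <- d["b", "a"] <- 0.01
  d["a", "c"] <- d["c", "a"] <- 0.02
  d["b", "c"] <- d["c", "b"] <- 0.03
  d[1:3, 4:5] <- 0.1; d[4:5, 1:3] <- 0.1; d["d", "e"] <- d["e", "d"] <- 0.1
  dm2 <- list(sample_ids = letters[1:5], d = d,
              valid = matrix(TRUE, 5, 5, dimnames = dimnames(d)),
              n_invalid_pairs = 0L)
  class(dm2) <- "k2p_matrix"
  labels <- setNames(c("A", "A", "A", "B", "E"), letters[1:5])
  gs2 <- group_distance_summary(dm2, labels)
  expect_equal(unname(gs2$theta["estimate"]), mean(intra))
  expect_equal(unname(gs2$coalescence_depth["estimate"]), max(intra))

  expect_error(
    group_distance_summary(dm2, setNames(rep("A", 5), letters[1:5])),
    "interspecific")
})

test_that("group summary equals brute-force re-averaging on small instances", {
  set.seed(23)
  for (rep in 1:5) {
    ds <- simulate_dataset(marker_spec("m", 300, 0.02, 0.01), 4,
                           seed = 100 + rep)
    aln <- ds$alignments$m
    dm <- pairwise_matrix(aln)
    sp <- species_labels(aln)
    gs <- group_distance_summary(dm, sp)
    ids <- sample_ids(aln)
    inter <- intra <- c()
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      dij <- dm$d[ids[i], ids[j]]
      if (sp[ids[i]] == sp[ids[j]]) intra <- c(intra, dij)
      else inter <- c(inter, dij)
    }
    expect_equal(unname(gs$mean_inter["estimate"]), mean(inter))
    expect_equal(unname(gs$mean_intra["estimate"]), mean(intra))
  }
})

test_that("barcoding gap verdict and histograms behave", {
  mk <- function(intra_d, inter_d) {
    n <- 4
    d <- matrix(inter_d, n, n,
                dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
    diag(d) <- 0
    d[1, 2] <- d[2, 1] <- intra_d[1]
    d[3, 4] <- d[4, 3] <- intra_d[2]
    structure(list(sample_ids = rownames(d), d = d,
                   valid = matrix(TRUE, n, n, dimnames = dimnames(d)),
                   n_invalid_pairs = 0L), class = "k2p_matrix")
  }
  labels <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))

  g1 <- barcoding_gap(mk(c(0.004, 0.008), 0.025), labels)
  expect_true(g1$gap_present)
  expect_null(g1$overlap_interval)
  expect_equal(g1$max_intra, 0.008)
  expect_equal(g1$min_inter, 0.025)
  expect_equal(sum(g1$intra_histogram$count), 2)
  expect_equal(sum(g1$inter_histogram$count), 4)

  g2 <- barcoding_gap(mk(c(0.05, 0.01), 0.02), labels)
  expect_false(g2$gap_present)
  expect_equal(g2$overlap_interval, c(0.02, 0.05))

  # adding an inter pair below max_intra can only destroy a gap
  dm3 <- mk(c(0.004, 0.008), 0.025)
  dm3$d["s1", "s3"] <- dm3$d["s3", "s1"] <- 0.005
  g3 <- barcoding_gap(dm3, labels)
  expect_false(g3$gap_present)

  one_sp <- setNames(rep("A", 4), paste0("s", 1:4))
  expect_error(barcoding_gap(mk(c(0.1, 0.1), 0.2),
                             setNames(c("A", "B", "C", "D"),
                                      paste0("s", 1:4))),
               "intraspecific")
})
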