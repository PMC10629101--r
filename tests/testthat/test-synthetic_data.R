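test_that("evolution respects branch length zero and the K2P rate ratio", {
  set.seed(71)
  parent <- sample.int(4, 200, replace = TRUE)
  expect_identical(evolve_sequence(parent, 0), parent)
  expect_equal(evolve_sequence("ACGT", 0), "ACGT")

  # kappa = 1: transition count ~ half the transversion count (two
  # transversion targets per site)
  long <- sample.int(4, 1e5, replace = TRUE)
  child <- evolve_sequence(long, 0.3, kappa = 1)
  changed <- long != child
  is_ts <- changed & (long %% 2 == child %% 2)
  ratio <- sum(is_ts) / sum(changed & !is_ts)
  expect_equal(ratio, 0.5, tolerance = 0.1)

  # kappa = 4 shifts the balance towards transitions
  child4 <- evolve_sequence(long, 0.1, kappa = 4)
  changed4 <- long != child4
  ts4 <- sum(changed4 & (long %% 2 == child4 %% 2))
  expect_gt(ts4 / sum(changed4), 0.5)
})

test_that("K2P distance estimates recover the simulated branch length", {
  set.seed(72)
  parent <- sample.int(4, 1e4, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  t_true <- 0.08
  ests <- replicate(5, {
    child <- evolve_sequence(parent, t_true)
    k2p_distance(paste(bases[parent], collapse = ""),
                 paste(bases[child], collapse = ""))$distance
  })
  # estimator SE at this length is ~0.003; 3 SE band on the mean of 5
  expect_lt(abs(mean(ests) - t_true), 3 * 0.003)
})

test_that("simulated datasets honour their stated world", {
  specs <- list(
    marker_spec("sep", 600, 0.03, 0, n_diagnostic_sites = 1),
    marker_spec("flat", 500, 0, 0),
    marker_spec("missing", 300, 0.02, 0.005, missing_rate = 0.4))
  ds <- simulate_dataset(specs, n_per_species = c(6, 8), seed = 73)
  expect_named(ds$alignments, c("sep", "flat", "missing"))
  expect_equal(nrow(ds$metadata), 14L)

  # zero divergence everywhere: all sequences identical, no variable sites
  flat <- ds$alignments$flat
  expect_equal(classify_sites(flat)$n_variable, 0L)

  # clean separation: intra 0, gap present, planted rule recovered exactly
  sep <- ds$alignments$sep
  dm <- pairwise_matrix(sep)
  sp <- species_labels(sep)
  gs <- group_distance_summary(dm, sp)
  expect_equal(unname(gs$mean_intra["estimate"]), 0)
  expect_true(barcoding_gap(dm, sp)$gap_present)
  truth <- ds$truth$diagnostics
  planted <- truth$position[truth$marker == "sep" & truth$planted]
  rules <- induce_rules(sep)
  pos_used <- unique(unlist(lapply(rules, function(r)
    unlist(lapply(r$alternatives, `[[`, "position")))))
  expect_true(planted %in% pos_used)
  expect_true(all(pos_used %in% truth$position[truth$marker == "sep"]))

  # missingness drops samples but never below 2 per species
  miss <- ds$alignments$missing
  expect_lt(nrow(miss$seq), 14L)
  expect_true(all(table(species_labels(miss)) >= 2))

  # diagnostic columns are immune to within-species mutation
  for (m in c("sep", "missing")) {
    aln <- ds$alignments[[m]]
    tru <- truth[truth$marker == m, ]
    spm <- species_labels(aln)
    for (k in seq_len(nrow(tru))) {
      col <- aln$seq[, tru$position[k]]
      expect_true(all(col[spm == "species_A"] == tru$state_species1[k]))
      expect_true(all(col[spm == "species_B"] == tru$state_species2[k]))
    }
  }
})

test_that("ancestral GC tracks the target", {
  set.seed(74)
  for (gc in c(0.3, 0.5, 0.64)) {
    ds <- simulate_dataset(marker_spec("g", 800, 0, 0, gc_target = gc),
                           2, seed = round(100 * gc))
    expect_equal(gc_ratio(ds$alignments$g), 100 * gc, tolerance = 5)
  }
})

test_that("same seed gives byte-identical output; different seed differs", {
  spec <- list(marker_spec("m", 150, 0.02, 0.004))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(spec, 4, seed = 11), dir1)
  write_dataset(simulate_dataset(spec, 4, seed = 11), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  ds3 <- simulate_dataset(spec, 4, seed = 12)
  ds1 <- simulate_dataset(spec, 4, seed = 11)
  expect_false(identical(ds1$alignments$m$seq, ds3$alignments$m$seq))
})

test_that("invalid marker specifications are rejected", {
  expect_error(marker_spec("x", 10, 0.1, 0.1, n_diagnostic_sites = 11),
               "diagnostic")
  expect_error(marker_spec("x", 0, 0.1, 0.1))
  expect_error(marker_spec("x", 10, -1, 0.1))
  expect_error(marker_spec("x", 10, 0.1, 0.1, missing_rate = 1))
})

test_that("gap injection exercises pairwise deletion", {
  ds <- simulate_dataset(marker_spec("m", 300, 0.02, 0.002), 4, seed = 75,
                         gap_rate = 0.05)
  aln <- ds$alignments$m
  expect_gt(sum(aln$seq == "-"), 0)
  dm <- pairwise_matrix(aln, min_overlap = 50)
  expect_true(all(dm$valid))
})
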