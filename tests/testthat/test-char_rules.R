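# Planted-site alignments with controlled backgrounds.
planted_aln <- function(n_per_species = 4, len = 30, pos = 10,
                        states = c("A", "C"), seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  rows <- lapply(seq_len(2 * n_per_species), function(i) {
    r <- base
    r[pos] <- if (i <= n_per_species) states[1] else states[2]
    r
  })
  toy_aln(vapply(rows, paste, character(1), collapse = ""),
          rep(c("sp1", "sp2"), each = n_per_species))
}

test_that("a single pure column yields one-clause rules for both species", {
  aln <- planted_aln(pos = 17)
  rules <- induce_rules(aln)
  expect_named(rules, c("sp1", "sp2"))
  expect_equal(rules$sp1$clauses,
               data.frame(position = 17, state = "A",
                          stringsAsFactors = FALSE))
  expect_equal(rules$sp2$clauses$position, 17)
  expect_equal(rules$sp2$clauses$state, "C")
  expect_equal(rules$sp1$support, 4L)
  expect_equal(format_rule(rules$sp1), "17 = A")

  # classification with those rules
  expect_equal(classify_with_rules(paste(aln$seq[1, ], collapse = ""),
                                   rules), "sp1")
  seq_other <- aln$seq[1, ]; seq_other[17] <- "G"
  expect_equal(classify_with_rules(paste(seq_other, collapse = ""), rules),
               "unclassified")
})

test_that("two-clause conjunctions are found when no single column is pure", {
  # columns 5 and 9: sp1 = (T, A); each clause alone is impure because one
  # sp2 sample shares it, but the conjunction is pure
  seqs <- c("AAAATAAAAG", "AAAATAAAAG",  # sp1: 5=T, 10=G
            "AAAATAAAAC", "AAAACAAAAG")  # sp2 shares one clause each
  aln <- toy_aln(seqs, c("sp1", "sp1", "sp2", "sp2"))
  rules <- induce_rules(aln, max_clauses = 2)
  expect_equal(rules$sp1$clauses$position, c(5, 10))
  expect_equal(rules$sp1$clauses$state, c("T", "G"))
  expect_equal(classify_with_rules(seqs[1], rules), "sp1")
  # sp2 itself has no fixed difference, so it stays rule-less (reported,
  # not an error) and its members are unclassified
  expect_null(rules$sp2)
  expect_equal(classify_with_rules("AAAACAAAAC", rules), "unclassified")

  # with max_clauses = 1 no rule exists for sp1
  rules1 <- induce_rules(aln, max_clauses = 1)
  expect_null(rules1$sp1)

  # identical species: no rules at all
  none <- induce_rules(toy_aln(rep("ACGT", 4),
                               rep(c("sp1", "sp2"), each = 2)))
  expect_length(none, 0)
  expect_error(induce_rules(toy_aln(rep("ACGT", 3), c("a", "b", "c"))),
               "exactly 2")
})

test_that("gaps and ambiguity codes never satisfy a clause", {
  # column 3 separates the species, but one sp1 sample has N there
  aln <- toy_aln(c("AANA", "AAAA", "AACA", "AACA"),
                 c("sp1", "sp1", "sp2", "sp2"))
  rules <- induce_rules(aln)
  expect_null(rules$sp1)      # N breaks purity for sp1
  expect_false(is.null(rules$sp2))  # 3 = C still pure for sp2
  expect_equal(classify_with_rules("AA-A", rules), "unclassified")
})

test_that("engineered overlap produces a conflict, counted as wc", {
  aln <- planted_aln(pos = 5)
  rules <- induce_rules(aln)
  # build a rule set whose targets both match the same sequence
  fake <- rules
  fake$sp2$alternatives <- rules$sp1$alternatives
  expect_equal(classify_with_rules(paste(aln$seq[1, ], collapse = ""),
                                   fake), "conflict")
})

test_that("greedy induction matches exhaustive search on random instances", {
  exhaustive <- function(aln) {
    mat <- aln$seq
    sp <- species_labels(aln)
    out <- list()
    for (target in unique(sp)) {
      S <- mat[sp[rownames(mat)] == target, , drop = FALSE]
      O <- mat[sp[rownames(mat)] != target, , drop = FALSE]
      singles <- list()
      for (p in seq_len(ncol(mat))) for (b in c("A", "C", "G", "T"))
        if (all(S[, p] == b) && !any(O[, p] == b))
          singles[[length(singles) + 1]] <- c(p, b)
      if (length(singles)) { out[[target]] <- singles; next }
      pairs <- list()
      for (p in seq_len(ncol(mat))) for (q in seq_len(ncol(mat)))
        if (p < q) for (b1 in c("A", "C", "G", "T"))
          for (b2 in c("A", "C", "G", "T"))
            if (all(S[, p] == b1) && all(S[, q] == b2) &&
                !any(O[, p] == b1 & O[, q] == b2))
              pairs[[length(pairs) + 1]] <- c(p, b1, q, b2)
      if (length(pairs)) out[[target]] <- pairs
    }
    out
  }
  set.seed(41)
  for (rep in 1:8) {
    n <- 5
    len <- 12
    seqs <- replicate(2 * n, random_seq(len))
    # plant partial structure in some replicates
    aln <- toy_aln(seqs, rep(c("sp1", "sp2"), each = n))
    rules <- induce_rules(aln, max_clauses = 2)
    oracle <- exhaustive(aln)
    nm <- function(x) if (is.null(names(x))) character(0) else names(x)
    expect_identical(sort(nm(rules)), sort(nm(oracle)))
    for (s in names(oracle)) {
      # primary rule must appear in the oracle's enumeration
      cl <- rules[[s]]$clauses
      key <- paste(t(cbind(cl$position, cl$state)), collapse = "_")
      okeys <- vapply(oracle[[s]], paste, character(1), collapse = "_")
      expect_true(key %in% okeys)
      # and alternative count matches for the same clause size
      expect_equal(length(rules[[s]]$alternatives), length(oracle[[s]]))
    }
  }
})

test_that("rule positions shift with prepended conserved columns and ignore row order", {
  aln <- planted_aln(pos = 11, seed = 5)
  rules <- induce_rules(aln)
  k <- 7
  shifted_seqs <- paste0(strrep("G", k),
                         apply(aln$seq, 1, paste, collapse = ""))
  aln_shift <- toy_aln(shifted_seqs, aln$meta$species, sample_ids(aln))
  rules_shift <- induce_rules(aln_shift)
  expect_equal(rules_shift$sp1$clauses$position,
               rules$sp1$clauses$position + k)

  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  aln_perm <- toy_aln(apply(aln$seq, 1, paste, collapse = "")[perm],
                      aln$meta$species[perm], sample_ids(aln)[perm])
  rules_perm <- induce_rules(aln_perm)
  expect_equal(rules_perm$sp1$clauses, rules$sp1$clauses)
})

test_that("evaluation schemes produce the documented cc/wc/nc patterns", {
  # perfectly separable: LOO cc = 100 for both species
  aln <- planted_aln(n_per_species = 5, pos = 9)
  ev <- evaluate_rules(aln)
  expect_equal(ev$per_species$cc, c(100, 100))
  expect_equal(ev$per_species$wc, c(0, 0))
  expect_equal(ev$per_species$nc, c(0, 0))
  expect_equal(rowSums(ev$per_species[, c("cc", "wc", "nc")]),
               c(100, 100), ignore_attr = TRUE)

  # resubstitution cc = 100 whenever a pure rule exists
  ev_r <- evaluate_rules(aln, scheme = "resubstitution")
  expect_equal(ev_r$per_species$cc, c(100, 100))

  # destroy the diagnostic in half of sp1: those samples fall to nc/wc
  # under LOO (held-out sample no longer matches the remainder's rule)
  mat <- aln$seq
  mat[1:2, 9] <- "G"
  aln2 <- toy_aln(apply(mat, 1, paste, collapse = ""), aln$meta$species,
                  sample_ids(aln))
  ev2 <- evaluate_rules(aln2)
  sp1 <- ev2$per_species[ev2$per_species$species == "sp1", ]
  expect_lt(sp1$cc, 100)
  expect_gt(sp1$nc + sp1$wc, 0)

  # identical sequences, arbitrary labels: nothing classifiable
  ev3 <- evaluate_rules(toy_aln(rep(strrep("ACGT", 5), 6),
                                rep(c("sp1", "sp2"), each = 3)))
  expect_equal(ev3$per_species$cc, c(0, 0))
  expect_equal(ev3$per_species$nc, c(100, 100))
})
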