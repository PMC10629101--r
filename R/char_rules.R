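## Character-based diagnosis: induction of pure conjunctive rules
## (position = state clauses) separating two species, and cc/wc/nc scoring.

.rule_states <- c("A", "C", "G", "T")

#' Induce diagnostic character rules for a two-species alignment
#'
#' Searches for pure diagnostic rules: conjunctions of
#' `(position, nucleotide)` clauses that every sample of the target species
#' satisfies and no sample of the other species does. Gap and ambiguity
#' characters never satisfy a clause, so a column with a gap in any target
#' sample cannot support a rule for that species.
#'
#' Single positions are searched first; every pure single-position clause is
#' reported as an alternative, with the lowest position as the primary rule.
#' If no single position separates a class, conjunctions of up to
#' `max_clauses` positions are searched: pairs exhaustively over clauses
#' whose state is fixed within the target species, larger conjunctions by
#' greedy set cover (each step adds the clause excluding the most remaining
#' non-target samples, ties broken by lowest position). Rules with fewer
#' clauses are always preferred; among equal sizes, lower positions win.
#'
#' @param aln A [labeled_alignment()] with exactly two species.
#' @param max_clauses Maximum number of clauses per conjunction (default 2).
#' @return A list of class `diagnostic_rules`, one `diagnostic_rule` per
#'   species for which a rule exists (species with no rule at `max_clauses`
#'   are absent, not an error). Each rule has `target_species`, `clauses`
#'   (data frame `position`, `state`), `alternatives` (list of clause
#'   frames, including the primary), and `support` (training samples
#'   matched).
#' @export
induce_rules <- function(aln, max_clauses = 2) {
  sp <- species_labels(aln)
  classes <- unique(sp)
  if (length(classes) != 2L)
    stop("rule induction supports exactly 2 species, got ",
         length(classes), call. = FALSE)
  mat <- aln$seq
  rules <- list()
  for (target in classes) {
    in_target <- sp[rownames(mat)] == target
    alts <- .pure_singles(mat, in_target)
    if (length(alts) == 0L && max_clauses >= 2L)
      alts <- .pure_conjunctions(mat, in_target, max_clauses)
    if (length(alts)) {
      rules[[target]] <- structure(list(
        target_species = target,
        clauses = alts[[1L]],
        alternatives = alts,
        support = sum(in_target)
      ), class = "diagnostic_rule")
    }
  }
  structure(rules, class = "diagnostic_rules")
}

# All single-position pure clauses, ordered by position.
.pure_singles <- function(mat, in_target) {
  S <- mat[in_target, , drop = FALSE]
  O <- mat[!in_target, , drop = FALSE]
  nS <- nrow(S)
  out <- list()
  for (b in .rule_states) {
    pure <- (colSums(S == b) == nS) & (colSums(O == b) == 0)
    for (p in which(pure))
      out[[length(out) + 1L]] <- data.frame(position = p, state = b,
                                            stringsAsFactors = FALSE)
  }
  out[order(vapply(out, function(cl) cl$position[1L], numeric(1)))]
}

# Conjunctions of 2..max_clauses clauses over states fixed within the target
# species. Pairs are searched exhaustively; beyond 2 clauses, greedy cover.
.pure_conjunctions <- function(mat, in_target, max_clauses) {
  S <- mat[in_target, , drop = FALSE]
  O <- mat[!in_target, , drop = FALSE]
  nS <- nrow(S)
  # candidate clauses: (position, state) with the state fixed in all target
  # samples and not already pure (pure singles were handled upstream)
  cand <- do.call(rbind, lapply(.rule_states, function(b) {
    pos <- which(colSums(S == b) == nS)
    if (length(pos)) data.frame(position = pos, state = b,
                                stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(cand) || nrow(cand) < 2L) return(list())
  cand <- cand[order(cand$position), , drop = FALSE]
  # B[r, c]: does non-target row r satisfy candidate clause c?
  B <- vapply(seq_len(nrow(cand)),
              function(c) O[, cand$position[c]] == cand$state[c],
              logical(nrow(O)))
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(O))

  # exhaustive pair search
  CC <- crossprod(B)  # co-satisfaction counts over non-target rows
  pure_pairs <- which(CC == 0, arr.ind = TRUE)
  pure_pairs <- pure_pairs[pure_pairs[, 1L] < pure_pairs[, 2L] &
    cand$position[pure_pairs[, 1L]] != cand$position[pure_pairs[, 2L]], ,
    drop = FALSE]
  if (nrow(pure_pairs)) {
    ord <- order(cand$position[pure_pairs[, 1L]],
                 cand$position[pure_pairs[, 2L]])
    pure_pairs <- pure_pairs[ord, , drop = FALSE]
    return(lapply(seq_len(nrow(pure_pairs)), function(k) {
      cl <- cand[pure_pairs[k, ], , drop = FALSE]
      rownames(cl) <- NULL
      cl
    }))
  }
  if (max_clauses < 3L) return(list())

  # greedy set cover for >2 clauses
  chosen <- integer(0)
  alive <- rep(TRUE, nrow(O))
  for (step in seq_len(max_clauses)) {
    remaining <- vapply(seq_len(nrow(cand)), function(c) {
      if (cand$position[c] %in% cand$position[chosen]) return(Inf)
      sum(alive & B[, c])
    }, numeric(1))
    best <- which.min(remaining)  # ties -> lowest position (cand is sorted)
    chosen <- c(chosen, best)
    alive <- alive & B[, best]
    if (!any(alive)) {
      cl <- cand[chosen, , drop = FALSE]
      cl <- cl[order(cl$position), , drop = FALSE]
      rownames(cl) <- NULL
      return(list(cl))
    }
  }
  list()
}

#' Format a diagnostic rule as a logic formula string
#'
#' @param rule A `diagnostic_rule`.
#' @param alternatives Include all alternative conjunctions joined by
#'   `" OR "` (default `FALSE`: primary conjunction only).
#' @return A string like `"196 = A"` or `"243 = A AND 375 = T"`.
#' @export
format_rule <- function(rule, alternatives = FALSE) {
  fmt1 <- function(cl) paste(cl$position, "=", cl$state, collapse = " AND ")
  if (alternatives)
    paste(vapply(rule$alternatives, fmt1, character(1)), collapse = " OR ")
  else fmt1(rule$clauses)
}

#' @export
print.diagnostic_rule <- function(x, ...) {
  cat("<diagnostic_rule>", x$target_species, ":",
      format_rule(x, alternatives = length(x$alternatives) > 1L),
      sprintf("(support %d)\n", x$support))
  invisible(x)
}

#' @export
print.diagnostic_rules <- function(x, ...) {
  if (!length(x)) cat("<diagnostic_rules> none\n")
  for (r in x) print(r)
  invisible(x)
}

#' Classify one sequence with induced rules
#'
#' A rule matches when any of its alternative conjunctions is fully
#' satisfied (clause-wise equality on unambiguous bases; a gap or ambiguity
#' code never satisfies a clause).
#'
#' @param sequence Character string or single-character vector.
#' @param rules A `diagnostic_rules` list from [induce_rules()].
#' @return The target species of the unique matching rule, `"unclassified"`
#'   if no rule matches, or `"conflict"` if rules for different species
#'   match.
#' @export
classify_with_rules <- function(sequence, rules) {
  chars <- if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(toupper(sequence), "")[[1L]] else toupper(sequence)
  matches <- vapply(rules, function(rule) {
    any(vapply(rule$alternatives, function(cl) {
      all(cl$position <= length(chars)) &&
        all(chars[cl$position] == cl$state)
    }, logical(1)))
  }, logical(1))
  hit <- names(rules)[matches]
  if (length(hit) == 0L) "unclassified"
  else if (length(hit) > 1L) "conflict"
  else hit
}

#' Evaluate diagnostic rules (cc/wc/nc rates)
#'
#' Scores rule-based identification per species. Under the default
#' leave-one-out scheme, each sample is classified by rules induced on the
#' remaining samples; under resubstitution, rules induced once on the full
#' alignment classify every sample. Per species: `cc` is the percentage of
#' its samples classified to it, `wc` the percentage classified to the other
#' species or hitting a rule conflict, `nc` the percentage left
#' unclassified; `cc + wc + nc = 100`.
#'
#' @param aln A two-species [labeled_alignment()].
#' @param max_clauses Passed to [induce_rules()].
#' @param scheme `"loo"` (default) or `"resubstitution"`.
#' @return A list of class `rule_evaluation`: `per_species` data frame
#'   (`species`, `n`, `cc`, `wc`, `nc`), `scheme`, and `rules` (induced on
#'   the full alignment, for reporting).
#' @export
evaluate_rules <- function(aln, max_clauses = 2,
                           scheme = c("loo", "resubstitution")) {
  scheme <- match.arg(scheme)
  sp <- species_labels(aln)
  ids <- sample_ids(aln)
  full_rules <- induce_rules(aln, max_clauses)

  calls <- character(length(ids))
  names(calls) <- ids
  for (id in ids) {
    rules <- if (scheme == "resubstitution") full_rules else {
      rest <- aln
      keep <- ids != id
      rest$seq <- rest$seq[keep, , drop = FALSE]
      rest$meta <- rest$meta[keep, , drop = FALSE]
      induce_rules(rest, max_clauses)
    }
    calls[id] <- classify_with_rules(aln$seq[id, ], rules)
  }

  classes <- unique(sp)
  per <- do.call(rbind, lapply(classes, function(cl) {
    mine <- calls[ids[sp[ids] == cl]]
    n <- length(mine)
    cc <- sum(mine == cl)
    nc <- sum(mine == "unclassified")
    wc <- n - cc - nc  # wrong species or conflict
    data.frame(species = cl, n = n,
               cc = 100 * cc / n, wc = 100 * wc / n, nc = 100 * nc / n,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(per_species = per, scheme = scheme, rules = full_rules,
                 calls = calls),
            class = "rule_evaluation")
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat("<rule_evaluation> scheme:", x$scheme, "\n")
  print(x$per_species)
  invisible(x)
}
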