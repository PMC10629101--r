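## Best-match identification against a local labeled reference library,
## with the success / error / ambiguous rate taxonomy.

.degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Percent identity between two sequences
#'
#' Global pairwise alignment (match +1, mismatch -1, gap -2 per gap
#' position) with free end gaps; identity is 100 x matches / aligned
#' columns, end gaps excluded. Gap characters in the inputs are stripped
#' before alignment, so aligned or unaligned sequences are both accepted.
#'
#' @param query,reference Character strings (IUPAC nucleotides, `-` allowed
#'   and ignored).
#' @param check_revcomp Also align the reverse complement of the query and
#'   keep the better orientation (default `FALSE`).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(query, reference, check_revcomp = FALSE) {
  q <- .degap(toupper(query)); r <- .degap(toupper(reference))
  if (!nzchar(q) || !nzchar(r))
    stop("empty sequence", call. = FALSE)
  max(.identity_vector(q, r, check_revcomp))
}

# Identities of one query against many references in one vectorised call.
.identity_vector <- function(query, refs, check_revcomp = FALSE) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  refs_set <- Biostrings::DNAStringSet(refs)
  align_pid <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = refs_set, subject = Biostrings::DNAString(q),
      type = "overlap", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 2)
    Biostrings::pid(aln, type = "PID1")
  }
  ident <- align_pid(query)
  if (check_revcomp) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(query)))
    ident <- pmax(ident, align_pid(rc))
  }
  ident
}

#' Best-match identification of one query against a reference library
#'
#' Computes the percent identity of the query against every reference, takes
#' the top hit(s) (ties within `tie_margin` of the best identity), and
#' classifies the outcome at species and genus level:
#' * `success`: all top hits belong to the query's true taxon;
#' * `error`: no top hit belongs to the true taxon;
#' * `ambiguous`: top hits mix the true taxon with others.
#'
#' Calls are only made when the top identity reaches `min_identity`
#' (`passed_threshold`); otherwise both calls are `NA`.
#'
#' @param query Character string (the query sequence).
#' @param library A [labeled_alignment()] used as reference library (gaps
#'   are stripped per sequence), or a list with elements `seqs` (named
#'   character vector) and `meta` (data frame `sample_id`, `species`,
#'   `genus`).
#' @param true_species,true_genus The query's true labels (evaluation mode).
#' @param min_identity Identity threshold in percent (default 97).
#' @param tie_margin Hits within this much of the top identity count as tied
#'   (default 0: exact ties only).
#' @param check_revcomp Try both query orientations (default `FALSE`).
#' @param query_id Id recorded on the result.
#' @return A list of class `identification_result`: `query_id`, `best_hits`
#'   (data frame `ref_id`, `ref_species`, `ref_genus`, `identity`, sorted by
#'   identity descending), `species_call`, `genus_call`, `passed_threshold`,
#'   `top_identity`.
#' @export
best_match_identify <- function(query, library, true_species, true_genus,
                                min_identity = 97, tie_margin = 0,
                                check_revcomp = FALSE, query_id = "query") {
  lib <- .as_library(library)
  if (length(lib$seqs) == 0L) stop("empty reference library", call. = FALSE)
  q <- .degap(toupper(query))
  if (!nzchar(q)) stop("empty sequence", call. = FALSE)

  ident <- .identity_vector(q, .degap(toupper(lib$seqs)), check_revcomp)
  top <- max(ident)
  hit <- ident >= top - tie_margin
  hits <- data.frame(
    ref_id = names(lib$seqs)[hit],
    ref_species = lib$meta$species[hit],
    ref_genus = lib$meta$genus[hit],
    identity = ident[hit], stringsAsFactors = FALSE)
  hits <- hits[order(-hits$identity, hits$ref_id), , drop = FALSE]
  rownames(hits) <- NULL

  passed <- top >= min_identity
  call_level <- function(truth, labels) {
    if (!passed) return(NA_character_)
    in_truth <- labels == truth
    if (all(in_truth)) "success"
    else if (!any(in_truth)) "error"
    else "ambiguous"
  }
  structure(list(
    query_id = query_id, best_hits = hits,
    species_call = call_level(true_species, hits$ref_species),
    genus_call = call_level(true_genus, hits$ref_genus),
    passed_threshold = passed, top_identity = top
  ), class = "identification_result")
}

.as_library <- function(library) {
  if (inherits(library, "labeled_alignment")) {
    seqs <- apply(library$seq, 1L, paste, collapse = "")
    list(seqs = seqs, meta = library$meta)
  } else {
    stopifnot(is.list(library), !is.null(library$seqs), !is.null(library$meta))
    seqs <- library$seqs
    meta <- library$meta[match(names(seqs), library$meta$sample_id), ,
                         drop = FALSE]
    list(seqs = seqs, meta = meta)
  }
}

#' Leave-one-out identification over a labeled alignment
#'
#' Queries each sequence against the library formed by all remaining
#' sequences, mirroring the evaluation of a barcode library against itself.
#'
#' @param aln A [labeled_alignment()].
#' @inheritParams best_match_identify
#' @return A list of `identification_result` objects, one per sample.
#' @export
identify_loo <- function(aln, min_identity = 97, tie_margin = 0,
                         check_revcomp = FALSE) {
  ids <- sample_ids(aln)
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  lapply(ids, function(id) {
    keep <- ids != id
    lib <- list(seqs = seqs[keep], meta = aln$meta[keep, , drop = FALSE])
    row <- match(id, aln$meta$sample_id)
    best_match_identify(seqs[id], lib,
                        true_species = aln$meta$species[row],
                        true_genus = aln$meta$genus[row],
                        min_identity = min_identity, tie_margin = tie_margin,
                        check_revcomp = check_revcomp, query_id = id)
  })
}

#' Summarise identification outcomes into a rate table
#'
#' @param results List of `identification_result` objects.
#' @return A list of class `identification_summary`: `rates` data frame with
#'   one row per level (`species`, `genus`) and columns `success`, `error`,
#'   `ambiguous` (percent), their counts, `n` (queries passing the
#'   threshold), plus formatted `"x% (x/n)"` strings; and `n_below_threshold`.
#' @export
summarize_identification <- function(results) {
  passed <- Filter(function(r) r$passed_threshold, results)
  if (length(passed) == 0L)
    stop("no queries passed the identity threshold", call. = FALSE)
  level_row <- function(field) {
    calls <- vapply(passed, function(r) r[[field]], character(1))
    n <- length(calls)
    cnt <- c(success = sum(calls == "success"),
             error = sum(calls == "error"),
             ambiguous = sum(calls == "ambiguous"))
    pct <- 100 * cnt / n
    fmt <- ifelse(cnt == 0, sprintf("0 (0/%d)", n),
                  sprintf("%.1f%% (%d/%d)", pct, cnt, n))
    data.frame(level = sub("_call", "", field),
               success = pct[["success"]], error = pct[["error"]],
               ambiguous = pct[["ambiguous"]],
               success_fmt = fmt[[1]], error_fmt = fmt[[2]],
               ambiguous_fmt = fmt[[3]], n = n, stringsAsFactors = FALSE)
  }
  rates <- rbind(level_row("species_call"), level_row("genus_call"))
  rownames(rates) <- NULL
  structure(list(rates = rates,
                 n_below_threshold = length(results) - length(passed)),
            class = "identification_summary")
}

#' @export
print.identification_summary <- function(x, ...) {
  cat("<identification_summary>\n")
  print(x$rates[, c("level", "success_fmt", "error_fmt", "ambiguous_fmt")])
  if (x$n_below_threshold)
    cat("  below threshold:", x$n_below_threshold, "\n")
  invisible(x)
}
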