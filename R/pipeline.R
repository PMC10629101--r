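## Orchestration: run every evaluation stage over single markers and
## configured combinations, and emit a report bundle.

#' Build a pipeline run configuration
#'
#' @param alignments Named list of [labeled_alignment()] objects, or a named
#'   character vector of FASTA paths (names = marker names).
#' @param metadata Metadata data frame or TSV path (required when
#'   `alignments` are paths).
#' @param combinations List of character vectors of marker names to
#'   concatenate and evaluate as combined barcodes.
#' @param bin_width Histogram bin width for the gap assessment.
#' @param bootstrap Bootstrap replicates for tree support (>= 1).
#' @param seed Integer seed for the bootstrap (marker `i` uses `seed + i`).
#' @param max_clauses Maximum clauses per diagnostic rule.
#' @param min_identity Identity threshold (percent) for identification.
#' @param min_overlap Minimum comparable sites per pair for K2P distances.
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alignments, metadata = NULL, combinations = list(),
                       bin_width = 0.005, bootstrap = 1000, seed = 1,
                       max_clauses = 2, min_identity = 97, min_overlap = 50,
                       out_dir = NULL) {
  stopifnot(length(alignments) >= 1L, bootstrap >= 1)
  structure(list(alignments = alignments, metadata = metadata,
                 combinations = combinations, bin_width = bin_width,
                 bootstrap = bootstrap, seed = seed,
                 max_clauses = max_clauses, min_identity = min_identity,
                 min_overlap = min_overlap, out_dir = out_dir),
            class = "run_config")
}

.load_alignments <- function(config) {
  alns <- config$alignments
  if (is.character(alns)) {
    meta <- if (is.character(config$metadata)) read_metadata(config$metadata)
            else config$metadata
    nm <- names(alns)
    if (is.null(nm)) nm <- sub("\\.[^.]*$", "", basename(alns))
    alns <- Map(function(p, n) read_labeled_fasta(p, meta, n), alns, nm)
    names(alns) <- nm
  }
  alns
}

#' Run the full barcode evaluation pipeline
#'
#' For each single marker and each configured combination: sequence
#' characteristics, K2P distance summary, barcoding-gap assessment,
#' leave-one-out best-match identification, diagnostic-rule evaluation, and
#' an NJ tree with bootstrap support plus per-species monophyly verdicts;
#' then Wilcoxon signed-rank comparisons of interspecific distances over all
#' pairs of evaluated matrices. A summary table flags, per marker, the four
#' criteria of a usable barcode: barcoding gap present, 100% species-level
#' identification success, diagnostic rules with cc = 100 (wc = nc = 0) for
#' both species, and both species monophyletic on the NJ tree.
#'
#' A stage failing on one marker is logged and skipped; only unreadable
#' inputs abort the run. When `config$out_dir` is set the bundle is also
#' written to disk via [write_report_tables()].
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle` with data frames `site_stats`,
#'   `distance_summary`, `gap`, `wilcoxon`, `identification`, `rules`,
#'   `monophyly`, `summary`; plus `trees` (named list of `bootstrap_tree`),
#'   `histograms` (per-marker gap histograms), and `log` (character).
#' @export
run_pipeline <- function(config) {
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  try_stage <- function(marker, stage, expr) {
    tryCatch(expr, error = function(e) {
      note("skip [", marker, "/", stage, "]: ", conditionMessage(e))
      NULL
    })
  }

  singles <- .load_alignments(config)
  matrices <- singles
  for (combo in config$combinations) {
    nm <- paste(combo, collapse = "+")
    cb <- try_stage(nm, "concatenate", {
      missing <- setdiff(combo, names(singles))
      if (length(missing)) stop("unknown markers: ",
                                paste(missing, collapse = ", "))
      concatenate_markers(singles[combo], order = combo)
    })
    if (!is.null(cb)) matrices[[nm]] <- cb
  }

  site_stats <- distance_summary <- gap_tab <- ident_tab <- rules_tab <-
    mono_tab <- summary_tab <- NULL
  trees <- list()
  histograms <- list()
  dms <- list()

  for (mi in seq_along(matrices)) {
    aln <- matrices[[mi]]
    nm <- names(matrices)[mi]
    sp <- species_labels(aln)

    st <- try_stage(nm, "seqstats", classify_sites(aln))
    if (!is.null(st))
      site_stats <- rbind(site_stats, data.frame(
        marker = nm, n_sequences = st$n_sequences,
        aligned_length = st$aligned_length, n_conserved = st$n_conserved,
        n_variable = st$n_variable, n_informative = st$n_informative,
        n_singleton = st$n_singleton, gc_ratio = st$gc_ratio,
        stringsAsFactors = FALSE))

    dm <- try_stage(nm, "distance",
                    pairwise_matrix(aln, min_overlap = config$min_overlap))
    if (is.null(dm)) next
    dms[[nm]] <- dm

    gs <- try_stage(nm, "distance_summary", group_distance_summary(dm, sp))
    if (!is.null(gs))
      distance_summary <- rbind(distance_summary, data.frame(
        marker = nm,
        mean_inter = gs$mean_inter[1], se_inter = gs$mean_inter[2],
        mean_intra = gs$mean_intra[1], se_intra = gs$mean_intra[2],
        theta = gs$theta[1], se_theta = gs$theta[2],
        coalescence_depth = gs$coalescence_depth[1],
        se_depth = gs$coalescence_depth[2],
        n_inter_pairs = gs$n_inter_pairs, n_intra_pairs = gs$n_intra_pairs,
        stringsAsFactors = FALSE))

    gp <- try_stage(nm, "gap",
                    barcoding_gap(dm, sp, bin_width = config$bin_width))
    gap_present <- NA
    if (!is.null(gp)) {
      gap_present <- gp$gap_present
      histograms[[nm]] <- list(intra = gp$intra_histogram,
                               inter = gp$inter_histogram)
      gap_tab <- rbind(gap_tab, data.frame(
        marker = nm, max_intra = gp$max_intra, min_inter = gp$min_inter,
        gap_present = gp$gap_present, stringsAsFactors = FALSE))
    }

    ident_ok <- NA
    ident <- try_stage(nm, "identify", {
      res <- identify_loo(aln, min_identity = config$min_identity)
      summarize_identification(res)
    })
    if (!is.null(ident)) {
      r <- ident$rates
      ident_ok <- r$success[r$level == "species"] == 100
      ident_tab <- rbind(ident_tab,
                         cbind(marker = nm, r, stringsAsFactors = FALSE))
    }

    rules_ok <- NA
    rev <- try_stage(nm, "rules",
                     evaluate_rules(aln, max_clauses = config$max_clauses))
    if (!is.null(rev)) {
      per <- rev$per_species
      formulas <- vapply(per$species, function(s) {
        if (!is.null(rev$rules[[s]]))
          format_rule(rev$rules[[s]],
                      alternatives = length(rev$rules[[s]]$alternatives) > 1L)
        else ""
      }, character(1))
      rules_ok <- all(per$cc == 100) && all(per$wc == 0) && all(per$nc == 0)
      rules_tab <- rbind(rules_tab, data.frame(
        marker = nm, species = per$species, cc = per$cc, wc = per$wc,
        nc = per$nc, formula = formulas, stringsAsFactors = FALSE))
    }

    mono_ok <- NA
    bt <- try_stage(nm, "tree",
                    bootstrap_support(aln, n_replicates = config$bootstrap,
                                      seed = config$seed + mi,
                                      min_overlap = config$min_overlap))
    if (!is.null(bt)) {
      trees[[nm]] <- bt
      mono <- vapply(unique(sp), function(s)
        is_species_monophyletic(bt$tree, sp, s), logical(1))
      mono_ok <- all(mono)
      mono_tab <- rbind(mono_tab, data.frame(
        marker = nm, species = names(mono), monophyletic = unname(mono),
        stringsAsFactors = FALSE))
    }

    summary_tab <- rbind(summary_tab, data.frame(
      marker = nm, combined = grepl("+", nm, fixed = TRUE),
      gap_present = gap_present, identification_success = ident_ok,
      rules_perfect = rules_ok, both_monophyletic = mono_ok,
      all_criteria = isTRUE(gap_present) && isTRUE(ident_ok) &&
        isTRUE(rules_ok) && isTRUE(mono_ok),
      stringsAsFactors = FALSE))
  }

  # Wilcoxon over all pairs of evaluated matrices
  wilcox_tab <- NULL
  all_labels <- stats::setNames(character(0), character(0))
  for (aln in matrices)
    all_labels[sample_ids(aln)] <- species_labels(aln)
  nms <- names(dms)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
      w <- try_stage(paste(nms[i], nms[j]), "wilcoxon",
                     compare_marker_distances(dms[[nms[i]]], dms[[nms[j]]],
                                              all_labels, nms[i], nms[j]))
      if (!is.null(w))
        wilcox_tab <- rbind(wilcox_tab, data.frame(
          markerA = nms[i], markerB = nms[j], w_plus = w$w_plus,
          w_minus = w$w_minus, n = w$n, p_value = w$p_value,
          method = w$method, verdict = w$verdict, stringsAsFactors = FALSE))
    }
  }

  bundle <- structure(list(
    site_stats = site_stats, distance_summary = distance_summary,
    gap = gap_tab, wilcoxon = wilcox_tab, identification = ident_tab,
    rules = rules_tab, monophyly = mono_tab, summary = summary_tab,
    trees = trees, histograms = histograms, log = log_lines,
    config = config
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_tables(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", nrow(x$summary), "matrices evaluated\n")
  print(x$summary)
  if (length(x$log)) cat("log:\n", paste(" ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits TSV tables (site statistics, distance summaries, gap verdicts and
#' per-marker histograms, Wilcoxon comparisons, identification rates, rule
#' table, monophyly verdicts, criteria summary), one Newick tree per marker
#' with bootstrap supports as internal node labels, a JSON summary, and the
#' run log. Output is deterministic given the bundle.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("site_stats", "distance_summary", "gap", "wilcoxon",
            "identification", "rules", "monophyly", "summary")
  for (t in tabs)
    if (!is.null(bundle[[t]]))
      .write_tsv(bundle[[t]], file.path(dir, paste0(t, ".tsv")))
  if (length(bundle$histograms)) {
    hdir <- file.path(dir, "histograms")
    dir.create(hdir, showWarnings = FALSE)
    for (nm in names(bundle$histograms)) {
      h <- bundle$histograms[[nm]]
      df <- rbind(cbind(set = "intra", h$intra),
                  cbind(set = "inter", h$inter))
      .write_tsv(df, file.path(hdir, paste0(.safe_name(nm), ".tsv")))
    }
  }
  if (length(bundle$trees)) {
    tdir <- file.path(dir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(bundle$trees))
      write_newick(bundle$trees[[nm]]$tree,
                   file.path(tdir, paste0(.safe_name(nm), ".nwk")))
  }
  if (!is.null(bundle$summary))
    jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                         dataframe = "rows", pretty = TRUE)
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

.safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
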