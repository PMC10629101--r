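## Seeded two-species, multi-marker sequence simulator with known truth.
## Species-diagnostic columns (planted or arising on the species-ancestor
## branches) are recorded in the truth table and kept immune to
## within-species mutation, so fixed differences stay fixed: the regime the
## evaluated workflow assumes for a usable barcode.

#' Specify one simulated marker
#'
#' @param name Marker name.
#' @param length Aligned length in bp.
#' @param inter_divergence Expected substitutions/site separating the two
#'   species-ancestral sequences.
#' @param intra_divergence Expected substitutions/site between two samples
#'   of the same species (each terminal branch gets half).
#' @param kappa Transition/transversion rate ratio of the K2P process
#'   (default 2).
#' @param n_diagnostic_sites Number of planted diagnostic columns (fixed
#'   states differing between species, immune to mutation). Default 0.
#' @param gc_target Target GC fraction of the ancestral sequence
#'   (default 0.4).
#' @param missing_rate Probability that a sample is absent from this marker
#'   (default 0); at least two samples per species are always retained.
#' @return A list of class `marker_spec`.
#' @export
marker_spec <- function(name, length, inter_divergence, intra_divergence,
                        kappa = 2, n_diagnostic_sites = 0, gc_target = 0.4,
                        missing_rate = 0) {
  stopifnot(length > 0, inter_divergence >= 0, intra_divergence >= 0,
            kappa > 0, gc_target > 0, gc_target < 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_diagnostic_sites > length)
    stop("more diagnostic sites than columns", call. = FALSE)
  structure(list(name = name, length = as.integer(length),
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence, kappa = kappa,
                 n_diagnostic_sites = as.integer(n_diagnostic_sites),
                 gc_target = gc_target, missing_rate = missing_rate),
            class = "marker_spec")
}

# K2P substitution probabilities after branch length t (expected
# substitutions/site): c(transition, each transversion).
.k2p_probs <- function(t, kappa) {
  e1 <- exp(-4 * t / (kappa + 2))
  e2 <- exp(-2 * t * (kappa + 1) / (kappa + 2))
  c(ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)
}

#' Evolve a sequence under the Kimura two-parameter process
#'
#' Each site substitutes independently according to the K2P transition
#' probabilities at the given branch length (expected substitutions/site)
#' and transition/transversion rate ratio `kappa`. Randomness comes from the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param parent Integer vector coding the parent sequence (1=A, 2=C, 3=G,
#'   4=T) or a character string/vector of bases.
#' @param branch_length Expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @return Child sequence in the same representation as `parent`.
#' @export
evolve_sequence <- function(parent, branch_length, kappa = 2) {
  stopifnot(branch_length >= 0)
  as_char <- is.character(parent)
  if (as_char) {
    chars <- if (length(parent) == 1L && nchar(parent) > 1L)
      strsplit(toupper(parent), "")[[1L]] else toupper(parent)
    code <- match(chars, c("A", "C", "G", "T"))
    if (anyNA(code)) stop("parent must contain only A/C/G/T", call. = FALSE)
  } else code <- as.integer(parent)
  if (branch_length == 0) {
    return(if (as_char) paste(c("A", "C", "G", "T")[code], collapse = "")
           else code)
  }
  p <- .k2p_probs(branch_length, kappa)
  u <- stats::runif(length(code))
  child <- code
  # transition partner: A<->G, C<->T; transversion targets: other class
  ts_map <- c(3L, 4L, 1L, 2L)
  tv1_map <- c(2L, 1L, 2L, 1L)  # first transversion target
  tv2_map <- c(4L, 3L, 4L, 3L)  # second transversion target
  is_ts <- u < p["ts"]
  is_tv1 <- !is_ts & u < p["ts"] + p["tv"]
  is_tv2 <- !is_ts & !is_tv1 & u < p["ts"] + 2 * p["tv"]
  child[is_ts] <- ts_map[code[is_ts]]
  child[is_tv1] <- tv1_map[code[is_tv1]]
  child[is_tv2] <- tv2_map[code[is_tv2]]
  if (as_char) paste(c("A", "C", "G", "T")[child], collapse = "") else child
}

#' Simulate a two-species multi-marker dataset with known truth
#'
#' Per marker (with its own RNG substream derived from `seed`): an ancestral
#' sequence is drawn at the target GC; the two species ancestors evolve from
#' it along branches of `inter_divergence / 2` each; `n_diagnostic_sites`
#' additional columns are overwritten with fixed differing states. Every
#' column where the species ancestors differ is recorded as a diagnostic
#' column (`planted` flags the overwritten ones) and is immune to the
#' within-species process: each sample then evolves from its species
#' ancestor along a terminal branch of `intra_divergence / 2` restricted to
#' the non-diagnostic columns. Finally samples are dropped from the marker
#' at `missing_rate` (always keeping at least two per species). Alignments
#' are simulated gap-free; `gap_rate` optionally masks random cells with
#' `-` to exercise pairwise-deletion code paths.
#'
#' @param specs List of [marker_spec()] objects.
#' @param n_per_species Samples per species: a single integer or a length-2
#'   vector (default `c(16, 22)`).
#' @param seed Integer seed; marker `i` uses substream `seed + i`.
#' @param species_names Length-2 character vector of species labels.
#' @param genus Genus label shared by both species.
#' @param gap_rate Per-cell probability of masking with `-` (default 0).
#' @return A list of class `barcode_dataset`: `alignments` (named list of
#'   [labeled_alignment()]), `metadata` (data frame over all samples),
#'   `truth` (list with `diagnostics` data frame — `marker`, `position`,
#'   `state_species1`, `state_species2`, `planted` — and `divergences`
#'   data frame), and `seed`.
#' @export
simulate_dataset <- function(specs, n_per_species = c(16, 22), seed = 1,
                             species_names = c("species_A", "species_B"),
                             genus = "Genus", gap_rate = 0) {
  if (inherits(specs, "marker_spec")) specs <- list(specs)
  if (length(n_per_species) == 1L)
    n_per_species <- rep(n_per_species, 2L)
  stopifnot(all(n_per_species >= 2L), length(species_names) == 2L)

  bases <- c("A", "C", "G", "T")
  ids <- c(paste0("A", seq_len(n_per_species[1L])),
           paste0("B", seq_len(n_per_species[2L])))
  sp_of <- rep(species_names, n_per_species)
  metadata <- data.frame(sample_id = ids, species = sp_of,
                         genus = genus, origin = "simulated",
                         stringsAsFactors = FALSE)

  alignments <- list()
  diag_rows <- list()
  for (mi in seq_along(specs)) {
    spec <- specs[[mi]]
    set.seed(seed + mi)
    L <- spec$length
    gc <- spec$gc_target
    root <- sample.int(4L, L, replace = TRUE,
                       prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    anc1 <- evolve_sequence(root, spec$inter_divergence / 2, spec$kappa)
    anc2 <- evolve_sequence(root, spec$inter_divergence / 2, spec$kappa)

    if (spec$n_diagnostic_sites > 0L) {
      free <- setdiff(seq_len(L), which(anc1 != anc2))
      if (length(free) < spec$n_diagnostic_sites)
        stop("not enough columns left for planted diagnostics", call. = FALSE)
      planted <- sort(sample(free, spec$n_diagnostic_sites))
      # force a transition difference at each planted column
      anc2[planted] <- c(3L, 4L, 1L, 2L)[anc1[planted]]
    } else planted <- integer(0)

    diagnostic <- which(anc1 != anc2)
    if (length(diagnostic))
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        marker = spec$name, position = diagnostic,
        state_species1 = bases[anc1[diagnostic]],
        state_species2 = bases[anc2[diagnostic]],
        planted = diagnostic %in% planted, stringsAsFactors = FALSE)

    evolve_masked <- function(anc) {
      child <- evolve_sequence(anc, spec$intra_divergence / 2, spec$kappa)
      child[diagnostic] <- anc[diagnostic]
      child
    }
    seq_mat <- matrix("", nrow = length(ids), ncol = L,
                      dimnames = list(ids, NULL))
    for (k in seq_along(ids)) {
      anc <- if (sp_of[k] == species_names[1L]) anc1 else anc2
      seq_mat[k, ] <- bases[evolve_masked(anc)]
    }
    if (gap_rate > 0) {
      mask <- matrix(stats::runif(length(seq_mat)) < gap_rate,
                     nrow = nrow(seq_mat))
      seq_mat[mask] <- "-"
    }

    keep <- stats::runif(length(ids)) >= spec$missing_rate
    for (s in species_names) {  # never drop a species below 2 samples
      rows <- which(sp_of == s)
      if (sum(keep[rows]) < 2L) keep[rows[1:2]] <- TRUE
    }
    alignments[[spec$name]] <- labeled_alignment(
      seq_mat[keep, , drop = FALSE], metadata, marker = spec$name,
      sample_ids = ids[keep])
  }

  truth <- list(
    diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows)
      else data.frame(marker = character(0), position = integer(0),
                      state_species1 = character(0),
                      state_species2 = character(0), planted = logical(0)),
    divergences = data.frame(
      marker = vapply(specs, `[[`, character(1), "name"),
      inter_divergence = vapply(specs, `[[`, numeric(1), "inter_divergence"),
      intra_divergence = vapply(specs, `[[`, numeric(1), "intra_divergence"),
      stringsAsFactors = FALSE),
    species_names = species_names
  )
  structure(list(alignments = alignments, metadata = metadata,
                 truth = truth, seed = seed),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat("<barcode_dataset>", length(x$alignments), "markers;",
      nrow(x$metadata), "samples; seed", x$seed, "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned FASTA per marker plus `metadata.tsv` and `truth.tsv`,
#' all byte-deterministic given the dataset.
#'
#' @param dataset A `barcode_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in dataset$alignments)
    write_labeled_fasta(aln, file.path(dir, paste0(aln$marker, ".fasta")))
  .write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  .write_tsv(dataset$truth$diagnostics, file.path(dir, "truth.tsv"))
  invisible(dir)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
}

#' Marker specifications emulating the published two-species study design
#'
#' Seven single markers whose aligned lengths, GC contents, missingness and
#' divergence regimes emulate the published per-marker summaries for a pair
#' of closely related tree species: one marker (`trnH-psbA`-like) with a
#' clean species separation and a planted diagnostic column, one highly
#' variable marker whose intraspecific variation rivals the interspecific
#' signal (`trnL-trnF`-like), one with intraspecific exceeding interspecific
#' divergence (`ycf3`-like), and weakly informative plastid markers. The
#' ancestral separation of each marker is the reported mean interspecific
#' minus mean intraspecific distance (floored at 0), so that realised mean
#' interspecific distances approximate the reported values.
#'
#' @return A named list of [marker_spec()] objects.
#' @export
dalbergia_specs <- function() {
  make <- function(name, len, inter, intra, gc, n_obs, n_diag = 0) {
    marker_spec(name, len,
                inter_divergence = max(0, inter - intra),
                intra_divergence = intra, gc_target = gc,
                n_diagnostic_sites = n_diag,
                missing_rate = max(0, 1 - n_obs / 38))
  }
  specs <- list(
    make("ITS2",      558, 0.0067, 0.0054, 0.637, 37),
    make("matK",      866, 0.0021, 0.0012, 0.366, 16),
    make("trnS-psbC", 347, 0.0033, 0.0030, 0.392, 29),
    make("trnH-psbA", 256, 0.0279, 0.0000, 0.276, 33, n_diag = 1),
    make("trnL-trnF", 409, 0.0828, 0.0652, 0.354, 14),
    make("trnL_intron", 519, 0.0005, 0.0005, 0.341, 30),
    make("ycf3",      690, 0.0154, 0.0161, 0.288, 15)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Marker combinations evaluated alongside the single markers
#'
#' @return List of character vectors of marker names, matching the
#'   combined-barcode constructions evaluated with [dalbergia_specs()].
#' @export
dalbergia_combinations <- function() {
  list(c("trnL-trnF", "ITS2"),
       c("trnL-trnF", "trnH-psbA"),
       c("ITS2", "trnH-psbA"),
       c("trnL-trnF", "ITS2", "trnH-psbA"))
}
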