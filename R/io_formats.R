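## Labeled alignments: the central container tying aligned sequences to
## sample ids and species/genus labels.

.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

#' Construct a labeled alignment
#'
#' A labeled alignment holds the aligned sequences of one marker (or of a
#' concatenation of markers) together with the sample id, species and genus
#' of every row. All downstream analyses (site statistics, K2P distances,
#' diagnostic rules, trees) consume this container.
#'
#' @param seqs Either a character vector of equal-length aligned sequences
#'   (IUPAC nucleotide codes plus `-`), or a character matrix with one row
#'   per sample and one single-character column per alignment position.
#' @param meta A data frame with columns `sample_id`, `species`, `genus`
#'   (and optionally `origin`), one row per sequence, matched by `sample_id`.
#' @param marker Marker name.
#' @param sample_ids Sample ids for the rows of `seqs`; defaults to
#'   `names(seqs)`/`rownames(seqs)`.
#' @param partitions Optional named integer vector of per-marker lengths for
#'   concatenated alignments (in concatenation order, summing to the total
#'   alignment length).
#' @return An object of class `labeled_alignment`: a list with elements
#'   `marker`, `seq` (character matrix, rownames = sample ids), `meta`
#'   (data frame aligned to the rows), `length`, and `partitions`.
#' @seealso [read_labeled_fasta()], [concatenate_markers()]
#' @export
labeled_alignment <- function(seqs, meta, marker = "marker",
                              sample_ids = NULL, partitions = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    if (is.null(sample_ids)) sample_ids <- rownames(seqs)
  } else {
    if (!is.character(seqs) || length(seqs) == 0L)
      stop("'seqs' must be a non-empty character vector or matrix", call. = FALSE)
    if (is.null(sample_ids)) sample_ids <- names(seqs)
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(range(widths), collapse = "-"), ")", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  }
  if (is.null(sample_ids))
    stop("sample ids are required (names/rownames of 'seqs')", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in alignment", call. = FALSE)
  rownames(mat) <- sample_ids

  bad <- setdiff(unique(as.vector(mat)), .IUPAC_CHARS)
  if (length(bad))
    stop("alignment error: non-IUPAC characters: ",
         paste(bad, collapse = " "), call. = FALSE)

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "species", "genus")
  if (!all(req %in% names(meta)))
    stop("metadata error: metadata must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  missing_ids <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_ids))
    stop("metadata error: sample ids absent from metadata: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(!nzchar(meta$species)) || any(!nzchar(meta$genus)) ||
      anyNA(meta$species) || anyNA(meta$genus))
    stop("metadata error: species and genus must be non-empty", call. = FALSE)

  if (!is.null(partitions)) {
    partitions[] <- as.integer(round(partitions))
    if (is.null(names(partitions)) || sum(partitions) != ncol(mat))
      stop("'partitions' must be named and sum to the alignment length",
           call. = FALSE)
  }

  structure(
    list(marker = marker, seq = mat, meta = meta,
         length = ncol(mat), partitions = partitions),
    class = "labeled_alignment"
  )
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("<labeled_alignment> marker:", x$marker, "\n")
  cat("  ", nrow(x$seq), "samples x", x$length, "columns;",
      length(unique(x$meta$species)), "species\n")
  if (!is.null(x$partitions))
    cat("  partitions:",
        paste(names(x$partitions), x$partitions, sep = "=", collapse = " "),
        "\n")
  invisible(x)
}

#' @export
as.matrix.labeled_alignment <- function(x, ...) x$seq

#' Sample ids of a labeled alignment
#' @param aln A [labeled_alignment()].
#' @return Character vector of sample ids in row order.
#' @export
sample_ids <- function(aln) rownames(aln$seq)

#' Species labels of a labeled alignment
#' @param aln A [labeled_alignment()].
#' @return Named character vector (names = sample ids).
#' @export
species_labels <- function(aln) {
  stats::setNames(aln$meta$species, aln$meta$sample_id)
}

#' Read an aligned FASTA file with sample metadata
#'
#' Reads one marker's aligned FASTA and attaches species/genus labels from a
#' metadata table. FASTA record ids must match `sample_id` entries exactly
#' (no description parsing); records absent from the metadata are rejected.
#' Sequences are uppercased on read; gaps (`-`) and IUPAC ambiguity codes are
#' kept as stored and interpreted downstream.
#'
#' @param fasta_path Path to an aligned FASTA file (equal-length records).
#' @param metadata_path Path to a tab-separated metadata file with a header
#'   and columns `sample_id`, `species`, `genus`, `origin` (or a data frame).
#' @param marker_name Marker name recorded on the result.
#' @return A [labeled_alignment()].
#' @export
read_labeled_fasta <- function(fasta_path, metadata_path, marker_name) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L)
    stop("input error: no sequences in ", fasta_path, call. = FALSE)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("alignment error: records in ", fasta_path,
         " have unequal lengths; input must be aligned", call. = FALSE)
  meta <- if (is.data.frame(metadata_path)) metadata_path else
    read_metadata(metadata_path)
  ids <- sub("\\s.*$", "", names(seqs))  # ids must be bare; be strict below
  if (!identical(ids, names(seqs)))
    stop("metadata error: FASTA ids must equal sample_id exactly ",
         "(no descriptions)", call. = FALSE)
  labeled_alignment(as.character(seqs), meta, marker = marker_name,
                    sample_ids = ids)
}

#' Read a sample metadata table
#'
#' @param path Path to a TSV with header columns `sample_id`, `species`,
#'   `genus` and optionally `origin`.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  req <- c("sample_id", "species", "genus")
  if (!all(req %in% names(meta)))
    stop("metadata error: ", path, " must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("metadata error: duplicate sample_id in ", path, call. = FALSE)
  meta
}

#' Write a labeled alignment as FASTA
#'
#' @param aln A [labeled_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_fasta <- function(aln, path) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  con <- file(path, open = "wb")  # byte-deterministic output
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con, sep = "\n")
  invisible(path)
}

#' Concatenate marker alignments into a combined barcode
#'
#' Builds a combined-barcode alignment from two or more single-marker
#' alignments. The combined sample set is the intersection of the input
#' sample sets (a sample missing from any one marker is dropped), so the
#' combined sample count can fall below each input's count. Partition
#' boundaries are recorded so positions in the combined matrix can be mapped
#' back to (marker, local position) with [map_combined_position()].
#'
#' @param alignments List of [labeled_alignment()] objects.
#' @param order Character vector of marker names giving the concatenation
#'   order; must cover exactly the supplied markers. Defaults to input order.
#' @return A [labeled_alignment()] whose `marker` is the `+`-joined marker
#'   names and whose `partitions` record per-marker lengths.
#' @export
concatenate_markers <- function(alignments, order = NULL) {
  if (length(alignments) < 2L)
    stop("need at least two alignments to concatenate", call. = FALSE)
  nm <- vapply(alignments, function(a) a$marker, character(1))
  names(alignments) <- nm
  if (is.null(order)) order <- nm
  if (!setequal(order, nm) || length(order) != length(nm))
    stop("'order' must cover exactly the given markers", call. = FALSE)
  alignments <- alignments[order]

  shared <- Reduce(intersect, lapply(alignments, sample_ids))
  if (length(shared) == 0L)
    stop("concatenation error: no samples shared by all markers",
         call. = FALSE)
  meta <- alignments[[1L]]$meta
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  if (length(unique(meta$species)) < 2L)
    stop("concatenation error: fewer than 2 species among shared samples",
         call. = FALSE)

  mats <- lapply(alignments, function(a) a$seq[shared, , drop = FALSE])
  combined <- do.call(cbind, mats)
  partitions <- stats::setNames(
    vapply(alignments, function(a) a$length, integer(1)), order)
  labeled_alignment(combined, meta, marker = paste(order, collapse = "+"),
                    sample_ids = shared, partitions = partitions)
}

#' Map a combined-alignment position back to its source marker
#'
#' @param aln A concatenated [labeled_alignment()] with partitions.
#' @param position 1-based column index in the combined alignment.
#' @return A list with `marker` and `position` (1-based within that marker).
#' @export
map_combined_position <- function(aln, position) {
  if (is.null(aln$partitions))
    return(list(marker = aln$marker, position = as.integer(position)))
  if (position < 1L || position > aln$length)
    stop("position out of range", call. = FALSE)
  ends <- cumsum(aln$partitions)
  idx <- which(position <= ends)[1L]
  offset <- if (idx == 1L) 0L else ends[idx - 1L]
  list(marker = names(aln$partitions)[idx],
       position = as.integer(position - offset))
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are always written; internal-node support values (stored in
#' `node.label`) are written as internal node labels when present.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0L)
    stop("empty or invalid tree", call. = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}
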