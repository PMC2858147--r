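#' @useDynLib recombscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd rexp rpois runif pnorm setNames
#' @importFrom utils read.delim write.table combn head
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# bitmask state sets (A=1, C=2, G=4, T=8) used by the parsimony kernels
IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                V = 7L, N = 15L, "-" = 15L)

# plain ACGT codes (1..4); ambiguity and gaps are 0 = unscored
ACGT_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Construct a per-locus alignment
#'
#' A `locus_alignment` stores one aligned locus as a character matrix
#' (strains in rows, columns in alignment coordinates) over the IUPAC DNA
#' alphabet plus `-`.  Sequences are upper-cased and `U` is normalised to
#' `T` on construction.
#'
#' @param seqs named character vector of aligned sequences, or a character
#'   matrix with one row per strain (rownames = strain ids).
#' @param locus_name name of the locus (e.g. `"tef1"`).
#' @return an object of class `locus_alignment` with fields `locus_name`,
#'   `ids`, `seqs` (character matrix) and `length`.
#' @export
locus_alignment <- function(seqs, locus_name = "locus") {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    mat <- toupper(seqs)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named by strain id")
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment error: rows have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (anyDuplicated(ids)) {
    stop("id error: duplicate strain ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), IUPAC_CHARS)
  if (length(bad)) {
    stop("alphabet error: illegal characters: ", paste(bad, collapse = ", "))
  }
  structure(list(locus_name = locus_name, ids = ids, seqs = mat,
                 length = ncol(mat)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_name, ": ", length(x$ids),
      " sequences x ", x$length, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA file of pre-aligned sequences and validates it as a
#' [locus_alignment]: equal row lengths, unique ids, IUPAC alphabet.
#' Headers are taken up to the first whitespace.
#'
#' @param path path to an aligned FASTA file.
#' @param locus_name locus label for the resulting alignment.
#' @return a [locus_alignment].
#' @export
read_fasta_alignment <- function(path, locus_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1L]], ">")) {
    stop("input error: not a FASTA file: ", path)
  }
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  # split() orders by factor level; restore file order
  seqs <- seqs[order(as.integer(names(seqs)))]
  names(seqs) <- ids
  locus_alignment(seqs, locus_name)
}

#' Write a locus alignment to FASTA
#'
#' @param alignment a [locus_alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  d <- ape::as.DNAbin(alignment$seqs)
  ape::write.FASTA(d, path)
  invisible(path)
}

#' Read a strain manifest
#'
#' Parses the tab-separated strain manifest (one row per strain: id,
#' collection numbers, origin, habitat, one GenBank accession column per
#' locus, subclade label, teleomorph and ex-type flags).  A record is
#' "complete" when accessions are present for all three loci.
#'
#' @param path path to a TSV manifest.
#' @param locus_cols names of the accession columns
#'   (default `c("tef1","cal1","chi18_5")`).
#' @return a `data.frame` with one row per strain and a logical
#'   `complete` column appended.
#' @export
read_strain_manifest <- function(path,
                                 locus_cols = c("tef1", "cal1", "chi18_5")) {
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(m) == 0L) stop("input error: empty manifest: ", path)
  required <- c("strain_id", "origin", "habitat", locus_cols,
                "subclade", "teleomorph", "ex_type")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    stop("schema error: manifest lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(m$strain_id)) {
    stop("id error: duplicate strain ids in manifest")
  }
  m$teleomorph <- as.logical(m$teleomorph)
  m$ex_type <- as.logical(m$ex_type)
  acc <- as.matrix(m[, locus_cols, drop = FALSE])
  m$complete <- apply(acc, 1L, function(r) all(!is.na(r) & nzchar(trimws(r))))
  m
}

#' Assemble a multilocus dataset
#'
#' Binds per-locus alignments to a strain manifest over a shared strain
#' set.  Under `policy = "strict"` every manifest strain must be present in
#' every alignment; under `"intersect"` the dataset is restricted to
#' strains present in the manifest and in all loci, and the dropped strains
#' are recorded in the `drops` attribute.
#'
#' @param manifest data.frame with a `strain_id` column.
#' @param alignments named list of [locus_alignment] objects (names are
#'   locus names).
#' @param policy `"strict"` or `"intersect"`.
#' @return a `multilocus_dataset`: list with `loci` (named list of
#'   alignments, rows in manifest order) and `manifest`.
#' @export
assemble_dataset <- function(manifest, alignments,
                             policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  if (anyDuplicated(names(alignments)) || is.null(names(alignments))) {
    stop("locus names must be unique and non-empty")
  }
  shared <- manifest$strain_id
  for (a in alignments) shared <- intersect(shared, a$ids)
  if (policy == "strict") {
    for (a in alignments) {
      miss <- setdiff(manifest$strain_id, a$ids)
      if (length(miss)) {
        stop("dataset error: strains missing from locus ", a$locus_name,
             ": ", paste(miss, collapse = ", "))
      }
    }
  }
  if (!length(shared)) stop("dataset error: empty strain intersection")
  drops <- setdiff(manifest$strain_id, shared)
  keep <- manifest$strain_id %in% shared
  manifest <- manifest[keep, , drop = FALSE]
  loci <- lapply(alignments, function(a) {
    m <- a$seqs[match(manifest$strain_id, a$ids), , drop = FALSE]
    rownames(m) <- manifest$strain_id
    locus_alignment(m, a$locus_name)
  })
  names(loci) <- names(alignments)
  structure(list(loci = loci, manifest = manifest),
            class = "multilocus_dataset", drops = drops)
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("<multilocus_dataset> ", nrow(x$manifest), " strains, ",
      length(x$loci), " loci (",
      paste(vapply(x$loci, function(a) paste0(a$locus_name, ":", a$length),
                   ""), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Concatenate the loci of a dataset
#'
#' @param dataset a `multilocus_dataset`.
#' @return list with `alignment` (a [locus_alignment] named `"concat"`) and
#'   `partition`, a data.frame of 0-based half-open column ranges
#'   (`locus`, `start`, `end`) in concatenated coordinates.
#' @export
concatenate <- function(dataset) {
  mats <- lapply(dataset$loci, function(a) a$seqs)
  lens <- vapply(dataset$loci, function(a) a$length, 0L)
  ends <- cumsum(lens)
  partition <- data.frame(locus = vapply(dataset$loci,
                                         function(a) a$locus_name, ""),
                          start = c(0L, head(ends, -1L)),
                          end = ends, row.names = NULL,
                          stringsAsFactors = FALSE)
  aln <- locus_alignment(do.call(cbind, mats), "concat")
  list(alignment = aln, partition = partition)
}

#' Extract one partition's columns from a concatenated alignment
#'
#' @param alignment concatenated [locus_alignment].
#' @param partition partition table from [concatenate()].
#' @param locus locus name to slice out.
#' @return a [locus_alignment] restricted to that locus's columns.
#' @export
slice_partition <- function(alignment, partition, locus) {
  row <- partition[partition$locus == locus, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown locus: ", locus)
  cols <- seq.int(row$start + 1L, row$end)
  locus_alignment(alignment$seqs[, cols, drop = FALSE], locus)
}

#' Clone-correct a multilocus dataset
#'
#' Strains whose concatenated sequences are exactly identical (literal
#' string equality, gaps and ambiguity codes included) are collapsed to a
#' single representative, the first member in manifest order.
#'
#' @param dataset a `multilocus_dataset`.
#' @return list with `dataset` (clone-corrected) and `map`, a data.frame
#'   mapping every input `strain_id` to its `representative`.
#' @export
clone_correct <- function(dataset) {
  if (nrow(dataset$manifest) < 1L) stop("dataset has no strains")
  strings <- do.call(paste0, lapply(dataset$loci, function(a) {
    apply(a$seqs, 1L, paste0, collapse = "")
  }))
  rep_idx <- match(strings, strings)  # first occurrence in manifest order
  ids <- dataset$manifest$strain_id
  map <- data.frame(strain_id = ids, representative = ids[rep_idx],
                    stringsAsFactors = FALSE)
  keep <- !duplicated(strings)
  manifest <- dataset$manifest[keep, , drop = FALSE]
  loci <- lapply(dataset$loci, function(a) {
    locus_alignment(a$seqs[keep, , drop = FALSE], a$locus_name)
  })
  out <- structure(list(loci = loci, manifest = manifest),
                   class = "multilocus_dataset")
  list(dataset = out, map = map)
}

#' Filter alignment columns by gap/ambiguity fraction
#'
#' Removes columns whose fraction of gap or ambiguity characters (anything
#' other than A, C, G, T) exceeds `max_gap_fraction`; a plain stand-in for
#' heavier alignment-trimming pipelines.
#'
#' @param alignment a [locus_alignment].
#' @param max_gap_fraction threshold in \[0, 1\].
#' @return filtered [locus_alignment]; the removed 1-based column indices
#'   are in attribute `removed_columns`.
#' @export
filter_columns <- function(alignment, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  frac <- colMeans(matrix(!(alignment$seqs %in% c("A", "C", "G", "T")),
                          nrow = nrow(alignment$seqs)))
  keep <- frac <= max_gap_fraction
  if (!any(keep)) stop("empty-alignment error: all columns removed")
  out <- locus_alignment(alignment$seqs[, keep, drop = FALSE],
                         alignment$locus_name)
  attr(out, "removed_columns") <- which(!keep)
  out
}

# internal: encode an alignment as bitmask states (tips x sites)
aln_bits <- function(alignment) {
  m <- matrix(IUPAC_BITS[alignment$seqs], nrow = nrow(alignment$seqs))
  rownames(m) <- alignment$ids
  m
}

# internal: encode as plain ACGT codes, 0 = gap/ambiguity (unscored)
aln_codes <- function(alignment) {
  v <- ACGT_CODE[alignment$seqs]
  v[is.na(v)] <- 0L
  m <- matrix(as.integer(v), nrow = nrow(alignment$seqs))
  rownames(m) <- alignment$ids
  m
}

# internal: subset an alignment to a strain set (keeping given order)
subset_alignment <- function(alignment, ids) {
  miss <- setdiff(ids, alignment$ids)
  if (length(miss)) stop("id error: unknown strains: ",
                         paste(miss, collapse = ", "))
  locus_alignment(alignment$seqs[match(ids, alignment$ids), , drop = FALSE],
                  alignment$locus_name)
}

# internal: subset a dataset to a strain set (manifest order preserved)
subset_dataset <- function(dataset, ids) {
  keep <- dataset$manifest$strain_id %in% ids
  if (!any(keep)) stop("dataset error: no strains retained")
  manifest <- dataset$manifest[keep, , drop = FALSE]
  loci <- lapply(dataset$loci, function(a)
    subset_alignment(a, manifest$strain_id))
  structure(list(loci = loci, manifest = manifest),
            class = "multilocus_dataset")
}
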