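#' Evaluate one candidate clade against per-locus clade tables
#'
#' Genealogical concordance species recognition (Dettman-style criteria):
#' a candidate clade is *supported* in a locus iff, restricted to that
#' locus's taxa, it equals one side of a supported bipartition; it is
#' *contradicted* in a locus iff any supported bipartition there is
#' incompatible with it ([clades_compatible]).  The verdict is
#' `"recognized"` when the clade is supported in at least one locus and
#' contradicted in none, `"contradicted"` when any locus contradicts it,
#' and `"unsupported"` otherwise.  Restrictions to fewer than two taxa
#' count as neither support nor contradiction.
#'
#' @param clade character vector of strain ids (>= 2, and not the whole
#'   taxon set).
#' @param clade_tables list of `clade_table` objects, one per locus (build
#'   with [extract_clades()]); their `support` values are assumed already
#'   filtered at construction, and `support_threshold` re-filters here.
#' @param support_threshold minimum support for a bipartition to count.
#' @return a `species_hypothesis`: list with `clade`, `supporting_loci`,
#'   `contradicting_loci`, `verdict`.
#' @export
evaluate_candidate <- function(clade, clade_tables,
                               support_threshold = 0.95) {
  clade <- sort(unique(clade))
  all_taxa <- sort(unique(unlist(lapply(clade_tables,
                                        function(ct) ct$taxa))))
  if (length(clade) < 2L || setequal(clade, all_taxa)) {
    stop("trivial-clade error: candidate must be a proper clade of >= 2")
  }
  supporting <- character(0)
  contradicting <- character(0)
  for (ct in clade_tables) {
    restricted <- intersect(clade, ct$taxa)
    if (length(restricted) < 2L) next
    keep <- which(ct$support >= support_threshold)
    supported_here <- FALSE
    contradicted_here <- FALSE
    for (k in keep) {
      side <- ct$sides[[k]]
      other <- setdiff(ct$taxa, side)
      if (setequal(restricted, side) || setequal(restricted, other)) {
        supported_here <- TRUE
      }
      if (!clades_compatible(side, restricted, ct$taxa)) {
        contradicted_here <- TRUE
      }
    }
    if (supported_here) supporting <- c(supporting, ct$locus_name)
    if (contradicted_here) contradicting <- c(contradicting, ct$locus_name)
  }
  verdict <- if (length(contradicting)) "contradicted"
    else if (length(supporting)) "recognized" else "unsupported"
  structure(list(clade = clade, supporting_loci = supporting,
                 contradicting_loci = contradicting, verdict = verdict),
            class = "species_hypothesis")
}

#' @export
print.species_hypothesis <- function(x, ...) {
  cat("<species_hypothesis> {", paste(x$clade, collapse = ","), "}: ",
      x$verdict, "\n  supported in: ",
      paste(x$supporting_loci, collapse = ", "),
      if (length(x$contradicting_loci))
        paste0("\n  contradicted in: ",
               paste(x$contradicting_loci, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Recognize phylogenetic species by genealogical concordance
#'
#' Runs [evaluate_candidate()] over a candidate set and reports every
#' hypothesis, ordered by clade size then lexicographically.  Nested
#' recognized clades are annotated with their containing recognized clade
#' (`contained_in`).
#'
#' @param clade_tables list of per-locus `clade_table` objects.
#' @param candidates either a list of character vectors (user candidates),
#'   a single `clade_table` (e.g. from the combined tree -- its supported
#'   sides become the candidates), or `NULL` to use the union of all
#'   supported clade sides across the per-locus tables.
#' @param support_threshold minimum support.
#' @return data.frame with columns `clade` (comma-separated ids), `size`,
#'   `verdict`, `supporting_loci`, `contradicting_loci`, `contained_in`.
#' @export
recognize_species <- function(clade_tables, candidates = NULL,
                              support_threshold = 0.95) {
  all_taxa <- sort(unique(unlist(lapply(clade_tables,
                                        function(ct) ct$taxa))))
  both_sides <- function(ct) {
    sides <- ct$sides[ct$support >= support_threshold]
    c(sides, lapply(sides, function(s) setdiff(ct$taxa, s)))
  }
  cand <- if (is.null(candidates)) {
    unlist(lapply(clade_tables, both_sides), recursive = FALSE)
  } else if (inherits(candidates, "clade_table")) {
    both_sides(candidates)
  } else candidates
  cand <- lapply(cand, function(x) sort(unique(x)))
  cand <- cand[!duplicated(vapply(cand, paste, "", collapse = ","))]
  cand <- Filter(function(x) length(x) >= 2L && !setequal(x, all_taxa),
                 cand)
  if (!length(cand)) {
    warning("empty candidate set")
    return(data.frame(clade = character(0), size = integer(0),
                      verdict = character(0), supporting_loci = character(0),
                      contradicting_loci = character(0),
                      contained_in = character(0)))
  }
  key <- vapply(cand, paste, "", collapse = ",")
  ord <- order(lengths(cand), key)
  cand <- cand[ord]
  hyps <- lapply(cand, evaluate_candidate, clade_tables = clade_tables,
                 support_threshold = support_threshold)
  recognized <- which(vapply(hyps, function(h) h$verdict == "recognized",
                             NA))
  contained <- rep(NA_character_, length(hyps))
  for (i in recognized) {
    for (j in recognized) {
      if (i == j) next
      if (length(hyps[[j]]$clade) > length(hyps[[i]]$clade) &&
            all(hyps[[i]]$clade %in% hyps[[j]]$clade)) {
        contained[i] <- paste(hyps[[j]]$clade, collapse = ",")
        break
      }
    }
  }
  data.frame(
    clade = vapply(hyps, function(h) paste(h$clade, collapse = ","), ""),
    size = vapply(hyps, function(h) length(h$clade), 0L),
    verdict = vapply(hyps, function(h) h$verdict, ""),
    supporting_loci = vapply(hyps, function(h)
      paste(h$supporting_loci, collapse = ","), ""),
    contradicting_loci = vapply(hyps, function(h)
      paste(h$contradicting_loci, collapse = ","), ""),
    contained_in = contained,
    stringsAsFactors = FALSE)
}
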