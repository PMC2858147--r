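#' Rank candidate strains by phylogenetic proximity to a focal clade
#'
#' Each candidate is scored by its mean patristic distance (on a supplied
#' tree, typically the combined NJ tree) to the focal-clade members, and
#' candidates are returned in ascending order; ties break lexicographically
#' by strain id.
#'
#' @param tree a `phylo` with branch lengths containing all strains.
#' @param focal_clade character vector of focal strain ids.
#' @param candidates character vector of candidate strain ids.
#' @return data.frame with `strain` and `distance`, ordered.
#' @export
rank_candidates <- function(tree, focal_clade, candidates) {
  miss <- setdiff(c(focal_clade, candidates), tree$tip.label)
  if (length(miss)) stop("id error: strains not in tree: ",
                         paste(miss, collapse = ", "))
  if (!length(focal_clade)) stop("focal clade is empty")
  D <- stats::cophenetic(tree)
  dist <- vapply(candidates, function(s)
    mean(D[s, focal_clade]), 0)
  ord <- order(dist, candidates)
  data.frame(strain = candidates[ord], distance = unname(dist[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan for the inner and outer borders of a recombining population
#'
#' Implements the iterative trial-and-error procedure: a non-recombining
#' baseline is formed from the focal clade plus distant control strains
#' and must itself pass the Phi test (`p >= alpha`).  Candidates are then
#' tested in order of increasing phylogenetic distance to the focal clade.
#' In `"fixed-baseline"` mode (default) each candidate is tested as
#' baseline + that candidate alone, so a triggering strain is excluded
#' from all later samples; in `"cumulative"` mode non-triggering
#' candidates accumulate into the sample.  The scan continues past the
#' first trigger through progressively more distant candidates; the first
#' triggering strain marks the inner border, the last the outer border,
#' and the recombining population is the focal clade plus all triggering
#' candidates.  Steps where Phi is not computable (too few informative
#' sites) are recorded and skipped.
#'
#' @param dataset a `multilocus_dataset` containing all strains involved.
#' @param tree ranking tree (combined NJ tree) containing all strains.
#' @param focal_clade character vector: the focal clade.
#' @param distant_controls character vector: distant control strains.
#' @param candidates candidate strains; defaults to all dataset strains
#'   not in the focal clade or controls.
#' @param alpha significance level for a Phi trigger.
#' @param phi_opts list of options passed to [phi_test()] (`window_w`,
#'   `n_permutations`).
#' @param mode `"fixed-baseline"` or `"cumulative"`.
#' @param seed master seed; each step uses `seed + step index`.
#' @return a `border_scan` result: `focal_clade`, `baseline` (strains and
#'   its phi p), `steps` (data.frame: strain, rank_distance, sample_size,
#'   phi_p, triggered), `inner_border_trigger`, `outer_border`,
#'   `recombining_population`, `alpha`, `seed`.
#' @export
scan_borders <- function(dataset, tree, focal_clade, distant_controls,
                         candidates = NULL, alpha = 0.05,
                         phi_opts = list(), mode = c("fixed-baseline",
                                                     "cumulative"),
                         seed = 1L) {
  mode <- match.arg(mode)
  ids <- dataset$manifest$strain_id
  if (is.null(candidates)) {
    candidates <- setdiff(ids, c(focal_clade, distant_controls))
  }
  if (!length(candidates)) stop("scan error: empty candidate list")
  window_w <- phi_opts$window_w %||% 100L
  n_perm <- phi_opts$n_permutations %||% 1000L
  conc_all <- concatenate(dataset)$alignment
  phi_on <- function(strains, step_seed) {
    aln <- subset_alignment(conc_all, strains)
    tryCatch(
      phi_test(aln, window_w = window_w, n_permutations = n_perm,
               seed = step_seed)$p_permutation,
      phi_not_computable = function(e) NA_real_)
  }
  baseline <- c(focal_clade, distant_controls)
  p_base <- phi_on(baseline, seed)
  if (!is.na(p_base) && p_base < alpha) {
    stop("baseline error: baseline sample already shows recombination (p = ",
         signif(p_base, 4), ")")
  }
  ranked <- rank_candidates(tree, focal_clade, candidates)
  sample_now <- baseline
  steps <- vector("list", nrow(ranked))
  triggers <- character(0)
  for (i in seq_len(nrow(ranked))) {
    s <- ranked$strain[i]
    test_set <- if (mode == "fixed-baseline") c(baseline, s)
                else c(sample_now, s)
    p <- phi_on(test_set, seed + i)
    triggered <- !is.na(p) && p < alpha
    if (triggered) triggers <- c(triggers, s)
    else if (mode == "cumulative" && !is.na(p)) sample_now <- test_set
    steps[[i]] <- data.frame(strain = s,
                             rank_distance = ranked$distance[i],
                             sample_size = length(test_set),
                             phi_p = p, triggered = triggered,
                             stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, steps)
  structure(list(
    focal_clade = focal_clade,
    baseline = list(strains = baseline, phi_p = p_base),
    steps = steps,
    inner_border_trigger = if (length(triggers)) triggers[1L] else NA_character_,
    outer_border = if (length(triggers)) triggers[length(triggers)]
                   else NA_character_,
    recombining_population = if (length(triggers))
      c(focal_clade, triggers) else focal_clade,
    alpha = alpha, mode = mode, seed = seed), class = "border_scan")
}

#' @export
print.border_scan <- function(x, ...) {
  cat("<border_scan> focal clade of", length(x$focal_clade),
      "strains; baseline p =", signif(x$baseline$phi_p, 4), "\n",
      sum(x$steps$triggered), "of", nrow(x$steps),
      "candidates triggered (alpha =", x$alpha, ")\n")
  if (any(x$steps$triggered)) {
    cat(" inner border:", x$inner_border_trigger,
        "| outer border:", x$outer_border, "\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg summary of scan step p-values
#'
#' The scan itself applies no multiple-testing correction (individual
#' tests, as the original procedure ran them); this optional summary
#' reports BH-adjusted step p-values separately.
#'
#' @param scan a `border_scan` result.
#' @return the step table with an added `phi_p_bh` column.
#' @export
scan_bh_summary <- function(scan) {
  st <- scan$steps
  st$phi_p_bh <- stats::p.adjust(st$phi_p, method = "BH")
  st
}
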