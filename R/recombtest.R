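#' Refined incompatibility score of a site pair
#'
#' The minimum number of extra (homoplasious) changes needed to fit two
#' sites jointly on any one tree: `l = (V-1) + (C-1) - (k_a-1) - (k_b-1)`,
#' where V is the number of distinct observed joint-state pairs, C the
#' number of connected components of the bipartite graph linking states
#' observed together, and k_a, k_b the per-site state counts.  `l = 0` iff
#' the sites are compatible; for two biallelic sites `l = 1` is the
#' classical four-gamete incompatibility.  Rows that are gapped or
#' ambiguous at either site are excluded pairwise.
#'
#' @param site_a,site_b character vectors (one state per taxon, same
#'   taxa in the same order).
#' @return non-negative integer score.
#' @export
pair_incompatibility <- function(site_a, site_b) {
  stopifnot(length(site_a) == length(site_b))
  a <- ACGT_CODE[toupper(site_a)]; a[is.na(a)] <- 0L
  b <- ACGT_CODE[toupper(site_b)]; b[is.na(b)] <- 0L
  if (sum(a > 0L & b > 0L) < 2L) {
    stop("score undefined: fewer than 2 jointly scored taxa")
  }
  L <- cpp_pair_incompat(cbind(as.integer(a), as.integer(b)))
  as.integer(L[1L, 2L])
}

# internal: condition signalled when Phi cannot be computed (small clades)
phi_not_computable <- function(msg) {
  errorCondition(msg, class = c("phi_not_computable", "recombscan_error"))
}

# internal: parsimony-informative columns of a coded matrix
informative_columns <- function(codes) {
  apply(codes, 2L, function(col) {
    tab <- tabulate(col[col > 0L], nbins = 4L)
    sum(tab >= 2L) >= 2L
  })
}

#' Pairwise homoplasy index (Phi) permutation test for recombination
#'
#' Phi is the mean refined incompatibility ([pair_incompatibility]) over
#' all pairs of parsimony-informative sites whose alignment positions lie
#' within `window_w` nucleotides of each other.  Without recombination the
#' genealogy is shared along the sequence, so incompatibility is unrelated
#' to inter-site distance and site positions are exchangeable; with
#' recombination, nearby sites share genealogies and are *less*
#' incompatible than distant ones, so the observed (nearby-pair) Phi falls
#' below its permutation null.  The permutation p-value is therefore the
#' lower tail: `p = (1 + #\{permuted Phi <= observed\}) / (n + 1)`.
#'
#' @param alignment a [locus_alignment] with >= 4 sequences (typically the
#'   concatenated multilocus alignment).
#' @param window_w window width in alignment positions (nt).
#' @param n_permutations number of site-position permutations.
#' @param seed integer seed for the permutations.
#' @param analytic also report a normal-approximation p-value from the
#'   permutation-null mean and variance.
#' @return a `phi_result`: `phi`, `window_w`, `n_informative_sites`,
#'   `p_permutation`, `p_analytic`, `n_permutations`, `seed`.
#' @export
phi_test <- function(alignment, window_w = 100L, n_permutations = 1000L,
                     seed = NULL, analytic = FALSE) {
  if (length(alignment$ids) < 4L) stop("phi test needs >= 4 sequences")
  codes <- aln_codes(alignment)
  inf <- informative_columns(codes)
  if (sum(inf) < 2L) {
    stop(phi_not_computable(paste0("phi not computable: ", sum(inf),
                                   " informative site(s)")))
  }
  pos <- which(inf)
  S <- length(pos)
  Lm <- cpp_pair_incompat(codes[, inf, drop = FALSE])
  dpos <- outer(pos, pos, function(x, y) y - x)
  pr <- which(dpos >= 1L & dpos <= window_w, arr.ind = TRUE)
  if (nrow(pr) == 0L) {
    stop(phi_not_computable("phi not computable: no site pairs in window"))
  }
  ia <- pr[, 1L]; ib <- pr[, 2L]
  phi_obs <- mean(Lm[ia + (ib - 1L) * S], na.rm = TRUE)
  if (!is.null(seed)) set.seed(seed)
  perm_phi <- cpp_phi_perms(Lm, ia, ib, n_permutations)
  b <- sum(perm_phi <= phi_obs + 1e-12)
  p_perm <- (1 + b) / (n_permutations + 1)
  p_analytic <- NA_real_
  if (analytic) {
    s <- sd(perm_phi)
    p_analytic <- if (s > 0) pnorm((phi_obs - mean(perm_phi)) / s) else 1
  }
  structure(list(phi = phi_obs, window_w = window_w,
                 n_informative_sites = S, n_window_pairs = nrow(pr),
                 p_permutation = p_perm, p_analytic = p_analytic,
                 n_permutations = n_permutations, seed = seed),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat("Phi test: phi =", signif(x$phi, 4), "over", x$n_informative_sites,
      "informative sites (window", x$window_w, "nt)\n",
      "permutation p =", signif(x$p_permutation, 4),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Index of association test for multilocus linkage
#'
#' Computes IA on clone-corrected haplotypes: with `d(j,k)` the number of
#' loci at which haplotypes j and k carry different alleles,
#' `IA = V_obs / V_exp - 1`, where `V_obs` is the variance of `d` over all
#' pairs and `V_exp` the sum of per-locus variances of the mismatch
#' indicator (its value under linkage equilibrium).  IA is 0 under
#' panmixia.  The null distribution permutes allele assignments among
#' individuals independently at each locus; `p = (1 + #\{permuted IA >=
#' observed\}) / (n + 1)`.
#'
#' @param dataset a `multilocus_dataset`.
#' @param n_permutations number of permutations.
#' @param seed integer seed.
#' @param clone_correct collapse identical multilocus haplotypes first
#'   (the default; disable only for worked examples).
#' @return an `ia_result` with fields `ia`, `v_obs`, `v_exp`,
#'   `p_permutation`, `heuristic_reading` (the `<1` supports-panmixia /
#'   `>1` rejects-recombination rule of thumb),
#'   `n_haplotypes_after_clone_correction`, `n_permutations`, `seed`.
#' @export
index_of_association <- function(dataset, n_permutations = 999L,
                                 seed = NULL, clone_correct = TRUE) {
  if (clone_correct) dataset <- clone_correct(dataset)$dataset
  n <- nrow(dataset$manifest)
  if (n < 3L) {
    stop("undefined: fewer than 3 haplotypes after clone correction")
  }
  alleles <- lapply(dataset$loci, function(a) {
    s <- apply(a$seqs, 1L, paste0, collapse = "")
    match(s, unique(s))
  })
  pair_mismatch <- function(a) {
    m <- outer(a, a, "!=")
    as.numeric(m[upper.tri(m)])
  }
  # a locus contributes no linkage-equilibrium variance when its mismatch
  # indicator is constant: monomorphic, or every haplotype unique
  poly <- vapply(alleles, function(a) var(pair_mismatch(a)) > 0, NA)
  if (any(!poly)) {
    warning("dropping loci without mismatch variance: ",
            paste(names(dataset$loci)[!poly], collapse = ", "))
    alleles <- alleles[poly]
  }
  if (length(alleles) < 2L) {
    stop("undefined: fewer than 2 polymorphic loci")
  }
  ia_stat <- function(alls) {
    ind <- vapply(alls, pair_mismatch, numeric(n * (n - 1L) / 2L))
    v_obs <- var(rowSums(ind))
    v_exp <- sum(apply(ind, 2L, var))
    c(ia = v_obs / v_exp - 1, v_obs = v_obs, v_exp = v_exp)
  }
  obs <- ia_stat(alleles)
  if (!is.null(seed)) set.seed(seed)
  perm_ia <- vapply(seq_len(n_permutations), function(k) {
    ia_stat(lapply(alleles, function(a) a[sample.int(n)]))[["ia"]]
  }, 0)
  p <- (1 + sum(perm_ia >= obs[["ia"]] - 1e-12)) / (n_permutations + 1)
  structure(list(ia = obs[["ia"]], v_obs = obs[["v_obs"]],
                 v_exp = obs[["v_exp"]], p_permutation = p,
                 heuristic_reading = if (obs[["ia"]] < 1)
                   "supports panmixia (IA < 1)" else
                     "rejects recombination (IA > 1)",
                 n_haplotypes_after_clone_correction = n,
                 n_permutations = n_permutations, seed = seed),
            class = "ia_result")
}

#' @export
print.ia_result <- function(x, ...) {
  cat("Index of association:", signif(x$ia, 4), "over",
      x$n_haplotypes_after_clone_correction, "haplotypes\n",
      "permutation p =", signif(x$p_permutation, 4), "|",
      x$heuristic_reading, "\n")
  invisible(x)
}

# internal: fast per-partition parsimony machinery for the PHT.
# Site patterns are compressed once over the whole concatenated alignment;
# patterns with a state shared by all rows can never require changes and
# are dropped from scoring.
pht_engine <- function(alignment) {
  bits <- aln_bits(alignment)
  key <- apply(bits, 2L, paste0, collapse = ",")
  uk <- unique(key)
  pat_id <- match(key, uk)
  states <- bits[, match(uk, key), drop = FALSE]
  variable <- apply(states, 2L, function(col) Reduce(bitwAnd, col) == 0L)
  list(pat_id = pat_id, states = states, variable = variable,
       npat = length(uk), ntip = nrow(bits))
}

pht_partition_length <- function(eng, cols, n_starts, nni_max) {
  w <- tabulate(eng$pat_id[cols], nbins = eng$npat)
  sel <- which(w > 0L & eng$variable)
  if (!length(sel)) return(0L)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    ord <- sample.int(eng$ntip) - 1L
    len <- cpp_mp_search(eng$states[, sel, drop = FALSE], w[sel], ord,
                         nni_max)$length
    if (is.null(best) || len < best) best <- len
  }
  best
}

#' Partition-homogeneity (incongruence length difference) test
#'
#' The observed statistic is the sum over partitions (loci) of the
#' maximum-parsimony tree length for that partition's columns.  Each
#' replicate randomly reassigns the concatenated alignment's columns to
#' partitions of the same sizes and recomputes the sum.  Under clonality
#' the loci share one genealogy, so re-partitioned sums resemble the
#' observed one; recombination between loci makes the observed per-locus
#' trees shorter than random re-partitions, hence the lower tail:
#' `p = (1 + #\{T_rep <= T_obs\}) / (n_replicates + 1)`; small p indicates
#' incongruence, i.e. recombination between loci.
#'
#' @param concatenated concatenated [locus_alignment] (>= 4 taxa).
#' @param partition partition table from [concatenate()] (>= 2 rows).
#' @param n_replicates number of random re-partitions.
#' @param seed integer seed.
#' @param search_opts list of options for the internal parsimony search:
#'   `n_starts` (default 1) and `nni_max`.
#' @return a `pht_result` with `t_obs`, `partition_lengths`,
#'   `replicate_lengths`, `p_value`, `n_replicates`, `seed`.
#' @export
pht_test <- function(concatenated, partition, n_replicates = 1000L,
                     seed = NULL, search_opts = list()) {
  if (nrow(partition) < 2L) stop("pht test needs >= 2 partitions")
  if (length(concatenated$ids) < 4L) stop("pht test needs >= 4 taxa")
  n_starts <- search_opts$n_starts %||% 1L
  nni_max <- search_opts$nni_max %||% 10000L
  if (!is.null(seed)) set.seed(seed)
  eng <- pht_engine(concatenated)
  ranges <- lapply(seq_len(nrow(partition)), function(i)
    seq.int(partition$start[i] + 1L, partition$end[i]))
  part_len <- vapply(ranges, function(cols) {
    w <- tabulate(eng$pat_id[cols], nbins = eng$npat)
    if (!any(w > 0L & eng$variable)) {
      warning("partition with no variable columns contributes length 0")
    }
    pht_partition_length(eng, cols, n_starts, nni_max)
  }, 0L)
  t_obs <- sum(part_len)
  L <- concatenated$length
  reps <- vapply(seq_len(n_replicates), function(r) {
    perm <- sample.int(L)
    sum(vapply(ranges, function(cols)
      pht_partition_length(eng, perm[cols], n_starts, nni_max), 0L))
  }, 0L)
  p <- (1 + sum(reps <= t_obs)) / (n_replicates + 1)
  structure(list(t_obs = t_obs, partition_lengths = part_len,
                 replicate_lengths = reps, p_value = p,
                 n_replicates = n_replicates, seed = seed),
            class = "pht_result")
}

#' @export
print.pht_result <- function(x, ...) {
  cat("Partition-homogeneity test: T_obs =", x$t_obs,
      "( per partition:", paste(x$partition_lengths, collapse = " + "),
      ")\n p =", signif(x$p_value, 4), "from", x$n_replicates,
      "re-partitions\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
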