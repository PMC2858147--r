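#' Diversity statistics: S, pi, Watterson theta, Tajima's D
#'
#' Segregating sites S and Tajima's D are computed on complete-deletion
#' columns (sites with any gap/ambiguity dropped); mean pairwise
#' differences pi are reported both on the complete-deletion columns (the
#' value entering D) and under pairwise deletion.  Watterson's estimator
#' is `theta_w = S / a1`, `a1 = sum_{i=1}^{n-1} 1/i`; Tajima's D uses the
#' textbook variance constants (a1, a2, b1, b2, c1, c2, e1, e2).
#'
#' @param alignment a [locus_alignment] with >= 2 sequences.
#' @return a `diversity_stats` list: `n`, `S`, `pi` (complete-deletion,
#'   per sequence pair), `pi_per_site`, `pi_pairwise_deletion`, `theta_w`,
#'   `theta_w_per_site`, `tajima_d` (NA when S = 0, flagged in
#'   `tajima_defined`), `n_complete_sites`.
#' @export
diversity_stats <- function(alignment) {
  codes <- aln_codes(alignment)
  n <- nrow(codes)
  if (n < 2L) stop("diversity statistics need >= 2 sequences")
  complete <- colSums(codes == 0L) == 0L
  cc <- codes[, complete, drop = FALSE]
  S <- sum(apply(cc, 2L, function(col) length(unique(col)) > 1L))
  pairs <- combn(n, 2L)
  diffs_cc <- apply(pairs, 2L, function(p) sum(cc[p[1L], ] != cc[p[2L], ]))
  pi_cc <- mean(diffs_cc)
  diffs_pw <- apply(pairs, 2L, function(p) {
    a <- codes[p[1L], ]; b <- codes[p[2L], ]
    ok <- a > 0L & b > 0L
    sum(a[ok] != b[ok])
  })
  a1 <- sum(1 / seq_len(n - 1L))
  theta_w <- S / a1
  tajima_d <- NA_real_
  if (S > 0L) {
    a2 <- sum(1 / seq_len(n - 1L)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    v <- e1 * S + e2 * S * (S - 1)
    if (v > 0) tajima_d <- (pi_cc - theta_w) / sqrt(v)
  }
  L <- sum(complete)
  structure(list(n = n, S = S, pi = pi_cc,
                 pi_per_site = if (L > 0L) pi_cc / L else NA_real_,
                 pi_pairwise_deletion = mean(diffs_pw),
                 theta_w = theta_w,
                 theta_w_per_site = if (L > 0L) theta_w / L else NA_real_,
                 tajima_d = tajima_d, tajima_defined = S > 0L,
                 n_complete_sites = L),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("n =", x$n, " S =", x$S, " pi =", signif(x$pi, 4),
      " theta_w =", signif(x$theta_w, 4),
      " Tajima's D =", if (x$tajima_defined) signif(x$tajima_d, 4)
      else "undefined (S = 0)", "\n")
  invisible(x)
}

#' Hudson-style FST between two populations
#'
#' `FST = 1 - Hw / Hb`, where `Hw` is the mean within-population pairwise
#' difference count (the two populations' means weighted by their pair
#' counts) and `Hb` the mean pairwise difference count across populations.
#' Values near 0 indicate little differentiation, near 1 strong
#' differentiation; negative estimates are reported as computed.
#'
#' @param alignment a [locus_alignment].
#' @param pop_assignment character or factor of population labels, one per
#'   sequence in alignment order (exactly two populations, each >= 2).
#' @return an `fst_result` list: `pop_labels`, `hw`, `hb`, `fst`.
#' @export
hudson_fst <- function(alignment, pop_assignment) {
  pops <- as.character(pop_assignment)
  labs <- unique(pops)
  if (length(labs) != 2L) stop("exactly two populations required")
  if (any(table(pops) < 2L)) stop("each population needs >= 2 sequences")
  codes <- aln_codes(alignment)
  pd <- function(i, j) {
    a <- codes[i, ]; b <- codes[j, ]
    ok <- a > 0L & b > 0L
    sum(a[ok] != b[ok])
  }
  idx1 <- which(pops == labs[1L]); idx2 <- which(pops == labs[2L])
  within <- function(idx) {
    pr <- combn(idx, 2L)
    vapply(seq_len(ncol(pr)), function(k) pd(pr[1L, k], pr[2L, k]), 0)
  }
  w1 <- within(idx1); w2 <- within(idx2)
  hw <- (sum(w1) + sum(w2)) / (length(w1) + length(w2))
  between <- outer(idx1, idx2, Vectorize(pd))
  hb <- mean(between)
  if (hb == 0) stop("undefined: populations are identical (Hb = 0)")
  structure(list(pop_labels = labs, hw = hw, hb = hb, fst = 1 - hw / hb),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Hudson FST(", x$pop_labels[1L], "vs", x$pop_labels[2L], ") =",
      signif(x$fst, 4), "( Hw =", signif(x$hw, 4), ", Hb =",
      signif(x$hb, 4), ")\n")
  invisible(x)
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Screens all pairs of biallelic sites for four-gamete incompatibility
#' and returns the size of a maximal set of non-overlapping incompatible
#' intervals -- a lower bound on the number of recombination events in the
#' history of the sample.  Sites with gaps/ambiguity or more than two
#' states are skipped.
#'
#' @param alignment a [locus_alignment] with >= 2 sequences.
#' @return integer Rm.
#' @export
min_recombination_events <- function(alignment) {
  codes <- aln_codes(alignment)
  if (nrow(codes) < 2L) stop("Rm needs >= 2 sequences")
  biallelic <- which(apply(codes, 2L, function(col) {
    u <- unique(col[col > 0L])
    length(u) == 2L
  }))
  if (length(biallelic) < 2L) return(0L)
  # four-gamete incompatible intervals
  ivl <- list()
  for (ai in seq_len(length(biallelic) - 1L)) {
    for (bi in seq.int(ai + 1L, length(biallelic))) {
      i <- biallelic[ai]; j <- biallelic[bi]
      a <- codes[, i]; b <- codes[, j]
      ok <- a > 0L & b > 0L
      if (sum(ok) < 2L) next
      if (nrow(unique(cbind(a[ok], b[ok]))) == 4L) {
        ivl[[length(ivl) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(ivl)) return(0L)
  # greedy maximum set of pairwise disjoint open intervals, by right end
  ivl <- ivl[order(vapply(ivl, `[`, 0, 2L))]
  rm_count <- 0L
  last_right <- -Inf
  for (iv in ivl) {
    if (iv[1L] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- iv[2L]
    }
  }
  rm_count
}
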