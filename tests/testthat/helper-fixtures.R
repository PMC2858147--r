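# Small builders and independent oracles used across the test files.

mk_aln <- function(x, name = "L") locus_alignment(x, name)

mk_dataset <- function(...) {
  loci <- list(...)
  if (is.null(names(loci)) || any(!nzchar(names(loci)))) {
    names(loci) <- paste0("L", seq_along(loci))
  }
  alns <- lapply(names(loci), function(nm) mk_aln(loci[[nm]], nm))
  names(alns) <- names(loci)
  ids <- alns[[1L]]$ids
  assemble_dataset(data.frame(strain_id = ids, stringsAsFactors = FALSE),
                   alns, policy = "strict")
}

rand_aln <- function(n, L, gap_rate = 0, seed = NULL, name = "L") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (gap_rate > 0) m[runif(n * L) < gap_rate] <- "-"
  rownames(m) <- paste0("t", seq_len(n))
  locus_alignment(m, name)
}

# Exhaustive-topology joint-Fitch oracle for the refined incompatibility
# score: min over all unrooted topologies of the two-site Fitch length,
# minus the per-site minima (k-1).  Independent route: phangorn.
oracle_pair_incompat <- function(site_a, site_b) {
  ok <- site_a %in% c("A", "C", "G", "T") & site_b %in% c("A", "C", "G", "T")
  a <- site_a[ok]; b <- site_b[ok]
  ka <- length(unique(a)); kb <- length(unique(b))
  n <- length(a)
  if (n < 4L) {
    # with <= 3 usable taxa every pair of sites fits one tree perfectly
    return(0L)
  }
  m <- rbind(a, b)
  m <- t(m); rownames(m) <- paste0("u", seq_len(n))
  pd <- phangorn::phyDat(m, type = "DNA")
  trees <- phangorn::allTrees(n, tip.label = rownames(m))
  best <- min(vapply(trees, function(tr)
    phangorn::fitch(tr, pd), 0))
  as.integer(best - (ka - 1L) - (kb - 1L))
}

# independent patristic oracle: accumulate edge lengths along the path
# found by breadth-first search on the edge list
oracle_patristic <- function(tree, id1, id2) {
  n <- length(tree$tip.label)
  from <- match(id1, tree$tip.label); to <- match(id2, tree$tip.label)
  adj <- list()
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]; w <- tree$edge.length[k]
    adj[[as.character(u)]] <- rbind(adj[[as.character(u)]], c(v, w))
    adj[[as.character(v)]] <- rbind(adj[[as.character(v)]], c(u, w))
  }
  dist <- setNames(rep(NA_real_, n + tree$Nnode),
                   as.character(seq_len(n + tree$Nnode)))
  dist[as.character(from)] <- 0
  queue <- from
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (r in seq_len(NROW(adj[[as.character(u)]]))) {
      v <- adj[[as.character(u)]][r, 1L]
      w <- adj[[as.character(u)]][r, 2L]
      if (is.na(dist[as.character(v)])) {
        dist[as.character(v)] <- dist[as.character(u)] + w
        queue <- c(queue, v)
      }
    }
  }
  unname(dist[as.character(to)])
}

# brute-force maximum set of pairwise disjoint open intervals
oracle_max_disjoint <- function(intervals) {
  if (!length(intervals)) return(0L)
  k <- length(intervals)
  best <- 0L
  for (mask in seq_len(2^k) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1L) {
      for (i in seq_len(length(sel) - 1L)) {
        for (j in seq.int(i + 1L, length(sel))) {
          a <- intervals[[sel[i]]]; b <- intervals[[sel[j]]]
          if (max(a[1L], b[1L]) < min(a[2L], b[2L])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(sel)
  }
  best
}
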