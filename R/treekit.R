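#' Pairwise distance matrix under p or Kimura 3-ST models
#'
#' Distances use pairwise deletion: a site enters a pair's comparison only
#' when both rows carry an unambiguous A/C/G/T.  Under `"p"` the distance
#' is the mismatch fraction.  Under `"K3ST"`, with P, Q and R the observed
#' frequencies of the three substitution classes (transitions; A-T / G-C
#' transversions; A-C / G-T transversions),
#' `d = -1/4 * log((1-2P-2Q) * (1-2P-2R) * (1-2Q-2R))`.
#'
#' @param alignment a [locus_alignment].
#' @param model `"p"` or `"K3ST"`.
#' @return a `dist_matrix`: list with `ids` and symmetric matrix `d`.
#' @export
distance_matrix <- function(alignment, model = c("p", "K3ST")) {
  model <- match.arg(model)
  codes <- aln_codes(alignment)
  n <- nrow(codes)
  ids <- alignment$ids
  # substitution class of an ordered base pair: 0 same, 1 transition,
  # 2 A-T/G-C transversion, 3 A-C/G-T transversion  (bases 1=A 2=C 3=G 4=T)
  cls <- matrix(0L, 4L, 4L)
  cls[cbind(c(1, 3, 2, 4), c(3, 1, 4, 2))] <- 1L
  cls[cbind(c(1, 4, 3, 2), c(4, 1, 2, 3))] <- 2L
  cls[cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))] <- 3L
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L && model == "p") {
    # vectorised mismatch fractions: matches via per-base indicator
    # cross-products, comparable-site counts via the validity indicator
    valid <- codes > 0L
    storage.mode(valid) <- "double"
    comp <- valid %*% t(valid)
    match_ct <- matrix(0, n, n)
    for (b in 1:4) {
      ib <- codes == b
      storage.mode(ib) <- "double"
      match_ct <- match_ct + ib %*% t(ib)
    }
    zero <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)
    if (nrow(zero)) {
      stop("distance error: no comparable sites for pair ",
           ids[zero[1L, 1L]], " / ", ids[zero[1L, 2L]])
    }
    d <- (comp - match_ct) / comp
    diag(d) <- 0
    dimnames(d) <- list(ids, ids)
  } else if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- codes[i, ]; b <- codes[j, ]
        ok <- a > 0L & b > 0L
        m <- sum(ok)
        if (m == 0L) {
          stop("distance error: no comparable sites for pair ",
               ids[i], " / ", ids[j])
        }
        {
          k <- cls[cbind(a[ok], b[ok])]
          P <- sum(k == 1L) / m; Q <- sum(k == 2L) / m; R <- sum(k == 3L) / m
          args <- c(1 - 2 * P - 2 * Q, 1 - 2 * P - 2 * R, 1 - 2 * Q - 2 * R)
          if (any(args <= 0)) {
            stop("saturation error: K3ST distance undefined for pair ",
                 ids[i], " / ", ids[j])
          }
          dij <- -0.25 * sum(log(args))
        }
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  structure(list(ids = ids, d = d), class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' Saitou--Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero, with the total clamped deficit recorded in attribute
#' `clamped_deficit`.
#'
#' @param dm a `dist_matrix` from [distance_matrix()], a `dist`, or a
#'   symmetric matrix with dimnames.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (nrow(m) < 3L) stop("size error: neighbor joining needs >= 3 taxa")
  tr <- ape::nj(m)
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

# internal: bitmask state matrix restricted/ordered to tree tips, plus
# site-pattern compression
pattern_states <- function(alignment, tip_labels) {
  sub <- subset_alignment(alignment, tip_labels)
  bits <- aln_bits(sub)
  key <- apply(bits, 2L, paste0, collapse = ",")
  uk <- unique(key)
  w <- as.integer(table(factor(key, levels = uk)))
  list(states = bits[, match(uk, key), drop = FALSE], weights = w)
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of state changes summed over alignment columns, with
#' IUPAC ambiguity codes as their state sets and `-`/`N` as the full set.
#' Polytomies are scored as an arbitrary binary resolution.
#'
#' @param tree a `phylo` whose tip labels are alignment strain ids.
#' @param alignment a [locus_alignment] covering all tips.
#' @return integer parsimony length.
#' @export
fitch_length <- function(tree, alignment) {
  miss <- setdiff(tree$tip.label, alignment$ids)
  if (length(miss)) stop("id error: tips without sequences: ",
                         paste(miss, collapse = ", "))
  ps <- pattern_states(alignment, tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  cpp_fitch_edges(ps$states, ps$weights, tr$edge, length(tr$tip.label))
}

# internal: convert the C++ search result (edge matrix over 0-based node
# ids, rooted binary) into an unrooted ape phylo
cpp_edges_to_phylo <- function(edge, root, tip_labels) {
  ntip <- length(tip_labels)
  nodes <- sort(unique(as.vector(edge)))
  internal <- setdiff(nodes, seq_len(ntip) - 1L)
  internal <- c(root, setdiff(internal, root))  # ape wants root = ntip+1
  newid <- integer(max(nodes) + 1L)
  newid[seq_len(ntip)] <- seq_len(ntip)          # tip i (0-based) -> i+1
  newid[internal + 1L] <- ntip + seq_along(internal)
  e <- cbind(newid[edge[, 1L] + 1L], newid[edge[, 2L] + 1L])
  tr <- structure(list(edge = e, tip.label = tip_labels,
                       Nnode = length(internal)), class = "phylo")
  if (ntip >= 3L) tr <- ape::unroot(tr)
  tr
}

#' Maximum-parsimony tree search
#'
#' Heuristic mode runs random-order stepwise addition followed by
#' nearest-neighbour-interchange hill climbing to a local optimum
#' (first-improving move in a deterministic edge ordering), best of
#' `n_starts` random addition orders.  Exact mode enumerates every unrooted
#' topology (allowed up to 11 taxa) and is used as its own oracle in tests.
#'
#' @param alignment a [locus_alignment] (>= 3 taxa; >= 4 for heuristic
#'   search to be meaningful).
#' @param n_starts number of random addition orders.
#' @param seed integer seed controlling the addition orders.
#' @param exact logical; enumerate all topologies instead.
#' @param nni_max cap on accepted NNI moves per start.
#' @return list with `tree` (unrooted `phylo`, no branch lengths) and
#'   `length` (its Fitch parsimony length).
#' @export
mp_search <- function(alignment, n_starts = 3L, seed = NULL, exact = FALSE,
                      nni_max = 10000L) {
  ntip <- length(alignment$ids)
  if (ntip < 3L) stop("size error: need >= 3 taxa")
  ps <- pattern_states(alignment, alignment$ids)
  if (exact) {
    if (ntip > 11L) stop("exact mode allowed for <= 11 taxa")
    res <- cpp_mp_exact(ps$states, ps$weights)
  } else {
    if (!is.null(seed)) set.seed(seed)
    res <- NULL
    for (s in seq_len(max(1L, n_starts))) {
      ord <- sample.int(ntip) - 1L
      cand <- cpp_mp_search(ps$states, ps$weights, ord, nni_max)
      if (is.null(res) || cand$length < res$length) res <- cand
    }
  }
  tree <- cpp_edges_to_phylo(res$edge, res$root, alignment$ids)
  list(tree = tree, length = res$length)
}

# internal: tip label sets below each internal node of a phylo
node_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Extract supported bipartitions from a tree
#'
#' Internal edges whose support value meets `support_threshold` become rows
#' of a clade table; trivial splits (single tip, or all but one tip) are
#' excluded.  Supports are read from `tree$node.label`; values on a 0--100
#' scale are rescaled to 0--1, and missing labels count as unsupported.
#'
#' @param tree a `phylo`, typically with bootstrap or posterior supports as
#'   node labels.
#' @param support_threshold minimum support in \[0, 1\].
#' @param locus_name label recorded in the table.
#' @return a `clade_table`: list with `locus_name`, `taxa`, `sides` (list
#'   of tip-label vectors) and `support`.
#' @export
extract_clades <- function(tree, support_threshold = 0.95,
                           locus_name = "locus") {
  ntip <- length(tree$tip.label)
  supp <- tree$node.label
  if (is.null(supp)) supp <- rep(NA_character_, tree$Nnode)
  supp <- suppressWarnings(as.numeric(supp))
  if (any(supp > 1, na.rm = TRUE)) supp <- supp / 100
  below <- node_descendant_tips(tree)
  sides <- list(); keep_supp <- numeric(0)
  root <- ntip + 1L
  taxa <- sort(tree$tip.label)
  seen <- character(0)
  for (v in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    if (v == root) next  # root "split" is the whole taxon set
    side <- below[[v]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    s <- supp[v - ntip]
    if (is.na(s) || s < support_threshold) next
    # canonical key so a rooted input cannot list one bipartition twice
    side <- sort(side)
    comp <- setdiff(taxa, side)
    key <- paste(if (length(side) < length(comp) ||
                       (length(side) == length(comp) &&
                          side[1L] <= comp[1L])) side else comp,
                 collapse = ",")
    if (key %in% seen) {
      keep_supp[match(key, seen)] <- max(keep_supp[match(key, seen)], s)
      next
    }
    seen <- c(seen, key)
    sides[[length(sides) + 1L]] <- side
    keep_supp <- c(keep_supp, s)
  }
  structure(list(locus_name = locus_name, taxa = taxa,
                 sides = sides, support = keep_supp),
            class = "clade_table")
}

#' @export
print.clade_table <- function(x, ...) {
  cat("<clade_table> ", x$locus_name, ": ", length(x$sides),
      " supported bipartitions over ", length(x$taxa), " taxa\n", sep = "")
  invisible(x)
}

#' Are two splits compatible?
#'
#' Both splits are first restricted to `shared_taxa`; they are compatible
#' iff at least one of the four pairwise intersections of their sides is
#' empty.  With fewer than four shared taxa the pair is vacuously
#' compatible.
#'
#' @param split1,split2 character vectors: one side of each bipartition.
#' @param shared_taxa the taxon set over which to compare.
#' @return logical.
#' @export
clades_compatible <- function(split1, split2, shared_taxa) {
  if (length(shared_taxa) < 4L) return(TRUE)
  a <- intersect(split1, shared_taxa)
  b <- intersect(split2, shared_taxa)
  ac <- setdiff(shared_taxa, a)
  bc <- setdiff(shared_taxa, b)
  !all(lengths(list(intersect(a, b), intersect(a, bc),
                    intersect(ac, b), intersect(ac, bc))) > 0L)
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths on the unique path between two tips.
#'
#' @param tree a `phylo` with branch lengths.
#' @param id1,id2 tip labels.
#' @return numeric distance.
#' @export
patristic_distance <- function(tree, id1, id2) {
  i <- match(c(id1, id2), tree$tip.label)
  if (anyNA(i)) stop("id error: unknown leaf: ",
                     paste(c(id1, id2)[is.na(i)], collapse = ", "))
  if (i[1L] == i[2L]) return(0)
  stats::cophenetic(tree)[id1, id2]
}

#' Neighbor-joining gene tree with bootstrap supports
#'
#' Builds the NJ tree for one locus and attaches nonparametric bootstrap
#' supports (fraction of column-resampled NJ trees containing each
#' bipartition) as node labels -- a desk-scale surrogate for Bayesian
#' posterior supports.
#'
#' @param alignment a [locus_alignment].
#' @param model distance model passed to [distance_matrix()].
#' @param bootstrap number of bootstrap replicates (0 = no supports).
#' @param seed integer seed for the resampling.
#' @return a `phylo` with `node.label` supports in \[0, 1\].
#' @export
gene_tree <- function(alignment, model = "p", bootstrap = 100L,
                      seed = NULL) {
  ref <- neighbor_joining(distance_matrix(alignment, model))
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    L <- alignment$length
    boots <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      cols <- sample.int(L, L, replace = TRUE)
      ab <- locus_alignment(alignment$seqs[, cols, drop = FALSE],
                            alignment$locus_name)
      boots[[b]] <- neighbor_joining(distance_matrix(ab, model))
    }
    counts <- ape::prop.clades(ref, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    ref$node.label <- counts / bootstrap
  }
  ref
}

#' Read a gene tree with support values
#'
#' Reads newick via [ape::read.tree()]; numeric internal-node labels are
#' treated as supports and rescaled from 0--100 to 0--1 when needed.
#'
#' @param path newick file.
#' @return a `phylo`.
#' @export
read_gene_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (!is.null(tr$node.label)) {
    s <- suppressWarnings(as.numeric(tr$node.label))
    if (any(s > 1, na.rm = TRUE)) s <- s / 100
    tr$node.label <- s
  }
  tr
}

#' Write a tree to newick
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
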