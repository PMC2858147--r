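#' Simulation configuration
#'
#' Collects and validates the parameters of the multilocus simulator.
#' Times are in coalescent units; `theta_per_locus` is the population
#' mutation rate per locus (mutations arise at rate theta/2 per lineage
#' per unit time), so under the infinite-sites model the expected number
#' of segregating sites for n sampled haplotypes is `theta * a1(n)`.
#'
#' @param n_strains number of haploid strains sampled.
#' @param n_loci number of unlinked loci.
#' @param locus_lengths locus lengths in nt (recycled to `n_loci`).
#' @param theta_per_locus per-locus theta (recycled to `n_loci`).
#' @param mode one of `"clonal"` (one shared genealogy for all loci),
#'   `"free_recomb"` (independent genealogy per locus), `"intralocus"`
#'   (independent genealogy per contiguous block within each locus),
#'   `"structured"` (two demes diverged `tau` ago) or
#'   `"border_scenario"` (clonal core + recombining halo + distant
#'   controls).
#' @param n_blocks blocks per locus (`intralocus` and halo mosaics).
#' @param tau divergence time of the two demes (`structured`).
#' @param deme_sizes integer vector of two deme sizes (`structured`);
#'   default splits `n_strains` evenly.
#' @param mutation_model `"infinite_sites"` (no homoplasy, at most one
#'   mutation per site) or `"JC"` (finite sites, recurrent substitution).
#' @param core_size,halo_size,control_size,n_donors,halo_intensity,tau_control
#'   border-scenario parameters: sizes of the clonal core, recombining
#'   halo and distant-control groups; number of hidden donor lineages the
#'   halo mosaics copy from; per-block probability that a halo block is
#'   drawn from a random donor rather than the strain's home donor;
#'   divergence time of the control deme.
#' @param seed master seed; all randomness flows from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_strains = 20L, n_loci = 3L,
                       locus_lengths = 500L, theta_per_locus = 10,
                       mode = c("clonal", "free_recomb", "intralocus",
                                "structured", "border_scenario"),
                       n_blocks = 4L, tau = 3, deme_sizes = NULL,
                       mutation_model = c("infinite_sites", "JC"),
                       core_size = 8L, halo_size = 10L, control_size = 5L,
                       n_donors = 6L, halo_intensity = 1, tau_control = 5,
                       seed = 1L) {
  mode <- match.arg(mode)
  mutation_model <- match.arg(mutation_model)
  if (mode == "border_scenario") {
    n_strains <- core_size + halo_size + control_size
  }
  locus_lengths <- as.integer(rep_len(locus_lengths, n_loci))
  theta_per_locus <- rep_len(theta_per_locus, n_loci)
  if (n_strains < 2L || n_loci < 1L) stop("config error: counts too small")
  if (any(locus_lengths < 1L)) stop("config error: locus length < 1")
  if (any(theta_per_locus <= 0)) stop("config error: theta must be > 0")
  if (tau < 0) stop("config error: tau must be >= 0")
  if (mode == "intralocus" && any(n_blocks > locus_lengths)) {
    stop("config error: more blocks than columns")
  }
  if (is.null(deme_sizes)) {
    deme_sizes <- c(floor(n_strains / 2), ceiling(n_strains / 2))
  }
  if (mode == "structured" && sum(deme_sizes) != n_strains) {
    stop("config error: deme sizes must sum to n_strains")
  }
  structure(list(n_strains = n_strains, n_loci = n_loci,
                 locus_lengths = locus_lengths,
                 theta_per_locus = theta_per_locus, mode = mode,
                 n_blocks = as.integer(n_blocks), tau = tau,
                 deme_sizes = as.integer(deme_sizes),
                 mutation_model = mutation_model,
                 core_size = as.integer(core_size),
                 halo_size = as.integer(halo_size),
                 control_size = as.integer(control_size),
                 n_donors = as.integer(n_donors),
                 halo_intensity = halo_intensity,
                 tau_control = tau_control, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Kingman coalescent genealogy
#'
#' Pairwise merging with waiting times Exp(k(k-1)/2) in coalescent units.
#' With `demes`/`tau`, lineages coalesce only within their deme until
#' `tau`, when the demes merge (a two-population split model).
#'
#' @param n number of tips.
#' @param seed optional seed (omit when embedding in a seeded simulation).
#' @param tip_labels tip labels (default `s1..sn`).
#' @param demes optional integer vector of deme ids (1 or 2) per tip.
#' @param tau deme merge time (required with `demes`).
#' @return a rooted `phylo` with branch lengths.
#' @export
simulate_coalescent_tree <- function(n, seed = NULL, tip_labels = NULL,
                                     demes = NULL, tau = NULL) {
  if (n < 2L) stop("size error: need >= 2 lineages")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tip_labels)) tip_labels <- paste0("s", seq_len(n))
  if (is.null(demes)) demes <- rep(1L, n)
  active <- seq_len(n)              # phylo node ids of active lineages
  lin_deme <- demes
  height <- rep(0, 2L * n - 1L)
  edge <- matrix(0L, 0L, 2L); edge_len <- numeric(0)
  next_internal <- 2L * n - 1L      # assign down so the root ends at n+1
  t_now <- 0
  merged <- length(unique(demes)) == 1L
  if (!merged && is.null(tau)) stop("tau required with demes")
  while (length(active) > 1L) {
    if (!merged) {
      ds <- sort(unique(lin_deme))
      rates <- vapply(ds, function(d) {
        k <- sum(lin_deme == d); k * (k - 1) / 2
      }, 0)
      rate <- sum(rates)
      wait <- if (rate > 0) rexp(1L, rate) else Inf
      if (t_now + wait >= tau) {
        t_now <- tau
        lin_deme <- rep(1L, length(active))
        merged <- TRUE
        next
      }
      t_now <- t_now + wait
      d <- ds[sample.int(length(ds), 1L, prob = rates)]
      pool <- which(lin_deme == d)
    } else {
      k <- length(active)
      t_now <- t_now + rexp(1L, k * (k - 1) / 2)
      pool <- seq_along(active)
    }
    pick <- sample(pool, 2L)
    u <- active[pick[1L]]; v <- active[pick[2L]]
    w <- next_internal; next_internal <- next_internal - 1L
    height[w] <- t_now
    edge <- rbind(edge, c(w, u), c(w, v))
    edge_len <- c(edge_len, t_now - height[u], t_now - height[v])
    active <- c(active[-pick], w)
    lin_deme <- c(lin_deme[-pick], lin_deme[pick[1L]])
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = tip_labels, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Evolve sequences along a genealogy
#'
#' Under `"infinite_sites"`, `Poisson(theta/2 * total branch length)`
#' mutations are placed on the tree (edges weighted by length), each at a
#' distinct site, guaranteeing zero homoplasy; if more mutations than
#' sites are drawn the draw is repeated (`on_capacity = "resample"`) or an
#' error is raised.  Under `"JC"`, substitution events occur along each
#' branch at total rate theta/2 per unit time (rate theta/(2 length) per
#' site), with recurrent substitution allowed.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param length locus length in nt.
#' @param theta per-locus population mutation rate.
#' @param model `"infinite_sites"` or `"JC"`.
#' @param seed optional seed.
#' @param locus_name locus label.
#' @param on_capacity `"resample"` or `"fail"` when infinite-sites draws
#'   exceed the number of sites.
#' @return a [locus_alignment] over the tree's tips.
#' @export
evolve_sequences <- function(tree, length, theta,
                             model = c("infinite_sites", "JC"),
                             seed = NULL, locus_name = "sim",
                             on_capacity = c("resample", "fail")) {
  model <- match.arg(model)
  on_capacity <- match.arg(on_capacity)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  anc <- sample(bases, length, replace = TRUE)
  if (model == "infinite_sites") {
    total <- sum(tree$edge.length)
    nmut <- rpois(1L, theta / 2 * total)
    tries <- 0L
    while (nmut > length) {
      if (on_capacity == "fail") {
        stop("capacity error: ", nmut, " mutations for ", length, " sites")
      }
      tries <- tries + 1L
      if (tries > 100L) stop("capacity error: theta too large for length")
      nmut <- rpois(1L, theta / 2 * total)
    }
    mat <- matrix(rep(anc, each = ntip), nrow = ntip)
    if (nmut > 0L) {
      below <- node_descendant_tips(tree)
      pos <- sample.int(length, nmut)
      eidx <- sample.int(nrow(tree$edge), nmut, replace = TRUE,
                         prob = tree$edge.length)
      for (k in seq_len(nmut)) {
        tips <- match(below[[tree$edge[eidx[k], 2L]]], tree$tip.label)
        derived <- sample(setdiff(bases, anc[pos[k]]), 1L)
        mat[tips, pos[k]] <- derived
      }
    }
  } else {
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    nnode <- ntip + tr$Nnode
    seqs <- vector("list", nnode)
    root <- tr$edge[1L, 1L]
    seqs[[root]] <- anc
    for (k in seq_len(nrow(tr$edge))) {
      p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
      s <- seqs[[p]]
      nev <- rpois(1L, tr$edge.length[k] * theta / 2)
      if (nev > 0L) {
        sites <- sample.int(length, nev, replace = TRUE)
        for (e in seq_len(nev)) {
          s[sites[e]] <- sample(setdiff(bases, s[sites[e]]), 1L)
        }
      }
      seqs[[ch]] <- s
    }
    mat <- do.call(rbind, seqs[seq_len(ntip)])
  }
  rownames(mat) <- tree$tip.label
  locus_alignment(mat, locus_name)
}

# internal: split a locus into n contiguous blocks of near-equal length
block_ranges <- function(length, n_blocks) {
  cuts <- round(seq(0, length, length.out = n_blocks + 1L))
  lapply(seq_len(n_blocks), function(b) seq.int(cuts[b] + 1L, cuts[b + 1L]))
}

# internal: manifest scaffold for simulated strains
sim_manifest <- function(ids, subclade, truth) {
  data.frame(strain_id = ids, origin = "simulated", habitat = "simulated",
             subclade = subclade, teleomorph = FALSE, ex_type = FALSE,
             truth_label = truth, stringsAsFactors = FALSE)
}

#' Simulate a multilocus dataset with known truth
#'
#' Dispatches on `config$mode`; see [sim_config()].  All randomness
#' derives from `config$seed`, so identical configurations reproduce
#' identical datasets.
#'
#' @param config a [sim_config()].
#' @return a `simulated_dataset`: list with `dataset` (a
#'   `multilocus_dataset`), `true_trees` (per locus; per block for
#'   `intralocus`), `truth_labels` (named vector: `clonal_core`,
#'   `recombining` or `control`) and `config`.
#' @export
simulate_multilocus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode == "border_scenario") {
    return(simulate_border_scenario(config))
  }
  set.seed(config$seed)
  n <- config$n_strains
  ids <- sprintf("s%02d", seq_len(n))
  demes <- NULL
  subclade <- rep(config$mode, n)
  if (config$mode == "structured") {
    demes <- rep(1:2, times = config$deme_sizes)
    subclade <- paste0("deme", demes)
  }
  make_tree <- function() {
    if (config$mode == "structured") {
      simulate_coalescent_tree(n, tip_labels = ids, demes = demes,
                               tau = config$tau)
    } else {
      simulate_coalescent_tree(n, tip_labels = ids)
    }
  }
  shared <- if (config$mode == "clonal") make_tree()
  loci <- list(); true_trees <- list()
  for (l in seq_len(config$n_loci)) {
    lname <- paste0("L", l)
    len <- config$locus_lengths[l]
    th <- config$theta_per_locus[l]
    if (config$mode == "intralocus") {
      blocks <- block_ranges(len, config$n_blocks)
      btrees <- list(); mats <- list()
      for (b in seq_along(blocks)) {
        btrees[[b]] <- make_tree()
        a <- evolve_sequences(btrees[[b]], length(blocks[[b]]),
                              th * length(blocks[[b]]) / len,
                              model = config$mutation_model,
                              locus_name = lname)
        mats[[b]] <- a$seqs[ids, , drop = FALSE]
      }
      loci[[lname]] <- locus_alignment(do.call(cbind, mats), lname)
      true_trees[[lname]] <- btrees
    } else {
      tr <- if (config$mode == "clonal") shared else make_tree()
      a <- evolve_sequences(tr, len, th, model = config$mutation_model,
                            locus_name = lname)
      loci[[lname]] <- locus_alignment(a$seqs[ids, , drop = FALSE], lname)
      true_trees[[lname]] <- tr
    }
  }
  truth <- setNames(rep("clonal_core", n), ids)
  if (config$mode %in% c("free_recomb", "intralocus")) {
    truth[] <- "recombining"
  }
  manifest <- sim_manifest(ids, subclade, unname(truth))
  ds <- structure(list(loci = loci, manifest = manifest),
                  class = "multilocus_dataset")
  structure(list(dataset = ds, true_trees = true_trees,
                 truth_labels = truth, config = config),
            class = "simulated_dataset")
}

#' Simulate the border scenario: clonal core, recombining halo, controls
#'
#' One structured genealogy (core + hidden donor lineages in one deme,
#' distant controls in the other, merged at `tau_control`) is shared by
#' all loci, so core and control strains are perfectly clonal and, under
#' infinite sites, mutually compatible.  Each halo strain is a mosaic: per
#' locus and per block it copies the sequence of its home donor lineage
#' or (with probability `halo_intensity`) a random lineage of the clade
#' -- a core strain or another donor -- creating the inter- and
#' intra-locus reshuffling that the recombination tests detect.  Donor
#' lineages are dropped from the output.
#'
#' @param config a [sim_config()] with `mode = "border_scenario"`.
#' @return a `simulated_dataset` (see [simulate_multilocus()]).
#' @export
simulate_border_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$core_size + config$halo_size + config$control_size !=
        config$n_strains) {
    stop("config error: core + halo + controls must equal n_strains")
  }
  set.seed(config$seed)
  core_ids <- sprintf("core%02d", seq_len(config$core_size))
  halo_ids <- sprintf("halo%02d", seq_len(config$halo_size))
  ctrl_ids <- sprintf("ctrl%02d", seq_len(config$control_size))
  donor_ids <- sprintf("donor%02d", seq_len(config$n_donors))
  tree_ids <- c(core_ids, donor_ids, ctrl_ids)
  demes <- c(rep(1L, config$core_size + config$n_donors),
             rep(2L, config$control_size))
  tr <- simulate_coalescent_tree(length(tree_ids), tip_labels = tree_ids,
                                 demes = demes, tau = config$tau_control)
  home <- setNames(sample(donor_ids, config$halo_size, replace = TRUE),
                   halo_ids)
  out_ids <- c(core_ids, halo_ids, ctrl_ids)
  loci <- list()
  halo_parents <- list()
  for (l in seq_len(config$n_loci)) {
    lname <- paste0("L", l)
    len <- config$locus_lengths[l]
    base <- evolve_sequences(tr, len, config$theta_per_locus[l],
                             model = "infinite_sites", locus_name = lname)
    blocks <- block_ranges(len, config$n_blocks)
    mat <- matrix("", nrow = length(out_ids), ncol = len,
                  dimnames = list(out_ids, NULL))
    mat[core_ids, ] <- base$seqs[core_ids, , drop = FALSE]
    mat[ctrl_ids, ] <- base$seqs[ctrl_ids, , drop = FALSE]
    parents <- matrix("", nrow = config$halo_size, ncol = config$n_blocks,
                      dimnames = list(halo_ids, NULL))
    pool <- c(core_ids, donor_ids)
    for (h in halo_ids) {
      for (b in seq_along(blocks)) {
        donor <- if (runif(1L) < config$halo_intensity)
          sample(pool, 1L) else home[[h]]
        parents[h, b] <- donor
        mat[h, blocks[[b]]] <- base$seqs[donor, blocks[[b]]]
      }
    }
    halo_parents[[lname]] <- parents
    loci[[lname]] <- locus_alignment(mat, lname)
  }
  truth <- setNames(c(rep("clonal_core", config$core_size),
                      rep("recombining", config$halo_size),
                      rep("control", config$control_size)), out_ids)
  subclade <- c(rep("core", config$core_size),
                rep("halo", config$halo_size),
                rep("control", config$control_size))
  manifest <- sim_manifest(out_ids, subclade, unname(truth))
  ds <- structure(list(loci = loci, manifest = manifest),
                  class = "multilocus_dataset")
  structure(list(dataset = ds, true_trees = tr, truth_labels = truth,
                 halo_parents = halo_parents, config = config),
            class = "simulated_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned FASTA per locus, the manifest with truth labels as
#' TSV, the true genealogies in newick, and a JSON echo of the
#' configuration.
#'
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in sim$dataset$loci) {
    write_fasta_alignment(a, file.path(dir, paste0(a$locus_name, ".fasta")))
  }
  write.table(sim$dataset$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  trees <- sim$true_trees
  if (inherits(trees, "phylo")) trees <- list(shared = trees)
  tf <- file.path(dir, "true_trees.nwk")
  unlink(tf)
  for (nm in names(trees)) {
    tt <- trees[[nm]]
    if (inherits(tt, "phylo")) tt <- list(tt)
    for (t1 in tt) cat(ape::write.tree(t1), "\n", file = tf, append = TRUE,
                       sep = "")
  }
  cfg <- sim$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
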