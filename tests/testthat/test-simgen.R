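test_that("configurations are validated", {
  expect_error(sim_config(n_strains = 1), "config error")
  expect_error(sim_config(theta_per_locus = 0), "theta")
  expect_error(sim_config(tau = -1), "tau")
  expect_error(sim_config(mode = "intralocus", n_blocks = 600,
                          locus_lengths = 500), "blocks")
  expect_error(sim_config(mode = "structured", deme_sizes = c(3, 4),
                          n_strains = 10), "deme sizes")
  cfg <- sim_config(mode = "border_scenario", core_size = 8,
                    halo_size = 10, control_size = 5)
  expect_equal(cfg$n_strains, 23L)
  bad <- cfg; bad$n_strains <- 20L
  expect_error(simulate_border_scenario(bad), "config error")
})

test_that("coalescent trees have valid shape and reproducible draws", {
  expect_error(simulate_coalescent_tree(1), "size error")
  tr <- simulate_coalescent_tree(8, seed = 4)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 8L)
  expect_equal(tr$Nnode, 7L)
  expect_true(all(tr$edge.length >= 0))
  tr2 <- simulate_coalescent_tree(8, seed = 4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # ultrametric: all tips equidistant from the root
  D <- ape::dist.nodes(tr)
  root <- length(tr$tip.label) + 1L
  expect_equal(sd(D[root, 1:8]), 0, tolerance = 1e-10)
})

test_that("structured genealogies respect the divergence time", {
  demes <- rep(1:2, each = 5)
  for (i in 1:5) {
    tr <- simulate_coalescent_tree(10, seed = 80 + i, demes = demes,
                                   tau = 2)
    D <- ape::dist.nodes(tr)
    root <- 11L
    height <- D[root, 1L]
    # cross-deme pairs cannot coalesce before tau
    for (a in 1:5) for (b in 6:10) {
      expect_gte(D[a, b] / 2, 2 - 1e-9)
    }
    expect_gte(height, 2)
  }
})

test_that("infinite-sites sequences are homoplasy-free", {
  tr <- simulate_coalescent_tree(10, seed = 90)
  a <- evolve_sequences(tr, 400, 8, model = "infinite_sites", seed = 90)
  codes <- matrix(match(a$seqs, c("A", "C", "G", "T"), nomatch = 0L),
                  nrow = 10)
  # every site biallelic at most, every pair compatible
  expect_true(all(apply(codes, 2, function(col)
    length(unique(col)) <= 2)))
  varying <- which(apply(codes, 2, function(col)
    length(unique(col)) > 1))
  if (length(varying) >= 2) {
    for (k in 1:20) {
      ij <- sample(varying, 2)
      expect_equal(pair_incompatibility(a$seqs[, ij[1]], a$seqs[, ij[2]]),
                   0L)
    }
  }
  # theta -> 0: no variation
  a0 <- evolve_sequences(tr, 100, 1e-9, model = "infinite_sites", seed = 1)
  expect_equal(length(unique(apply(a0$seqs, 1, paste0, collapse = ""))), 1L)
  # capacity error with on_capacity = "fail"
  expect_error(evolve_sequences(tr, 3, 50, model = "infinite_sites",
                                seed = 7, on_capacity = "fail"),
               "capacity error")
})

test_that("JC sequences accumulate recurrent substitutions", {
  tr <- simulate_coalescent_tree(6, seed = 91)
  a <- evolve_sequences(tr, 200, 10, model = "JC", seed = 91)
  expect_true(all(a$seqs %in% c("A", "C", "G", "T")))
  expect_gt(sum(apply(a$seqs, 2, function(col)
    length(unique(col)) > 1)), 0)
})

test_that("simulation modes produce the advertised genealogy structure", {
  clonal <- simulate_multilocus(sim_config(n_strains = 8, seed = 31))
  expect_length(clonal$true_trees, 3L)
  expect_identical(ape::write.tree(clonal$true_trees$L1),
                   ape::write.tree(clonal$true_trees$L2))
  free <- simulate_multilocus(sim_config(n_strains = 8,
                                         mode = "free_recomb", seed = 31))
  expect_false(identical(ape::write.tree(free$true_trees$L1),
                         ape::write.tree(free$true_trees$L2)))
  intra <- simulate_multilocus(sim_config(n_strains = 8,
                                          mode = "intralocus",
                                          n_blocks = 4, seed = 31))
  expect_length(intra$true_trees$L1, 4L)
  struct <- simulate_multilocus(sim_config(n_strains = 8,
                                           mode = "structured", tau = 3,
                                           seed = 31))
  expect_equal(sort(unique(struct$dataset$manifest$subclade)),
               c("deme1", "deme2"))
  expect_true(all(struct$truth_labels == "clonal_core"))
  # labels cover all strains
  expect_equal(sort(names(struct$truth_labels)),
               sort(struct$dataset$manifest$strain_id))
})

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(n_strains = 10, theta_per_locus = 6,
                    mode = "free_recomb", seed = 77)
  s1 <- simulate_multilocus(cfg)
  s2 <- simulate_multilocus(cfg)
  expect_identical(s1$dataset$loci$L2$seqs, s2$dataset$loci$L2$seqs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_dataset(s1, d1)
  write_simulated_dataset(s2, d2)
  for (f in c("L1.fasta", "L2.fasta", "L3.fasta", "manifest.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("border scenario labels and mosaic structure are consistent", {
  cfg <- sim_config(mode = "border_scenario", theta_per_locus = 30,
                    seed = 50)
  sim <- simulate_multilocus(cfg)
  expect_equal(unname(table(sim$truth_labels)[c("clonal_core", "control",
                                                "recombining")]),
               c(8L, 5L, 10L), ignore_attr = TRUE)
  # at intensity 0 every halo strain copies a single home lineage
  cfg0 <- sim_config(mode = "border_scenario", theta_per_locus = 30,
                     halo_intensity = 0, seed = 50)
  sim0 <- simulate_multilocus(cfg0)
  for (l in names(sim0$halo_parents)) {
    expect_true(all(apply(sim0$halo_parents[[l]], 1,
                          function(r) length(unique(r)) == 1L)))
  }
  # at intensity 1 mosaics mix lineages
  expect_gt(mean(apply(sim$halo_parents$L1, 1,
                       function(r) length(unique(r)))), 1)
})

test_that("coalescent mean heights track theory at small n", {
  set.seed(12)
  h2 <- vapply(1:2000, function(i) {
    tr <- simulate_coalescent_tree(2)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  # E[T_MRCA] = 1 for n = 2, var = 1; 2000 draws give SE ~ 0.022
  expect_lt(abs(mean(h2) - 1), 3 / sqrt(2000))
})
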