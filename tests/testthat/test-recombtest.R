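test_that("pair incompatibility scores canonical configurations", {
  expect_equal(pair_incompatibility(c("A", "A", "G", "G"),
                                    c("C", "C", "T", "T")), 0L)
  expect_equal(pair_incompatibility(c("A", "A", "G", "G"),
                                    c("C", "T", "C", "T")), 1L)
  # symmetry
  set.seed(3)
  for (i in 1:20) {
    a <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    b <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    expect_equal(pair_incompatibility(a, b), pair_incompatibility(b, a))
  }
  # a site with all-distinct states is compatible with anything
  a <- c("A", "C", "G", "T")
  expect_equal(pair_incompatibility(a, c("A", "A", "T", "T")), 0L)
  expect_error(pair_incompatibility(c("A", "-"), c("C", "C")),
               "undefined")
})

test_that("the closed form equals the exhaustive-topology Fitch oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    a <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                prob = c(rep(0.23, 4), 0.08))
    b <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                prob = c(rep(0.23, 4), 0.08))
    if (sum(a != "-" & b != "-") < 2) next
    expect_equal(pair_incompatibility(a, b), oracle_pair_incompat(a, b),
                 info = paste(paste(a, collapse = ""),
                              paste(b, collapse = "")))
  }
})

test_that("Phi is exactly zero with p = 1 on clonal infinite-sites data", {
  for (i in 1:5) {
    cfg <- sim_config(n_strains = 12, theta_per_locus = 10,
                      mode = "clonal", seed = 900 + i)
    cc <- concatenate(simulate_multilocus(cfg)$dataset)
    r <- phi_test(cc$alignment, seed = i)
    expect_equal(r$phi, 0)
    expect_equal(r$p_permutation, 1)
  }
})

test_that("Phi p-values are reproducible and bounded", {
  cfg <- sim_config(n_strains = 15, theta_per_locus = 8, mode = "clonal",
                    mutation_model = "JC", seed = 55)
  cc <- concatenate(simulate_multilocus(cfg)$dataset)
  r1 <- phi_test(cc$alignment, n_permutations = 200, seed = 9,
                 analytic = TRUE)
  r2 <- phi_test(cc$alignment, n_permutations = 200, seed = 9)
  expect_identical(r1$p_permutation, r2$p_permutation)
  expect_gte(r1$p_permutation, 1 / 201)
  expect_lte(r1$p_permutation, 1)
  expect_gte(r1$phi, 0)
  expect_true(r1$p_analytic >= 0 && r1$p_analytic <= 1)
})

test_that("Phi reports non-computable inputs as a typed condition", {
  tiny <- mk_aln(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAT"))
  expect_error(phi_test(tiny), class = "phi_not_computable")
  expect_error(phi_test(mk_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"))),
               ">= 4")
})

test_that("Phi detects intra-locus recombination", {
  hits <- 0
  for (i in 1:10) {
    cfg <- sim_config(n_strains = 20, theta_per_locus = 10,
                      mode = "intralocus", seed = 1500 + i)
    cc <- concatenate(simulate_multilocus(cfg)$dataset)
    p <- phi_test(cc$alignment, seed = i)$p_permutation
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("IA reproduces the perfect-association worked example", {
  ds <- mk_dataset(L1 = c(a = "AA", b = "AA", c = "TT", d = "TT"),
                   L2 = c(a = "CC", b = "CC", c = "GG", d = "GG"),
                   L3 = c(a = "AT", b = "AT", c = "TA", d = "TA"))
  # clone correction collapses this to 2 haplotypes: too few
  expect_error(index_of_association(ds, seed = 1), "fewer than 3")
  r <- index_of_association(ds, clone_correct = FALSE,
                            n_permutations = 99, seed = 1)
  expect_equal(r$ia, 2)
  expect_match(r$heuristic_reading, "rejects")
  expect_equal(r$n_haplotypes_after_clone_correction, 4L)
})

test_that("IA is invariant to allele labels and locus order", {
  ds <- mk_dataset(L1 = c(a = "AA", b = "AT", c = "TT", d = "AA"),
                   L2 = c(a = "CC", b = "GG", c = "CG", d = "CC"),
                   L3 = c(a = "AC", b = "AG", c = "AA", d = "AC"))
  r1 <- index_of_association(ds, n_permutations = 0, seed = 1,
                             clone_correct = FALSE)
  # relabel alleles at L1 by complementing the sequences
  comp <- chartr("ACGT", "TGCA", apply(ds$loci$L1$seqs, 1, paste0,
                                       collapse = ""))
  ds2 <- ds
  ds2$loci$L1 <- locus_alignment(comp, "L1")
  r2 <- index_of_association(ds2, n_permutations = 0, seed = 1,
                             clone_correct = FALSE)
  expect_equal(r2$ia, r1$ia)
  ds3 <- ds
  ds3$loci <- rev(ds3$loci)
  r3 <- index_of_association(ds3, n_permutations = 0, seed = 1,
                             clone_correct = FALSE)
  expect_equal(r3$ia, r1$ia)
})

test_that("IA drops variance-free loci with a warning", {
  ds <- mk_dataset(L1 = c(a = "AA", b = "AA", c = "AA", d = "AA"),
                   L2 = c(a = "CC", b = "GG", c = "CG", d = "CC"),
                   L3 = c(a = "AC", b = "AG", c = "AA", d = "AC"))
  expect_warning(r <- index_of_association(ds, n_permutations = 9,
                                           seed = 1,
                                           clone_correct = FALSE),
                 "without mismatch variance")
  ds2 <- mk_dataset(L1 = c(a = "AA", b = "AA", c = "AA", d = "AA"),
                    L2 = c(a = "CC", b = "GG", c = "CG", d = "CC"))
  expect_warning(expect_error(
    index_of_association(ds2, clone_correct = FALSE),
    "fewer than 2 polymorphic"))
})

test_that("PHT is degenerate at p = 1 for duplicated partitions", {
  cfg <- sim_config(n_strains = 8, n_loci = 1, theta_per_locus = 12,
                    mode = "clonal", mutation_model = "JC", seed = 13)
  a <- simulate_multilocus(cfg)$dataset$loci$L1
  dup <- locus_alignment(cbind(a$seqs, a$seqs), "dup")
  part <- data.frame(locus = c("A", "B"), start = c(0L, a$length),
                     end = c(a$length, 2L * a$length))
  r <- pht_test(dup, part, n_replicates = 100, seed = 2)
  expect_equal(r$p_value, 1)
  expect_true(all(r$replicate_lengths == r$t_obs))
})

test_that("PHT flags strongly conflicting loci and is seed-reproducible", {
  for (i in 1:3) {
    cfg <- sim_config(n_strains = 16, n_loci = 2, theta_per_locus = 10,
                      mode = "free_recomb", seed = 60 + i)
    cc <- concatenate(simulate_multilocus(cfg)$dataset)
    r <- pht_test(cc$alignment, cc$partition, n_replicates = 99, seed = i)
    expect_lte(r$p_value, 0.05)
  }
  cfg <- sim_config(n_strains = 10, n_loci = 2, theta_per_locus = 8,
                    mode = "clonal", seed = 64)
  cc <- concatenate(simulate_multilocus(cfg)$dataset)
  r1 <- pht_test(cc$alignment, cc$partition, n_replicates = 50, seed = 3)
  r2 <- pht_test(cc$alignment, cc$partition, n_replicates = 50, seed = 3)
  expect_identical(r1$replicate_lengths, r2$replicate_lengths)
  expect_error(pht_test(cc$alignment, cc$partition[1, , drop = FALSE]),
               ">= 2 partitions")
})
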