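test_that("p and K3ST distances match direct recounts and ape", {
  a <- mk_aln(c(x = "AAAA", y = "AAAA"))
  expect_equal(distance_matrix(a, "p")$d["x", "y"], 0)
  expect_equal(distance_matrix(a, "K3ST")$d["x", "y"], 0)
  b <- mk_aln(c(x = "AAAA", y = "AATT"))
  expect_equal(distance_matrix(b, "p")$d["x", "y"], 0.5)

  set.seed(11)
  # moderately diverged sequences (random sequences would be saturated)
  base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  m <- t(vapply(1:6, function(i) {
    s <- base
    mut <- sample(400, 60)
    s[mut] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    s[sample(400, 10)] <- "-"
    s
  }, character(400)))
  rownames(m) <- paste0("t", 1:6)
  r <- locus_alignment(m, "L")
  # direct formula recount for one pair
  s1 <- r$seqs[1, ]; s2 <- r$seqs[2, ]
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  s1 <- s1[ok]; s2 <- s2[ok]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  tv1 <- c("AT", "TA", "GC", "CG")
  key <- paste0(s1, s2)
  P <- mean(key %in% ts_pairs); Q <- mean(key %in% tv1)
  R <- mean(s1 != s2) - P - Q
  expected <- -0.25 * log((1 - 2 * P - 2 * Q) * (1 - 2 * P - 2 * R) *
                            (1 - 2 * Q - 2 * R))
  dk <- distance_matrix(r, "K3ST")
  expect_equal(dk$d[1, 2], expected, tolerance = 1e-12)
  # independent library route
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(r$seqs), model = "K81",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dk$d), unname(ref[rownames(dk$d), colnames(dk$d)]),
               tolerance = 1e-10)
  dp <- distance_matrix(r, "p")
  refp <- as.matrix(ape::dist.dna(ape::as.DNAbin(r$seqs), model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(dp$d), unname(refp[rownames(dp$d), colnames(dp$d)]),
               tolerance = 1e-12)

  z <- mk_aln(c(x = "AC--", y = "--GT"))
  expect_error(distance_matrix(z, "p"), "distance error")
  sat <- mk_aln(c(x = "ACGTACGTACGT", y = "CATGCATGCATG"))
  expect_error(distance_matrix(sat, "K3ST"), "saturation error.*x.*y")
})

test_that("neighbor joining recovers additive trees exactly", {
  # three taxa: lengths solve the three-point equations
  m <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(m)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  D <- stats::cophenetic(tr)
  expect_equal(D["a", "b"], 3)
  expect_equal(D["a", "c"], 5)
  expect_equal(D["b", "c"], 6)
  # additive 4-taxon matrix from a known tree
  ref <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  m4 <- stats::cophenetic(ref)
  tr4 <- neighbor_joining(m4)
  expect_equal(ape::dist.topo(ape::unroot(ref), tr4), 0,
               ignore_attr = TRUE)
  expect_equal(stats::cophenetic(tr4)[rownames(m4), colnames(m4)], m4,
               tolerance = 1e-10)
  # all equal distances: internal branch lengths zero
  me <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(me) <- 0
  tre <- neighbor_joining(me)
  internal <- tre$edge[, 2] > length(tre$tip.label)
  expect_true(all(tre$edge.length[internal] < 1e-12))
  expect_error(neighbor_joining(m[1:2, 1:2]), "size error")
})

test_that("fitch_length matches phangorn and is invariant to rooting", {
  tr <- ape::read.tree(text = "((a1,a2),(c1,c2));")
  aln <- mk_aln(c(a1 = "AA", a2 = "AA", c1 = "AC", c2 = "AC"))
  expect_equal(fitch_length(tr, aln), 1L)
  const <- mk_aln(c(a1 = "GGG", a2 = "GGG", c1 = "GGG", c2 = "GGG"))
  expect_equal(fitch_length(tr, const), 0L)

  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    rt <- ape::rtree(n)
    aln <- rand_aln(n, 40, gap_rate = 0.05)
    rownames(aln$seqs) <- aln$ids <- rt$tip.label
    pd <- phangorn::phyDat(aln$seqs, type = "DNA")
    expect_equal(fitch_length(rt, aln),
                 as.integer(phangorn::fitch(rt, pd)))
    # re-rooting invariance
    rt2 <- ape::root(ape::unroot(rt), outgroup = rt$tip.label[2],
                     resolve.root = TRUE)
    expect_equal(fitch_length(rt2, aln), fitch_length(rt, aln))
    # leaf-order permutation of the alignment
    perm <- sample(n)
    aln2 <- locus_alignment(aln$seqs[perm, , drop = FALSE], "p")
    expect_equal(fitch_length(rt, aln2), fitch_length(rt, aln))
  }

  expect_error(fitch_length(tr, mk_aln(c(a1 = "A", a2 = "A", c1 = "A"))),
               "id error")
})

test_that("heuristic MP search attains the exhaustive optimum", {
  # three taxa: the single topology
  a3 <- mk_aln(c(a = "ACGT", b = "AGGT", c = "ACTT"))
  r3 <- mp_search(a3)
  expect_equal(length(r3$tree$tip.label), 3L)
  # all-constant alignment: length 0
  ac <- mk_aln(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_equal(mp_search(ac, seed = 1)$length, 0L)
  # simulated strong signal: heuristic equals exact
  for (i in 1:5) {
    cfg <- sim_config(n_strains = 7, n_loci = 1, theta_per_locus = 15,
                      mode = "clonal", seed = 40 + i)
    aln <- simulate_multilocus(cfg)$dataset$loci$L1
    ex <- mp_search(aln, exact = TRUE)
    he <- mp_search(aln, n_starts = 3, seed = i)
    expect_equal(he$length, ex$length)
    expect_lte(ex$length, fitch_length(he$tree, aln))
  }
  expect_error(mp_search(mk_aln(c(a = "A", b = "A"))), "size error")
  expect_error(mp_search(rand_aln(12, 10), exact = TRUE), "exact mode")
})

test_that("extract_clades keeps supported non-trivial bipartitions", {
  tr <- ape::read.tree(text = "((a,b)0.99,(c,(d,e)0.99)0.99);")
  ct <- extract_clades(tr, 0.95, "x")
  expect_equal(length(ct$sides), 2L)   # n - 3 for a resolved 5-taxon tree
  expect_true(any(vapply(ct$sides, setequal, NA, y = c("a", "b"))))
  expect_true(any(vapply(ct$sides, setequal, NA, y = c("d", "e"))))
  # threshold boundary: 0.94 dropped, 0.96 kept
  tr2 <- ape::read.tree(text = "((a,b)0.94,(c,(d,e)0.96)0.5);")
  ct2 <- extract_clades(tr2, 0.95)
  expect_equal(length(ct2$sides), 1L)
  expect_true(setequal(ct2$sides[[1]], c("d", "e")))
  # star tree: no internal edges
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_equal(length(extract_clades(star, 0.95)$sides), 0L)
  # sides partition the leaf set
  for (s in ct$sides) {
    expect_true(all(s %in% ct$taxa))
    expect_gt(length(setdiff(ct$taxa, s)), 0L)
  }
})

test_that("split compatibility follows the four-intersection rule", {
  taxa <- c("A", "B", "C", "D")
  expect_true(clades_compatible(c("A", "B"), c("A", "B"), taxa))
  expect_true(clades_compatible(c("A", "B"), c("C", "D"), taxa))
  expect_false(clades_compatible(c("A", "B"), c("A", "C"), taxa))
  # fewer than 4 shared taxa: vacuously compatible
  expect_true(clades_compatible(c("A", "B"), c("A", "C"), c("A", "B", "C")))
})

test_that("patristic distances match an independent traversal", {
  cherry <- ape::read.tree(text = "(x:1,y:2);")
  expect_equal(patristic_distance(cherry, "x", "y"), 3)
  expect_equal(patristic_distance(cherry, "x", "x"), 0)
  set.seed(31)
  tr <- ape::rtree(8)
  for (pair in list(c(1, 5), c(2, 8), c(3, 4))) {
    i <- tr$tip.label[pair[1]]; j <- tr$tip.label[pair[2]]
    expect_equal(patristic_distance(tr, i, j), oracle_patristic(tr, i, j),
                 tolerance = 1e-12)
  }
  expect_error(patristic_distance(tr, "nope", tr$tip.label[1]), "id error")
})

test_that("NJ gene trees carry bootstrap supports", {
  cfg <- sim_config(n_strains = 10, n_loci = 1, theta_per_locus = 12,
                    mode = "clonal", seed = 77)
  aln <- simulate_multilocus(cfg)$dataset$loci$L1
  tr <- gene_tree(aln, bootstrap = 50, seed = 5)
  expect_equal(length(tr$node.label), tr$Nnode)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 1))
  tr2 <- gene_tree(aln, bootstrap = 50, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("newick round-trip preserves supports", {
  f <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "((a,b)95,(c,d)40);")
  writeLines("((a,b)95,(c,d)40);", f)
  g <- read_gene_tree(f)
  expect_equal(sort(g$node.label), c(0.40, 0.95))
  write_gene_tree(g, f)
  expect_true(file.exists(f))
})
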