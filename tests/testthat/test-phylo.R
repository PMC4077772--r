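test_that("pairwise distances follow the p and Poisson definitions", {
  aln <- as_alignment(c(x = "AAAAAAAAAA", y = "AAAAAAAAGG",
                        z = "AAAAAAAAAA"))
  dp <- pairwise_distance(aln, model = "p")
  expect_equal(dp["x", "y"], 0.2)
  expect_equal(dp["x", "z"], 0)
  dpois <- pairwise_distance(aln, model = "poisson")
  expect_equal(dpois["x", "y"], -log(0.8), tolerance = 1e-5)
  expect_equal(dpois["x", "y"], 0.22314, tolerance = 1e-4)
  # poisson >= p with equality only at zero
  expect_true(dpois["x", "y"] > dp["x", "y"])
  expect_equal(dpois["x", "z"], dp["x", "z"])
})

test_that("gap handling: pairwise vs complete deletion", {
  aln <- as_alignment(c(x = "AC-TT", y = "ACGTA", z = "-CGTT"))
  dp <- pairwise_distance(aln, model = "p", gap_mode = "pairwise")
  expect_equal(dp["x", "y"], 1 / 4)  # 4 comparable sites, 1 mismatch
  expect_equal(dp["x", "z"], 0)      # 3 comparable sites, identical
  dc <- pairwise_distance(aln, model = "p", gap_mode = "complete")
  expect_equal(dc["x", "y"], 1 / 3)  # columns 2,4,5 survive

  sat <- as_alignment(c(x = "AAAA", y = "CCCC", z = "AAAA"))
  expect_error(pairwise_distance(sat, model = "poisson"), "x.*y|undefined")
  all_gap <- as_alignment(c(x = "A--A", y = "-GG-", z = "AGGA"))
  expect_error(pairwise_distance(all_gap, model = "p"), "comparable")
})

test_that("neighbor joining reproduces closed-form small trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)

  d4 <- matrix(c(0, 2, 3, 3, 2, 0, 3, 3, 3, 3, 0, 2, 3, 3, 2, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- neighbor_joining(d4)
  expect_equal(tree_bipartitions(t4), "C|D")  # the AB|CD split
  # external branches 1, internal branch 1
  expect_equal(sort(t4$edge.length), c(1, 1, 1, 1, 1))

  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B")))),
               ">= 3")
  asym <- d4; asym[1, 2] <- 5
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("neighbor joining is invariant to input label order", {
  ad <- random_additive_matrix(6, seed = 21)
  t1 <- neighbor_joining(ad$dm)
  perm <- sample(rownames(ad$dm))
  t2 <- neighbor_joining(ad$dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tree_bipartitions(t1)), sort(tree_bipartitions(t2)))
})

test_that("neighbor joining agrees with an independent implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:8, 1)
    m <- matrix(stats::runif(n * n, 0.2, 2), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    rownames(m) <- colnames(m) <- LETTERS[1:n]
    mine <- suppressWarnings(neighbor_joining(m))
    ref <- ape::nj(m)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("negative branch estimates are clamped with a warning", {
  d <- matrix(c(0, 10, 1, 10, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_warning(tree <- neighbor_joining(d), "clamped")
  expect_true(all(tree$edge.length >= 0))
})

test_that("newick io round-trips and reports parse errors with position", {
  t1 <- read_newick("((A:1,B:1):1,C:3);")
  expect_equal(write_newick(t1), "((A:1,B:1):1,C:3);")
  # absent lengths stay absent, not zero
  t2 <- read_newick("(A,B,C);")
  expect_null(t2$edge.length)
  # internal support labels survive
  t3 <- read_newick("((A:1,B:1)98:1,C:3,D:1);")
  expect_true("98" %in% t3$node.label)
  expect_equal(write_newick(t3), "((A:1,B:1)98:1,C:3,D:1);")
  expect_error(read_newick("((A,B);"), "unclosed")
  expect_error(read_newick("(A,B));"), "character 6")
})

test_that("outgroup rooting places the root on the pendant edge and keeps supports", {
  aln <- clean_four_taxon_alignment()
  tree <- bootstrap_support(aln, model = "p", n_reps = 50, seed = 2)
  rooted <- root_with_outgroup(tree, "D")
  expect_true(ape::is.rooted(rooted))
  # bipartitions (and so supports) are unchanged by rooting
  expect_equal(sort(tree_bipartitions(ape::unroot(rooted))),
               sort(tree_bipartitions(tree)))
  expect_identical(attr(rooted, "bipartition_support"),
                   attr(tree, "bipartition_support"))
  # rooting then unrooting restores the unrooted topology
  expect_equal(ape::dist.topo(ape::unroot(rooted), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  # 3-taxon tree rooted on C: C hangs directly off the root
  t3 <- neighbor_joining(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                                dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C"))))
  r3 <- root_with_outgroup(t3, "C")
  root_children <- r3$edge[r3$edge[, 1] == length(r3$tip.label) + 1L, 2]
  expect_true(which(r3$tip.label == "C") %in% root_children)
  expect_error(root_with_outgroup(t3, "Z"), "not found")
})

test_that("bootstrap supports behave like bipartition frequencies", {
  aln <- clean_four_taxon_alignment()
  one <- bootstrap_support(aln, model = "p", n_reps = 1, seed = 9)
  sup <- attr(one, "bipartition_support")$support
  expect_true(all(sup %in% c(0, 100)))

  # same seed, same supports
  b1 <- bootstrap_support(aln, model = "p", n_reps = 25, seed = 4)
  b2 <- bootstrap_support(aln, model = "p", n_reps = 25, seed = 4)
  expect_identical(attr(b1, "bipartition_support"),
                   attr(b2, "bipartition_support"))

  # clean signal: different seeds agree to within binomial noise
  tre <- eight_taxon_tree()
  a8 <- evolve_alignment(tre, 400, seed = 13)
  s1 <- attr(bootstrap_support(a8, n_reps = 300, seed = 1),
             "bipartition_support")
  s2 <- attr(bootstrap_support(a8, n_reps = 300, seed = 2),
             "bipartition_support")
  merged <- merge(s1, s2, by = "bipartition")
  expect_true(all(abs(merged$support.x - merged$support.y) < 5))
})
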