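test_that("pairwise distances follow pairwise deletion and the Poisson correction", {
  aln <- tibble::tibble(
    id = c("s1", "s2"), description = "", residues = c("AAAA", "AAAT")
  )
  expect_equal(pairwise_distance(aln, "p")["s1", "s2"], 0.25)
  expect_equal(pairwise_distance(aln, "poisson")["s1", "s2"], -log(0.75))

  aln <- tibble::tibble(
    id = c("s1", "s2"), description = "", residues = c("A-AA", "AGAT")
  )
  expect_equal(pairwise_distance(aln, "p")["s1", "s2"], 1 / 3)

  ident <- tibble::tibble(
    id = c("x", "y"), description = "", residues = c("MKV-", "MKV-")
  )
  expect_equal(max(pairwise_distance(ident, "p")), 0)
  expect_equal(max(pairwise_distance(ident, "poisson")), 0)

  # saturated pair under poisson is capped, not infinite
  sat <- tibble::tibble(
    id = c("x", "y"), description = "", residues = c("AAAA", "TTTT")
  )
  expect_equal(pairwise_distance(sat, "poisson")["x", "y"], -log(1 - 0.999))

  disjoint <- tibble::tibble(
    id = c("x", "y"), description = "", residues = c("AA--", "--TT")
  )
  expect_error(pairwise_distance(disjoint, "p"), "x / y")
})

test_that("neighbor joining reproduces the worked quartet exactly", {
  # additive matrix of A-1-u, B-2-u, u-1-v, C-3-v, D-4-v
  d <- matrix(
    c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
    dimnames = list(LETTERS[1:4], LETTERS[1:4])
  )
  tr <- nj_tree(d)
  got <- ape::dist.nodes(tr)[1:4, 1:4]
  dimnames(got) <- list(tr$tip.label, tr$tip.label)
  expect_lt(max(abs(got[LETTERS[1:4], LETTERS[1:4]] - d)), 1e-12)
  # AB|CD is the internal split
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
})

test_that("three labels resolve by the closed-form three-point formulas", {
  d <- matrix(
    c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tr <- nj_tree(d)
  lens <- setNames(
    tr$edge.length[match(1:3, tr$edge[, 2])],
    tr$tip.label
  )
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 2, 4))
})

test_that("neighbor joining is invariant to input label order", {
  set.seed(5)
  for (rep in 1:20) {
    tr0 <- random_unrooted_tree(sample(4:10, 1))
    d <- additive_matrix(tr0)
    perm <- sample(nrow(d))
    t1 <- nj_tree(d)
    t2 <- nj_tree(d[perm, perm])
    expect_identical(write_newick(t1), write_newick(t2))
  }
})

test_that("neighbor joining rejects malformed matrices", {
  d <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
  d <- matrix(0, 2, 2, dimnames = list(letters[1:2], letters[1:2]))
  expect_error(nj_tree(d), "at least 3")
  d <- matrix(c(0, Inf, Inf, 0), 2, 2, dimnames = list(letters[1:2], letters[1:2]))
  expect_error(nj_tree(d), "finite|at least")
})

test_that("midpoint rooting reproduces hand-worked cases", {
  # two tips 3 apart: root 1.5 from each
  rt <- midpoint_root(read_newick("(A:1,B:2);"))
  expect_equal(root_tip_depths(rt), c(1.5, 1.5))

  # quartet: longest path B-D = 7, root 0.5 from v on the v-D edge
  d <- matrix(
    c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
    dimnames = list(LETTERS[1:4], LETTERS[1:4])
  )
  rt <- midpoint_root(nj_tree(d))
  dn <- ape::dist.nodes(rt)
  depths <- setNames(dn[5, 1:4], rt$tip.label)
  expect_equal(unname(depths["D"]), 3.5)
  expect_equal(unname(depths["B"]), 3.5)
  expect_equal(max(depths), 3.5)

  expect_error(midpoint_root(read_newick("(A:0,(B:0,C:0):0);")), "zero")
})

test_that("midpoint rooting matches the brute-force oracle and phangorn", {
  set.seed(13)
  for (rep in 1:50) {
    tr <- random_unrooted_tree(8)
    rt <- midpoint_root(tr)
    expect_true(ape::is.rooted(rt))
    expect_equal(root_tip_depths(rt), oracle_midpoint_depths(tr), tolerance = 1e-9)
    # independent cross-check against phangorn's implementation
    ph <- phangorn::midpoint(tr)
    expect_equal(max(root_tip_depths(rt)), max(root_tip_depths(ph)), tolerance = 1e-8)
  }
})

test_that("midpoint rooting keeps supports attached to their bipartitions", {
  # unrooted tree with support on the AB edge; root lands on the D pendant
  tr <- read_newick("((A:1,B:1)0.9:1,C:1,D:8);")
  rt <- midpoint_root(tr)
  cs <- clade_support(rt, c("A", "B"))
  expect_true(cs$is_monophyletic)
  expect_equal(cs$support, 0.9)
  # deeper internal edge keeps its support too
  tr <- read_newick("(((A:1,B:1)0.9:1,C:1)0.7:1,D:1,E:9);")
  rt <- midpoint_root(tr)
  expect_equal(clade_support(rt, c("A", "B"))$support, 0.9)
  expect_equal(clade_support(rt, c("A", "B", "C"))$support, 0.7)
})

test_that("bootstrap support is 1 when every column supports the split", {
  aln <- tibble::tibble(
    id = c("A", "B", "C", "D"), description = "",
    residues = c(strrep("A", 100), strrep("A", 100), strrep("T", 100), strrep("T", 100))
  )
  bt <- bootstrap_support(aln, "p", n_replicates = 50, seed = 1)
  sup <- bt$node.label[!is.na(bt$node.label)]
  expect_equal(sup, 1)
  expect_equal(attr(bt, "n_dropped"), 0L)
  expect_equal(glance(bt)$mean_support, 1)
  expect_equal(tidy(bt)$split, "A|B")
})

test_that("bootstrap supports are deterministic under seed, in [0,1], and tip-order invariant", {
  set.seed(31)
  aln <- random_alignment(6, 60, gap_prob = 0.1)
  # ensure pairwise comparability across resamples
  aln$residues <- paste0(aln$residues, strrep("A", 20))
  b1 <- bootstrap_support(aln, "poisson", n_replicates = 30, seed = 42)
  b2 <- bootstrap_support(aln, "poisson", n_replicates = 30, seed = 42)
  expect_identical(b1$node.label, b2$node.label)
  sup <- b1$node.label[!is.na(b1$node.label)]
  expect_true(all(sup >= 0 & sup <= 1))

  perm <- sample(nrow(aln))
  b3 <- bootstrap_support(aln[perm, ], "poisson", n_replicates = 30, seed = 42)
  expect_equal(sort(tidy(b3)$split), sort(tidy(b1)$split))
  expect_equal(
    tidy(b3)$support[order(tidy(b3)$split)],
    tidy(b1)$support[order(tidy(b1)$split)]
  )

  # single replicate: support is 0 or 1
  b4 <- bootstrap_support(aln, "poisson", n_replicates = 1, seed = 9)
  sup4 <- b4$node.label[!is.na(b4$node.label)]
  expect_true(all(sup4 %in% c(0, 1)))
})
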