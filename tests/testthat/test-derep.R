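test_that("matching cherries are found only among true sister tips", {
  tax <- tibble::tibble(
    seq_id = c("A1", "A2", "B", "C"),
    cell_domain = "prokaryote",
    genus = c("X", "X", "Y", "Z")
  )
  ch <- find_matching_cherries(read_newick("((A1,A2),B);"), tax, "genus")
  expect_equal(ch$tip_a, "A1")
  expect_equal(ch$tip_b, "A2")

  # same genus but not sisters
  ch <- find_matching_cherries(read_newick("((A1,B),(A2,C));"), tax, "genus")
  expect_equal(nrow(ch), 0)

  # NA-labelled pairs are excluded
  tax_na <- tax
  tax_na$genus <- c(NA, NA, "Y", "Z")
  ch <- find_matching_cherries(read_newick("((A1,A2),B);"), tax_na, "genus")
  expect_equal(nrow(ch), 0)

  expect_error(
    find_matching_cherries(read_newick("((A1,A2),ZZ);"), tax, "genus"),
    "ZZ"
  )
  expect_error(
    find_matching_cherries(read_newick("((A1,A2),B);"), tax, "family"),
    "family"
  )
})

test_that("dereplication drops the lower-scoring sister and sums branch lengths", {
  tax <- tibble::tibble(
    seq_id = c("A1", "A2", "B"),
    cell_domain = "prokaryote",
    genus = c("X", "X", "Y")
  )
  res <- dereplicate_tree(
    read_newick("((A1:1.0,A2:1.0):0.5,B:2.0);"),
    tax, c(A1 = 50, A2 = 60, B = 10), "genus"
  )
  expect_setequal(res$retained, c("A2", "B"))
  expect_equal(res$dropped, "A1")
  a2_edge <- res$tree$edge.length[match(
    match("A2", res$tree$tip.label), res$tree$edge[, 2]
  )]
  expect_equal(a2_edge, 1.5)
  expect_equal(glance(res)$n_dropped, 1L)
})

test_that("same-taxon caterpillars collapse to the maximum-score tip", {
  tax <- tibble::tibble(
    seq_id = c("a", "b", "c", "d"),
    cell_domain = "prokaryote",
    genus = c("X", "X", "X", "Y")
  )
  res <- dereplicate_tree(
    read_newick("(((a:1,b:1):1,c:1):1,d:5);"),
    tax, c(a = 10, b = 20, c = 30, d = 1), "genus"
  )
  expect_setequal(res$retained, c("c", "d"))

  set.seed(17)
  for (rep in 1:30) {
    inst <- caterpillar_instance(sample(3:8, 1))
    res <- dereplicate_tree(inst$tree, inst$taxonomy, inst$scores, "genus")
    survivors <- setdiff(res$retained, "out")
    expect_length(survivors, 1)
    clade_scores <- inst$scores[setdiff(names(inst$scores), "out")]
    expect_equal(unname(inst$scores[survivors]), max(clade_scores))
  }
})

test_that("score ties drop the lexicographically larger id", {
  tax <- tibble::tibble(
    seq_id = c("A1", "A2", "B"), cell_domain = "prokaryote",
    genus = c("X", "X", "Y")
  )
  res <- dereplicate_tree(
    read_newick("((A1:1,A2:1):1,B:1);"),
    tax, c(A1 = 5, A2 = 5, B = 1), "genus"
  )
  expect_setequal(res$retained, c("A1", "B"))
})

test_that("dereplication reaches a fixpoint, is idempotent, and conserves tips", {
  set.seed(23)
  for (rep in 1:60) {
    inst <- random_derep_instance(sample(4:10, 1))
    res <- dereplicate_tree(inst$tree, inst$taxonomy, inst$scores, "genus")
    expect_equal(nrow(find_matching_cherries(res$tree, inst$taxonomy, "genus")), 0)
    expect_setequal(c(res$retained, res$dropped), inst$tree$tip.label)
    # idempotence
    res2 <- dereplicate_tree(res$tree, inst$taxonomy, inst$scores, "genus")
    expect_equal(res2$dropped, character(0))
    expect_setequal(res2$retained, res$retained)
    # degree-2 suppression preserves distances among survivors
    if (length(res$retained) >= 2 && length(res$dropped) > 0) {
      before <- ape::cophenetic.phylo(inst$tree)[res$retained, res$retained]
      after <- ape::cophenetic.phylo(res$tree)[res$retained, res$retained]
      expect_equal(after, before, tolerance = 1e-9)
    }
  }
})

test_that("dereplication collapses an all-matching tree to a single tip", {
  tax <- tibble::tibble(
    seq_id = c("a", "b", "c"), cell_domain = "prokaryote", genus = "X"
  )
  res <- dereplicate_tree(
    read_newick("((a:1,b:1):1,c:1);"),
    tax, c(a = 1, b = 3, c = 2), "genus"
  )
  expect_equal(res$retained, "b")
  expect_setequal(res$dropped, c("a", "c"))
})

test_that("the iterative pipeline subsets records round by round", {
  tax <- tibble::tibble(
    seq_id = c(paste0("clone", 1:5), paste0("g", 1:3)),
    cell_domain = "prokaryote",
    genus = c(rep("X", 5), "P", "Q", "R")
  )
  set.seed(2)
  base <- paste(sample(c("A", "C", "D", "E", "F"), 60, replace = TRUE), collapse = "")
  jitter <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(c("G", "H", "I", "K"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- tibble::tibble(
    id = tax$seq_id,
    description = "",
    residues = c(
      vapply(1:5, function(i) jitter(base, 2), character(1)),
      vapply(1:3, function(i) jitter(base, 25), character(1))
    )
  )
  scores <- setNames(c(1:5, 9, 9, 9), tax$seq_id)

  # rounds = 0 is the identity
  r0 <- derep_pipeline(seqs, tax, scores, "genus", rounds = 0)
  expect_equal(r0$records, seqs)

  r1 <- derep_pipeline(seqs, tax, scores, "genus", rounds = 1)
  expect_true(all(c("g1", "g2", "g3") %in% r1$records$id))
  expect_lt(sum(grepl("clone", r1$records$id)), 5)

  # rounds = 2 equals two successive single rounds with rebuilt trees
  r2 <- derep_pipeline(seqs, tax, scores, "genus", rounds = 2)
  r11 <- derep_pipeline(r1$records, tax, scores, "genus", rounds = 1)
  expect_equal(r2$records, r11$records)

  small <- seqs[1:2, ]
  expect_warning(derep_pipeline(small, tax, scores, "genus", rounds = 1), "skipped")
})
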