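test_that("species tree simulation honours group structure and determinism", {
  cfg <- sim_config(
    group_spec = tibble::tibble(
      group = c("G1", "G2"), cell_domain = c("prokaryote", "eukaryote"),
      n = c(2L, 2L)
    ),
    domain_lengths = c(D = 50L),
    hgt_events = list(), seed = 1
  )
  st <- simulate_species_tree(cfg, seed = 1)
  expect_equal(length(st$tree$tip.label), 4)
  expect_equal(st$tree$Nnode, 3)
  expect_setequal(st$taxonomy$group, c("G1", "G2"))
  # groups are monophyletic
  for (g in c("G1", "G2")) {
    tips <- st$taxonomy$seq_id[st$taxonomy$group == g]
    expect_true(clade_support(st$tree, tips)$is_monophyletic)
  }
  st2 <- simulate_species_tree(cfg, seed = 1)
  expect_identical(write_newick(st$tree), write_newick(st2$tree))

  bad <- tibble::tibble(group = "G", cell_domain = "prokaryote", n = 2L)
  expect_error(sim_config(group_spec = bad, hgt_events = list()), "at least 4")
})

test_that("exponential branch lengths recover their configured mean", {
  cfg <- sim_config(
    group_spec = tibble::tibble(
      group = "G1", cell_domain = "prokaryote", n = 5000L
    ),
    branch_length_mean = 2.0,
    domain_lengths = c(D = 50L), hgt_events = list(), seed = 1
  )
  st <- simulate_species_tree(cfg, seed = 99)
  bl <- st$tree$edge.length
  expect_gte(length(bl), 9000)
  se <- 2.0 / sqrt(length(bl))
  expect_lt(abs(mean(bl) - 2.0), 3 * se)
})

test_that("per-branch substitution fractions match 1 - exp(-rt)", {
  tr <- read_newick("(A:1,B:0);")
  root <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 10000, replace = TRUE),
    collapse = ""
  )
  tips <- evolve_domain(tr, root, subst_rate = 0.3, seed = 8)
  # zero-length branch: unchanged
  expect_equal(tips[["B"]], root)
  p_exp <- 1 - exp(-0.3)
  p_obs <- mean(strsplit(tips[["A"]], "")[[1]] != strsplit(root, "")[[1]])
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # rate zero: every tip equals the root
  expect_true(all(evolve_domain(tr, root, 0) == root))
  expect_error(evolve_domain(tr, root, -1), "non-negative")
  expect_error(evolve_domain(tr, "AC-D", 0.1), "gap-free")
})

test_that("sibling lineages mutate independently (identity matches closed form)", {
  tr <- read_newick("(A:1,B:1);")
  p <- 1 - exp(-0.3)
  # P(match) per site: both unmutated, or both mutated to the same residue
  p_match <- (1 - p)^2 + p^2 / 19
  obs <- numeric(20)
  for (s in 1:20) {
    root <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 2000, replace = TRUE),
      collapse = ""
    )
    tips <- evolve_domain(tr, root, 0.3, seed = s)
    obs[s] <- mean(strsplit(tips[["A"]], "")[[1]] == strsplit(tips[["B"]], "")[[1]])
  }
  se <- sqrt(p_match * (1 - p_match) / (2000 * 20))
  expect_lt(abs(mean(obs) - p_match), 3 * se)
})

test_that("horizontal transfer copies the donor cassette into recipients", {
  seqs <- list(
    CrtI = c(don = strrep("M", 60), other = strrep("K", 60)),
    CrtB = c(don = strrep("W", 40), other = strrep("F", 40))
  )
  # scale 0: exact copies
  res <- apply_hgt(seqs, "don", c("r1", "r2"), c("CrtI", "CrtB"),
    subst_rate = 0.2, post_transfer_scale = 0, seed = 1
  )
  expect_equal(res$tip_sequences$CrtI[["r1"]], strrep("M", 60))
  expect_equal(res$tip_sequences$CrtB[["r2"]], strrep("W", 40))
  expect_setequal(res$recipient_ids, c("r1", "r2"))

  # no recipients: identity
  res0 <- apply_hgt(seqs, "don", character(), c("CrtI"), 0.2, 0.1)
  expect_identical(res0$tip_sequences, seqs)

  # recipient already carrying a cassette domain is an error
  seqs_bad <- seqs
  seqs_bad$CrtI <- c(seqs_bad$CrtI, r1 = strrep("A", 60))
  expect_error(
    apply_hgt(seqs_bad, "don", "r1", c("CrtI"), 0.2, 0.1),
    "already carry"
  )
  expect_error(
    apply_hgt(seqs, "ghost", "r1", c("CrtI"), 0.2, 0.1),
    "ghost"
  )
})

test_that("domain fusion concatenates with exact envelope coordinates and scores", {
  doms <- c(
    CrtI = strrep("M", 500), CrtB = strrep("K", 300), `CrtYc/d` = strrep("W", 120)
  )
  fz <- fuse_domains(doms, names(doms), linker = "GS", seq_id = "p")
  expect_equal(nchar(fz$record$residues), 924)
  expect_equal(fz$hits$env_start, c(1L, 503L, 805L))
  expect_equal(fz$hits$env_end, c(500L, 802L, 924L))
  # zero divergence: bit score equals the domain length
  expect_equal(fz$hits$bit_score, c(500, 300, 120))

  one <- fuse_domains(doms, "CrtB", seq_id = "q")
  expect_equal(one$hits$env_start, 1L)
  expect_equal(one$hits$env_end, 300L)
  expect_equal(one$record$residues, doms[["CrtB"]])

  expect_error(fuse_domains(doms, character()), "at least one")
})

test_that("datasets are deterministic and conserve records across tables", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- tiny_config(seed = 7)
  build_dataset(cfg, out_dir = d1)
  build_dataset(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(
      readLines(file.path(d1, f), warn = FALSE),
      readLines(file.path(d2, f), warn = FALSE)
    )
  }

  ds <- build_dataset(cfg)
  # every protein record appears once in taxonomy and at least once in hits
  expect_true(all(ds$proteins$id %in% ds$taxonomy$seq_id))
  expect_equal(anyDuplicated(ds$taxonomy$seq_id), 0)
  expect_true(all(ds$proteins$id %in% ds$hits$seq_id))
  expect_equal(nrow(ds$scores), nrow(ds$hits))
  # every record is covered by exactly one truth architecture (fragments via parent)
  base_id <- sub("\\.f\\d+$", "", ds$proteins$id)
  expect_true(all(base_id %in% ds$truth$architectures$seq_id))
  # hit coordinates stay within their protein
  len_of <- setNames(nchar(ds$proteins$residues), ds$proteins$id)
  expect_true(all(ds$hits$env_end <= len_of[ds$hits$seq_id]))
  # recipients are eukaryotic
  rec_cd <- ds$taxonomy$cell_domain[match(
    ds$truth$recipient_protein_ids, ds$taxonomy$seq_id
  )]
  expect_true(all(rec_cd == "eukaryote"))
})

test_that("outlier and fragment injection produce the configured counts", {
  cfg0 <- tiny_config(seed = 2, outlier_fraction = 0, fragment_fraction = 0)
  ds0 <- build_dataset(cfg0)
  expect_equal(ds0$truth$outlier_ids, character())
  expect_equal(ds0$truth$fragment_parent_ids, character())
  # nothing for the curation stage to do: filters are no-ops per family
  fam <- family_records(ds0, "CrtI")
  expect_equal(nrow(length_filter(fam$records)$removed), 0)
  expect_true(all(is.na(fam$hits$parent_id)))

  cfg <- tiny_config(seed = 2, outlier_fraction = 0.1, fragment_fraction = 0.05)
  ds <- build_dataset(cfg)
  n_rec <- nrow(ds$full_proteins)
  expect_length(ds$truth$outlier_ids, round(0.1 * n_rec))
  expect_length(ds$truth$fragment_parent_ids, round(0.05 * n_rec))
  # each fragment parent contributes exactly two fragment records
  for (p in ds$truth$fragment_parent_ids) {
    expect_setequal(
      ds$proteins$id[startsWith(ds$proteins$id, paste0(p, "."))],
      paste0(p, ".f", 1:2)
    )
  }
  # outliers fall outside the one-sd keep interval of their family
  for (dom in names(cfg$domain_lengths)) {
    fam <- family_records(ds, dom)
    out_here <- intersect(ds$truth$outlier_ids, fam$records$id)
    if (length(out_here) > 0) {
      lf <- length_filter(fam$records)
      expect_true(all(out_here %in% lf$removed$id))
    }
  }
})
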