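# Fixture generators and independent brute-force oracles.
# These deliberately avoid the package's own code paths wherever they serve
# as a reference: the midpoint and trimming oracles are direct enumerations,
# and additive matrices come from ape path lengths on a known tree.

random_unrooted_tree <- function(ntip, min_len = 0.05, max_len = 2) {
  tr <- ape::rtree(ntip, rooted = FALSE)
  tr$tip.label <- sprintf("t%02d", seq_len(ntip))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

random_rooted_tree <- function(ntip, min_len = 0.05, max_len = 2) {
  tr <- ape::rtree(ntip)
  tr$tip.label <- sprintf("t%02d", seq_len(ntip))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# path-length (additive) distance matrix of a tree
additive_matrix <- function(tr) {
  ntip <- length(tr$tip.label)
  d <- ape::dist.nodes(tr)[seq_len(ntip), seq_len(ntip)]
  dimnames(d) <- list(tr$tip.label, tr$tip.label)
  d
}

# brute force: minimise the maximum root-to-tip depth over every position on
# every edge; returns the sorted depth vector at the optimum
oracle_midpoint_depths <- function(tr) {
  ntip <- length(tr$tip.label)
  dn <- ape::dist.nodes(tr)
  best <- Inf
  best_depths <- NULL
  for (k in seq_len(nrow(tr$edge))) {
    u <- tr$edge[k, 1]
    v <- tr$edge[k, 2]
    L <- tr$edge.length[k]
    du <- dn[u, seq_len(ntip)]
    dv <- dn[v, seq_len(ntip)]
    uside <- abs(du + L - dv) < 1e-9 # tip reached through u
    mu <- if (any(uside)) max(du[uside]) else -Inf
    mv <- if (any(!uside)) max(dv[!uside]) else -Inf
    xstar <- min(max((mv - mu + L) / 2, 0), L)
    val <- max(mu + xstar, mv + L - xstar)
    if (val < best - 1e-15) {
      best <- val
      best_depths <- ifelse(uside, du + xstar, dv + (L - xstar))
    }
  }
  sort(unname(best_depths))
}

root_tip_depths <- function(rooted) {
  ntip <- length(rooted$tip.label)
  sort(unname(ape::dist.nodes(rooted)[ntip + 1, seq_len(ntip)]))
}

# brute-force per-column gap counting
oracle_kept_columns <- function(seqs, threshold) {
  m <- do.call(rbind, strsplit(seqs$residues, ""))
  keep <- integer()
  for (j in seq_len(ncol(m))) {
    if (sum(m[, j] == "-") / nrow(m) < threshold) keep <- c(keep, j)
  }
  keep
}

random_alignment <- function(n_rec, n_col, gap_prob = 0.2) {
  residues <- replicate(n_rec, paste(
    sample(c("A", "C", "G", "T", "M", "K", "-"), n_col,
      replace = TRUE,
      prob = c(rep((1 - gap_prob) / 6, 6), gap_prob)
    ),
    collapse = ""
  ))
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n_rec)),
    description = "",
    residues = residues
  )
}

random_derep_instance <- function(ntip, n_taxa = 3) {
  tr <- random_rooted_tree(ntip)
  tax <- tibble::tibble(
    seq_id = tr$tip.label,
    cell_domain = "prokaryote",
    genus = sample(LETTERS[seq_len(n_taxa)], ntip, replace = TRUE)
  )
  scores <- stats::setNames(stats::runif(ntip, 1, 100), tr$tip.label)
  list(tree = tr, taxonomy = tax, scores = scores)
}

# caterpillar of k same-genus tips plus a distinct-genus outgroup
caterpillar_instance <- function(k) {
  tips <- sprintf("c%02d", seq_len(k))
  nwk <- tips[1]
  for (i in seq(2, k)) nwk <- sprintf("(%s:1,%s:1)", nwk, tips[i])
  nwk <- sprintf("(%s:1,out:5);", nwk)
  tax <- tibble::tibble(
    seq_id = c(tips, "out"),
    cell_domain = "prokaryote",
    genus = c(rep("X", k), "Y")
  )
  scores <- stats::setNames(c(sample(seq_len(k) * 10), 1), c(tips, "out"))
  list(tree = carotscan::read_newick(nwk), taxonomy = tax, scores = scores)
}

tiny_config <- function(seed = 1, ...) {
  sim_config(
    group_spec = tibble::tibble(
      group = c("ProkA", "ProkB", "EukA", "EukB", "EukC"),
      cell_domain = c("prokaryote", "prokaryote", rep("eukaryote", 3)),
      n = c(3L, 3L, 2L, 2L, 2L)
    ),
    domain_lengths = c(CrtI = 300L, CrtB = 200L, Rpe65 = 100L),
    hgt_events = list(list(
      donor_species = "ProkA_sp01",
      recipients = c("EukA_sp01", "EukB_sp01", "EukC_sp01"),
      cassette = c("CrtI", "CrtB"),
      post_transfer_scale = 0.1
    )),
    seed = seed,
    ...
  )
}
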