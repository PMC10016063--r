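# --- bipartitions --------------------------------------------------------
# Canonical key of the split induced by the edge above each internal node:
# the side containing the alphabetically first tip, sorted and pasted.
# Returns a character vector indexed by node number (NA for tips, the root,
# and trivial splits).
node_split_keys <- function(tr) {
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  first_tip <- sort(tr$tip.label)[1]
  sets <- vector("list", nn)
  for (t in seq_len(ntip)) sets[[t]] <- tr$tip.label[t]
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    c <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  root <- ntip + 1
  keys <- rep(NA_character_, nn)
  for (v in seq(ntip + 1, nn)) {
    if (v == root) next
    side <- sets[[v]]
    if (length(side) < 2 || ntip - length(side) < 2) next
    if (!(first_tip %in% side)) side <- setdiff(tr$tip.label, side)
    keys[v] <- paste(sort(side), collapse = "|")
  }
  keys
}

tree_split_set <- function(tr) {
  k <- node_split_keys(tr)
  k[!is.na(k)]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Nonparametric (Felsenstein) bootstrap: alignment columns are resampled
#' with replacement, the distance + neighbor-joining tree is rebuilt for each
#' replicate, and the support of every internal edge of the original tree is
#' the fraction of replicates containing the same bipartition (compared as
#' unordered tip-set splits). A replicate in which some pair of sequences has
#' no comparable columns is dropped and counted; the support denominator is
#' adjusted accordingly (attribute `n_dropped`).
#'
#' @param seqs Alignment tibble.
#' @param model Distance model passed to [pairwise_distance()].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; identical seeds give identical supports.
#' @return The neighbor-joining tree of the full alignment, of class
#'   `caro_tree`/`phylo`, with numeric `$node.label` support values in
#'   `[0, 1]` (NA on the root and on trivial edges) and attributes
#'   `n_replicates`, `n_dropped`, `model`.
#' @seealso [tidy.caro_tree()], [glance.caro_tree()]
#' @export
bootstrap_support <- function(seqs, model = c("poisson", "p"),
                              n_replicates = 1000, seed = NULL) {
  model <- match.arg(model)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  validate_seqs(seqs, aligned = TRUE)
  m <- aln_matrix(seqs)
  tr0 <- nj_tree(distance_from_matrix(m, model))
  keys0 <- node_split_keys(tr0)
  idx <- which(!is.na(keys0))
  counts <- integer(length(idx))
  dropped <- 0L
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(m)
  for (rep in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    dr <- tryCatch(
      distance_from_matrix(m[, cols, drop = FALSE], model),
      error = function(e) NULL
    )
    if (is.null(dr)) {
      dropped <- dropped + 1L
      next
    }
    rep_keys <- tree_split_set(nj_tree(dr))
    counts <- counts + (keys0[idx] %in% rep_keys)
  }
  denom <- n_replicates - dropped
  ntip <- length(tr0$tip.label)
  lab <- rep(NA_real_, tr0$Nnode)
  if (denom > 0) lab[idx - ntip] <- counts / denom
  tr0$node.label <- lab
  class(tr0) <- unique(c("caro_tree", class(tr0)))
  attr(tr0, "n_replicates") <- n_replicates
  attr(tr0, "n_dropped") <- dropped
  attr(tr0, "model") <- model
  tr0
}

#' Tidy bootstrap-tree supports into a tibble
#'
#' One row per internal edge with a defined bipartition: the two tip sets
#' of the split (as a `|`-joined key for the side holding the alphabetically
#' first tip) and the bootstrap support.
#'
#' @param x A `caro_tree` from [bootstrap_support()].
#' @param ... Unused.
#' @return A tibble with columns `node`, `split`, `n_tips_side`, `support`.
#' @export
tidy.caro_tree <- function(x, ...) {
  keys <- node_split_keys(x)
  ntip <- length(x$tip.label)
  idx <- which(!is.na(keys))
  tibble(
    node = idx,
    split = keys[idx],
    n_tips_side = lengths(strsplit(keys[idx], "|", fixed = TRUE)),
    support = x$node.label[idx - ntip]
  )
}

#' One-row summary of a bootstrap tree
#'
#' @param x A `caro_tree` from [bootstrap_support()].
#' @param ... Unused.
#' @return A tibble with `n_tips`, `n_replicates`, `n_dropped`,
#'   `mean_support`, `min_support`.
#' @export
glance.caro_tree <- function(x, ...) {
  sup <- x$node.label[!is.na(x$node.label)]
  tibble(
    n_tips = length(x$tip.label),
    n_replicates = attr(x, "n_replicates") %||% NA_integer_,
    n_dropped = attr(x, "n_dropped") %||% NA_integer_,
    mean_support = if (length(sup)) mean(sup) else NA_real_,
    min_support = if (length(sup)) min(sup) else NA_real_
  )
}
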