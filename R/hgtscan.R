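# tip descendants of every node, as a list indexed by node number
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) sets[[t]] <- tree$tip.label[t]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    c <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

node_parents <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    return(1.0) # singleton clade: supported by convention
  }
  if (is.null(tree$node.label)) {
    return(NA_real_)
  }
  normalise_support(tree$node.label)[node - ntip]
}

#' Monophyly and support of a tip set
#'
#' Tests whether some node's tip descendants equal `tip_set` exactly; if so,
#' returns the support of the edge above that node. A singleton tip set is
#' monophyletic with support 1 by convention, as is the full tip set (the
#' root). Non-monophyletic sets return `(FALSE, NA)`.
#'
#' @param tree A rooted `phylo` tree, optionally with support labels.
#' @param tip_set Character vector of tip labels.
#' @return A list: `is_monophyletic` (logical), `support` (numeric or NA).
#' @export
clade_support <- function(tree, tip_set) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(tip_set, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown tip(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(tip_set) == 0) abort("tip_set must be non-empty")
  if (setequal(tip_set, tree$tip.label)) {
    return(list(is_monophyletic = TRUE, support = 1.0))
  }
  sets <- node_tip_sets(tree)
  want <- sort(unique(tip_set))
  for (v in seq_along(sets)) {
    if (length(sets[[v]]) == length(want) && setequal(sets[[v]], want)) {
      return(list(is_monophyletic = TRUE, support = node_support(tree, v)))
    }
  }
  list(is_monophyletic = FALSE, support = NA_real_)
}

#' Scan for taxonomically disjunct eukaryote clades
#'
#' Reports every maximal clade of a rooted tree whose tips are all
#' eukaryotic, span at least `min_groups` distinct labels at
#' `grouping_rank`, and carry support at least `min_support` (`NA` support
#' passes only when `min_support = 0`). For each reported clade the fraction
#' of foreign (prokaryotic or viral) tips among the parent clade's other
#' descendants is reported — a nesting context measure, not a filter.
#' Reports are mutually non-nested and sorted by support (descending, NA
#' last), then by group count.
#'
#' @param tree Rooted `phylo` tree with (optional) support labels.
#' @param taxonomy Taxonomy tibble covering every tip (`cell_domain` and the
#'   grouping rank required).
#' @param grouping_rank Rank column whose label diversity is counted.
#' @param min_groups Minimum number of distinct rank labels (default 3).
#' @param min_support Minimum clade support in `[0, 1]` (default 0:
#'   support is reported, not thresholded).
#' @return Tibble with one row per reported clade: `tips` (list column),
#'   `n_tips`, `n_groups`, `support`, `parent_context_foreign_fraction`,
#'   `depth` (edges from the root).
#' @export
scan_disjunct_clades <- function(tree, taxonomy, grouping_rank,
                                 min_groups = 3, min_support = 0) {
  stopifnot(inherits(tree, "phylo"))
  group_of <- rank_labels(taxonomy, tree$tip.label, grouping_rank)
  cd <- rank_labels(taxonomy, tree$tip.label, "cell_domain")
  sets <- node_tip_sets(tree)
  parent <- node_parents(tree)
  nn <- length(sets)

  qualifies <- vapply(seq_len(nn), function(v) {
    tips <- sets[[v]]
    if (!all(cd[tips] == "eukaryote")) {
      return(FALSE)
    }
    groups <- unique(group_of[tips])
    groups <- groups[!is.na(groups)]
    if (length(groups) < min_groups) {
      return(FALSE)
    }
    sup <- node_support(tree, v)
    if (is.na(sup)) min_support == 0 else sup >= min_support
  }, logical(1))

  # maximal only: no reported clade nested inside another reported clade
  maximal <- qualifies
  for (v in which(qualifies)) {
    p <- parent[v]
    while (!is.na(p)) {
      if (qualifies[p]) {
        maximal[v] <- FALSE
        break
      }
      p <- parent[p]
    }
  }

  depth_of <- function(v) {
    d <- 0
    while (!is.na(parent[v])) {
      v <- parent[v]
      d <- d + 1
    }
    d
  }

  rows <- lapply(which(maximal), function(v) {
    tips <- sort(sets[[v]])
    p <- parent[v]
    foreign <- NA_real_
    if (!is.na(p)) {
      context <- setdiff(sets[[p]], tips)
      if (length(context) > 0) {
        foreign <- mean(cd[context] %in% c("prokaryote", "virus"))
      }
    }
    groups <- unique(group_of[tips])
    clade_tips <- tips
    tibble(
      tips = list(clade_tips),
      n_tips = length(clade_tips),
      n_groups = length(groups[!is.na(groups)]),
      support = node_support(tree, v),
      parent_context_foreign_fraction = foreign,
      depth = depth_of(v)
    )
  })
  out <- if (length(rows) == 0) {
    tibble(
      tips = list(), n_tips = integer(), n_groups = integer(),
      support = numeric(), parent_context_foreign_fraction = numeric(),
      depth = integer()
    )
  } else {
    bind_rows(rows)
  }
  arrange(out, desc(!is.na(.data$support)), desc(.data$support), desc(.data$n_groups))
}
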