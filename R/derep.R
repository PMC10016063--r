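rank_labels <- function(taxonomy, tips, rank) {
  if (!rank %in% names(taxonomy)) {
    abort(paste0("rank '", rank, "' not found in the taxonomy table"))
  }
  missing <- setdiff(tips, taxonomy$seq_id)
  if (length(missing) > 0) {
    abort(paste0("tip(s) missing from taxonomy: ", paste(missing, collapse = ", ")))
  }
  lab <- taxonomy[[rank]][match(tips, taxonomy$seq_id)]
  lab[lab %in% "NA"] <- NA_character_
  setNames(lab, tips)
}

#' Find cherries whose two tips share a taxon
#'
#' A cherry is a pair of tips that are children of the same node with no
#' other tip descendants between them — the operational meaning of "sister"
#' sequences. Returns all cherries whose labels at `rank` are equal and not
#' missing, sorted by the lexicographically smaller tip id.
#'
#' @param tree A `phylo` tree.
#' @param taxonomy Taxonomy tibble ([read_taxonomy()] schema) covering all
#'   tips.
#' @param rank Rank column name at which tips are compared.
#' @return Tibble with columns `tip_a`, `tip_b` (sorted within pair),
#'   `taxon`.
#' @export
find_matching_cherries <- function(tree, taxonomy, rank) {
  stopifnot(inherits(tree, "phylo"))
  lab <- rank_labels(taxonomy, tree$tip.label, rank)
  ntip <- length(tree$tip.label)
  out <- tibble(tip_a = character(), tip_b = character(), taxon = character())
  if (ntip < 2 || is.null(tree$edge)) {
    return(out)
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (ch in kids) {
    tips <- ch[ch <= ntip]
    if (length(tips) < 2) next
    for (i in seq_len(length(tips) - 1)) {
      for (j in seq(i + 1, length(tips))) {
        a <- tree$tip.label[tips[i]]
        b <- tree$tip.label[tips[j]]
        la <- lab[[a]]
        lb <- lab[[b]]
        if (!is.na(la) && !is.na(lb) && la == lb) {
          pair <- sort(c(a, b))
          out <- bind_rows(out, tibble(tip_a = pair[1], tip_b = pair[2], taxon = la))
        }
      }
    }
  }
  arrange(out, .data$tip_a, .data$tip_b)
}

# minimal one-tip phylo, for the degenerate end point of dereplication
single_tip_tree <- function(label, length = 0) {
  structure(
    list(
      edge = matrix(c(2L, 1L), 1, 2),
      tip.label = label,
      edge.length = length,
      Nnode = 1L
    ),
    class = "phylo"
  )
}

#' Tree-guided taxonomic dereplication
#'
#' Iteratively removes redundancy at a chosen taxonomic rank: while any
#' cherry of same-rank tips exists, the first cherry in sorted order is
#' resolved by dropping the lower-scoring tip (ties drop the
#' lexicographically larger id). Removing a tip suppresses the resulting
#' degree-2 node by summing its two incident branch lengths, preserving
#' tip-to-tip distances among survivors. The result is a fixpoint: no
#' same-rank cherry remains.
#'
#' @param tree A `phylo` tree.
#' @param taxonomy Taxonomy tibble covering all tips.
#' @param scores Named numeric vector or tibble (`seq_id`, `bit_score`)
#'   giving a bit score for every tip.
#' @param rank Rank column name (the desired taxonomic level).
#' @return A list of class `caro_derep`: `tree` (pruned), `retained` and
#'   `dropped` tip id vectors (their union is the original tip set), and
#'   `rank`.
#' @examples
#' tr <- read_newick("((A1:1.0,A2:1.0):0.5,B:2.0);")
#' tax <- tibble::tibble(
#'   seq_id = c("A1", "A2", "B"),
#'   cell_domain = "prokaryote", genus = c("X", "X", "Y")
#' )
#' dereplicate_tree(tr, tax, c(A1 = 50, A2 = 60, B = 10), "genus")$retained
#' @export
dereplicate_tree <- function(tree, taxonomy, scores, rank) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(scores)) {
    scores <- setNames(scores$bit_score, scores$seq_id)
  }
  missing <- setdiff(tree$tip.label, names(scores))
  if (length(missing) > 0) {
    abort(paste0("tip(s) missing a bit score: ", paste(missing, collapse = ", ")))
  }
  original <- tree$tip.label
  dropped <- character()
  repeat {
    cherries <- find_matching_cherries(tree, taxonomy, rank)
    if (nrow(cherries) == 0) break
    a <- cherries$tip_a[1]
    b <- cherries$tip_b[1]
    loser <- if (scores[[a]] < scores[[b]]) {
      a
    } else if (scores[[b]] < scores[[a]]) {
      b
    } else {
      max(a, b) # tie: drop the lexicographically larger id
    }
    dropped <- c(dropped, loser)
    if (length(tree$tip.label) == 2) {
      winner <- setdiff(c(a, b), loser)
      tree <- single_tip_tree(winner, sum(tree$edge.length))
    } else {
      tree <- ape::drop.tip(tree, loser)
    }
  }
  structure(
    list(
      tree = tree,
      retained = tree$tip.label,
      dropped = dropped,
      rank = rank
    ),
    class = "caro_derep"
  )
}

#' @export
tidy.caro_derep <- function(x, ...) {
  tibble(
    seq_id = c(x$retained, x$dropped),
    status = c(
      rep("retained", length(x$retained)),
      rep("dropped", length(x$dropped))
    )
  )
}

#' @export
glance.caro_derep <- function(x, ...) {
  tibble(
    rank = x$rank,
    n_retained = length(x$retained),
    n_dropped = length(x$dropped)
  )
}

#' Iterative build-tree-and-dereplicate pipeline
#'
#' For each round, builds a tree from the current records with
#' `tree_builder` (default: Poisson pairwise distances + neighbor joining),
#' dereplicates it at `rank`, and subsets the records to the retained tips.
#' Small families, where one pass already removes all redundancy, can set
#' `rounds = 1`;
#' `rounds = 0` is the identity. A round that would start with fewer than 3
#' records is skipped with a warning.
#'
#' @param seqs Aligned record tibble (ids are the future tips).
#' @param taxonomy Taxonomy tibble covering all ids.
#' @param scores Named numeric vector or tibble (`seq_id`, `bit_score`).
#' @param rank Rank column name.
#' @param rounds Number of rebuild-and-dereplicate rounds (default 2).
#' @param tree_builder Function `seqs -> phylo` used to build each
#'   intermediate tree.
#' @return A list: `records` (retained records), `dropped` (ids, all
#'   rounds), `trees` (the per-round intermediate trees).
#' @export
derep_pipeline <- function(seqs, taxonomy, scores, rank, rounds = 2,
                           tree_builder = NULL) {
  if (is.null(tree_builder)) {
    tree_builder <- function(s) nj_tree(pairwise_distance(s, "poisson"))
  }
  dropped <- character()
  trees <- list()
  if (rounds >= 1) {
    for (round in seq_len(rounds)) {
      if (nrow(seqs) < 3) {
        warn(sprintf(
          "dereplication round %d skipped: only %d record(s) left",
          round, nrow(seqs)
        ))
        next
      }
      tr <- tree_builder(seqs)
      res <- dereplicate_tree(tr, taxonomy, scores, rank)
      trees[[length(trees) + 1]] <- res$tree
      dropped <- c(dropped, res$dropped)
      seqs <- seqs[seqs$id %in% res$retained, , drop = FALSE]
    }
  }
  list(records = seqs, dropped = dropped, trees = trees)
}
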