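# --- undirected graph view of a phylo tree -------------------------------
# Dense matrices are fine at desk scale; supports are carried per edge so
# they stay attached to the correct bipartition across re-rooting.
tree_graph <- function(tr) {
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  if (is.null(tr$edge.length)) abort("tree has no branch lengths")
  adj <- vector("list", nn)
  len <- matrix(NA_real_, nn, nn)
  sup <- matrix(NA_real_, nn, nn)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]
    c <- tr$edge[k, 2]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
    len[p, c] <- len[c, p] <- tr$edge.length[k]
    if (c > ntip && !is.null(tr$node.label)) {
      s <- normalise_support(tr$node.label)[c - ntip]
      sup[p, c] <- sup[c, p] <- s
    }
  }
  list(ntip = ntip, n = nn, adj = adj, len = len, sup = sup, tips = tr$tip.label)
}

# single-source distances + predecessors over the tree graph
graph_dist <- function(g, from) {
  dist <- rep(NA_real_, g$n)
  pred <- rep(NA_integer_, g$n)
  dist[from] <- 0
  stack <- from
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in g$adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + g$len[v, w]
        pred[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  list(dist = dist, pred = pred)
}

fmt_len <- function(x) sprintf("%.15g", x)
fmt_sup <- function(x) if (is.na(x)) "" else sprintf("%.10g", x)

# rooted newick of the subtree at v, entered from parent p (label = support
# of the edge p-v, length appended by the caller)
graph_subtree_newick <- function(g, v, p) {
  nb <- setdiff(g$adj[[v]], p)
  if (length(nb) == 0) {
    return(g$tips[v])
  }
  inner <- vapply(nb, function(w) {
    paste0(graph_subtree_newick(g, w, v), ":", fmt_len(g$len[v, w]))
  }, character(1))
  paste0("(", paste(inner, collapse = ","), ")", fmt_sup(g$sup[p, v]))
}

root_graph_at_node <- function(g, k) {
  inner <- vapply(g$adj[[k]], function(w) {
    paste0(graph_subtree_newick(g, w, k), ":", fmt_len(g$len[k, w]))
  }, character(1))
  read_newick(paste0("(", paste(inner, collapse = ","), ");"))
}

root_graph_on_edge <- function(g, u, v, x_from_u) {
  left <- paste0(graph_subtree_newick(g, u, v), ":", fmt_len(x_from_u))
  right <- paste0(
    graph_subtree_newick(g, v, u), ":",
    fmt_len(g$len[u, v] - x_from_u)
  )
  read_newick(paste0("(", left, ",", right, ");"))
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path. If the
#' midpoint falls exactly on an existing node the tree is rooted there;
#' ties between equally longest paths are broken by the lexicographically
#' smallest tip pair. Edge supports travel with their bipartition: when the
#' root splits an edge, both root-adjacent edges inherit that edge's support.
#'
#' @param tree A `phylo` tree (rooted or unrooted) with finite, non-negative
#'   branch lengths; at least one branch must be positive.
#' @return A rooted `phylo` tree.
#' @examples
#' midpoint_root(read_newick("(A:3,B:0);")) # root 1.5 from each tip
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) abort("midpoint rooting needs at least 2 tips")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("midpoint rooting needs finite branch lengths")
  }
  if (any(tree$edge.length < 0)) abort("branch lengths must be non-negative")
  if (all(tree$edge.length == 0)) {
    abort("all branch lengths are zero: midpoint undefined")
  }
  if (ntip == 2) {
    # degree-2 nodes between the two tips are suppressed by construction
    tips <- sort(tree$tip.label)
    total <- sum(tree$edge.length)
    return(read_newick(sprintf(
      "(%s:%s,%s:%s);",
      tips[1], fmt_len(total / 2), tips[2], fmt_len(total / 2)
    )))
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  g <- tree_graph(tree)

  # longest tip-to-tip path, ties by lexicographically smallest tip pair
  tip_ids <- seq_len(g$ntip)
  dd <- lapply(tip_ids, function(t) graph_dist(g, t))
  best <- NULL
  for (i in tip_ids) {
    for (j in tip_ids) {
      if (i >= j) next
      dij <- dd[[i]]$dist[j]
      key <- sort(c(g$tips[i], g$tips[j]))
      if (is.null(best) || dij > best$d + 1e-15 ||
        (abs(dij - best$d) <= 1e-15 &&
          (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(d = dij, i = i, j = j, key = key)
      }
    }
  }
  # walk from the lexicographically smaller endpoint
  a <- if (g$tips[best$i] <= g$tips[best$j]) best$i else best$j
  b <- if (a == best$i) best$j else best$i
  pred <- dd[[a]]$pred
  path <- b
  while (path[1] != a) path <- c(pred[path[1]], path)

  half <- best$d / 2
  tol <- 1e-12 * max(1, best$d)
  cum <- 0
  for (s in seq_len(length(path) - 1)) {
    u <- path[s]
    v <- path[s + 1]
    step <- g$len[u, v]
    if (abs(cum - half) <= tol) {
      return(root_graph_at_node(g, u))
    }
    if (cum + step > half + tol) {
      return(root_graph_on_edge(g, u, v, half - cum))
    }
    cum <- cum + step
  }
  root_graph_at_node(g, path[length(path)])
}
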