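#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining with the standard Q criterion. The agglomeration
#' is fully deterministic: input labels are canonicalised to sorted order
#' before the loop, and ties in Q are broken by the lexicographically smallest
#' pair of cluster representative labels (a cluster is represented by its
#' smallest tip label). Negative estimated branch lengths are clamped to zero;
#' the total clamped deficit is attached as the attribute
#' `negative_length_deficit`. On an additive matrix the generating topology
#' and branch lengths are recovered exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and unique
#'   row/column labels (at least 3).
#' @return An unrooted `phylo` tree.
#' @examples
#' d <- matrix(
#'   c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || !is.numeric(d)) abort("d must be a numeric matrix")
  labels <- rownames(d)
  if (is.null(labels) || is.null(colnames(d)) || !identical(labels, colnames(d))) {
    abort("d must carry identical, non-NULL row and column labels")
  }
  if (anyDuplicated(labels)) abort("distance matrix labels must be unique")
  if (any(!is.finite(d))) abort("distance matrix must be finite")
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal must be zero")
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 labels")

  ord <- order(labels, method = "radix")
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]

  frag <- labels # newick fragment per active cluster
  rep_lab <- labels # representative (smallest tip) label per cluster
  D <- d
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      deficit <<- deficit + (-x)
      0
    } else {
      x
    }
  }

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest representative pair
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys, method = "radix")[1], ]
    i <- pick[1]
    j <- pick[2]

    bi <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    bj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))))
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], bi, frag[j], bj)
    new_rep <- min(rep_lab[i], rep_lab[j])

    others <- setdiff(seq_len(r), c(i, j))
    new_d <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, new_d), c(new_d, 0))
    frag <- c(frag[others], new_frag)
    rep_lab <- c(rep_lab[others], new_rep)
  }

  # final three clusters: closed-form three-point branch lengths
  ba <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  bb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  bc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf(
    "(%s:%.15g,%s:%.15g,%s:%.15g);",
    frag[1], ba, frag[2], bb, frag[3], bc
  )
  tr <- ape::read.tree(text = txt)
  attr(tr, "negative_length_deficit") <- deficit
  tr
}
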