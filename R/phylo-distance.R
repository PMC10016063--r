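#' Pairwise distances from a protein alignment
#'
#' Computes pairwise distances under pairwise deletion: for each pair of
#' records, only columns where neither sequence has a gap are compared.
#' The `p` model returns the mismatch proportion; the `poisson` model the
#' Poisson correction `-ln(1 - p)`. Saturated pairs (`p = 1`) are capped at
#' `-ln(1 - 0.999)` so the matrix stays finite.
#'
#' @param seqs Alignment tibble (equal-length `residues`).
#' @param model `"p"` (proportion of differing sites) or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by `id`.
#' @examples
#' aln <- tibble::tibble(
#'   id = c("s1", "s2"), description = "",
#'   residues = c("AAAA", "AAAT")
#' )
#' pairwise_distance(aln, "p") # 0.25
#' @export
pairwise_distance <- function(seqs, model = c("p", "poisson")) {
  model <- match.arg(model)
  validate_seqs(seqs, aligned = TRUE)
  distance_from_matrix(aln_matrix(seqs), model)
}

# internal workhorse on a character matrix (used per bootstrap replicate)
distance_from_matrix <- function(m, model) {
  n <- nrow(m)
  labels <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !(gap[i, ] | gap[j, ])
      nc <- sum(comp)
      if (nc == 0) {
        abort(sprintf(
          "no comparable (gap-free in both) columns for pair %s / %s",
          labels[i], labels[j]
        ))
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d[i, j] <- d[j, i] <- if (model == "p") {
        p
      } else {
        -log(1 - min(p, 0.999))
      }
    }
  }
  d
}
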