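#' Default fusion-architecture registry
#'
#' Maps ordered (N- to C-terminal) domain tuples to named fusion patterns:
#' the trifunctional CrtI+CrtB+CrtYc/d protein of thraustochytrids, the
#' quadrifunctional variant with a C-terminal Blh oxygenase domain, the two
#' bifunctional CrtB/CrtI + CrtYc/d patterns, and single-domain proteins.
#' Anything else classifies as `"other"`.
#'
#' @return Tibble with columns `architecture` (a `+`-joined ordered tuple)
#'   and `label`.
#' @export
architecture_registry <- function() {
  tibble(
    architecture = c(
      "CrtI+CrtB+CrtYc/d",
      "CrtI+CrtB+CrtYc/d+Blh",
      "CrtB+CrtYc/d",
      "CrtI+CrtYc/d"
    ),
    label = c(
      "trifunctional_CrtIBY",
      "quadrifunctional_CrtIBY_Blh",
      "bifunctional_CrtB_CrtYcd",
      "bifunctional_CrtI_CrtYcd"
    )
  )
}

overlap_len <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2) + 1)
}

#' Resolve overlapping domain hits on one protein
#'
#' Greedy selection by descending bit score (ties: smaller `env_start`
#' first): a hit is kept iff its envelope overlaps every already-kept hit by
#' at most `max_overlap_fraction` of the shorter of the two envelopes.
#' Output is sorted by `env_start`.
#'
#' @param hits Hit tibble, all rows sharing one `seq_id`.
#' @param max_overlap_fraction Tolerated overlap as a fraction of the
#'   shorter envelope, in `[0, 1)` (default 0.2).
#' @return The retained hits, sorted N- to C-terminal.
#' @export
resolve_hits <- function(hits, max_overlap_fraction = 0.2) {
  if (nrow(hits) == 0) {
    return(hits)
  }
  if (length(unique(hits$seq_id)) != 1) {
    abort("resolve_hits expects hits for a single seq_id")
  }
  if (max_overlap_fraction < 0 || max_overlap_fraction >= 1) {
    abort("max_overlap_fraction must lie in [0, 1)")
  }
  ord <- order(-hits$bit_score, hits$env_start)
  hits <- hits[ord, , drop = FALSE]
  kept <- integer()
  for (k in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in kept) {
      ov <- overlap_len(
        hits$env_start[k], hits$env_end[k],
        hits$env_start[j], hits$env_end[j]
      )
      shorter <- min(
        hits$env_end[k] - hits$env_start[k] + 1,
        hits$env_end[j] - hits$env_start[j] + 1
      )
      if (ov > max_overlap_fraction * shorter) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, k)
  }
  out <- hits[kept, , drop = FALSE]
  out[order(out$env_start), , drop = FALSE]
}

#' N-to-C architecture string of resolved hits
#'
#' Joins domain names with `+` in ascending `env_start` order; an empty hit
#' set yields `"none"`. Input must already be overlap-resolved
#' (see [resolve_hits()]).
#'
#' @param hits Resolved, non-overlapping hit tibble for one protein.
#' @param max_overlap_fraction Overlap bound used to verify the
#'   precondition.
#' @return A single string such as `"CrtI+CrtB+CrtYc/d+Blh"`.
#' @export
architecture_string <- function(hits, max_overlap_fraction = 0.2) {
  if (nrow(hits) == 0) {
    return("none")
  }
  hits <- hits[order(hits$env_start), , drop = FALSE]
  if (nrow(hits) >= 2) {
    for (i in seq_len(nrow(hits) - 1)) {
      for (j in seq(i + 1, nrow(hits))) {
        ov <- overlap_len(
          hits$env_start[i], hits$env_end[i],
          hits$env_start[j], hits$env_end[j]
        )
        shorter <- min(
          hits$env_end[i] - hits$env_start[i] + 1,
          hits$env_end[j] - hits$env_start[j] + 1
        )
        if (ov > max_overlap_fraction * shorter) {
          abort("architecture_string requires overlap-resolved hits; run resolve_hits() first")
        }
      }
    }
  }
  paste(hits$domain, collapse = "+")
}

#' Classify an architecture string against a registry
#'
#' Exact ordered-tuple lookup: registry entries first, then any single
#' domain as `"single_domain_<name>"`, otherwise `"other"`.
#'
#' @param architecture Architecture string (e.g. from
#'   [architecture_string()]).
#' @param registry Registry tibble (default [architecture_registry()]).
#' @return The label string.
#' @export
classify_architecture <- function(architecture, registry = architecture_registry()) {
  stopifnot(is.character(architecture), length(architecture) == 1)
  hit <- registry$label[registry$architecture == architecture]
  if (length(hit) == 1) {
    return(hit)
  }
  if (architecture != "none" && !grepl("+", architecture, fixed = TRUE)) {
    return(paste0("single_domain_", architecture))
  }
  "other"
}

#' Per-protein architecture summary of a hit table
#'
#' Resolves overlaps, reads the N-to-C architecture, and classifies it for
#' every protein in a hit table.
#'
#' @param hits Hit tibble (any number of proteins).
#' @param registry Registry tibble.
#' @param max_overlap_fraction Overlap bound for [resolve_hits()].
#' @return Tibble with one row per `seq_id`: `architecture`, `label`.
#' @export
summarise_architectures <- function(hits, registry = architecture_registry(),
                                    max_overlap_fraction = 0.2) {
  ids <- sort(unique(hits$seq_id))
  arch <- vapply(ids, function(id) {
    architecture_string(
      resolve_hits(hits[hits$seq_id == id, , drop = FALSE], max_overlap_fraction),
      max_overlap_fraction
    )
  }, character(1))
  tibble(
    seq_id = ids,
    architecture = unname(arch),
    label = vapply(arch, classify_architecture, character(1), registry = registry)
  )
}
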