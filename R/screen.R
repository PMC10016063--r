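#' End-to-end horizontal-transfer screen of one domain family
#'
#' Runs the whole desk-scale pipeline on one domain family of a synthetic
#' dataset: fragment merging, median +/- 1 sd length filtering, optional
#' tree-guided dereplication, neighbor-joining with bootstrap support,
#' midpoint rooting, and the scan for taxonomically disjunct eukaryote
#' clades nested in prokaryotic context.
#'
#' @param dataset A [build_dataset()] result.
#' @param domain Domain family to screen (e.g. `"CrtI"`).
#' @param rank Grouping rank for the disjunct-clade scan (default
#'   `"group"`).
#' @param n_bootstrap Bootstrap replicates (default 100).
#' @param seed Optional seed for the bootstrap resampling.
#' @param min_groups Minimum distinct rank labels for a reported clade.
#' @param min_support Minimum support for a reported clade (default 0:
#'   support is reported, not thresholded).
#' @param sd_multiplier Width of the length filter keep interval.
#' @param derep_rounds Tree-guided dereplication rounds before the final
#'   tree (default 0, matching a single-family screen; set 1-2 for large
#'   redundant families).
#' @return A list: `report` (disjunct-clade tibble), `tree` (midpoint-rooted
#'   tree with supports), `nj` (unrooted bootstrap tree), `records` (the
#'   curated family records that went into the tree).
#' @export
hgt_screen <- function(dataset, domain, rank = "group", n_bootstrap = 100,
                       seed = NULL, min_groups = 3, min_support = 0,
                       sd_multiplier = 1, derep_rounds = 0) {
  fam <- family_records(dataset, domain)
  pool <- dplyr::distinct(
    bind_rows(
      fam$records[, c("id", "description", "residues")],
      dataset$full_proteins
    ),
    .data$id,
    .keep_all = TRUE
  )
  merged <- merge_split_hits(fam$hits, pool)$records
  kept <- length_filter(merged, sd_multiplier)$kept
  if (derep_rounds > 0) {
    scores <- setNames(kept$bit_score, kept$id)
    kept <- derep_pipeline(
      kept, dataset$taxonomy, scores, rank,
      rounds = derep_rounds
    )$records
  }
  nj <- bootstrap_support(kept, "poisson", n_replicates = n_bootstrap, seed = seed)
  rooted <- midpoint_root(nj)
  report <- scan_disjunct_clades(
    rooted, dataset$taxonomy, rank,
    min_groups = min_groups, min_support = min_support
  )
  list(report = report, tree = rooted, nj = nj, records = kept)
}
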