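#' Remove length outliers around the median
#'
#' Removes every record whose length deviates from the median family length
#' by more than `sd_multiplier` sample standard deviations (n - 1
#' denominator). The boundary is inclusive-keep: a record exactly at
#' `median +/- sd_multiplier * sd` is retained. When all lengths are equal
#' the standard deviation is zero and nothing is removed.
#'
#' Re-running the rule on its own output recomputes the standard deviation
#' and may remove further records; to re-apply the original bounds, use the
#' `lower`/`upper` values in the returned report.
#'
#' @param seqs Tibble of sequence records (at least 2; the standard
#'   deviation is undefined for a single record — pass such families through
#'   unfiltered).
#' @param sd_multiplier Positive width of the keep interval in standard
#'   deviations (default 1, i.e. one standard deviation from the median).
#' @return A list with `kept` and `removed` record tibbles (their union is
#'   the input) and a one-row `report` tibble (`n`, `median`, `sd`,
#'   `lower`, `upper`, `n_removed`).
#' @examples
#' fam <- tibble::tibble(
#'   id = paste0("s", 1:5), description = "",
#'   residues = strrep("A", c(100, 100, 100, 100, 300))
#' )
#' length_filter(fam)$removed$id # "s5"
#' @export
length_filter <- function(seqs, sd_multiplier = 1) {
  validate_seqs(seqs, allow_gaps = TRUE)
  if (nrow(seqs) < 2) {
    abort("length_filter needs >= 2 records (sd undefined); pass the family through unfiltered")
  }
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0) {
    abort("sd_multiplier must be positive")
  }
  len <- seq_lengths(seqs)
  med <- median(len)
  s <- sd(len)
  lower <- med - sd_multiplier * s
  upper <- med + sd_multiplier * s
  keep <- abs(len - med) <= sd_multiplier * s
  list(
    kept = seqs[keep, , drop = FALSE],
    removed = seqs[!keep, , drop = FALSE],
    report = tibble(
      n = length(len), median = med, sd = s,
      lower = lower, upper = upper, n_removed = sum(!keep)
    )
  )
}

#' Merge split fragments back into full-length records
#'
#' Incomplete or split sequences selected by a domain search arrive as two or
#' more hit rows sharing a `parent_id` (and domain). Each such group is
#' replaced by a single record holding the full parent protein sequence and
#' the maximum bit score of the group. Hits without a `parent_id` (or alone
#' in their group) pass through with their own sequence.
#'
#' @param hits Hit tibble (`seq_id`, `domain`, `bit_score`, optional
#'   `parent_id`).
#' @param sequences Tibble of sequence records indexed by `id`, containing
#'   both the hit records themselves and the full parent sequences.
#' @return A list with `records` (tibble: `id`, `description`, `residues`,
#'   `domain`, `bit_score`) and `report` (one row per merged parent:
#'   `parent_id`, `domain`, `n_fragments`, `bit_score`).
#' @export
merge_split_hits <- function(hits, sequences) {
  validate_seqs(sequences, allow_gaps = TRUE)
  seq_of <- setNames(sequences$residues, sequences$id)
  desc_of <- setNames(
    if ("description" %in% names(sequences)) sequences$description else rep("", nrow(sequences)),
    sequences$id
  )
  has_parent <- if ("parent_id" %in% names(hits)) !is.na(hits$parent_id) else rep(FALSE, nrow(hits))

  lookup <- function(id, what) {
    if (!id %in% names(seq_of)) {
      abort(paste0(what, " '", id, "' not found in the supplied sequences"))
    }
    seq_of[[id]]
  }

  frag <- hits[has_parent, , drop = FALSE]
  solo <- hits[!has_parent, , drop = FALSE]

  merged <- tibble(
    id = character(), description = character(), residues = character(),
    domain = character(), bit_score = numeric()
  )
  report <- tibble(
    parent_id = character(), domain = character(),
    n_fragments = integer(), bit_score = numeric()
  )
  if (nrow(frag) > 0) {
    groups <- split(frag, paste(frag$parent_id, frag$domain, sep = "\r"))
    for (grp in groups) {
      if (nrow(grp) >= 2) {
        pid <- grp$parent_id[1]
        merged <- bind_rows(merged, tibble(
          id = pid,
          description = unname(desc_of[pid]) %||% "",
          residues = lookup(pid, "parent_id"),
          domain = grp$domain[1],
          bit_score = max(grp$bit_score)
        ))
        report <- bind_rows(report, tibble(
          parent_id = pid, domain = grp$domain[1],
          n_fragments = nrow(grp), bit_score = max(grp$bit_score)
        ))
      } else {
        solo <- bind_rows(solo, grp)
      }
    }
  }
  solo_records <- tibble(
    id = solo$seq_id,
    description = unname(desc_of[solo$seq_id]),
    residues = unname(vapply(solo$seq_id, lookup, character(1), what = "seq_id")),
    domain = solo$domain,
    bit_score = solo$bit_score
  )
  records <- bind_rows(solo_records, merged)
  records$description[is.na(records$description)] <- ""
  records <- arrange(records, .data$id)
  list(records = records, report = report)
}

#' Trim high-gap columns from an alignment
#'
#' A column is retained iff the fraction of sequences with a gap in it is
#' strictly less than `gap_threshold` — i.e. positions where at least
#' `gap_threshold` of sequences contain a gap are removed. The conventional
#' thresholds are 0.90 and 0.99.
#'
#' @param seqs Alignment tibble.
#' @param gap_threshold Gap fraction in `(0, 1]` at or above which a column
#'   is removed (default 0.90).
#' @return A list with `alignment` (trimmed, record order unchanged) and
#'   `kept_indices` (original 1-based column numbers, ascending).
#' @export
trim_columns <- function(seqs, gap_threshold = 0.90) {
  validate_seqs(seqs, aligned = TRUE)
  if (!is.numeric(gap_threshold) || gap_threshold <= 0 || gap_threshold > 1) {
    abort("gap_threshold must lie in (0, 1]")
  }
  m <- aln_matrix(seqs)
  gap_frac <- colSums(m == "-") / nrow(m)
  keep <- which(gap_frac < gap_threshold)
  if (length(keep) == 0) {
    abort("trimming removed every column; an empty alignment is invalid")
  }
  trimmed <- matrix_to_seqs(
    m[, keep, drop = FALSE],
    description = if ("description" %in% names(seqs)) seqs$description else NULL
  )
  list(alignment = trimmed, kept_indices = keep)
}
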