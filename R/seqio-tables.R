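read_tsv_checked <- function(path, required, kind) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s table '%s' is missing required column(s): %s",
      kind, path, paste(missing, collapse = ", ")
    ))
  }
  tab
}

#' Read a typed tab-separated table
#'
#' Umbrella reader dispatching on `kind`; see [read_taxonomy()],
#' [read_hits()], [read_scores()] and [read_spectrum()] for the schemas.
#'
#' @param path Path to a TSV file with a header row.
#' @param kind One of `"taxonomy"`, `"hits"`, `"scores"`, `"spectrum"`.
#' @return A validated tibble; unknown extra columns are preserved.
#' @export
read_table <- function(path, kind = c("taxonomy", "hits", "scores", "spectrum")) {
  kind <- match.arg(kind)
  switch(kind,
    taxonomy = read_taxonomy(path),
    hits = read_hits(path),
    scores = read_scores(path),
    spectrum = read_spectrum(path)
  )
}

#' Read a taxonomy table
#'
#' Maps each sequence id to an ordered, ranked lineage plus a cellular-domain
#' flag. Required columns: `seq_id` and `cell_domain` (one of `prokaryote`,
#' `eukaryote`, `virus`); every other column is treated as a named rank
#' (e.g. `group`, `species`), in column order from coarse to fine. Missing
#' rank labels may be encoded as the literal string `"NA"` and are read as
#' `NA`.
#'
#' @param path Path to a TSV file.
#' @return Tibble with `seq_id`, `cell_domain`, and one column per rank.
#' @export
read_taxonomy <- function(path) {
  tab <- read_tsv_checked(path, c("seq_id", "cell_domain"), "taxonomy")
  validate_taxonomy(tab)
}

validate_taxonomy <- function(tab) {
  dup <- tab$seq_id[duplicated(tab$seq_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate seq_id(s) in taxonomy: ", paste(unique(dup), collapse = ", ")))
  }
  ok <- tab$cell_domain %in% c("prokaryote", "eukaryote", "virus")
  if (!all(ok)) {
    abort(sprintf(
      "cell_domain must be prokaryote/eukaryote/virus (row %d is '%s')",
      which(!ok)[1], tab$cell_domain[which(!ok)[1]]
    ))
  }
  ranks <- setdiff(names(tab), c("seq_id", "cell_domain"))
  for (r in ranks) {
    v <- tab[[r]]
    v[v %in% "NA"] <- NA_character_
    tab[[r]] <- v
  }
  tab
}

#' Read a domain-hit table
#'
#' One row per domain match on a protein, the tabular subset of a profile
#' search's per-domain output: `seq_id`, `domain`, envelope coordinates
#' `env_start`/`env_end` (1-based, inclusive), `bit_score`, `e_value`.
#' An optional `parent_id` column marks split fragments of a full-length
#' parent protein (see [merge_split_hits()]).
#'
#' @param path Path to a TSV file.
#' @return Validated tibble of hits.
#' @export
read_hits <- function(path) {
  tab <- read_tsv_checked(
    path, c("seq_id", "domain", "env_start", "env_end", "bit_score", "e_value"),
    "hits"
  )
  validate_hits(tab)
}

validate_hits <- function(tab) {
  bad <- which(!(tab$env_start >= 1 & tab$env_start <= tab$env_end))
  if (length(bad) > 0) {
    abort(sprintf(
      "hit row %d violates 1 <= env_start <= env_end (%s: %d..%d)",
      bad[1], tab$seq_id[bad[1]], tab$env_start[bad[1]], tab$env_end[bad[1]]
    ))
  }
  if (any(!is.finite(tab$bit_score))) abort("bit_score must be finite")
  if (any(tab$e_value < 0)) abort("e_value must be non-negative")
  tab
}

#' Read a bit-score table
#'
#' Schema: `seq_id`, `bit_score`, plus optional columns (e.g. `domain`).
#'
#' @param path Path to a TSV file.
#' @return Validated tibble of scores.
#' @export
read_scores <- function(path) {
  tab <- read_tsv_checked(path, c("seq_id", "bit_score"), "scores")
  if (any(!is.finite(tab$bit_score))) abort("bit_score must be finite")
  tab
}

#' Read an absorbance spectrum
#'
#' Schema: `wavelength_nm` (strictly increasing), `absorbance` (finite).
#'
#' @param path Path to a TSV file.
#' @return Tibble of class `caro_spectrum`.
#' @export
read_spectrum <- function(path) {
  tab <- read_tsv_checked(path, c("wavelength_nm", "absorbance"), "spectrum")
  validate_spectrum(tab)
}

validate_spectrum <- function(tab) {
  if (any(diff(tab$wavelength_nm) <= 0)) {
    abort("spectrum wavelengths must be strictly increasing")
  }
  if (any(!is.finite(tab$absorbance))) abort("spectrum absorbance must be finite")
  class(tab) <- unique(c("caro_spectrum", class(tab)))
  tab
}
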