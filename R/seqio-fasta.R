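#' Read a protein FASTA file
#'
#' Reads plain or aligned protein FASTA into a tibble of sequence records.
#' The record id is the first whitespace-delimited token of the header and
#' the remainder of the header is kept losslessly as the description.
#' Residues are uppercased and validated against the 20-letter amino-acid
#' alphabet plus `X` and the gap character `-`.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, additionally require all records to have equal
#'   length (i.e. the file holds an alignment).
#' @return A tibble with columns `id`, `description`, `residues`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first record", "MKV", ">b", "MML"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # read as raw strings so residue validation (with position reporting)
  # stays in one place below
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  seqs <- tibble(
    id = id,
    description = description,
    residues = unname(toupper(as.character(set)))
  )
  validate_seqs(seqs, aligned = aligned, allow_gaps = TRUE)
  if (!aligned && any(grepl("-", seqs$residues, fixed = TRUE))) {
    abort("unaligned FASTA contains gap characters; use aligned = TRUE")
  }
  seqs
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` returns `x`
#' (id, description, residues) exactly.
#'
#' @param seqs Tibble with columns `id`, `description`, `residues`.
#' @param path Output path.
#' @param wrap_width Residues per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap_width = 60) {
  validate_seqs(seqs, allow_gaps = TRUE)
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc[is.na(desc)] <- ""
  headers <- ifelse(desc == "", seqs$id, paste(seqs$id, desc))
  set <- Biostrings::AAStringSet(seqs$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = wrap_width)
  invisible(path)
}
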