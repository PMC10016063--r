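#' Plot an absorbance spectrum
#'
#' Line plot of absorbance against wavelength with the baseline-zeroing and
#' quantification wavelengths marked.
#'
#' @param spectrum Spectrum tibble.
#' @param params [pigment_params()] list (for the marked wavelengths).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, params = pigment_params()) {
  spectrum <- validate_spectrum(spectrum)
  ggplot2::ggplot(spectrum, ggplot2::aes(.data$wavelength_nm, .data$absorbance)) +
    ggplot2::geom_line(colour = "darkorange3") +
    ggplot2::geom_vline(
      xintercept = c(params$read_wavelength, params$zero_wavelength),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance") +
    ggplot2::theme_minimal()
}

#' Plot N-to-C domain organisation diagrams
#'
#' Draws each protein as a horizontal line with its resolved domain
#' envelopes as coloured segments, N- to C-terminus — the usual way fusion
#' architectures (trifunctional CrtI+CrtB+CrtYc/d and relatives) are
#' displayed.
#'
#' @param hits Hit tibble covering one or more proteins.
#' @param max_overlap_fraction Overlap bound passed to [resolve_hits()].
#' @return A ggplot object.
#' @export
plot_architectures <- function(hits, max_overlap_fraction = 0.2) {
  resolved <- bind_rows(lapply(
    split(hits, hits$seq_id),
    resolve_hits,
    max_overlap_fraction = max_overlap_fraction
  ))
  ggplot2::ggplot(resolved) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$env_start, xend = .data$env_end,
        y = .data$seq_id, yend = .data$seq_id,
        colour = .data$domain
      ),
      linewidth = 4
    ) +
    ggplot2::labs(x = "residue position", y = NULL, colour = "domain") +
    ggplot2::theme_minimal()
}
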