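#' Constants for beta-carotene quantification in acetone
#'
#' Defaults: molar extinction coefficient 134,000 L mol^-1 cm^-1 (acetone),
#' molar mass 536.88 g/mol, baseline zeroing at 600 nm, absorbance read at
#' 454 nm, 1 cm cuvette path length.
#'
#' @param epsilon Extinction coefficient (L mol^-1 cm^-1).
#' @param molar_mass Molar mass (g/mol).
#' @param zero_wavelength Baseline wavelength (nm).
#' @param read_wavelength Quantification wavelength (nm).
#' @param path_length_cm Cuvette path length (cm).
#' @return A named list of parameters.
#' @export
pigment_params <- function(epsilon = 134000, molar_mass = 536.88,
                           zero_wavelength = 600, read_wavelength = 454,
                           path_length_cm = 1.0) {
  p <- list(
    epsilon = epsilon, molar_mass = molar_mass,
    zero_wavelength = zero_wavelength, read_wavelength = read_wavelength,
    path_length_cm = path_length_cm
  )
  if (any(unlist(p) <= 0)) abort("all pigment parameters must be positive")
  p
}

# absorbance at the sampled wavelength nearest wl (must lie within 0.25 nm)
spectrum_at <- function(spectrum, wl) {
  i <- which.min(abs(spectrum$wavelength_nm - wl))
  if (abs(spectrum$wavelength_nm[i] - wl) > 0.25) {
    abort(sprintf(
      "spectrum has no sample within 0.25 nm of %g nm (range %g-%g)",
      wl, min(spectrum$wavelength_nm), max(spectrum$wavelength_nm)
    ))
  }
  spectrum$absorbance[i]
}

#' Zero a spectrum at the baseline wavelength
#'
#' Subtracts the absorbance at the sampled wavelength nearest
#' `zero_wavelength` (within 0.25 nm) from every absorbance. Idempotent.
#'
#' @param spectrum Spectrum tibble (`wavelength_nm`, `absorbance`).
#' @param params [pigment_params()] list.
#' @return The zeroed spectrum.
#' @export
zero_spectrum <- function(spectrum, params = pigment_params()) {
  spectrum <- validate_spectrum(spectrum)
  a0 <- spectrum_at(spectrum, params$zero_wavelength)
  spectrum$absorbance <- spectrum$absorbance - a0
  spectrum
}

#' Beta-carotene mass per wet biomass from an absorbance spectrum
#'
#' Beer-Lambert conversion: concentration `c = A / (epsilon * l)` from the
#' (zeroed) absorbance at the read wavelength, then
#' `mass_mg = c * V * M * 1000` and finally mg per gram of wet biomass.
#' A negative zeroed absorbance is clamped to zero with a warning
#' (measurement at or below blank).
#'
#' @param spectrum Spectrum tibble; zeroed internally unless
#'   `zeroed = TRUE`.
#' @param extract_volume_l Acetone extract volume in litres.
#' @param biomass_g Wet pellet mass in grams.
#' @param params [pigment_params()] list.
#' @param zeroed Set `TRUE` if the spectrum was already baseline-zeroed.
#' @return One-row tibble: `a_read` (zeroed absorbance at the read
#'   wavelength), `conc_mol_l`, `mass_mg`, `mg_per_g`.
#' @examples
#' s <- tibble::tibble(
#'   wavelength_nm = c(454, 600),
#'   absorbance = c(0.154, 0.02)
#' )
#' beta_carotene_mass(s, extract_volume_l = 0.001, biomass_g = 0.080)
#' @export
beta_carotene_mass <- function(spectrum, extract_volume_l, biomass_g,
                               params = pigment_params(), zeroed = FALSE) {
  if (!is.numeric(extract_volume_l) || extract_volume_l <= 0) {
    abort("extract_volume_l must be positive")
  }
  if (!is.numeric(biomass_g) || biomass_g <= 0) abort("biomass_g must be positive")
  if (!zeroed) spectrum <- zero_spectrum(spectrum, params)
  a <- spectrum_at(spectrum, params$read_wavelength)
  if (a < 0) {
    warn(sprintf("zeroed absorbance at %g nm is negative (%.4g); clamped to 0", params$read_wavelength, a))
    a <- 0
  }
  conc <- a / (params$epsilon * params$path_length_cm)
  mass_mg <- conc * extract_volume_l * params$molar_mass * 1000
  tibble(
    a_read = a,
    conc_mol_l = conc,
    mass_mg = mass_mg,
    mg_per_g = mass_mg / biomass_g
  )
}
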