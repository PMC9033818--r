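#' Build a Gaussian-peak spectral library on a regular wavelength grid
#'
#' Emulates the emission library measured from single-stained reference
#' slides on a multispectral system acquiring bands from `band_start_nm` to
#' `band_end_nm` every `band_step_nm` (the default grid, 440-720 nm in 20 nm
#' steps, gives 15 bands). Each fluorophore endmember is a Gaussian emission
#' curve normalised to unit peak; tissue autofluorescence is modelled as one
#' broad additional spectrum.
#'
#' @param band_start_nm,band_end_nm,band_step_nm band grid in nm;
#'   `band_step_nm` must divide the range exactly.
#' @param peak_positions named numeric vector of emission maxima (nm), one
#'   per fluorophore; names must be unique. Defaults cover DAPI and the four
#'   Opal dyes used for NDUFB8/MTCO1/TOMM20/pan-cytokeratin.
#' @param width_nm Gaussian SD of each emission curve (nm).
#' @param af_peak_nm,af_width_nm centre and SD of the broad
#'   autofluorescence spectrum.
#' @return An object of class `spectral_library`: a list with
#'   `wavelengths` (length B), `endmembers` (B x F matrix, unit peak per
#'   column) and `autofluorescence` (length B, unit peak).
#' @examples
#' lib <- make_spectral_library()
#' length(lib$wavelengths)   # 15
#' @export
make_spectral_library <- function(band_start_nm = 440, band_end_nm = 720,
                                  band_step_nm = 20,
                                  peak_positions = c(DAPI = 460,
                                                     Opal520 = 520,
                                                     Opal570 = 570,
                                                     Opal620 = 620,
                                                     Opal690 = 690),
                                  width_nm = 25,
                                  af_peak_nm = 500, af_width_nm = 90) {
  if (band_start_nm >= band_end_nm)
    stop("band_start_nm must be below band_end_nm")
  rng <- band_end_nm - band_start_nm
  if (abs(rng / band_step_nm - round(rng / band_step_nm)) > 1e-9)
    stop("band_step_nm does not divide the spectral range")
  nm <- names(peak_positions)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("peak_positions must have unique non-empty fluorophore names")
  if (any(peak_positions < band_start_nm | peak_positions > band_end_nm))
    stop("all emission peaks must lie within the band range")
  if (width_nm <= 0 || af_width_nm <= 0) stop("spectral widths must be > 0")

  wl <- seq(band_start_nm, band_end_nm, by = band_step_nm)
  gauss <- function(mu, sdv) {
    v <- exp(-0.5 * ((wl - mu) / sdv)^2)
    v / max(v)
  }
  em <- vapply(peak_positions, gauss, numeric(length(wl)), sdv = width_nm)
  lib <- list(wavelengths = wl,
              endmembers = em,
              autofluorescence = gauss(af_peak_nm, af_width_nm))
  class(lib) <- "spectral_library"
  validate_spectral_library(lib)
  lib
}

validate_spectral_library <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  B <- length(lib$wavelengths)
  if (B < 2 || any(diff(lib$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing, length >= 2")
  if (nrow(lib$endmembers) != B || length(lib$autofluorescence) != B)
    stop("all spectra must match the wavelength grid")
  if (any(lib$endmembers < 0) || any(lib$autofluorescence < 0))
    stop("spectra must be nonnegative")
  peaks <- apply(lib$endmembers, 2, max)
  if (any(abs(peaks - 1) > 1e-9))
    stop("endmembers must be unit-peak normalised")
  invisible(lib)
}

#' Cosine similarity between two spectra
#' @param a,b numeric vectors on the same grid.
#' @return A scalar in `[0, 1]` for nonnegative spectra.
#' @export
spectral_cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Read / write a spectral library as YAML
#' @param lib a `spectral_library`.
#' @param path file path.
#' @return `read_spectral_library` returns a `spectral_library`;
#'   `write_spectral_library` returns `path` invisibly.
#' @export
write_spectral_library <- function(lib, path) {
  validate_spectral_library(lib)
  yaml::write_yaml(list(
    wavelengths = lib$wavelengths,
    endmembers = stats::setNames(
      lapply(seq_len(ncol(lib$endmembers)),
             function(j) unname(lib$endmembers[, j])),
      colnames(lib$endmembers)),
    autofluorescence = unname(lib$autofluorescence)), path, precision = 15)
  invisible(path)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(path) {
  raw <- yaml::read_yaml(path)
  em <- do.call(cbind, lapply(raw$endmembers, as.numeric))
  colnames(em) <- names(raw$endmembers)
  lib <- list(wavelengths = as.numeric(raw$wavelengths),
              endmembers = em,
              autofluorescence = as.numeric(raw$autofluorescence))
  class(lib) <- "spectral_library"
  validate_spectral_library(lib)
  lib
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("Spectral library: %d bands (%g-%g nm), fluorophores: %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              paste(colnames(x$endmembers), collapse = ", ")))
  invisible(x)
}
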