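# Spectral library estimation from single-stain references and per-pixel
# linear unmixing by non-negative least squares.

cube_array <- function(cube) {
  if (inherits(cube, "tissue_cube")) cube$cube else cube
}
cube_wavelengths <- function(cube) {
  if (inherits(cube, "tissue_cube")) cube$wavelengths
  else attr(cube, "wavelengths")
}

#' Estimate a spectral library from single-stain reference cubes
#'
#' Per fluorophore, the mean spectrum of the brightest `bright_fraction` of
#' pixels (by total intensity across bands) is taken from its single-stain
#' cube; the autofluorescence reference spectrum — the mean spectrum over
#' all pixels of the unstained autofluorescence cube — is subtracted,
#' negatives are clipped to zero, and the result is normalised to unit
#' peak. The autofluorescence entry of the returned library is the
#' (unnormalised) autofluorescence mean spectrum itself.
#'
#' @param singleplex_cubes named list of cubes (arrays or `tissue_cube`s),
#'   one per fluorophore; all cubes must share one wavelength grid.
#' @param autofluorescence_cube cube of the unstained slide.
#' @param bright_fraction fraction of brightest pixels used, in `(0, 0.5]`.
#' @return A `spectral_library`.
#' @export
build_library_from_singleplex <- function(singleplex_cubes,
                                          autofluorescence_cube,
                                          bright_fraction = 0.02) {
  if (is.null(names(singleplex_cubes)) || any(names(singleplex_cubes) == ""))
    stop("singleplex_cubes must be a named list")
  if (bright_fraction <= 0 || bright_fraction > 0.5)
    stop("bright_fraction must be in (0, 0.5]")
  wl <- cube_wavelengths(singleplex_cubes[[1]])
  if (is.null(wl)) stop("cubes must carry a wavelength grid")
  for (cb in c(singleplex_cubes, list(autofluorescence_cube))) {
    w <- cube_wavelengths(cb)
    if (is.null(w) || length(w) != length(wl) || any(w != wl))
      stop("all cubes must share one wavelength grid")
  }
  af_arr <- cube_array(autofluorescence_cube)
  B <- dim(af_arr)[3]
  af_ref <- apply(af_arr, 3, mean)

  em <- vapply(names(singleplex_cubes), function(f) {
    arr <- cube_array(singleplex_cubes[[f]])
    if (max(arr) <= 0) stop("no signal in singleplex cube '", f, "'")
    total <- apply(arr, c(1, 2), sum)
    thr <- quantile(total, 1 - bright_fraction, names = FALSE)
    sel <- total >= thr
    spec <- vapply(seq_len(B), function(b) mean(arr[, , b][sel]), 0)
    spec <- pmax(spec - af_ref, 0)
    if (max(spec) <= 0)
      stop("no signal in singleplex cube '", f,
           "' after autofluorescence subtraction")
    spec / max(spec)
  }, numeric(B))

  lib <- list(wavelengths = wl, endmembers = em, autofluorescence = af_ref)
  class(lib) <- "spectral_library"
  B <- length(wl)
  if (nrow(em) != B) stop("internal: spectrum/grid mismatch")
  lib
}

#' Linearly unmix a multispectral cube against a spectral library
#'
#' Solves, per pixel, a nonnegativity-constrained least-squares fit of the
#' observed spectrum against all fluorophore endmembers plus the
#' autofluorescence spectrum (Lawson-Hanson active set). Autofluorescence
#' is estimated jointly — this is how its contribution is removed — but its
#' abundance plane is flagged non-marker and excluded from downstream
#' quantification. The per-pixel residual norm is retained as a QC plane.
#'
#' @param cube H x W x B array or `tissue_cube`; band grid must equal the
#'   library grid.
#' @param library a `spectral_library` with linearly independent
#'   endmembers.
#' @return An object of class `component_images`: list with `planes` (named
#'   list of H x W nonnegative abundance matrices, one per fluorophore plus
#'   `"autofluorescence"`), `residual` (H x W), `markers` (names of the
#'   marker planes) and `wavelengths`.
#' @export
unmix_cube <- function(cube, library) {
  validate_spectral_library(library)
  arr <- cube_array(cube)
  wl <- cube_wavelengths(cube)
  if (!is.null(wl) &&
      (length(wl) != length(library$wavelengths) ||
       any(wl != library$wavelengths)))
    stop("cube band grid does not match the library grid")
  if (dim(arr)[3] != length(library$wavelengths))
    stop("cube has ", dim(arr)[3], " bands but the library has ",
         length(library$wavelengths))

  S <- cbind(library$endmembers,
             autofluorescence = library$autofluorescence)
  if (qr(S)$rank < ncol(S)) {
    cs <- abs(stats::cor(S))
    diag(cs) <- 0
    worst <- which(cs == max(cs), arr.ind = TRUE)[1, ]
    stop(sprintf("library is rank deficient; '%s' and '%s' are collinear",
                 colnames(S)[worst[1]], colnames(S)[worst[2]]))
  }
  H <- dim(arr)[1]; W <- dim(arr)[2]
  Y <- matrix(arr, H * W, dim(arr)[3])
  fit <- .nnls_batch_cpp(S, Y)
  planes <- lapply(seq_len(ncol(S)),
                   function(j) matrix(fit$coef[, j], H, W))
  names(planes) <- colnames(S)
  out <- list(planes = planes,
              residual = matrix(fit$resid, H, W),
              markers = colnames(library$endmembers),
              wavelengths = library$wavelengths)
  class(out) <- "component_images"
  out
}

#' @export
print.component_images <- function(x, ...) {
  cat(sprintf("Component images: %s (+ autofluorescence), %dx%d px\n",
              paste(x$markers, collapse = ", "),
              nrow(x$residual), ncol(x$residual)))
  invisible(x)
}
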