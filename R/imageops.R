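# Small self-contained image operations used by the segmenter. Heavy parts
# (distance transform, flooding) are compiled; see src/imageops.cpp.

# separable Gaussian blur with replicated edges
blur_gaussian <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-k, k), sd = sigma)
  w <- w / sum(w)
  H <- nrow(mat); W <- ncol(mat)
  out <- matrix(0, H, W)
  for (o in seq(-k, k)) {                       # vertical pass
    rows <- pmin(pmax(seq_len(H) + o, 1L), H)
    out <- out + w[o + k + 1L] * mat[rows, , drop = FALSE]
  }
  out2 <- matrix(0, H, W)
  for (o in seq(-k, k)) {                       # horizontal pass
    cols <- pmin(pmax(seq_len(W) + o, 1L), W)
    out2 <- out2 + w[o + k + 1L] * out[, cols, drop = FALSE]
  }
  out2
}

#' Otsu threshold of a numeric sample
#'
#' Maximises between-class variance over a histogram split; used for
#' automatic DAPI foreground and cytokeratin bimodality thresholds.
#'
#' @param x numeric vector.
#' @param nbins histogram bins.
#' @return Scalar threshold; values strictly above it form the upper class.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[nbins]
  between <- (mu_tot * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # the criterion plateaus across empty gaps; cut mid-plateau
  best <- which(between >= max(between) * (1 - 1e-12))
  mean(mids[best])
}

# exact Euclidean distance (to background) of a logical foreground mask
distance_transform <- function(fg) {
  .edt_cpp(fg)
}

# 4- or 8-connected component labelling of a logical mask
label_components <- function(fg, connectivity = 4L) {
  .label_components_cpp(fg, as.integer(connectivity))
}

# local maxima (within a (2w+1)^2 window) of a height map, grouped into
# 8-connected marker labels
find_markers <- function(height, mask, window = 2L) {
  H <- nrow(height); W <- ncol(height)
  is_max <- mask
  for (oy in seq(-window, window)) {
    for (ox in seq(-window, window)) {
      if (oy == 0 && ox == 0) next
      rows <- pmin(pmax(seq_len(H) + oy, 1L), H)
      cols <- pmin(pmax(seq_len(W) + ox, 1L), W)
      is_max <- is_max & (height >= height[rows, cols, drop = FALSE])
    }
  }
  label_components(is_max & mask & height > 0, connectivity = 8L)
}
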