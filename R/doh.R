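# Scale-space determinant-of-Hessian blob detection.
#
# Coordinate convention: pixels are matrix cells frame[row, col] with 0-based
# image coordinates x = col - 1 (rightward), y = row - 1 (downward); pixel
# centers at integers. Angles are degrees counter-clockwise from +x, taken
# modulo 180 for orientations.

# 1-D Gaussian (order 0/1/2 derivative) kernel sampled at integer offsets.
# Order-2 kernels are recentered to zero sum so a constant image responds 0.
gaussKernel <- function(s, order = 0, radius = NULL) {
  if (is.null(radius)) radius <- max(2L, as.integer(ceiling(3 * s)))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * s^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) return(-x / s^2 * g)
  k <- (x^2 / s^4 - 1 / s^2) * g
  k - mean(k)
}

# Gaussian second-derivative images and their combinations at one scale.
dohParts <- function(frame, s) {
  g0 <- gaussKernel(s, 0); g1 <- gaussKernel(s, 1); g2 <- gaussKernel(s, 2)
  lxx <- .sepConvolve(frame, g2, g0)
  lyy <- .sepConvolve(frame, g0, g2)
  lxy <- .sepConvolve(frame, g1, g1)
  list(det = (s^2 * lxx) * (s^2 * lyy) - (s^2 * lxy)^2,
       trace = s^2 * (lxx + lyy))
}

#' Scale-normalized determinant-of-Hessian response
#'
#' Convolves the frame with Gaussian second-derivative kernels at scale `s`
#' and returns the determinant of the scale-normalized Hessian,
#' `(s^2 Lxx)(s^2 Lyy) - (s^2 Lxy)^2`. Dark blobs of radius roughly
#' `sqrt(2) * s` produce positive response peaks with positive Laplacian.
#' Boundaries are handled by reflective padding.
#'
#' @param frame numeric matrix of gray values in `[0, 255]`.
#' @param s scale (px), the standard deviation of the Gaussian kernels.
#' @return numeric matrix of the same shape as `frame`.
#' @export
dohResponse <- function(frame, s) {
  checkFrame(frame)
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s <= 0)
    stop("scale s must be a single positive number")
  dohParts(frame, s)$det
}

#' Detect scale-space minima of the head-polarity response
#'
#' Builds the determinant-of-Hessian scale stack over `params@scaleGrid`,
#' restricts it to dark-blob polarity (positive determinant and positive
#' Laplacian, as for a local intensity minimum), negates it, and keeps the
#' strict minima over the full 26-neighborhood in (x, y, scale). Each
#' discrete minimum is refined to sub-grid accuracy by a local quadratic fit
#' of the lattice values, with offsets clamped to half a grid step. Minima
#' within `2 s` of the image border are discarded.
#'
#' @param frame numeric matrix of gray values.
#' @param params a [DetectionParams-class] object.
#' @return data.frame with columns `x`, `y` (sub-pixel, 0-based), `s`
#'   (refined scale, px), `dohValue` (negated normalized response; negative
#'   for every retained point) and `level` (index into the scale grid).
#' @export
detectScaleSpaceMinima <- function(frame, params = detectionParams()) {
  checkFrame(frame)
  grid <- params@scaleGrid
  nr <- nrow(frame); nc <- ncol(frame); ns <- length(grid)
  cube <- array(Inf, dim = c(nr, nc, ns))
  for (l in seq_len(ns)) {
    parts <- dohParts(frame, grid[l])
    cube[, , l] <- .polarityResponse(parts$det, parts$trace)
  }
  margins <- as.integer(ceiling(2 * grid))
  hits <- .stackMinima(as.numeric(cube), dim(cube), margins)
  if (nrow(hits) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), s = numeric(0),
                      dohValue = numeric(0), level = integer(0)))
  ref <- .refineMinima(as.numeric(cube), dim(cube), hits)
  # suppress numerical dust: strict minima whose response magnitude is at
  # the floating-point noise floor are not blobs
  keep <- abs(ref[, 4]) > 1e-9
  hits <- hits[keep, , drop = FALSE]
  ref <- ref[keep, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), s = numeric(0),
                      dohValue = numeric(0), level = integer(0)))
  # apply the scale offset in log-scale using the local grid ratio
  l <- hits[, 3]
  up <- ifelse(l < ns, grid[pmin(l + 1, ns)] / grid[l], grid[l] / grid[pmax(l - 1, 1)])
  dn <- ifelse(l > 1, grid[l] / grid[pmax(l - 1, 1)], grid[pmin(l + 1, ns)] / grid[l])
  s <- grid[l] * ifelse(ref[, 3] >= 0, up, dn)^ref[, 3]
  data.frame(x = (hits[, 2] - 1) + ref[, 1], y = (hits[, 1] - 1) + ref[, 2],
             s = s, dohValue = ref[, 4], level = l)
}
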