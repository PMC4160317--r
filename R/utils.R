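#' @useDynLib ShoalTrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Minimal circular difference between two orientations, modulo `period` degrees.
angleDiff <- function(a, b, period = 180) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Validate a grayscale frame: finite values in [0, 255], at least 32x32.
checkFrame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a numeric matrix of gray values")
  if (nrow(frame) < 32 || ncol(frame) < 32)
    stop("frame must be at least 32x32 pixels")
  if (any(!is.finite(frame)) || any(frame < 0) || any(frame > 255))
    stop("frame pixel values must be finite and within [0, 255]")
  invisible(frame)
}

# deterministic sub-seed derivation, kept below 2^31
subSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629
}
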