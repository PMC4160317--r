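#' @import methods
NULL

#' Detection parameters
#'
#' Parameters of the scale-space head detector: the determinant-of-Hessian
#' scale grid, the admissible head-width band, the contrast adjustment
#' parameter and the angle-constraint threshold.
#'
#' @slot scaleGrid strictly increasing vector of scales (px).
#' @slot wMin,wMax admissible fitted head width band (px); the defaults,
#'   16--24 px, suit heads of typical laboratory zebrafish imaged top-view.
#' @slot k contrast adjustment parameter: a candidate is an effective head
#'   region iff its local contrast is at least `k` (dimensionless).
#' @slot angleSep angle-constraint threshold (degrees): same-region candidate
#'   pairs closer in orientation than this are duplicate detections.
#' @slot minArea minimum segmented-region area kept by the Otsu labeling (px^2).
#' @export
setClass("DetectionParams",
  representation(scaleGrid = "numeric", wMin = "numeric", wMax = "numeric",
                 k = "numeric", angleSep = "numeric", minArea = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@scaleGrid) < 3) msg <- c(msg, "scaleGrid needs >= 3 scales")
    if (any(diff(object@scaleGrid) <= 0)) msg <- c(msg, "scaleGrid must be strictly increasing")
    if (any(object@scaleGrid <= 0)) msg <- c(msg, "scales must be positive")
    if (object@wMin >= object@wMax) msg <- c(msg, "wMin must be < wMax")
    if (object@k <= 0) msg <- c(msg, "k must be > 0")
    if (object@angleSep <= 0) msg <- c(msg, "angleSep must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn DetectionParams-class Constructor. The default scale grid is
#'   geometric with ratio 1.26, spanning `[wMin/4, wMax/1.5]`, which brackets
#'   the determinant-of-Hessian response peaks of heads in the width band.
#' @param wMin,wMax,k,angleSep,scaleGrid,minArea see slots; `NULL` picks defaults.
#' @export
detectionParams <- function(wMin = 16, wMax = 24, k = 0.03, angleSep = 30,
                            scaleGrid = NULL, minArea = NULL) {
  if (is.null(scaleGrid)) {
    sMin <- wMin / 4; sMax <- wMax / 1.5
    n <- ceiling(log(sMax / sMin) / log(1.26))
    scaleGrid <- sMin * 1.26^(0:n)
    scaleGrid[length(scaleGrid)] <- sMax
  }
  if (is.null(minArea)) minArea <- pi * wMin^2 / 8
  new("DetectionParams", scaleGrid = as.numeric(scaleGrid), wMin = wMin,
      wMax = wMax, k = k, angleSep = angleSep, minArea = minArea)
}

#' Tracking parameters
#'
#' Constant-velocity Kalman filter noise scales, cascade feature-matching
#' thresholds and the matching-region active-contour settings.
#'
#' @slot dt sampling interval between frames (frames; 1).
#' @slot q process noise scale (px^2): Q = q * diag(1/4, 1/4, 1, 1).
#' @slot r observation noise scale (px^2): R = r * I.
#' @slot p0 initial state covariance scale: P0 = p0 * I.
#' @slot tauW width-match threshold (px).
#' @slot tauA area-match threshold (px^2, symmetric difference after alignment).
#' @slot tauG grayscale-match threshold (1 - histogram intersection).
#' @slot gateRadius Kalman association gate (px); `NA` selects the adaptive
#'   gate 3 * sqrt(trace of predicted positional covariance) + mean head length.
#' @slot acIters iteration cap of the matching-region active contour.
#' @slot acSmooth smoothing weight of the active contour (dimensionless).
#' @export
setClass("TrackingParams",
  representation(dt = "numeric", q = "numeric", r = "numeric", p0 = "numeric",
                 tauW = "numeric", tauA = "numeric", tauG = "numeric",
                 gateRadius = "numeric", acIters = "numeric", acSmooth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@tauW <= 0 || object@tauA <= 0 || object@tauG <= 0)
      msg <- c(msg, "matching thresholds must be > 0")
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (object@q < 0 || object@r < 0) msg <- c(msg, "noise scales must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn TrackingParams-class Constructor with the default thresholds
#'   (width 5 px, area 50 px^2, grayscale 0.15).
#' @param dt,q,r,p0,tauW,tauA,tauG,gateRadius,acIters,acSmooth see slots.
#' @export
trackingParams <- function(dt = 1, q = 1, r = 1, p0 = 10, tauW = 5, tauA = 50,
                           tauG = 0.15, gateRadius = NA_real_, acIters = 100,
                           acSmooth = 0.1) {
  new("TrackingParams", dt = dt, q = q, r = r, p0 = p0, tauW = tauW,
      tauA = tauA, tauG = tauG, gateRadius = gateRadius,
      acIters = acIters, acSmooth = acSmooth)
}

#' Linking parameters
#'
#' Track lifecycle and trajectory-linking bounds.
#'
#' @slot T1 consecutive-miss limit (frames) before a track is closed as
#'   incomplete.
#' @slot T2 maximum time gap (frames, strict) between linkable fragments.
#' @slot D maximum distance (px, strict) between the end position of one
#'   fragment and the start position of the next.
#' @slot minTrackLen tracks shorter than this (frames) and never linked are
#'   removed as spurious.
#' @export
setClass("LinkingParams",
  representation(T1 = "numeric", T2 = "numeric", D = "numeric",
                 minTrackLen = "numeric"),
  validity = function(object) {
    if (object@T1 <= 0 || object@T2 <= 0 || object@D <= 0 || object@minTrackLen <= 0)
      "T1, T2, D and minTrackLen must all be > 0" else TRUE
  })

#' @describeIn LinkingParams-class Constructor with defaults T1 = 10 frames,
#'   T2 = 30 frames, D = 80 px, minTrackLen = 5 frames.
#' @param T1,T2,D,minTrackLen see slots.
#' @export
linkingParams <- function(T1 = 10, T2 = 30, D = 80, minTrackLen = 5) {
  new("LinkingParams", T1 = T1, T2 = T2, D = D, minTrackLen = minTrackLen)
}

#' Motion parameters of the synthetic school
#'
#' Controls the smooth-turning, burst-glide motion model of the simulated
#' fish and the square arena they swim in.
#'
#' @slot speedMean,speedSd cruise speed mean and s.d. (px/frame).
#' @slot headingReversion AR(1) coefficient of the turn-rate process in (0,1);
#'   larger values give smoother, more persistent turns.
#' @slot headingNoise s.d. of the per-frame turn-rate innovation (degrees).
#' @slot burstProb per-frame probability of a burst (speed surge).
#' @slot burstGain speed multiple added at a burst onset.
#' @slot arena side of the square arena (px).
#' @slot wallMargin distance from the wall at which headings are reflected (px).
#' @slot fps nominal frame rate (frames/s), used only to scale tail frequency.
#' @slot separation preferred inter-fish distance (px); 0 disables the
#'   separation steering used to emulate low-density, occlusion-free groups.
#' @export
setClass("MotionParams",
  representation(speedMean = "numeric", speedSd = "numeric",
                 headingReversion = "numeric", headingNoise = "numeric",
                 burstProb = "numeric", burstGain = "numeric",
                 arena = "numeric", wallMargin = "numeric", fps = "numeric",
                 separation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@speedMean < 0 || object@speedSd < 0) msg <- c(msg, "speeds must be >= 0")
    if (object@headingReversion < 0 || object@headingReversion >= 1)
      msg <- c(msg, "headingReversion must be in [0, 1)")
    if (object@arena < 64) msg <- c(msg, "arena must be >= 64 px")
    if (length(msg)) msg else TRUE
  })

#' @describeIn MotionParams-class Constructor. Defaults give cruise speeds of
#'   about 6 px/frame with occasional bursts, and per-frame heading changes
#'   within +/-45 degrees for over 99 percent of frames.
#' @param speedMean,speedSd,headingReversion,headingNoise,burstProb,burstGain
#'   see slots.
#' @param arena,wallMargin,fps,separation see slots.
#' @export
motionParams <- function(speedMean = 6, speedSd = 1.5, headingReversion = 0.7,
                         burstProb = 0.02, burstGain = 1.5, headingNoise = 6,
                         arena = 1024, wallMargin = 40, fps = 30,
                         separation = 0) {
  new("MotionParams", speedMean = speedMean, speedSd = speedSd,
      headingReversion = headingReversion, headingNoise = headingNoise,
      burstProb = burstProb, burstGain = burstGain, arena = arena,
      wallMargin = wallMargin, fps = fps, separation = separation)
}

#' Full pipeline configuration
#'
#' @slot detection a [DetectionParams-class] object.
#' @slot tracking a [TrackingParams-class] object.
#' @slot linking a [LinkingParams-class] object.
#' @slot seed integer seed governing any randomness.
#' @export
setClass("PipelineConfig",
  representation(detection = "DetectionParams", tracking = "TrackingParams",
                 linking = "LinkingParams", seed = "numeric"))

#' @describeIn PipelineConfig-class Constructor.
#' @param detection,tracking,linking,seed see slots.
#' @export
pipelineConfig <- function(detection = detectionParams(),
                           tracking = trackingParams(),
                           linking = linkingParams(), seed = 1) {
  new("PipelineConfig", detection = detection, tracking = tracking,
      linking = linking, seed = seed)
}

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams:", length(object@scaleGrid), "scales in [",
      round(min(object@scaleGrid), 2), ",", round(max(object@scaleGrid), 2),
      "] px; width band [", object@wMin, ",", object@wMax,
      "] px; k =", object@k, "; angleSep =", object@angleSep, "deg\n")
})

setMethod("show", "TrackingParams", function(object) {
  cat("TrackingParams: q =", object@q, ", r =", object@r,
      "; cascade thresholds width", object@tauW, "px, area", object@tauA,
      "px^2, grayscale", object@tauG, "\n")
})

setMethod("show", "LinkingParams", function(object) {
  cat("LinkingParams: T1 =", object@T1, "frames, T2 =", object@T2,
      "frames, D =", object@D, "px, minTrackLen =", object@minTrackLen, "\n")
})
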