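# Matching-region extraction and cascade width/area/grayscale feature
# matching.
#
# The matching region is the head-side part of the fish silhouette: a
# region-based active contour grown from the detected head ellipse gives the
# contour; the farthest contour point within +/-15 degrees of the body
# direction defines the alignment line; the cutting line through the ellipse
# center perpendicular to it bounds the region on the head side.

# Two-phase piecewise-constant active contour ("without edges") on a
# normalized image patch: alternate the optimal inside/outside means with a
# thresholding update, lightly smoothed by an 8-neighbor majority term.
# Deterministic; stops at a mask fixed point or after `iters` iterations.
activeContourMask <- function(img, init, iters = 100, smooth = 0.1) {
  im <- img / 255
  mask <- init
  nb <- function(m) {
    p <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    p[1:nrow(m), 1:ncol(m)] + p[1:nrow(m), 2:(ncol(m) + 1)] + p[1:nrow(m), 3:(ncol(m) + 2)] +
    p[2:(nrow(m) + 1), 1:ncol(m)] + p[2:(nrow(m) + 1), 3:(ncol(m) + 2)] +
    p[3:(nrow(m) + 2), 1:ncol(m)] + p[3:(nrow(m) + 2), 2:(ncol(m) + 1)] + p[3:(nrow(m) + 2), 3:(ncol(m) + 2)]
  }
  for (it in seq_len(iters)) {
    if (!any(mask) || all(mask)) break
    c1 <- mean(im[mask]); c2 <- mean(im[!mask])
    force_ <- (im - c1)^2 - (im - c2)^2 - smooth * (nb(mask) - 4) / 4
    new <- force_ < 0
    if (identical(new, mask)) break
    mask <- new
  }
  mask
}

#' Extract the matching region of a detected head
#'
#' Evolves a region-based active contour from the detected ellipse, finds the
#' farthest contour point from the ellipse center within +/-15 degrees of the
#' body direction (the outer endpoint), and cuts the silhouette with the line
#' through the center perpendicular to the center-to-outer-endpoint
#' (alignment) line. The closed region on the head side of the cut is the
#' matching region; its cutting-line width, area and gray histogram (32 bins of 8 levels)
#' are the cascade features.
#'
#' @param frame numeric matrix of gray values.
#' @param det one detection row from [detectHeads()] (fields `x`, `y`,
#'   `length`, `width`, `angle`), or any list with those fields.
#' @param params a [TrackingParams-class] (active-contour settings).
#' @param heading optional resolved heading (degrees); when given, the body
#'   direction is `heading + 180`, otherwise it is the ellipse-axis direction
#'   holding more silhouette mass.
#' @return an object of class `MatchingRegion`: list with `inner`, `outer`,
#'   `cutLine`, `alignAngle` (degrees, center toward outer endpoint),
#'   `width` (px), `area` (px^2), `hist` (sums to 1), `mask`, `origin`
#'   (absolute 0-based coordinates of `mask[1,1]`) and `contour`
#'   (n x 2 matrix of absolute x, y).
#' @export
extractMatchingRegion <- function(frame, det, params = trackingParams(),
                                  heading = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  cx <- det$x; cy <- det$y
  if (cx < 0 || cx > nc - 1 || cy < 0 || cy > nr - 1)
    stop("detection lies outside the frame")
  R0 <- ceiling(2 * det$length)
  j <- max(1, floor(cx - R0) + 1):min(nc, ceiling(cx + R0) + 1)
  i <- max(1, floor(cy - R0) + 1):min(nr, ceiling(cy + R0) + 1)
  patch <- frame[i, j, drop = FALSE]
  ox <- j[1] - 1; oy <- i[1] - 1          # absolute coords of patch[1,1]
  dx <- outer(rep(1, length(i)), (j - 1) - cx)
  dy <- outer((i - 1) - cy, rep(1, length(j)))
  th <- det$angle * pi / 180
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  init <- (u / (det$length / 2))^2 + (v / (det$width / 2))^2 <= 1
  mask <- activeContourMask(patch, init, params@acIters, params@acSmooth)
  # keep the component holding the ellipse center
  lab <- .labelComponents(mask)
  ci <- round(cy) - oy + 1; cj <- round(cx) - ox + 1
  lc <- if (ci >= 1 && ci <= nrow(lab) && cj >= 1 && cj <= ncol(lab)) lab[ci, cj] else 0
  if (lc == 0 && any(mask)) {
    w <- which(mask, arr.ind = TRUE)
    d2 <- (w[, 1] - ci)^2 + (w[, 2] - cj)^2
    lc <- lab[w[which.min(d2), , drop = FALSE]]
  }
  mask <- lab == lc & lc > 0
  # keep the contour to the head vicinity: the head is the rigid, stable
  # part, and without this clip a crossing neighbor merged into the same
  # dark region would inflate the width/area features
  mask <- mask & (dx^2 + dy^2 <= (1.25 * det$length)^2)
  if (sum(mask) < 4) {
    warning("active contour collapsed; falling back to the ellipse mask")
    mask <- init
  }
  # contour: mask pixels with a 4-neighbor outside (or at the patch edge)
  er <- mask
  er[-1, ] <- er[-1, ] & mask[-nrow(mask), ]
  er[-nrow(er), ] <- er[-nrow(er), ] & mask[-1, ]
  er[, -1] <- er[, -1] & mask[, -ncol(mask)]
  er[, -ncol(er)] <- er[, -ncol(er)] & mask[, -1]
  bnd <- which(mask & !er, arr.ind = TRUE)
  bx <- (bnd[, 2] - 1) + ox; by <- (bnd[, 1] - 1) + oy
  # body direction: resolved heading + 180, else the axis side with more mass
  bodyDir <- if (!is.null(heading)) {
    (heading + 180) %% 360
  } else {
    axial <- sum(sign(cos(th) * dx[mask] + sin(th) * dy[mask]))
    if (axial >= 0) det$angle %% 360 else (det$angle + 180) %% 360
  }
  ang <- (atan2(by - cy, bx - cx) * 180 / pi) %% 360
  distc <- sqrt((bx - cx)^2 + (by - cy)^2)
  cone <- angleDiff(ang, bodyDir, period = 360) <= 15
  kOut <- if (any(cone)) which(cone)[which.max(distc[cone])] else which.max(distc)
  outer_ <- c(bx[kOut], by[kOut])
  # the alignment direction is anchored on the rigid ellipse axis (the
  # center-to-outer-endpoint direction lies within +/-15 degrees of it by
  # construction, but wobbles with the tail bend; the axis does not)
  alignAngle <- bodyDir %% 360
  ua <- c(cos(alignAngle * pi / 180), sin(alignAngle * pi / 180))
  # cutting line: through the center, perpendicular to the alignment line
  proj <- (bx - cx) * ua[1] + (by - cy) * ua[2]
  perp <- -(bx - cx) * ua[2] + (by - cy) * ua[1]
  onCut <- abs(proj) <= 1
  if (any(onCut & perp > 0) && any(onCut & perp < 0)) {
    kb <- which(onCut & perp > 0)[which.max(perp[onCut & perp > 0])]
    kc <- which(onCut & perp < 0)[which.min(perp[onCut & perp < 0])]
    cutLine <- rbind(c(bx[kb], by[kb]), c(bx[kc], by[kc]))
    width <- sqrt(sum((cutLine[1, ] - cutLine[2, ])^2))
  } else {
    cutLine <- rbind(c(cx - ua[2] * det$width / 2, cy + ua[1] * det$width / 2),
                     c(cx + ua[2] * det$width / 2, cy - ua[1] * det$width / 2))
    width <- det$width
  }
  # head side: opposite the outer (body-ward) endpoint
  headSide <- mask & ((dx * ua[1] + dy * ua[2]) <= 0)
  if (!any(headSide)) headSide <- mask
  vals <- patch[headSide]
  # 32 bins of 8 gray levels: dense enough to discriminate individuals, yet
  # robust to pixel noise over regions of a few hundred pixels
  h <- tabulate(as.integer(round(vals)) %/% 8L + 1L, nbins = 32L)
  structure(list(
    inner = c(cx, cy), outer = outer_, cutLine = cutLine,
    alignAngle = alignAngle, width = width, area = sum(headSide),
    hist = h / sum(h), mask = headSide, origin = c(ox, oy),
    contour = cbind(x = bx, y = by)), class = "MatchingRegion")
}

#' @export
print.MatchingRegion <- function(x, ...) {
  cat(sprintf("MatchingRegion: center (%.1f, %.1f), width %.1f px, area %d px^2, alignment %.0f deg\n",
              x$inner[1], x$inner[2], x$width, x$area, x$alignAngle))
  invisible(x)
}

# Area of the symmetric difference of two matching-region masks after
# rigidly aligning b's alignment line onto a's (rotation about the region
# center + translation). b's mask is resampled bilinearly on a's pixel grid.
alignedSymDiff <- function(a, b) {
  delta <- (a$alignAngle - b$alignAngle) * pi / 180
  wa <- which(a$mask, arr.ind = TRUE)
  ax <- (wa[, 2] - 1) + a$origin[1] - a$inner[1]
  ay <- (wa[, 1] - 1) + a$origin[2] - a$inner[2]
  # bounding box: a's mask plus b's mask mapped into a's frame
  wb <- which(b$mask, arr.ind = TRUE)
  bx0 <- (wb[, 2] - 1) + b$origin[1] - b$inner[1]
  by0 <- (wb[, 1] - 1) + b$origin[2] - b$inner[2]
  bx <- cos(delta) * bx0 - sin(delta) * by0
  by <- sin(delta) * bx0 + cos(delta) * by0
  xs <- floor(min(ax, bx)):ceiling(max(ax, bx))
  ys <- floor(min(ay, by)):ceiling(max(ay, by))
  # rasterize a on the common grid
  A <- matrix(FALSE, length(ys), length(xs))
  A[cbind(round(ay) - ys[1] + 1, round(ax) - xs[1] + 1)] <- TRUE
  # sample b's mask at back-rotated grid positions (nearest neighbor, so a
  # region matched against itself mismatches nowhere); minimizing over
  # one-pixel shifts removes the mismatch floor from sub-pixel
  # center-localization noise without helping unlike regions
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  best <- Inf
  for (sdx in -1:1) for (sdy in -1:1) {
    px <- cos(delta) * (gx - sdx) + sin(delta) * (gy - sdy) + b$inner[1] - b$origin[1]
    py <- -sin(delta) * (gx - sdx) + cos(delta) * (gy - sdy) + b$inner[2] - b$origin[2]
    B <- nearestMask(b$mask, py, px)
    best <- min(best, sum(A != B))
  }
  best
}

# nearest-neighbor lookup of a logical matrix at (row, col) 0-based positions
nearestMask <- function(m, py, px) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- round(py); jj <- round(px)
  ok <- ii >= 0 & ii < nr & jj >= 0 & jj < nc
  out <- matrix(FALSE, nrow(py), ncol(py))
  out[ok] <- m[cbind(ii[ok] + 1, jj[ok] + 1)]
  out
}

#' Cascade feature matching of two matching regions
#'
#' Sequential tests with early rejection: (1) cutting-line width difference
#' at most `tauW`; (2) after rigid alignment of the alignment lines, the area
#' of the symmetric difference of the two region masks at most `tauA`;
#' (3) histogram distance (1 - intersection of the normalized 32-bin gray
#' histograms) at most `tauG`. The match score is the mean of the three
#' threshold-normalized statistics; smaller is better, and a region matched
#' against itself scores exactly 0.
#'
#' @param a,b `MatchingRegion` objects (see [extractMatchingRegion()]).
#' @param params a [TrackingParams-class] with thresholds.
#' @return list with `pass` (logical), `score` (NA unless all stages ran),
#'   `stage` (`"width"`, `"area"`, `"gray"` or `"pass"`), and the per-stage
#'   statistics `dWidth`, `dArea`, `dGray`.
#' @export
matchFeatures <- function(a, b, params = trackingParams()) {
  dW <- abs(a$width - b$width)
  if (dW > params@tauW)
    return(list(pass = FALSE, score = NA_real_, stage = "width",
                dWidth = dW, dArea = NA_real_, dGray = NA_real_))
  dA <- alignedSymDiff(a, b)
  if (dA > params@tauA)
    return(list(pass = FALSE, score = NA_real_, stage = "area",
                dWidth = dW, dArea = dA, dGray = NA_real_))
  dG <- 1 - sum(pmin(a$hist, b$hist))
  if (dG > params@tauG)
    return(list(pass = FALSE, score = NA_real_, stage = "gray",
                dWidth = dW, dArea = dA, dGray = dG))
  list(pass = TRUE,
       score = mean(c(dW / params@tauW, dA / params@tauA, dG / params@tauG)),
       stage = "pass", dWidth = dW, dArea = dA, dGray = dG)
}

#' Compensation search window
#'
#' The fallback search region used when Kalman gating finds no candidate: a
#' quarter circle centered on the last effective detection, with radius equal
#' to the ellipse major-axis length, spanning +/-45 degrees about the heading.
#'
#' @param det a detection row (fields `x`, `y`, `length`, `angle`).
#' @param heading resolved motion heading (degrees); defaults to the ellipse
#'   angle.
#' @return list with `center`, `radius`, `heading`.
#' @export
compensationWindow <- function(det, heading = NULL) {
  list(center = c(det$x, det$y), radius = det$length,
       heading = if (is.null(heading)) det$angle else heading %% 360)
}

#' @describeIn compensationWindow membership test of positions in the window.
#' @param win a window from `compensationWindow()`.
#' @param x,y positions to test (vectors).
#' @export
windowContains <- function(win, x, y) {
  d <- sqrt((x - win$center[1])^2 + (y - win$center[2])^2)
  ang <- (atan2(y - win$center[2], x - win$center[1]) * 180 / pi) %% 360
  d <= win$radius & angleDiff(ang, win$heading, period = 360) <= 45
}
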