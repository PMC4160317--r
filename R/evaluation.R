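# Detection and tracking evaluation against ground truth: precision/recall,
# occlusion ratios, optimal trajectory association, TCF and TFF.

#' Tally detections against ground truth
#'
#' A detection is a true positive iff its center lies within `matchRadius`
#' of a not-yet-matched ground-truth head center; matching is one-to-one,
#' greedy by distance, per frame. The default radius is half the mean
#' ground-truth head length.
#'
#' @param detections list of per-frame detection tables (from
#'   [detectHeads()]), indexed by frame.
#' @param truth ground-truth table (`frame`, `id`, `x`, `y`, optionally
#'   `occluded`), e.g. [sceneTruth()].
#' @param matchRadius true-positive match radius (px).
#' @return list of counts: `tp`, `fp`, `fn`, `nOcclusions`, `nOcclDetected`,
#'   `nFish`, `nFrames`.
#' @export
detectionTally <- function(detections, truth, matchRadius = NULL) {
  if (is.null(matchRadius)) {
    matchRadius <- if ("headLength" %in% names(truth)) mean(truth$headLength) / 2 else 12
  }
  tp <- 0L; fp <- 0L; fn <- 0L; nOcc <- 0L; nOccDet <- 0L
  frames <- sort(unique(truth$frame))
  for (t in frames) {
    tr <- truth[truth$frame == t, ]
    det <- if (t <= length(detections) && !is.null(detections[[t]]))
      detections[[t]] else data.frame(x = numeric(0), y = numeric(0))
    matched <- matchGreedy(det$x, det$y, tr$x, tr$y, matchRadius)
    tp <- tp + sum(!is.na(matched))
    fp <- fp + sum(is.na(matched))
    fn <- fn + (nrow(tr) - sum(!is.na(matched)))
    if ("occluded" %in% names(tr)) {
      occ <- which(tr$occluded)
      nOcc <- nOcc + length(occ)
      nOccDet <- nOccDet + sum(occ %in% matched)
    }
  }
  list(tp = tp, fp = fp, fn = fn, nOcclusions = nOcc, nOcclDetected = nOccDet,
       nFish = length(unique(truth$id)), nFrames = length(frames))
}

# one-to-one greedy matching by ascending distance; returns, per detection,
# the matched truth index or NA
matchGreedy <- function(dx, dy, tx, ty, radius) {
  nd <- length(dx); nt <- length(tx)
  out <- rep(NA_integer_, nd)
  if (nd == 0 || nt == 0) return(out)
  d <- sqrt(outer(dx, tx, "-")^2 + outer(dy, ty, "-")^2)
  d[d > radius] <- Inf
  repeat {
    k <- which.min(d)
    if (!is.finite(d[k])) break
    i <- (k - 1) %% nd + 1; j <- (k - 1) %/% nd + 1
    out[i] <- j
    d[i, ] <- Inf; d[, j] <- Inf
  }
  out
}

#' Detection precision and recall
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`. Zero denominators
#' yield `NA` with an explanatory attribute rather than an error.
#'
#' @param tally counts from [detectionTally()] (or any list with `tp`, `fp`,
#'   `fn`).
#' @return list with `precision` and `recall`.
#' @export
detectionMetrics <- function(tally) {
  precision <- if (tally$tp + tally$fp > 0) tally$tp / (tally$tp + tally$fp)
               else structure(NA_real_, reason = "no detections")
  recall <- if (tally$tp + tally$fn > 0) tally$tp / (tally$tp + tally$fn)
            else structure(NA_real_, reason = "no ground-truth targets")
  list(precision = precision, recall = recall)
}

#' Occlusion ratio and occlusion detection ratio
#'
#' `OR = occlusions / (fish x frames)`: the rate of occlusion events per
#' fish-frame. `ODR = detected occluded targets / occlusions`: the fraction
#' of occluded targets the detector still finds (0 when there are none).
#'
#' @param tally counts from [detectionTally()] (fields `nOcclusions`,
#'   `nOcclDetected`, `nFish`, `nFrames`).
#' @return list with `or` and `odr`.
#' @export
occlusionMetrics <- function(tally) {
  stopifnot(tally$nFish > 0, tally$nFrames > 0)
  or <- tally$nOcclusions / (tally$nFish * tally$nFrames)
  odr <- if (tally$nOcclusions > 0) tally$nOcclDetected / tally$nOcclusions else 0
  list(or = or, odr = odr)
}

#' Distance between two trajectories
#'
#' Mean Euclidean distance between corresponding positions over the frames
#' where both trajectories exist; infinite when they never overlap.
#'
#' @param a,b data.frames with columns `frame`, `x`, `y`.
#' @return distance in px (possibly `Inf`).
#' @export
trajectoryDistance <- function(a, b) {
  common <- intersect(a$frame, b$frame)
  if (length(common) == 0) return(Inf)
  ia <- match(common, a$frame); ib <- match(common, b$frame)
  mean(sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2))
}

splitTraj <- function(df, idcol) {
  ids <- unique(df[[idcol]])
  setNames(lapply(ids, function(i) df[df[[idcol]] == i, , drop = FALSE]),
           as.character(ids))
}

#' Optimal association of obtained trajectories with ground truth
#'
#' Each obtained trajectory is assigned to at most one ground-truth
#' trajectory; several obtained trajectories may share one truth
#' (fragmentation). The association minimizes the summed trajectory
#' distance: with per-truth multi-assignment permitted and no exclusivity,
#' the optimum assigns every obtained trajectory with at least one
#' temporally overlapping truth to its minimum-distance truth.
#'
#' @param obtained data.frame `frame`, `traj_id` (or `id`), `x`, `y`.
#' @param truth data.frame `frame`, `id`, `x`, `y`.
#' @return data.frame with `obtained`, `truth` (NA when never overlapping)
#'   and `distance`; total cost in attribute `cost`.
#' @export
associateTrajectories <- function(obtained, truth) {
  idcol <- if ("traj_id" %in% names(obtained)) "traj_id" else "id"
  obt <- splitTraj(obtained, idcol)
  tru <- splitTraj(truth, "id")
  if (length(tru) == 0) stop("empty ground truth")
  out <- data.frame(obtained = as.character(names(obt)),
                    truth = rep(NA_character_, length(obt)),
                    distance = rep(NA_real_, length(obt)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(obt)) {
    d <- vapply(tru, function(g) trajectoryDistance(obt[[k]], g), numeric(1))
    if (any(is.finite(d))) {
      j <- which.min(d)
      out$truth[k] <- names(tru)[j]
      out$distance[k] <- d[j]
    }
  }
  attr(out, "cost") <- sum(out$distance[is.finite(out$distance)])
  out
}

#' Trajectory completeness and fragmentation factors
#'
#' `TCF`: mean over ground-truth trajectories of the fraction of their
#' frames covered by the associated obtained trajectories. `TFF`: mean
#' number of obtained trajectories matched per matched ground-truth
#' trajectory (1 is ideal; larger means fragmentation).
#'
#' @param association result of [associateTrajectories()].
#' @param obtained,truth the trajectory tables passed to it.
#' @return list with `tcf` and `tff`.
#' @export
tcfTff <- function(association, obtained, truth) {
  idcol <- if ("traj_id" %in% names(obtained)) "traj_id" else "id"
  obt <- splitTraj(obtained, idcol)
  tru <- splitTraj(truth, "id")
  cover <- numeric(length(tru)); nfrag <- integer(length(tru))
  for (j in seq_along(tru)) {
    sel <- which(association$truth == names(tru)[j])
    nfrag[j] <- length(sel)
    if (length(sel)) {
      frames <- unique(unlist(lapply(association$obtained[sel],
                                     function(i) obt[[i]]$frame)))
      cover[j] <- length(intersect(frames, tru[[j]]$frame)) / nrow(tru[[j]])
    }
  }
  list(tcf = mean(cover),
       tff = if (any(nfrag > 0)) mean(nfrag[nfrag > 0]) else NA_real_)
}

#' Count identity switches
#'
#' For each obtained trajectory, the per-frame nearest ground-truth identity
#' (within `radius`) is recorded; every change of that identity along the
#' trajectory counts as one switch.
#'
#' @param obtained data.frame `frame`, `traj_id`, `x`, `y`.
#' @param truth data.frame `frame`, `id`, `x`, `y`.
#' @param radius identity match radius (px).
#' @return total number of switches.
#' @export
countIdentitySwitches <- function(obtained, truth, radius = 12) {
  idcol <- if ("traj_id" %in% names(obtained)) "traj_id" else "id"
  switches <- 0L
  for (tr in splitTraj(obtained, idcol)) {
    ids <- vapply(seq_len(nrow(tr)), function(k) {
      g <- truth[truth$frame == tr$frame[k], ]
      if (!nrow(g)) return(NA_integer_)
      d <- sqrt((g$x - tr$x[k])^2 + (g$y - tr$y[k])^2)
      if (min(d) > radius) NA_integer_ else as.integer(g$id[which.min(d)])
    }, integer(1))
    ids <- ids[!is.na(ids)]
    if (length(ids) > 1) switches <- switches + sum(diff(ids) != 0)
  }
  switches
}

#' Full tracking evaluation report
#'
#' @param obtained trajectory table (`frame`, `traj_id`, `x`, `y`).
#' @param truth ground-truth table (`frame`, `id`, `x`, `y`).
#' @param radius identity-switch match radius (px).
#' @return list with `tcf`, `tff`, `idSwitches` and the `association` table.
#' @export
evaluateTracking <- function(obtained, truth, radius = 12) {
  assoc <- associateTrajectories(obtained, truth)
  m <- tcfTff(assoc, obtained, truth)
  list(tcf = m$tcf, tff = m$tff,
       idSwitches = countIdentitySwitches(obtained, truth, radius),
       association = assoc)
}
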