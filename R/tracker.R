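# First-pass tracking: Kalman gating, compensation-window fallback, cascade
# feature matching and greedy one-to-one conflict resolution.

#' A set of tracks
#'
#' Container for the track records produced by [trackFish()] and consumed by
#' the linking pass. Each record holds the per-frame Kalman history, the
#' lifecycle status and the endpoint tags/regions used for linking.
#'
#' @slot tracks list of track records.
#' @slot nFrames number of frames tracked.
#' @slot tracking,linking the parameter objects used.
#' @export
setClass("TrackSet",
  representation(tracks = "list", nFrames = "numeric",
                 tracking = "TrackingParams", linking = "LinkingParams"),
  validity = function(object) {
    for (tr in object@tracks) {
      h <- tr$history
      if (any(duplicated(h$frame))) return("track has two states in one frame")
    }
    TRUE
  })

setMethod("show", "TrackSet", function(object) {
  n <- length(object@tracks)
  len <- vapply(object@tracks, function(t) nrow(t$history), numeric(1))
  cat("TrackSet:", n, "tracks over", object@nFrames, "frames; lengths",
      if (n) paste(range(len), collapse = "-") else "-", "\n")
})

#' @describeIn TrackSet-class number of tracks.
#' @param ts a `TrackSet`.
#' @export
nTracks <- function(ts) length(ts@tracks)

#' @describeIn TrackSet-class flat per-frame table: `frame`, `track_id`,
#'   `x`, `y`, `vx`, `vy`, `angle`, `associated`, `interpolated`.
#' @export
trackTable <- function(ts) {
  out <- do.call(rbind, lapply(ts@tracks, function(tr) {
    h <- tr$history
    h$track_id <- tr$id
    h
  }))
  if (is.null(out))
    return(data.frame(frame = integer(0), track_id = integer(0),
                      x = numeric(0), y = numeric(0), vx = numeric(0),
                      vy = numeric(0), angle = numeric(0),
                      associated = integer(0), interpolated = integer(0)))
  out[order(out$track_id, out$frame),
      c("frame", "track_id", "x", "y", "vx", "vy", "angle", "associated",
        "interpolated")]
}

# resolve an orientation (mod 180) into a direction (mod 360) closest to ref
resolveHeading <- function(angle, ref) {
  cand <- c(angle %% 360, (angle + 180) %% 360)
  cand[which.min(angleDiff(cand, ref, period = 360))]
}

newTrackRecord <- function(id, frame, det, region, params) {
  list(id = id,
       state = kalmanInit(det$x, det$y, params = params),
       history = data.frame(frame = frame, x = det$x, y = det$y, vx = 0,
                            vy = 0, angle = det$angle, associated = 1L,
                            interpolated = 0L),
       missCount = 0L, status = "active",
       heading = det$angle %% 360,
       meanArea = if (is.null(region)) NULL else region$area,
       assocCount = 1L, startRegionStable = NULL,
       lastDet = det, lastRegion = region,
       startTag = list(t = frame, p = c(det$x, det$y)),
       startRegion = region, endTag = NULL, endRegion = NULL,
       lastEffective = list(t = frame, p = c(det$x, det$y)))
}

#' Associate one frame of detections with the active tracks
#'
#' For each track the candidate detections are those inside the Kalman gate
#' around the predicted position; when the gate is empty, those inside the
#' quarter-circle compensation window around the last effective detection.
#' Every track-candidate pair is scored by cascade feature matching against
#' the track's cached matching region; conflicts are resolved globally and
#' greedily by ascending score, one-to-one.
#'
#' @param tracks list of active track records.
#' @param dets detections for the current frame (from [detectHeads()]).
#' @param frame the current frame matrix (for matching-region extraction).
#' @param params a [TrackingParams-class].
#' @param compensation use the compensation-window fallback (disable to
#'   ablate it).
#' @return list with `assignment` (per track, the matched detection index or
#'   `NA`), `priors` (per-track predicted states), `regions` (per-detection
#'   matching regions, filled lazily) and `newDets` (unmatched detection
#'   indices).
#' @export
associateFrame <- function(tracks, dets, frame, params = trackingParams(),
                           compensation = TRUE) {
  nT <- length(tracks); nD <- nrow(dets)
  priors <- lapply(tracks, function(tr) kalmanPredict(tr$state, params))
  regions <- vector("list", max(nD, 0))
  getRegion <- function(k) {
    if (is.null(regions[[k]]))
      regions[[k]] <<- extractMatchingRegion(frame, dets[k, ], params)
    regions[[k]]
  }
  pairs <- NULL
  for (ti in seq_len(nT)) {
    pr <- priors[[ti]]$m
    gate <- if (is.na(params@gateRadius)) {
      3 * sqrt(priors[[ti]]$P[1, 1] + priors[[ti]]$P[2, 2]) +
        mean(c(tracks[[ti]]$lastDet$length, dets$length))
    } else params@gateRadius
    cand <- if (nD) which(sqrt((dets$x - pr[1])^2 + (dets$y - pr[2])^2) <= gate) else integer(0)
    if (!length(cand) && nD && compensation) {
      win <- compensationWindow(tracks[[ti]]$lastDet, tracks[[ti]]$heading)
      cand <- which(windowContains(win, dets$x, dets$y))
    }
    for (k in cand) {
      m <- matchFeatures(tracks[[ti]]$lastRegion, getRegion(k), params)
      if (m$pass)
        pairs <- rbind(pairs, c(ti = ti, det = k, score = m$score))
    }
  }
  assignment <- rep(NA_integer_, nT)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, "score"]), , drop = FALSE]
    usedD <- logical(nD)
    for (r in seq_len(nrow(pairs))) {
      ti <- pairs[r, "ti"]; k <- pairs[r, "det"]
      if (is.na(assignment[ti]) && !usedD[k]) {
        assignment[ti] <- k
        usedD[k] <- TRUE
      }
    }
  }
  list(assignment = assignment, priors = priors, regions = regions,
       newDets = setdiff(seq_len(nD), assignment[!is.na(assignment)]))
}

#' Track detections across frames
#'
#' Runs the first tracking pass over a frame sequence: per-frame association
#' ([associateFrame()]), Kalman update on hits, coasting on virtual
#' observations with the track lifecycle of [updateLifecycle()], and spawning
#' of new tracks from unmatched detections.
#'
#' @param frames list of frame matrices (or a function `(t) -> matrix`).
#' @param detections optional list of per-frame detection tables; computed
#'   with [detectHeads()] when `NULL`.
#' @param tracking a [TrackingParams-class].
#' @param linking a [LinkingParams-class] (lifecycle bounds).
#' @param detection a [DetectionParams-class], used when `detections` is NULL.
#' @param nFrames number of frames; required when `frames` is a function.
#' @param compensation use the compensation-window fallback when the Kalman
#'   gate is empty (disable to ablate it).
#' @param verbose print per-frame association counts.
#' @return a [TrackSet-class].
#' @export
trackFish <- function(frames, detections = NULL, tracking = trackingParams(),
                      linking = linkingParams(), detection = detectionParams(),
                      nFrames = NULL, compensation = TRUE, verbose = FALSE) {
  getFrame <- if (is.function(frames)) frames else function(t) frames[[t]]
  if (is.null(nFrames)) nFrames <- length(frames)
  active <- list(); closed <- list(); nextId <- 1L
  for (t in seq_len(nFrames)) {
    fr <- getFrame(t)
    dets <- if (is.null(detections)) detectHeads(fr, detection) else detections[[t]]
    res <- associateFrame(active, dets, fr, tracking, compensation)
    keep <- logical(length(active))
    for (ti in seq_along(active)) {
      k <- res$assignment[ti]
      if (!is.na(k)) {
        reg <- res$regions[[k]]
        if (is.null(reg)) reg <- extractMatchingRegion(fr, dets[k, ], tracking)
        active[[ti]] <- updateLifecycle(active[[ti]],
          list(type = "associated", frame = t, prior = res$priors[[ti]],
               det = dets[k, ], region = reg, params = tracking), linking)
      } else {
        active[[ti]] <- updateLifecycle(active[[ti]],
          list(type = "missed", frame = t, prior = res$priors[[ti]]), linking)
      }
      keep[ti] <- active[[ti]]$status == "active"
    }
    closed <- c(closed, active[!keep])
    active <- active[keep]
    for (k in res$newDets) {
      reg <- res$regions[[k]]
      if (is.null(reg)) reg <- extractMatchingRegion(fr, dets[k, ], tracking)
      active[[length(active) + 1L]] <-
        newTrackRecord(nextId, t, dets[k, ], reg, tracking)
      nextId <- nextId + 1L
    }
    if (verbose)
      message(sprintf("frame %d: %d detections, %d tracks (%d associated)",
                      t, nrow(dets), length(active) + length(closed),
                      sum(!is.na(res$assignment))))
  }
  # close surviving tracks at the video end
  active <- lapply(active, function(tr) closeTrack(tr))
  new("TrackSet", tracks = c(closed, active), nFrames = nFrames,
      tracking = tracking, linking = linking)
}

# truncate trailing virtual observations and record the end tag
closeTrack <- function(tr, status = "ended") {
  tr$history <- tr$history[tr$history$frame <= tr$lastEffective$t, , drop = FALSE]
  tr$endTag <- tr$lastEffective
  tr$endRegion <- tr$lastRegion
  tr$status <- status
  tr
}
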