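# Track lifecycle under misses, spurious-track pruning and second-pass
# trajectory linking.

#' Update a track's lifecycle for one frame
#'
#' An associated frame applies the Kalman measurement update, marks the state
#' effective and resets the miss counter. A missed frame associates a virtual
#' observation: the state coasts on the prediction and is marked ineffective.
#' When the miss counter reaches `T1` consecutive frames, the track is closed
#' as incomplete: its history is truncated to the last effective frame, whose
#' time and position become the end tag used by trajectory linking.
#'
#' @param track a track record (see [trackFish()]).
#' @param frameResult list with `type` (`"associated"` or `"missed"`),
#'   `frame`, `prior` (predicted state) and, when associated, `det`,
#'   `region`, `params`.
#' @param params a [LinkingParams-class].
#' @return the updated track record.
#' @export
updateLifecycle <- function(track, frameResult, params = linkingParams()) {
  t <- frameResult$frame
  if (frameResult$type == "associated") {
    det <- frameResult$det
    post <- kalmanUpdate(frameResult$prior, c(det$x, det$y), frameResult$params)
    track$state <- post
    speed <- sqrt(post$m[3]^2 + post$m[4]^2)
    motionDir <- (atan2(post$m[4], post$m[3]) * 180 / pi) %% 360
    track$heading <- if (speed > 0.5) resolveHeading(det$angle, motionDir)
                     else resolveHeading(det$angle, track$heading)
    track$history <- rbind(track$history, data.frame(
      frame = t, x = post$m[1], y = post$m[2], vx = post$m[3], vy = post$m[4],
      angle = track$heading, associated = 1L, interpolated = 0L))
    track$missCount <- 0L
    track$lastDet <- det
    # template policy: keep the cached matching region only while its area
    # stays near the track's running level — a partially occluded region
    # would corrupt the appearance template right when it matters most
    reg <- frameResult$region
    if (!is.null(reg)) {
      areaOk <- is.null(track$meanArea) ||
        abs(reg$area - track$meanArea) <= 0.3 * track$meanArea
      if (areaOk) track$lastRegion <- reg
      # the area level itself always tracks, so a track born during a merge
      # recovers a clean template once the fish separates
      track$meanArea <- if (is.null(track$meanArea)) reg$area
                        else 0.8 * track$meanArea + 0.2 * reg$area
      track$assocCount <- (if (is.null(track$assocCount)) 1L else track$assocCount + 1L)
      # start-side template for linking: the stabilized region a few frames
      # after birth (birth regions of re-emerging fish are often still
      # contaminated by the occluder)
      if (track$assocCount == 5L) track$startRegionStable <- track$lastRegion
    }
    track$lastEffective <- list(t = t, p = c(post$m[1], post$m[2]))
  } else {
    prior <- frameResult$prior
    track$state <- prior
    track$history <- rbind(track$history, data.frame(
      frame = t, x = prior$m[1], y = prior$m[2], vx = prior$m[3],
      vy = prior$m[4], angle = track$heading, associated = 0L,
      interpolated = 0L))
    track$missCount <- track$missCount + 1L
    if (track$missCount >= params@T1)
      track <- closeTrack(track, status = "incomplete")
  }
  track
}

#' Remove spurious tracks
#'
#' Tracks caused by erroneous detections last only a few frames: any track
#' with fewer than `minTrackLen` observation-associated frames (coasted
#' virtual frames do not count, so a short-lived false track padded by
#' prediction is still removed) and never linked into a longer trajectory
#' is dropped. Idempotent.
#'
#' @param tracks list of track records, or a [TrackSet-class].
#' @param params a [LinkingParams-class].
#' @return the surviving tracks (same type as the input).
#' @export
pruneSpurious <- function(tracks, params = linkingParams()) {
  if (is(tracks, "TrackSet")) {
    tracks@tracks <- pruneSpurious(tracks@tracks, params)
    return(tracks)
  }
  Filter(function(tr) sum(tr$history$associated) >= params@minTrackLen, tracks)
}

#' Time constraint of trajectory linking
#'
#' True iff the start of the later fragment is strictly after the end of the
#' earlier one and the gap is strictly below `T2` frames.
#'
#' @param endTag list `(t, p)` of the earlier fragment's end.
#' @param startTag list `(t, p)` of the later fragment's start.
#' @param params a [LinkingParams-class].
#' @export
timeConstraint <- function(endTag, startTag, params = linkingParams()) {
  gap <- startTag$t - endTag$t
  gap > 0 && gap < params@T2
}

#' Space constraint of trajectory linking
#'
#' True iff the Euclidean distance between the end position of the earlier
#' fragment and the start position of the later one is strictly below `D` px.
#'
#' @inheritParams timeConstraint
#' @export
spaceConstraint <- function(endTag, startTag, params = linkingParams()) {
  sqrt(sum((endTag$p - startTag$p)^2)) < params@D
}

#' Link trajectory fragments
#'
#' Candidate pairs are an end-tagged fragment followed by a start-tagged
#' fragment satisfying both the time and the space constraint; each pair is
#' scored by cascade feature matching on the stored endpoint matching
#' regions. Passing pairs are linked greedily by ascending score, one-to-one
#' per side, and the gap is filled by linear interpolation of position
#' (flagged `interpolated`). The process iterates until no more links form.
#'
#' @param tracks list of track records or a [TrackSet-class].
#' @param params a [LinkingParams-class].
#' @param tracking a [TrackingParams-class] (matching thresholds).
#' @return same type as the input, with linked fragments merged.
#' @export
linkFragments <- function(tracks, params = linkingParams(),
                          tracking = trackingParams()) {
  if (is(tracks, "TrackSet")) {
    tracks@tracks <- linkFragments(tracks@tracks, params, tracking)
    return(tracks)
  }
  repeat {
    cand <- NULL
    for (a in seq_along(tracks)) {
      ta <- tracks[[a]]
      if (is.null(ta$endTag) || is.null(ta$endRegion)) next
      for (b in seq_along(tracks)) {
        if (a == b) next
        tb <- tracks[[b]]
        bStart <- if (!is.null(tb$startRegionStable)) tb$startRegionStable else tb$startRegion
        if (is.null(tb$startTag) || is.null(bStart)) next
        if (!timeConstraint(ta$endTag, tb$startTag, params)) next
        if (!spaceConstraint(ta$endTag, tb$startTag, params)) next
        m <- matchFeatures(ta$endRegion, bStart, tracking)
        if (m$pass) cand <- rbind(cand, c(a = a, b = b, score = m$score))
      }
    }
    if (is.null(cand)) break
    cand <- cand[order(cand[, "score"]), , drop = FALSE]
    usedA <- logical(length(tracks)); usedB <- logical(length(tracks))
    links <- NULL
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, "a"]; b <- cand[r, "b"]
      if (!usedA[a] && !usedB[b] && !usedA[b] && !usedB[a]) {
        links <- rbind(links, c(a, b)); usedA[a] <- TRUE; usedB[b] <- TRUE
      }
    }
    if (is.null(links)) break
    drop <- integer(0)
    for (r in seq_len(nrow(links))) {
      a <- links[r, 1]; b <- links[r, 2]
      tracks[[a]] <- mergeTracks(tracks[[a]], tracks[[b]])
      drop <- c(drop, b)
    }
    tracks <- tracks[-drop]
  }
  tracks
}

# concatenate two fragments, bridging the gap by linear interpolation
mergeTracks <- function(ta, tb) {
  et <- ta$endTag$t; st <- tb$startTag$t
  gapFrames <- seq(et + 1, st - 1)
  gap <- NULL
  if (length(gapFrames) && st - et > 1) {
    f <- (gapFrames - et) / (st - et)
    gap <- data.frame(
      frame = gapFrames,
      x = ta$endTag$p[1] + f * (tb$startTag$p[1] - ta$endTag$p[1]),
      y = ta$endTag$p[2] + f * (tb$startTag$p[2] - ta$endTag$p[2]),
      vx = (tb$startTag$p[1] - ta$endTag$p[1]) / (st - et),
      vy = (tb$startTag$p[2] - ta$endTag$p[2]) / (st - et),
      angle = ta$history$angle[nrow(ta$history)],
      associated = 0L, interpolated = 1L)
  }
  ta$history <- rbind(ta$history, gap, tb$history)
  ta$endTag <- tb$endTag
  ta$endRegion <- tb$endRegion
  ta$lastEffective <- tb$lastEffective
  ta$lastRegion <- tb$lastRegion
  ta$lastDet <- tb$lastDet
  ta$status <- tb$status
  ta
}

#' Final trajectories of a tracking run
#'
#' Linking followed by spurious-track pruning, flattened to the output
#' trajectory table.
#'
#' @param ts a [TrackSet-class].
#' @param link run the linking pass (default TRUE).
#' @return data.frame `frame, traj_id, x, y, angle, interpolated`.
#' @export
finalTrajectories <- function(ts, link = TRUE) {
  if (link) ts <- linkFragments(ts, ts@linking, ts@tracking)
  ts <- pruneSpurious(ts, ts@linking)
  tab <- trackTable(ts)
  data.frame(frame = tab$frame, traj_id = tab$track_id, x = tab$x, y = tab$y,
             angle = tab$angle, interpolated = tab$interpolated)
}
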