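# Seeded synthetic top-view fish-school video with per-frame ground truth.
#
# The generator emulates shallow-water laboratory footage: a light tank
# bottom with static speckle and slowly drifting suspended particles, and
# fish rendered as a rigid dark elliptical head plus a deformable tapering
# tail whose bend follows a sinusoidal phase. Motion mixes smooth
# mean-reverting turning, cruise-speed fluctuation and burst-glide events,
# with specular reflection at the arena walls.

#' Ground truth of a synthetic scene
#'
#' @slot truth data.frame with one row per (frame, fish): `frame` (1-based),
#'   `id`, `x`, `y` (head center, 0-based px), `heading` (degrees CCW from
#'   +x, y down), `speed` (px/frame), `phase` (tail phase, rad), `occluded`
#'   (another fish's body mask overlaps this head) and `headVisible`
#'   (under 25 percent of the head covered by other fish).
#' @slot fish data.frame of per-fish shape models: `id`, `headLength`,
#'   `headWidth`, `headIntensity`, `bodyLength`, `bodyIntensity`, `tailAmp`
#'   (deg), `tailFreq` (Hz).
#' @slot particles data.frame of drifting particles (`x`, `y`, `dx`, `dy`,
#'   `r`, `value`).
#' @slot speckle data.frame of static dark speckle dots (`x`, `y`, `value`).
#' @slot motion the [MotionParams-class] used.
#' @slot arena arena side (px); frames are `arena x arena`.
#' @slot nFrames,nFish scene dimensions.
#' @slot noise list with `bg` (background gray) and `sd` (pixel noise s.d.).
#' @slot composite `"darkest"` (order-independent) or `"painter"`
#'   (later fish occlude earlier ones; used by scripted occlusion fixtures).
#' @slot seed the generator seed; identical seeds give identical scenes.
#' @slot extra list of fixture-specific annotations (e.g. dropout frames).
#' @export
setClass("SceneTruth",
  representation(truth = "data.frame", fish = "data.frame",
                 particles = "data.frame", speckle = "data.frame",
                 motion = "MotionParams", arena = "numeric",
                 nFrames = "numeric", nFish = "numeric", noise = "list",
                 composite = "character", seed = "numeric", extra = "list"),
  validity = function(object) {
    msg <- character()
    tr <- object@truth
    need <- c("frame", "id", "x", "y", "heading")
    if (!all(need %in% names(tr))) msg <- c(msg, "truth lacks required columns")
    else if (nrow(tr) && (any(tr$x < 0) || any(tr$x > object@arena - 1) ||
                          any(tr$y < 0) || any(tr$y > object@arena - 1)))
      msg <- c(msg, "truth positions outside the arena")
    if (!object@composite %in% c("darkest", "painter"))
      msg <- c(msg, "composite must be 'darkest' or 'painter'")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", object@nFish, "fish x", object@nFrames, "frames,",
      object@arena, "x", object@arena, "px arena, seed", object@seed, "\n")
  if (nrow(object@truth))
    cat("  occluded head-frames:", sum(object@truth$occluded), "of",
        nrow(object@truth), "\n")
})

#' @describeIn SceneTruth-class the per-frame ground-truth table.
#' @param scene a `SceneTruth`.
#' @export
sceneTruth <- function(scene) scene@truth

#' Draw per-fish shape models
#'
#' Head widths are uniform on `[16, 24]` px; head length, body length and
#' tail parameters scale with the width the way small laboratory fish
#' (2-3 cm body) do when imaged from above.
#'
#' @param n number of fish.
#' @param seed RNG seed.
#' @return data.frame of fish models (see [SceneTruth-class]).
#' @export
fishModels <- function(n, seed = 1) {
  withSeed(seed, {
    hw <- runif(n, 16, 24)
    data.frame(
      id = seq_len(n),
      headLength = hw * 1.5,
      headWidth = hw,
      headIntensity = pmax(20, round(rnorm(n, 60, 6))),
      bodyLength = hw * 4.5,
      bodyIntensity = pmax(40, round(rnorm(n, 95, 6))),
      tailAmp = runif(n, 15, 30),
      tailFreq = runif(n, 2, 3.5)
    )
  })
}

# Geometric primitives of one fish pose: the head ellipse and the chain of
# tapering body/tail discs trailing behind it, bent by the tail phase.
fishGeometry <- function(x, y, heading, phase, model) {
  th <- heading * pi / 180
  nSeg <- 10
  segLen <- model$bodyLength / nSeg
  bend0 <- model$tailAmp * sin(phase)
  cx <- x - 0.25 * model$headLength * cos(th)
  cy <- y - 0.25 * model$headLength * sin(th)
  discs <- matrix(0, nSeg, 3)
  px <- cx; py <- cy
  for (k in seq_len(nSeg)) {
    bend <- bend0 * (k / nSeg)^1.5
    dir <- th + pi + bend * pi / 180
    px <- px + segLen * cos(dir)
    py <- py + segLen * sin(dir)
    discs[k, ] <- c(px, py, max(1, 0.45 * model$headWidth * (1 - 0.82 * k / nSeg)))
  }
  list(head = c(cx = x, cy = y, a = model$headLength / 2,
                b = model$headWidth / 2, th = th),
       discs = discs)
}

# Rasterize one fish into patch index/value/mask vectors, clipped to the
# frame. Head edges get a short linear ramp to the background so fitted
# widths track the nominal ones; the body is matte.
fishPatch <- function(geom, model, bg, nr, nc) {
  h <- geom$head
  pad <- 2
  xs <- c(h["cx"] + c(-1, 1) * (2 * h["a"]), geom$discs[, 1] + c(-1, 1) %o% geom$discs[, 3])
  ys <- c(h["cy"] + c(-1, 1) * (2 * h["a"]), geom$discs[, 2] + c(-1, 1) %o% geom$discs[, 3])
  j <- max(1, floor(min(xs)) - pad + 1):min(nc, ceiling(max(xs)) + pad + 1)
  i <- max(1, floor(min(ys)) - pad + 1):min(nr, ceiling(max(ys)) + pad + 1)
  if (length(i) == 0 || length(j) == 0)
    return(list(i = integer(0), j = integer(0), vals = NULL, mask = NULL, headMask = NULL))
  dx <- outer(rep(1, length(i)), (j - 1) - h[["cx"]])
  dy <- outer((i - 1) - h[["cy"]], rep(1, length(j)))
  u <- cos(h[["th"]]) * dx + sin(h[["th"]]) * dy
  v <- -sin(h[["th"]]) * dx + cos(h[["th"]]) * dy
  q <- sqrt((u / h[["a"]])^2 + (v / h[["b"]])^2)
  vals <- matrix(Inf, length(i), length(j))
  # anti-aliasing ramp centered on the nominal boundary, so measured widths
  # track the nominal ones
  ramp <- clamp((q - 0.875) / 0.25, 0, 1)
  headPix <- q <= 1.125
  vals[headPix] <- model$headIntensity +
    (bg - model$headIntensity) * ramp[headPix]
  headMask <- q <= 1
  for (k in seq_len(nrow(geom$discs))) {
    d2 <- (dx - (geom$discs[k, 1] - h[["cx"]]))^2 +
          (dy - (geom$discs[k, 2] - h[["cy"]]))^2
    inside <- d2 <= geom$discs[k, 3]^2
    vals[inside] <- pmin(vals[inside], model$bodyIntensity)
  }
  list(i = i, j = j, vals = vals, mask = is.finite(vals), headMask = headMask)
}

# Per-frame occlusion flags from rendered body masks: a fish is occluded
# when any other fish's mask overlaps its head mask; the head is visible
# when under 25 percent of its pixels are covered by others.
occlusionFlags <- function(frameTruth, fish, arena) {
  n <- nrow(frameTruth)
  cover <- matrix(0L, arena, arena)
  patches <- vector("list", n)
  for (k in seq_len(n)) {
    m <- fish[fish$id == frameTruth$id[k], ]
    geom <- fishGeometry(frameTruth$x[k], frameTruth$y[k],
                         frameTruth$heading[k], frameTruth$phase[k], m)
    p <- fishPatch(geom, m, bg = 255, nr = arena, nc = arena)
    patches[[k]] <- p
    if (length(p$i))
      cover[p$i, p$j] <- cover[p$i, p$j] + p$mask
  }
  occluded <- logical(n); visible <- logical(n)
  for (k in seq_len(n)) {
    p <- patches[[k]]
    if (!length(p$i) || !any(p$headMask)) { visible[k] <- TRUE; next }
    byOthers <- (cover[p$i, p$j] - p$mask)[p$headMask] > 0
    occluded[k] <- any(byOthers)
    visible[k] <- mean(byOthers) < 0.25
  }
  list(occluded = occluded, headVisible = visible)
}

#' Simulate a school of fish
#'
#' Evolves each fish with a mean-reverting turn-rate process (smooth heading
#' change), an AR(1) cruise speed with burst-glide surges, optional
#' separation steering, and specular wall reflection. Deterministic given
#' the seed; occlusion flags are computed from the rendered body masks.
#'
#' @param nFish number of fish (>= 1).
#' @param nFrames number of frames (>= 2).
#' @param motion a [MotionParams-class] object.
#' @param fish optional data.frame from [fishModels()]; drawn from the seed
#'   when omitted.
#' @param seed RNG seed; all randomness flows from it.
#' @return a [SceneTruth-class] object.
#' @export
simulateSchool <- function(nFish = 10, nFrames = 300, motion = motionParams(),
                           fish = NULL, seed = 1) {
  stopifnot(nFish >= 1, nFrames >= 2)
  if (is.null(fish)) fish <- fishModels(nFish, seed = subSeed(seed, 1))
  arena <- motion@arena
  lo <- motion@wallMargin; hi <- arena - 1 - motion@wallMargin
  rows <- withSeed(subSeed(seed, 2), {
    x <- numeric(nFish); y <- numeric(nFish)
    for (f in seq_len(nFish)) {   # keep initial spacing when steering is on
      for (try in 1:200) {
        x[f] <- runif(1, lo, hi); y[f] <- runif(1, lo, hi)
        if (f == 1 || motion@separation <= 0 ||
            all((x[seq_len(f - 1)] - x[f])^2 + (y[seq_len(f - 1)] - y[f])^2 >=
                motion@separation^2)) break
      }
    }
    heading <- runif(nFish, 0, 360)
    speed <- pmax(0.5, rnorm(nFish, motion@speedMean, motion@speedSd))
    omega <- rep(0, nFish)
    phase <- runif(nFish, 0, 2 * pi)
    out <- vector("list", nFrames)
    out[[1]] <- data.frame(frame = 1L, id = fish$id, x = x, y = y,
                           heading = heading, speed = speed, phase = phase)
    for (t in 2:nFrames) {
      omega <- motion@headingReversion * omega +
        rnorm(nFish, 0, motion@headingNoise)
      if (motion@separation > 0 && nFish > 1) {
        # steer away from the mean direction of all close neighbors
        for (f in seq_len(nFish)) {
          d2 <- (x - x[f])^2 + (y - y[f])^2
          d2[f] <- Inf
          close <- which(d2 < motion@separation^2)
          if (length(close)) {
            ax <- sum((x[f] - x[close]) / sqrt(d2[close]))
            ay <- sum((y[f] - y[close]) / sqrt(d2[close]))
            away <- atan2(ay, ax) * 180 / pi
            delta <- ((away - heading[f] + 180) %% 360) - 180
            heading[f] <- heading[f] + clamp(delta, -12, 12)
          }
        }
      }
      # gentle wall avoidance: steer toward the arena center near a wall,
      # so specular reflection stays a rare failsafe rather than an abrupt
      # heading flip
      nearWall <- x < lo + motion@wallMargin | x > hi - motion@wallMargin |
                  y < lo + motion@wallMargin | y > hi - motion@wallMargin
      if (any(nearWall)) {
        ctr <- (lo + hi) / 2
        toCtr <- atan2(ctr - y[nearWall], ctr - x[nearWall]) * 180 / pi
        delta <- ((toCtr - heading[nearWall] + 180) %% 360) - 180
        heading[nearWall] <- heading[nearWall] + clamp(delta, -10, 10)
      }
      burst <- runif(nFish) < motion@burstProb
      speed <- speed + 0.25 * (motion@speedMean - speed) +
        rnorm(nFish, 0, 0.3 * motion@speedSd) +
        burst * motion@burstGain * motion@speedMean
      speed <- clamp(speed, 0.5, 3 * motion@speedMean)
      heading <- heading + omega
      x <- x + speed * cos(heading * pi / 180)
      y <- y + speed * sin(heading * pi / 180)
      # specular reflection at the walls
      flipX <- x < lo | x > hi
      x[x < lo] <- 2 * lo - x[x < lo]; x[x > hi] <- 2 * hi - x[x > hi]
      heading[flipX] <- 180 - heading[flipX]
      flipY <- y < lo | y > hi
      y[y < lo] <- 2 * lo - y[y < lo]; y[y > hi] <- 2 * hi - y[y > hi]
      heading[flipY] <- -heading[flipY]
      heading <- heading %% 360
      omega[flipX | flipY] <- 0
      if (motion@separation > 0 && nFish > 1) {
        # soft collision floor: push pairs apart to half the preferred distance
        minD <- 0.5 * motion@separation
        for (f in seq_len(nFish - 1)) for (g in (f + 1):nFish) {
          dx_ <- x[g] - x[f]; dy_ <- y[g] - y[f]
          d <- sqrt(dx_^2 + dy_^2)
          if (d < minD && d > 1e-6) {
            push <- (minD - d) / 2
            x[f] <- clamp(x[f] - push * dx_ / d, lo, hi)
            y[f] <- clamp(y[f] - push * dy_ / d, lo, hi)
            x[g] <- clamp(x[g] + push * dx_ / d, lo, hi)
            y[g] <- clamp(y[g] + push * dy_ / d, lo, hi)
          }
        }
      }
      phase <- phase + 2 * pi * fish$tailFreq / motion@fps
      out[[t]] <- data.frame(frame = t, id = fish$id, x = x, y = y,
                             heading = heading, speed = speed, phase = phase)
    }
    do.call(rbind, out)
  })
  scene <- new("SceneTruth", truth = rows, fish = fish,
               particles = makeParticles(arena, seed), speckle = makeSpeckle(arena, seed),
               motion = motion, arena = arena, nFrames = nFrames,
               nFish = nFish, noise = list(bg = 220, sd = 4),
               composite = "darkest", seed = seed, extra = list())
  addOcclusionFlags(scene)
}

addOcclusionFlags <- function(scene) {
  tr <- scene@truth
  tr$occluded <- FALSE
  tr$headVisible <- TRUE
  for (t in unique(tr$frame)) {
    sel <- which(tr$frame == t)
    fl <- occlusionFlags(tr[sel, ], scene@fish, scene@arena)
    tr$occluded[sel] <- fl$occluded
    tr$headVisible[sel] <- fl$headVisible
  }
  scene@truth <- tr
  scene
}

makeParticles <- function(arena, seed) {
  withSeed(subSeed(seed, 3), {
    n <- max(1, round(arena^2 / 60000))
    data.frame(x = runif(n, 0, arena - 1), y = runif(n, 0, arena - 1),
               dx = rnorm(n, 0, 0.4), dy = rnorm(n, 0, 0.4),
               r = runif(n, 1.5, 3), value = runif(n, 140, 175))
  })
}

makeSpeckle <- function(arena, seed) {
  withSeed(subSeed(seed, 4), {
    n <- max(1, round(arena^2 / 15000))
    data.frame(x = runif(n, 0, arena - 1), y = runif(n, 0, arena - 1),
               value = runif(n, 165, 200))
  })
}

#' Render one frame of a synthetic scene
#'
#' Light background with Gaussian pixel noise, static speckle and drifting
#' particles; fish composited by the darkest-pixel rule (or painter's order
#' for scripted occlusion fixtures). Deterministic given the scene.
#'
#' @param scene a [SceneTruth-class] object.
#' @param t frame number (1-based).
#' @return 8-bit numeric matrix (`arena x arena`, values 0-255).
#' @export
renderFrame <- function(scene, t) {
  stopifnot(t >= 1, t <= scene@nFrames)
  arena <- scene@arena
  bg <- scene@noise$bg
  canvas <- withSeed(subSeed(scene@seed, 1000 + t), {
    matrix(rnorm(arena * arena, bg, scene@noise$sd), arena, arena)
  })
  # static speckle dots (tank-bottom noise)
  sp <- scene@speckle
  if (nrow(sp)) {
    idx <- cbind(round(sp$y) + 1, round(sp$x) + 1)
    ok <- idx[, 1] >= 1 & idx[, 1] <= arena & idx[, 2] >= 1 & idx[, 2] <= arena
    canvas[idx[ok, , drop = FALSE]] <- sp$value[ok]
  }
  # drifting particles (suspended matter)
  pa <- scene@particles
  for (k in seq_len(nrow(pa))) {
    px <- (pa$x[k] + t * pa$dx[k]) %% arena
    py <- (pa$y[k] + t * pa$dy[k]) %% arena
    r <- pa$r[k]
    jj <- max(1, floor(px - r) + 1):min(arena, ceiling(px + r) + 1)
    ii <- max(1, floor(py - r) + 1):min(arena, ceiling(py + r) + 1)
    d2 <- outer(((ii - 1) - py)^2, ((jj - 1) - px)^2, "+")
    piece <- canvas[ii, jj]
    piece[d2 <= r^2] <- pmin(piece[d2 <= r^2], pa$value[k])
    canvas[ii, jj] <- piece
  }
  tr <- scene@truth[scene@truth$frame == t, ]
  for (k in seq_len(nrow(tr))) {
    m <- scene@fish[scene@fish$id == tr$id[k], ]
    geom <- fishGeometry(tr$x[k], tr$y[k], tr$heading[k], tr$phase[k], m)
    p <- fishPatch(geom, m, bg, arena, arena)
    if (!length(p$i)) next
    piece <- canvas[p$i, p$j]
    if (scene@composite == "darkest") {
      piece[p$mask] <- pmin(piece[p$mask], p$vals[p$mask])
    } else {
      piece[p$mask] <- p$vals[p$mask]
    }
    canvas[p$i, p$j] <- piece
  }
  round(clamp(canvas, 0, 255))
}

#' @describeIn renderFrame Render every frame into a list of matrices.
#' @export
renderFrames <- function(scene) {
  lapply(seq_len(scene@nFrames), function(t) renderFrame(scene, t))
}

# Scripted straight-line scene from explicit per-fish path specs.
scriptedScene <- function(paths, fish, nFrames, arena, seed = 1,
                          composite = "darkest", extra = list()) {
  rows <- do.call(rbind, lapply(seq_along(paths), function(k) {
    p <- paths[[k]]
    t <- seq_len(nFrames)
    x <- clamp(p$x0 + (t - 1) * p$vx, 0, arena - 1)
    y <- clamp(p$y0 + (t - 1) * p$vy, 0, arena - 1)
    heading <- if (!is.null(p$heading)) rep(p$heading, nFrames) else
      rep((atan2(p$vy, p$vx) * 180 / pi) %% 360, nFrames)
    data.frame(frame = t, id = fish$id[k], x = x, y = y, heading = heading,
               speed = sqrt(p$vx^2 + p$vy^2), phase = 0)
  }))
  scene <- new("SceneTruth", truth = rows, fish = fish,
               particles = makeParticles(arena, seed)[0, ],
               speckle = makeSpeckle(arena, seed),
               motion = motionParams(arena = max(64, arena)),
               arena = arena, nFrames = nFrames, nFish = nrow(fish),
               noise = list(bg = 220, sd = 3), composite = composite,
               seed = seed, extra = extra)
  addOcclusionFlags(scene)
}

#' Scripted two-fish occlusion fixtures
#'
#' Three scripted scenarios exercising the detector's angle constraint and
#' the tracker's lifecycle/linking rules: `tail_cross` (heads stay visible
#' while bodies merge into one segmented region), `head_cover` (one head is
#' hidden under the other fish's body; `gap` controls the sweep speed and
#' hence the length of the covered window, reported in
#' `@extra$coverFrames`), and `dropout` (an annotation marks `gap` frames
#' whose detections should be deleted to force trajectory fragmentation).
#'
#' @param kind one of `"tail_cross"`, `"head_cover"`, `"dropout"`.
#' @param seed RNG seed for the rendering noise.
#' @param gap covered/dropped-window control (`head_cover`, `dropout`).
#' @param nFrames scene length.
#' @return a [SceneTruth-class]; fixture annotations (e.g. `dropFrames`,
#'   `coverFrames`, target fish id) are in `@extra`.
#' @export
makeOcclusionFixture <- function(kind = c("tail_cross", "head_cover", "dropout"),
                                 seed = 1, gap = 5, nFrames = 60) {
  kind <- match.arg(kind)
  arena <- 256
  if (kind == "tail_cross") {
    fish <- fishModels(2, seed = 11)
    # mid-band head sizes keep the fixture about the crossing geometry, not
    # about band-edge width fitting
    fish$headWidth <- c(20, 19)
    fish$headLength <- 1.5 * fish$headWidth
    fish$bodyLength <- 4.5 * fish$headWidth
    # fish 2 swims downward across fish 1's trailing tail; by frame 36 its
    # own trailing tail lies over fish 1's tail while both heads are clear
    paths <- list(list(x0 = 66, y0 = 128, vx = 2.7, vy = 0),
                  list(x0 = 95, y0 = 63.2, vx = 0, vy = 2.7))
    return(scriptedScene(paths, fish, nFrames, arena, seed,
                         extra = list(crossFrame = 36)))
  }
  if (kind == "head_cover") {
    fish <- fishModels(2, seed = 12)
    # a big-bodied fish 2 swims downward past fish 1; its trailing body
    # sweeps over fish 1's head (painter order: fish 2 drawn on top) for
    # roughly `gap` frames starting at frame t0
    fish$headWidth[2] <- 24; fish$headLength[2] <- 36; fish$bodyLength[2] <- 60
    t0 <- 25
    v2 <- 24 / max(1, gap - 1)
    paths <- list(
      list(x0 = 128, y0 = 128, vx = 0.5, vy = 0),
      list(x0 = 141.5 - 0.5 * (t0 - 1),
           y0 = (128 + fish$headLength[2]) - v2 * (t0 - 1), vx = 0.5, vy = v2))
    sc <- scriptedScene(paths, fish, nFrames, arena, seed,
                        composite = "painter",
                        extra = list(coverStart = t0, gap = gap, coveredId = 1))
    trc <- sc@truth[sc@truth$id == 1, ]
    sc@extra$coverFrames <- trc$frame[!trc$headVisible]
    return(sc)
  }
  fish <- fishModels(1, seed = 13)
  t0 <- 25
  paths <- list(list(x0 = 40, y0 = 128, vx = 2, vy = 0.4))
  scriptedScene(paths, fish, nFrames, arena, seed,
                extra = list(dropFrames = t0:(t0 + gap - 1), droppedId = 1))
}
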