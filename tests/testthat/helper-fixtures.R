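# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# dark Gaussian spot on a light background
gaussSpot <- function(n = 64, cx = NULL, cy = NULL, sigma = 5, bg = 220,
                      amp = 160, ratio = 1, angle = 0) {
  if (is.null(cx)) cx <- (n - 1) / 2
  if (is.null(cy)) cy <- (n - 1) / 2
  xs <- outer(rep(1, n), 0:(n - 1))
  ys <- outer(0:(n - 1), rep(1, n))
  th <- angle * pi / 180
  u <- cos(th) * (xs - cx) + sin(th) * (ys - cy)
  v <- -sin(th) * (xs - cx) + cos(th) * (ys - cy)
  bg - amp * exp(-(u^2 / (ratio^2) + v^2) / (2 * sigma^2))
}

# background-only frame: noise plus sub-threshold speckle
noiseFrame <- function(n = 128, seed = 1, bg = 220, sd = 4, nSpeck = 6) {
  ShoalTrack:::withSeed(seed, {
    f <- matrix(rnorm(n * n, bg, sd), n, n)
    ij <- cbind(sample(2:(n - 1), nSpeck), sample(2:(n - 1), nSpeck))
    f[ij] <- runif(nSpeck, 165, 195)
    ShoalTrack:::clamp(f, 0, 255)
  })
}

# brute-force global scale-space search: returns the discrete (x, y, s) of
# the strongest dark-blob response over a dense scale grid
oracleScaleSpace <- function(frame, scales) {
  best <- NULL; bestVal <- Inf
  for (s in scales) {
    parts <- ShoalTrack:::dohParts(frame, s)
    w <- ShoalTrack:::.polarityResponse(parts$det, parts$trace)
    k <- which.min(w)
    if (w[k] < bestVal) {
      bestVal <- w[k]
      best <- c(x = (k - 1) %/% nrow(frame), y = (k - 1) %% nrow(frame), s = s)
    }
  }
  best
}

# a scene holding one scripted fish on a straight path (no noise clutter)
singleFishScene <- function(seed = 1, arena = 256, nFrames = 40, vx = 2,
                            vy = 0.4, x0 = 40, y0 = 128, fishSeed = 13) {
  fish <- fishModels(1, seed = fishSeed)
  ShoalTrack:::scriptedScene(list(list(x0 = x0, y0 = y0, vx = vx, vy = vy)),
                             fish, nFrames, arena, seed)
}

# split one tracked trajectory into two fragments with recomputed endpoint
# tags and matching regions, as if the tracker had fragmented it
splitTrackRecord <- function(tr, scene, cutFrame, gap,
                             params = trackingParams()) {
  h <- tr$history
  a <- tr; b <- tr
  a$history <- h[h$frame <= cutFrame, , drop = FALSE]
  b$history <- h[h$frame >= cutFrame + gap + 1, , drop = FALSE]
  b$id <- tr$id + 1000L
  endRow <- a$history[nrow(a$history), ]
  startRow <- b$history[1, ]
  a$endTag <- list(t = endRow$frame, p = c(endRow$x, endRow$y))
  b$startTag <- list(t = startRow$frame, p = c(startRow$x, startRow$y))
  a$status <- "incomplete"
  det <- function(row) list(x = row$x, y = row$y, length = 30, width = 20,
                            angle = row$angle)
  dA <- detectHeads(renderFrame(scene, endRow$frame))
  dB <- detectHeads(renderFrame(scene, startRow$frame))
  kA <- which.min((dA$x - endRow$x)^2 + (dA$y - endRow$y)^2)
  kB <- which.min((dB$x - startRow$x)^2 + (dB$y - startRow$y)^2)
  a$endRegion <- extractMatchingRegion(renderFrame(scene, endRow$frame),
                                       dA[kA, ], params)
  b$startRegion <- extractMatchingRegion(renderFrame(scene, startRow$frame),
                                         dB[kB, ], params)
  b$endTag <- tr$endTag; b$endRegion <- tr$endRegion
  a$startTag <- tr$startTag; a$startRegion <- tr$startRegion
  list(a = a, b = b)
}
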