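test_that("scenes are bit-identical for identical seeds", {
  m <- motionParams(arena = 300)
  a <- simulateSchool(3, 10, m, seed = 9)
  b <- simulateSchool(3, 10, m, seed = 9)
  expect_identical(sceneTruth(a), sceneTruth(b))
  expect_identical(renderFrame(a, 5), renderFrame(b, 5))
  c <- simulateSchool(3, 10, m, seed = 10)
  expect_false(identical(sceneTruth(a), sceneTruth(c)))
})

test_that("a single noiseless fish swims in a straight line away from the walls", {
  m <- motionParams(arena = 800, speedSd = 0, headingNoise = 0, burstProb = 0)
  sc <- simulateSchool(1, 40, m, seed = 6)
  tr <- sceneTruth(sc)
  # restrict to the interior, where no wall-avoidance steering acts
  lo <- m@wallMargin * 2; hi <- m@arena - 1 - 2 * m@wallMargin
  interior <- tr$x > lo & tr$x < hi & tr$y > lo & tr$y < hi
  run <- tr[cumprod(interior) == 1, ]
  expect_gte(nrow(run), 10)
  fx <- lm(x ~ frame, run); fy <- lm(y ~ frame, run)
  expect_lt(max(abs(residuals(fx))), 1e-8)
  expect_lt(max(abs(residuals(fy))), 1e-8)
  expect_equal(length(unique(round(run$heading, 6))), 1)
})

test_that("per-frame heading changes stay within 45 degrees almost always", {
  sc <- simulateSchool(5, 400, motionParams(arena = 800), seed = 21)
  tr <- sceneTruth(sc)
  d <- unlist(lapply(split(tr, tr$id), function(g) {
    dh <- diff(g$heading[order(g$frame)])
    ShoalTrack:::angleDiff(dh, 0, period = 360)
  }))
  expect_lt(mean(d > 45), 0.01)
})

test_that("rendered heads are dark and sized as configured", {
  sc <- simulateSchool(6, 3, motionParams(arena = 420, separation = 110), seed = 31)
  fr <- renderFrame(sc, 2)
  tr <- sc@truth[sc@truth$frame == 2, ]
  for (k in seq_len(nrow(tr))) {
    cpix <- fr[round(tr$y[k]) + 1, round(tr$x[k]) + 1]
    expect_lt(cpix, sc@noise$bg - 50)
  }
  # moment-measured head widths stay in the configured band for
  # unoccluded fish (full sweep over several frames)
  widths <- c()
  for (t in 1:3) {
    frt <- renderFrame(sc, t)
    trt <- sc@truth[sc@truth$frame == t & !sc@truth$occluded, ]
    for (k in seq_len(nrow(trt))) {
      m <- sc@fish[sc@fish$id == trt$id[k], ]
      r <- 0.75 * m$headLength
      jj <- max(1, floor(trt$x[k] - r)):min(420 - 1, ceiling(trt$x[k] + r))
      ii <- max(1, floor(trt$y[k] - r)):min(420 - 1, ceiling(trt$y[k] + r))
      patch <- frt[ii + 1, jj + 1]
      # half-way cut between head and background recovers the nominal
      # boundary of the anti-aliased head ellipse
      sel <- which(patch < (m$headIntensity + sc@noise$bg) / 2, arr.ind = TRUE)
      cv <- stats::cov(cbind(jj[sel[, 2]], ii[sel[, 1]]))
      widths <- c(widths, 4 * sqrt(min(eigen(cv, only.values = TRUE)$values)))
    }
  }
  expect_gte(mean(widths >= 16 & widths <= 24), 0.95)
})

test_that("tail crossings leave both heads visible in the truth flags", {
  sc <- makeOcclusionFixture("tail_cross", seed = 3)
  tc <- sc@extra$crossFrame
  tr <- sc@truth[sc@truth$frame == tc, ]
  expect_true(all(tr$headVisible))
  # and the bodies merge into a single segmented dark region at the crossing
  fr <- renderFrame(sc, tc)
  lab <- segmentFishRegions(fr, otsuThreshold(fr), detectionParams()@minArea)
  at <- function(x, y) lab[round(y) + 1, round(x) + 1]
  expect_equal(at(tr$x[1], tr$y[1]), at(tr$x[2], tr$y[2]))
  expect_gt(at(tr$x[1], tr$y[1]), 0)
})

test_that("head-cover fixtures hide the covered head from the detector", {
  sc <- makeOcclusionFixture("head_cover", seed = 3, gap = 6)
  t0 <- sc@extra$coverStart
  trCover <- sc@truth[sc@truth$id == sc@extra$coveredId, ]
  covered <- trCover$frame[!trCover$headVisible]
  expect_gt(length(covered), 0)
  fr <- renderFrame(sc, covered[which.min(abs(covered - t0 - 3))])
  det <- detectHeads(fr)
  g <- trCover[trCover$frame == covered[which.min(abs(covered - t0 - 3))], ]
  if (nrow(det))
    expect_gt(min(sqrt((det$x - g$x)^2 + (det$y - g$y)^2)), 10)
})

test_that("an empty scene yields no downstream detections", {
  expect_equal(nrow(detectHeads(noiseFrame(200, seed = 77))), 0)
})
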