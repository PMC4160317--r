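test_that("ellipse fit is isotropic on an isotropic spot", {
  f <- gaussSpot(64, cx = 31, cy = 31, sigma = 6)
  pts <- detectScaleSpaceMinima(f, detectionParams(scaleGrid = 2 * 1.26^(0:8)))
  fit <- fitEllipse(f, pts[1, ])
  expect_true(fit$ok)
  expect_lt(fit$ratio, 1.05)
  expect_lt((fit$length - fit$width) / fit$width, 0.05)
  expect_gte(fit$length, fit$width)
})

test_that("ellipse fit recovers orientation of an anisotropic spot and is rotation-equivariant", {
  f0 <- gaussSpot(80, cx = 39, cy = 39, sigma = 5, ratio = 2, angle = 0)
  p <- detectionParams(scaleGrid = 2 * 1.26^(0:8))
  pts <- detectScaleSpaceMinima(f0, p)
  fit0 <- fitEllipse(f0, pts[which.min(pts$dohValue), ])
  expect_true(fit0$ok)
  expect_lt(min(abs(fit0$angle - 0), abs(fit0$angle - 180)), 5)
  expect_gt(fit0$length, fit0$width)
  # moments-based oracle on the thresholded spot
  mask <- f0 < 150
  w <- which(mask, arr.ind = TRUE)
  cv <- stats::cov(cbind(w[, 2], w[, 1]))
  e <- eigen(cv)
  oracleAngle <- (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  expect_lt(ShoalTrack:::angleDiff(fit0$angle, oracleAngle), 5)

  f90 <- gaussSpot(80, cx = 39, cy = 39, sigma = 5, ratio = 2, angle = 90)
  pts90 <- detectScaleSpaceMinima(f90, p)
  fit90 <- fitEllipse(f90, pts90[which.min(pts90$dohValue), ])
  expect_lt(ShoalTrack:::angleDiff(fit90$angle, (fit0$angle + 90) %% 180), 5)
  expect_lt(abs(fit90$length - fit0$length) / fit0$length, 0.02)
  expect_lt(abs(fit90$width - fit0$width) / fit0$width, 0.02)
})

test_that("degenerate Hessians are rejected with a reason", {
  f <- matrix(128, 64, 64)
  fit <- fitEllipse(f, list(x = 32, y = 32, s = 4))
  expect_false(fit$ok)
  expect_match(fit$reason, "degenerate")
})

test_that("local contrast matches direct arithmetic", {
  # black ellipse on white background
  f <- matrix(255, 64, 64)
  xs <- outer(rep(1, 64), 0:63); ys <- outer(0:63, rep(1, 64))
  inside <- ((xs - 32) / 10)^2 + ((ys - 32) / 6)^2 <= 1
  f[inside] <- 0
  expect_equal(computeContrast(f, 32, 32, 20, 12, 0), 1)
  # uniform frame
  expect_equal(computeContrast(matrix(90, 64, 64), 32, 32, 20, 12, 0), 0)
  # interior 55, annulus 200
  f2 <- matrix(200, 64, 64)
  f2[inside] <- 55
  expect_equal(computeContrast(f2, 32, 32, 20, 12, 0), (200 - 55) / 255,
               tolerance = 1e-12)
  expect_error(computeContrast(matrix(128, 64, 64), 500, 500, 20, 12, 0),
               "outside")
})

test_that("Otsu threshold equals the exhaustive maximizer with smallest-t tie-break", {
  bruteOtsu <- function(v) {
    v <- as.integer(round(v))
    best <- -Inf; bestT <- 0L
    for (t in 0:254) {
      g0 <- v[v <= t]; g1 <- v[v > t]
      if (!length(g0) || !length(g1)) next
      w0 <- length(g0) / length(v); w1 <- 1 - w0
      sb <- w0 * w1 * (mean(g0) - mean(g1))^2
      if (sb > best + 1e-12) { best <- sb; bestT <- t }
    }
    bestT
  }
  f <- matrix(c(0, 0, 0, 255, 255, 255), 32, 36)
  expect_equal(otsuThreshold(f), bruteOtsu(f))
  # bimodal: threshold falls between the modes
  set.seed(7)
  f2 <- matrix(ShoalTrack:::clamp(c(rnorm(600, 50, 10), rnorm(600, 200, 10)), 0, 255), 30, 40)
  t2 <- otsuThreshold(f2)
  expect_gt(t2, 50); expect_lt(t2, 200)
  expect_equal(t2, bruteOtsu(f2))
  # random images property (larger sweep in the acceptance suite)
  set.seed(11)
  for (k in 1:20) {
    f3 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    expect_equal(otsuThreshold(f3), bruteOtsu(f3))
  }
  expect_error(otsuThreshold(matrix(7, 32, 32)), "distinct")
})

test_that("segmentation labels 8-connected components and drops small noise", {
  f <- matrix(200, 64, 64)
  f[10:20, 10:20] <- 30          # blob 1
  f[40:50, 40:50] <- 30          # blob 2
  lab <- segmentFishRegions(f, 100)
  expect_equal(max(lab), 2)
  # merge them with a thin bridge (diagonal-touching counts as connected)
  f[21, 21] <- 30; f[seq(22, 39), seq(22, 39)] <- 30
  expect_equal(max(segmentFishRegions(f, 100)), 1)
  # speckle below the minimum area vanishes
  f2 <- matrix(200, 64, 64)
  f2[cbind(c(5, 20, 40), c(5, 30, 50))] <- 30
  expect_equal(max(segmentFishRegions(f2, 100, minArea = 10)), 0)
})

test_that("candidate constraints drop out-of-band widths and resolve duplicates by contrast", {
  regions <- matrix(1L, 64, 64)
  p <- detectionParams()
  cand <- function(x, y, width, angle, contrast)
    data.frame(x = x, y = y, length = width * 1.5, width = width,
               angle = angle, contrast = contrast, scale = width / 2.8)
  # width 10 < wMin = 16 is removed
  out <- applyConstraints(cand(30, 30, 10, 0, 0.5), regions, p)
  expect_equal(nrow(out), 0)
  # same region, angles 10 and 20 deg: keep the higher contrast
  cands <- rbind(cand(30, 30, 20, 10, 0.4), cand(34, 30, 20, 20, 0.6))
  out <- applyConstraints(cands, regions, p)
  expect_equal(nrow(out), 1)
  expect_equal(out$contrast, 0.6)
  # same region, 0 vs 90 deg (occluding pair): both kept
  cands <- rbind(cand(30, 30, 20, 0, 0.4), cand(34, 30, 20, 90, 0.6))
  expect_equal(nrow(applyConstraints(cands, regions, p)), 2)
  # contrast below k is removed
  expect_equal(nrow(applyConstraints(cand(30, 30, 20, 0, 0.01), regions, p)), 0)
})

test_that("applyConstraints never increases the candidate count and is idempotent", {
  set.seed(3)
  regions <- matrix(rep(1:4, each = 32 * 128), 128, 128)
  p <- detectionParams()
  for (k in 1:10) {
    n <- sample(1:12, 1)
    cands <- data.frame(x = runif(n, 5, 120), y = runif(n, 5, 120),
                        length = runif(n, 20, 40), width = runif(n, 10, 30),
                        angle = runif(n, 0, 180), contrast = runif(n, 0, 0.8),
                        scale = runif(n, 4, 12))
    out1 <- applyConstraints(cands, regions, p)
    expect_lte(nrow(out1), n)
    out2 <- applyConstraints(out1, regions, p)
    expect_equal(out2, out1)
  }
})

test_that("the full detector finds every separated fish and nothing in noise", {
  sc <- simulateSchool(nFish = 6, nFrames = 2,
                       motion = motionParams(arena = 420, separation = 110),
                       seed = 31)
  fr <- renderFrame(sc, 2)
  det <- detectHeads(fr)
  tr <- sc@truth[sc@truth$frame == 2, ]
  expect_equal(nrow(det), 6)
  err <- vapply(seq_len(nrow(det)), function(k)
    min(sqrt((tr$x - det$x[k])^2 + (tr$y - det$y[k])^2)), numeric(1))
  expect_lt(max(err), 2)
  # pure background: no detections
  expect_equal(nrow(detectHeads(noiseFrame(160, seed = 5))), 0)
})

test_that("two crossing fish with visible heads give two detections in one region", {
  sc <- makeOcclusionFixture("tail_cross", seed = 2)
  tc <- sc@extra$crossFrame
  fr <- renderFrame(sc, tc)
  det <- detectHeads(fr)
  tr <- sc@truth[sc@truth$frame == tc, ]
  expect_equal(nrow(det), 2)
  # both heads lie in the same Otsu-segmented region
  expect_equal(length(unique(det$region)), 1)
  expect_gt(ShoalTrack:::angleDiff(det$angle[1], det$angle[2]), 30)
  err <- vapply(1:2, function(k)
    min(sqrt((tr$x - det$x[k])^2 + (tr$y - det$y[k])^2)), numeric(1))
  expect_lt(max(err), 3)
})
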