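mkTrack <- function(id, frames, x, y, status = "active") {
  list(id = id,
       state = kalmanInit(x[length(x)], y[length(y)]),
       history = data.frame(frame = frames, x = x, y = y, vx = 0, vy = 0,
                            angle = 0, associated = 1L, interpolated = 0L),
       missCount = 0L, status = status, heading = 0,
       lastDet = list(x = x[length(x)], y = y[length(y)], length = 30,
                      width = 20, angle = 0),
       lastRegion = NULL, startTag = list(t = frames[1], p = c(x[1], y[1])),
       startRegion = NULL, endTag = NULL, endRegion = NULL,
       lastEffective = list(t = frames[length(frames)],
                            p = c(x[length(x)], y[length(y)])))
}

test_that("the miss counter closes a track as incomplete exactly at T1", {
  lp <- linkingParams(T1 = 10)
  tp <- trackingParams()
  tr <- mkTrack(1, 1:5, seq(10, 18, 2), rep(50, 5))
  tr$state <- kalmanInit(18, 50, 2, 0)
  # 9 misses: still active, coasting on the prediction
  for (k in 1:9) {
    prior <- kalmanPredict(tr$state, tp)
    tr <- updateLifecycle(tr, list(type = "missed", frame = 5 + k, prior = prior), lp)
  }
  expect_equal(tr$status, "active")
  expect_equal(tr$missCount, 9L)
  # the coasted positions equal the Kalman prediction (constant velocity)
  coasted <- tr$history[tr$history$associated == 0, ]
  expect_equal(coasted$x, 18 + 2 * (1:9), tolerance = 1e-9)
  # the 10th consecutive miss closes it with the end tag at the last hit
  prior <- kalmanPredict(tr$state, tp)
  tr <- updateLifecycle(tr, list(type = "missed", frame = 15, prior = prior), lp)
  expect_equal(tr$status, "incomplete")
  expect_equal(tr$endTag$t, 5)
  expect_equal(tr$endTag$p, c(18, 50))
  expect_equal(max(tr$history$frame), 5)  # trailing virtual states dropped
})

test_that("a hit resets the miss counter", {
  lp <- linkingParams(T1 = 10); tp <- trackingParams()
  tr <- mkTrack(1, 1:3, c(10, 12, 14), rep(50, 3))
  tr$state <- kalmanInit(14, 50, 2, 0)
  for (k in 1:9) {
    prior <- kalmanPredict(tr$state, tp)
    tr <- updateLifecycle(tr, list(type = "missed", frame = 3 + k, prior = prior), lp)
  }
  prior <- kalmanPredict(tr$state, tp)
  tr <- updateLifecycle(tr, list(
    type = "associated", frame = 13, prior = prior,
    det = data.frame(x = 34, y = 50, length = 30, width = 20, angle = 0),
    region = NULL, params = tp), lp)
  expect_equal(tr$status, "active")
  expect_equal(tr$missCount, 0L)
})

test_that("spurious short tracks are pruned, idempotently", {
  lp <- linkingParams(minTrackLen = 5)
  tracks <- list(mkTrack(1, 1:2, c(0, 1), c(0, 0)),
                 mkTrack(2, 1:100, seq(0, 99), rep(0, 100)),
                 mkTrack(3, 10:12, c(5, 6, 7), c(1, 1, 1)))
  kept <- pruneSpurious(tracks, lp)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$id, 2)
  expect_equal(pruneSpurious(kept, lp), kept)
})

test_that("time and space constraints are strict as stated", {
  lp <- linkingParams(T2 = 30, D = 80)
  tag <- function(t, x, y) list(t = t, p = c(x, y))
  expect_true(timeConstraint(tag(100, 0, 0), tag(110, 0, 0), lp))
  expect_false(timeConstraint(tag(100, 0, 0), tag(150, 0, 0), lp))
  expect_false(timeConstraint(tag(100, 0, 0), tag(100, 0, 0), lp))
  expect_false(timeConstraint(tag(100, 0, 0), tag(130, 0, 0), lp))  # gap == T2
  expect_true(spaceConstraint(tag(0, 0, 0), tag(0, 50, 0), lp))
  expect_false(spaceConstraint(tag(0, 0, 0), tag(0, 80, 0), lp))    # == D
  expect_true(spaceConstraint(tag(0, 7, 7), tag(0, 7, 7), lp))
})

test_that("a dropout-fragmented trajectory is relinked when the gap fits the bounds", {
  sc <- singleFishScene(seed = 23, nFrames = 70, vx = 2, vy = 0.4)
  ts <- trackFish(function(t) renderFrame(sc, t), nFrames = 70)
  expect_equal(nTracks(ts), 1)
  tr <- ts@tracks[[1]]
  pieces <- splitTrackRecord(tr, sc, cutFrame = 30, gap = 5)
  linked <- linkFragments(list(pieces$a, pieces$b), linkingParams(), ts@tracking)
  expect_equal(length(linked), 1)
  # gap filled by interpolation, flagged, frames strictly increasing
  h <- linked[[1]]$history
  expect_true(all(diff(h$frame) == 1))
  expect_equal(sum(h$interpolated), 5)
  # association count conserved
  expect_equal(sum(h$associated),
               sum(pieces$a$history$associated) + sum(pieces$b$history$associated))

  # a gap beyond T2 is never linked
  pieces40 <- splitTrackRecord(tr, sc, cutFrame = 15, gap = 40)
  notLinked <- linkFragments(list(pieces40$a, pieces40$b), linkingParams(), ts@tracking)
  expect_equal(length(notLinked), 2)
})

test_that("fragments of grossly different head sizes are not linked", {
  mkScene <- function(hw, seed) {
    fish <- fishModels(1, seed = 1)
    fish$headWidth <- hw; fish$headLength <- 1.5 * hw; fish$bodyLength <- 4.5 * hw
    ShoalTrack:::scriptedScene(list(list(x0 = 40, y0 = 128, vx = 2, vy = 0.4)),
                               fish, 40, 256, seed)
  }
  # both widths inside the detection band, but far enough apart for the
  # cascade's width stage to reject the pair
  scA <- mkScene(16.5, seed = 24)
  scB <- mkScene(23.5, seed = 25)
  tsA <- trackFish(function(t) renderFrame(scA, t), nFrames = 40)
  tsB <- trackFish(function(t) renderFrame(scB, t), nFrames = 40)
  expect_equal(nTracks(tsA), 1); expect_equal(nTracks(tsB), 1)
  a <- ShoalTrack:::closeTrack(tsA@tracks[[1]], "incomplete")
  b <- tsB@tracks[[1]]
  # shift b's start to sit 10 frames and a small distance after a's end
  b$startTag <- list(t = a$endTag$t + 10,
                     p = a$endTag$p + c(20, 0))
  b$history$frame <- b$history$frame + a$endTag$t + 9
  linked <- linkFragments(list(a, b), linkingParams(), trackingParams())
  expect_equal(length(linked), 2)
})
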