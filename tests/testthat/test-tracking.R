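# association and first-pass tracking on scripted scenes

test_that("a lone in-gate detection is assigned and off-gate detections spawn tracks", {
  sc <- singleFishScene(seed = 9, nFrames = 5)
  f1 <- renderFrame(sc, 1); f2 <- renderFrame(sc, 2)
  d1 <- detectHeads(f1); d2 <- detectHeads(f2)
  tp <- trackingParams()
  tr <- ShoalTrack:::newTrackRecord(1L, 1L, d1[1, ],
                                    extractMatchingRegion(f1, d1[1, ], tp), tp)
  res <- associateFrame(list(tr), d2, f2, tp)
  expect_equal(res$assignment, 1L)
  expect_equal(length(res$newDets), 0)
  # a detection far outside gate and window is left to spawn a new track
  dFar <- d2; dFar$x <- dFar$x + 150; dFar$y <- dFar$y + 150
  resFar <- associateFrame(list(tr), dFar, f2, tp)
  expect_true(is.na(resFar$assignment))
  expect_equal(resFar$newDets, 1L)
})

test_that("assignment is one-to-one in every frame", {
  sc <- simulateSchool(4, 25, motionParams(arena = 380, separation = 90), seed = 12)
  ts <- trackFish(function(t) renderFrame(sc, t), nFrames = 25)
  tab <- trackTable(ts)
  hits <- tab[tab$associated == 1, ]
  # no track occupies one frame twice
  expect_false(any(duplicated(hits[, c("frame", "track_id")])))
  # per frame, at most as many associations as there are detections
  for (t in unique(hits$frame)) {
    det <- detectHeads(renderFrame(sc, t))
    expect_lte(sum(hits$frame == t), nrow(det) + 0)
  }
})

test_that("crossing fish keep their identities through a tail crossing", {
  sc <- makeOcclusionFixture("tail_cross", seed = 14, nFrames = 40)
  res <- runPipeline(function(t) renderFrame(sc, t), nFrames = 40)
  ev <- evaluateTracking(res$trajectories, sc@truth[, c("frame", "id", "x", "y")])
  expect_equal(ev$idSwitches, 0)
  expect_gte(ev$tcf, 0.9)
})

test_that("disabling the compensation window cannot reduce missed track-frames under burst motion", {
  # scripted burst: constant slow motion, then a sudden fast leap
  fish <- fishModels(1, seed = 18)
  nFrames <- 24
  t <- seq_len(nFrames)
  xs <- 40 + 1.5 * (t - 1) + ifelse(t > 12, 22, 0)   # leap at frame 13
  rows <- data.frame(frame = t, id = 1, x = xs, y = 120, heading = 0,
                     speed = 2, phase = 0)
  sc <- new("SceneTruth", truth = rows, fish = fish,
            particles = ShoalTrack:::makeParticles(256, 1)[0, ],
            speckle = ShoalTrack:::makeSpeckle(256, 1),
            motion = motionParams(arena = 256), arena = 256,
            nFrames = nFrames, nFish = 1, noise = list(bg = 220, sd = 3),
            composite = "darkest", seed = 1, extra = list())
  frames <- renderFrames(sc)
  dets <- lapply(frames, detectHeads)
  misses <- function(comp) {
    ts <- trackFish(frames, dets, compensation = comp)
    tab <- trackTable(ts)
    sum(tab$associated == 0) + (nFrames - nrow(tab[tab$associated == 1, ]))
  }
  expect_gte(misses(FALSE), misses(TRUE))
})

test_that("track headings follow the motion direction, not just the axis", {
  sc <- singleFishScene(seed = 19, nFrames = 12, vx = -2.5, vy = 0)
  ts <- trackFish(function(t) renderFrame(sc, t), nFrames = 12)
  tab <- trackTable(ts)
  main <- tab[tab$track_id == names(sort(-table(tab$track_id)))[1], ]
  late <- main$angle[main$frame > 6]
  expect_true(all(ShoalTrack:::angleDiff(late, 180, period = 360) < 45))
})
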