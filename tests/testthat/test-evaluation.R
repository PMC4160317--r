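test_that("precision and recall follow their definitions, with explicit undefined cases", {
  m <- detectionMetrics(list(tp = 99, fp = 1, fn = 1))
  expect_equal(m$precision, 0.99)
  expect_equal(m$recall, 0.99)
  m0 <- detectionMetrics(list(tp = 0, fp = 0, fn = 10))
  expect_equal(m0$recall, 0)
  expect_true(is.na(m0$precision))
  expect_equal(attr(m0$precision, "reason"), "no detections")
})

test_that("occlusion metrics reproduce the printed occlusion-rate arithmetic", {
  or <- function(nOcc, nFish, nFrames)
    occlusionMetrics(list(nOcclusions = nOcc, nOcclDetected = 0,
                          nFish = nFish, nFrames = nFrames))$or
  expect_equal(or(125, 10, 500), 0.025)
  expect_equal(or(640, 20, 500), 0.064)
  expect_equal(or(3040, 40, 500), 0.152)
  odr <- occlusionMetrics(list(nOcclusions = 50, nOcclDetected = 50,
                               nFish = 10, nFrames = 100))$odr
  expect_equal(odr, 1)
  expect_equal(occlusionMetrics(list(nOcclusions = 0, nOcclDetected = 0,
                                     nFish = 10, nFrames = 100))$odr, 0)
})

test_that("trajectory distance is the mean over overlapping frames", {
  a <- data.frame(frame = 1:10, x = 1:10, y = rep(0, 10))
  expect_equal(trajectoryDistance(a, a), 0)
  b <- a; b$y <- 3
  expect_equal(trajectoryDistance(a, b), 3)
  c3 <- data.frame(frame = 1:3, x = c(1, 2, 3) + c(0, 3, 6), y = 0)
  a3 <- data.frame(frame = 1:3, x = 1:3, y = 0)
  expect_equal(trajectoryDistance(a3, c3), 3)
  d <- data.frame(frame = 11:20, x = 1:10, y = 0)
  expect_equal(trajectoryDistance(a, d), Inf)
})

test_that("trajectory association is the exhaustive-search optimum", {
  bruteAssoc <- function(obt, tru) {
    # every obtained with a feasible truth must be assigned; minimize cost
    D <- sapply(tru, function(g) sapply(obt, function(o) trajectoryDistance(o, g)))
    D <- matrix(D, nrow = length(obt))
    choices <- lapply(seq_len(nrow(D)), function(i) {
      f <- which(is.finite(D[i, ]))
      if (length(f)) f else NA_integer_
    })
    grid <- expand.grid(choices)
    costs <- apply(grid, 1, function(pick)
      sum(D[cbind(seq_len(nrow(D)), unlist(pick))], na.rm = TRUE))
    min(costs)
  }
  set.seed(5)
  for (rep in 1:20) {
    nT <- sample(1:4, 1); nO <- sample(1:5, 1)
    tru <- lapply(seq_len(nT), function(i) {
      t0 <- sample(1:10, 1); len <- sample(5:25, 1)
      data.frame(frame = t0:(t0 + len), id = i,
                 x = cumsum(rnorm(len + 1, 0, 3)) + 50 * i,
                 y = cumsum(rnorm(len + 1, 0, 3)))
    })
    obt <- lapply(seq_len(nO), function(i) {
      src <- tru[[sample(nT, 1)]]
      n <- nrow(src); sel <- sort(sample(n, max(2, floor(n / 2))))
      data.frame(frame = src$frame[sel], traj_id = i,
                 x = src$x[sel] + rnorm(length(sel)),
                 y = src$y[sel] + rnorm(length(sel)))
    })
    truth <- do.call(rbind, tru)
    obtained <- do.call(rbind, obt)
    assoc <- associateTrajectories(obtained, truth)
    expect_equal(attr(assoc, "cost"), bruteAssoc(obt, tru), tolerance = 1e-9)
  }
})

test_that("TCF and TFF follow their definitions", {
  tru <- data.frame(frame = 1:100, id = 1, x = 1:100, y = 0)
  full <- data.frame(frame = 1:100, traj_id = 1, x = 1:100, y = 0)
  a <- associateTrajectories(full, tru)
  m <- tcfTff(a, full, tru)
  expect_equal(m$tcf, 1); expect_equal(m$tff, 1)
  frag <- rbind(data.frame(frame = 1:40, traj_id = 1, x = 1:40, y = 0),
                data.frame(frame = 51:100, traj_id = 2, x = 51:100, y = 0))
  a2 <- associateTrajectories(frag, tru)
  m2 <- tcfTff(a2, frag, tru)
  expect_equal(m2$tcf, 0.9); expect_equal(m2$tff, 2)
  # no obtained trajectories at all
  none <- full[0, ]
  m3 <- tcfTff(associateTrajectories(rbind(none), tru), none, tru)
  expect_equal(m3$tcf, 0)
})

test_that("metric ranges hold on random instances", {
  set.seed(9)
  for (rep in 1:10) {
    tru <- do.call(rbind, lapply(1:3, function(i)
      data.frame(frame = 1:50, id = i, x = rnorm(50, 100 * i, 5), y = rnorm(50))))
    obt <- do.call(rbind, lapply(1:4, function(i) {
      sel <- sort(sample(50, 25))
      data.frame(frame = sel, traj_id = i, x = rnorm(25, 100 * sample(3, 1), 5),
                 y = rnorm(25))
    }))
    a <- associateTrajectories(obt, tru)
    m <- tcfTff(a, obt, tru)
    expect_gte(m$tcf, 0); expect_lte(m$tcf, 1)
    if (!is.na(m$tff)) expect_gte(m$tff, 1)
  }
})

test_that("splitting an obtained trajectory never raises TCF nor lowers TFF", {
  set.seed(13)
  tru <- do.call(rbind, lapply(1:3, function(i)
    data.frame(frame = 1:60, id = i, x = cumsum(rnorm(60, 0, 2)) + 200 * i,
               y = cumsum(rnorm(60, 0, 2)))))
  obt <- do.call(rbind, lapply(1:3, function(i) {
    g <- tru[tru$id == i, ]
    data.frame(frame = g$frame, traj_id = i, x = g$x + rnorm(60, 0, 0.5),
               y = g$y + rnorm(60, 0, 0.5))
  }))
  m0 <- with(list(a = associateTrajectories(obt, tru)),
             tcfTff(a, obt, tru))
  for (rep in 1:10) {
    vic <- sample(unique(obt$traj_id), 1)
    g <- obt[obt$traj_id == vic, ]
    cut <- sample(2:(nrow(g) - 1), 1)
    g$traj_id[cut:nrow(g)] <- max(obt$traj_id) + 1
    obt2 <- rbind(obt[obt$traj_id != vic, ], g)
    m1 <- with(list(a = associateTrajectories(obt2, tru)),
               tcfTff(a, obt2, tru))
    expect_lte(m1$tcf, m0$tcf + 1e-12)
    expect_gte(m1$tff, m0$tff - 1e-12)
    obt <- obt2; m0 <- m1
  }
})

test_that("identity switches are counted along obtained trajectories", {
  tru <- rbind(data.frame(frame = 1:20, id = 1, x = 0, y = 0),
               data.frame(frame = 1:20, id = 2, x = 100, y = 0))
  clean <- data.frame(frame = 1:20, traj_id = 1, x = 0, y = 0)
  expect_equal(countIdentitySwitches(clean, tru), 0)
  swapped <- clean
  swapped$x[11:20] <- 100
  expect_equal(countIdentitySwitches(swapped, tru), 1)
})
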