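mkTrial <- function(pos, dirDeg = 0, dist = 3, radius = 0.25, dt = 0.1,
                    mode = "hand") {
  CursorTrial(times = (seq_len(nrow(pos)) - 1) * dt, positions = pos,
              targetDirection = dirDeg, targetDistance = dist,
              targetRadius = radius, mode = mode, success = TRUE,
              timeout = 10)
}

test_that("path efficiency: straight, right-angle and bounded cases", {
  # axis-aligned straight path to a target at (3, 0): exactly 1
  straight <- mkTrial(cbind(0:3, 0))
  expect_identical(pathEfficiency(straight), 1)
  # two legs of a right isosceles triangle to the hypotenuse end
  legs <- mkTrial(cbind(c(0, 2, 2), c(0, 0, 2)), dirDeg = 45,
                  dist = sqrt(8))
  expect_equal(pathEfficiency(legs), sqrt(2) / 2)
  # any sampled path is at most 1
  set.seed(111)
  for (i in 1:20) {
    wob <- cbind(cumsum(runif(30, 0, 0.3)), rnorm(30, 0, 0.2))
    wob[1, ] <- c(0, 0); wob[30, ] <- c(3, 0)
    expect_lte(pathEfficiency(mkTrial(wob)), 1)
  }
})

test_that("path efficiency is invariant under rigid motions", {
  set.seed(112)
  pos <- cbind(cumsum(runif(20, 0, 0.3)), rnorm(20, 0, 0.1))
  pos[1, ] <- c(0, 0); pos[20, ] <- c(3, 0)
  t1 <- mkTrial(pos)
  ang <- 70 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  t2 <- mkTrial(t(R %*% t(pos)) + 5, dirDeg = 70)
  t2@positions <- t(R %*% t(pos)) + 5   # target rotated with the path
  # rotate the target too: rebuild with shifted origin
  tgt <- R %*% c(3, 0)
  t2 <- CursorTrial(t1@times, t(R %*% t(pos)),
                    targetDirection = 70, targetDistance = 3,
                    targetRadius = 0.25, mode = "hand", success = TRUE,
                    timeout = 10)
  expect_equal(pathEfficiency(t2), pathEfficiency(t1), tolerance = 1e-9)
})

test_that("time cost is the time of target acquisition", {
  pos <- cbind(seq(0, 3, length.out = 26), 0)   # reaches x = 3 at sample 26
  tr <- CursorTrial(times = (0:25) * 0.05, positions = pos,
                    targetDirection = 0, targetDistance = 3,
                    targetRadius = 0.12, mode = "hand", success = TRUE,
                    timeout = 10)
  expect_equal(timeCost(tr), 1.25)
  fail <- CursorTrial(times = c(0, 0.05), positions = cbind(c(0, 0.1), 0),
                      targetDirection = 0, mode = "hand", success = FALSE,
                      timeout = 10)
  expect_error(timeCost(fail))
  m <- taskMetrics(list(tr, fail))
  expect_true(is.na(m$time_cost[2]))
})

test_that("accuracy is successes over attempts, pooled consistently", {
  set.seed(113)
  trials <- genCursorTrials(40, noiseLevel = 0.9, speed = 4, seed = 113)
  acc <- taskAccuracy(trials)
  suc <- vapply(trials, function(t) t@success, logical(1))
  expect_equal(sum(acc$n_success), sum(suc))
  pooled <- sum(acc$accuracy * acc$n_attempts) / sum(acc$n_attempts)
  expect_equal(pooled, mean(suc))
  ten <- trials[1:10]
  a10 <- taskAccuracy(ten)
  expect_equal(sum(a10$n_success) / sum(a10$n_attempts),
               mean(vapply(ten, function(t) t@success, logical(1))))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhFdr(0.2), 0.2)
  set.seed(114)
  p <- runif(20)
  expect_true(all(bhFdr(p) >= p))
  expect_error(bhFdr(c(0.5, 1.7)))
})

test_that("Mann-Whitney p matches exact enumeration on tiny samples", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- suppressWarnings(wilcox.test(a, b)$p.value)
  expect_equal(got, 0.1)
  expect_equal(got, exactMannWhitneyP(a, b))
  set.seed(115)
  for (i in 1:5) {
    x <- round(rnorm(4), 2); y <- round(rnorm(4) + 0.5, 2)
    expect_equal(suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
                 exactMannWhitneyP(x, y), tolerance = 1e-9)
  }
})

test_that("mode comparison: null and extreme accuracy contrasts", {
  h <- genCursorTrials(40, noiseLevel = 0.3, seed = 116, mode = "hand")
  b <- genCursorTrials(40, noiseLevel = 0.3, seed = 116, mode = "brain")
  cmp <- compareModes(h, b, nBoot = 500, seed = 1)
  # identical trial sets: no metric can be significant
  expect_true(all(cmp$accuracy_p_adj > 0.5))
  expect_true(all(cmp$time_p_adj > 0.9, na.rm = TRUE))
  expect_true(all(cmp$path_p_adj > 0.9, na.rm = TRUE))

  # 0 of 20 versus 20 of 20 successes per direction
  mkSet <- function(success) lapply(rep(seq(0, 315, 45), length.out = 20),
    function(d) {
      pos <- if (success) cbind(seq(0, 7.5, length.out = 20) *
                                  cos(d * pi / 180),
                                seq(0, 7.5, length.out = 20) *
                                  sin(d * pi / 180))
             else cbind(seq(0, 0.5, length.out = 20), 0 * 1:20)
      CursorTrial((0:19) * 0.05, pos, d, mode = "hand", success = success,
                  timeout = 10)
    })
  cmp2 <- compareModes(mkSet(FALSE), mkSet(TRUE), nBoot = 2000, seed = 2)
  expect_true(all(cmp2$accuracy_p_adj < 0.01))
})

test_that("ridge decoder recovers an exact linear map and shrinks to zero", {
  set.seed(117)
  X <- matrix(rpois(400 * 6, 4), ncol = 6)
  W <- matrix(rnorm(12), ncol = 2)
  V <- X %*% W
  dec <- trainVelocityDecoder(X, V, lambda = 0)
  expect_equal(dec$weights, W, tolerance = 1e-8)
  pred <- predict(dec, X)
  expect_equal(pred, V, tolerance = 1e-8)
  big <- trainVelocityDecoder(X, V, lambda = 1e12)
  expect_lt(max(abs(big$weights)), 1e-6)
})

test_that("closed-loop control succeeds with a sane decoder, fails shuffled", {
  pop <- list(pref = seq(0, 315, 45), baseline = 5, modulation = 20)
  td <- genDecoderTrainingData(pop, nSamples = 1500, noiseless = TRUE,
                               seed = 118)
  dec <- trainVelocityDecoder(td$counts, td$velocities)
  ok <- simulateClosedLoop(dec, pop, seq(0, 315, 45), noiseless = TRUE,
                           seed = 1)
  expect_equal(mean(vapply(ok, function(t) t@success, logical(1))), 1)
  effs <- vapply(ok, pathEfficiency, numeric(1))
  expect_true(all(effs > 0.95))
  # decoded-direction error on noisy counts
  set.seed(119)
  dirs <- runif(200, 0, 360)
  lam <- outer(dirs, pop$pref, function(d, p)
    pop$baseline + pop$modulation * pmax(0, cos((d - p) * pi / 180))) * 0.05
  cnt <- matrix(rpois(length(lam), lam), nrow = 200)
  v <- predict(dec, cnt)
  err <- abs(((atan2(v[, 2], v[, 1]) * 180 / pi) - dirs + 180) %% 360 - 180)
  expect_lt(median(err), 30)

  shuf <- dec
  set.seed(120)
  shuf$weights <- dec$weights[sample(8), ]
  bad <- simulateClosedLoop(shuf, pop, rep(seq(0, 315, 45), 2),
                            noiseless = TRUE, seed = 2)
  expect_lt(mean(vapply(bad, function(t) t@success, logical(1))), 0.5)
  # determinism
  r1 <- simulateClosedLoop(dec, pop, c(0, 90), seed = 3)
  r2 <- simulateClosedLoop(dec, pop, c(0, 90), seed = 3)
  expect_identical(r1[[2]]@positions, r2[[2]]@positions)
})
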