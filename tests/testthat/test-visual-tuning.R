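mkTrials <- function(onsets, dur, cond) {
  tr <- emptyTrials()
  for (i in seq_along(onsets))
    tr[i, ] <- list(i, onsets[i], onsets[i] + dur, "orientation", cond[i],
                    NA_real_, NA_real_, NA_real_)
  tr
}

test_that("trial rates are counts over window length", {
  tr <- mkTrials(c(0, 1), 0.5, c(0, 90))
  st <- c(0.1, 0.2, 0.25, 0.3, 0.45, 1.2)
  expect_equal(trialRates(st, tr), c(10, 2))
  expect_equal(trialRates(numeric(0), tr), c(0, 0))
  # additivity over disjoint windows
  r1 <- trialRates(st, tr, window = c(0, 0.25)) * 0.25
  r2 <- trialRates(st, tr, window = c(0.25, 0.5)) * 0.25
  expect_equal(r1 + r2, trialRates(st, tr) * 0.5)
})

test_that("tuning curves normalize by the most active orientation", {
  r <- c(2, 2, 8, 8, 4, 4)
  o <- c(0, 0, 45, 45, 90, 90)
  cv <- orientationCurve(r, o)
  expect_equal(cv$normalized, c(0.25, 1, 0.5))
  expect_equal(max(cv$normalized), 1)
  expect_equal(cv$sem, c(0, 0, 0))
  flat <- orientationCurve(rep(3, 6), o)
  expect_equal(flat$normalized, rep(1, 3))
  expect_warning(orientationCurve(c(1, 2), c(0, 90)), "SEM")
  expect_error(orientationCurve(c(1, 2), c(0, 0)), "2 orientations")
})

test_that("OSI spans its limits and its 0.3 gate boundary", {
  cv <- function(rates) {
    out <- data.frame(condition = seq(0, 157.5, 22.5), mean_rate = rates)
    out
  }
  oneHot <- rep(0, 8); oneHot[1] <- 5
  expect_equal(osi(cv(oneHot)), 1)
  expect_equal(osi(cv(rep(4, 8))), 0)
  # Rpref = 6.5, Rorth = 3.5 -> OSI exactly 0.3, failing the strict gate
  r <- rep(3.5, 8); r[1] <- 6.5
  expect_equal(osi(cv(r)), 0.3)
  expect_false(osi(cv(r)) > 0.3)
  # bounded in [0, 1] for non-negative rates
  set.seed(81)
  for (i in 1:50) {
    v <- osi(cv(runif(8, 0, 20)))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("preferred orientation: vector sum, undefined cases, equivariance", {
  grid <- seq(0, 157.5, 22.5)
  one <- data.frame(condition = grid, mean_rate = c(0, 5, rep(0, 6)))
  expect_equal(preferredOrientation(one), 22.5)
  two <- data.frame(condition = grid,
                    mean_rate = c(4, 0, 0, 0, 4, 0, 0, 0))
  expect_true(is.na(preferredOrientation(two)))   # 0 and 90: zero vector
  expect_true(is.na(preferredOrientation(
    data.frame(condition = grid, mean_rate = rep(0, 8)))))
  base <- data.frame(condition = grid,
                     mean_rate = 2 + exp(2 * (cos(2 * (grid - 60) *
                                                    pi / 180) - 1)))
  p0 <- preferredOrientation(base)
  rot <- base; rot$condition <- (rot$condition + 40) %% 180
  expect_equal((preferredOrientation(rot) - p0) %% 180, 40,
               tolerance = 1e-9)
})

test_that("von Mises units are recovered near their true preference", {
  g <- genOrientationSession(nUnits = 4, nTrialsPerOrientation = 15,
                             seed = 82)
  tt <- trials(g$session)
  for (i in seq_along(units(g$session))) {
    r <- trialRates(spikeTimes(units(g$session)[[i]]), tt)
    cv <- orientationCurve(r[tt$condition_type == "orientation"],
                           tt$condition)
    est <- preferredOrientation(cv)
    err <- abs(est - g$truth$pref_orientation[i]) %% 180
    err <- min(err, 180 - err)
    expect_lt(err, 22.5)
  }
})

test_that("RF maps localize a spatial Gaussian response", {
  g <- genRfSession(nUnits = 2, nTrialsPerLoc = 10, seed = 83)
  tt <- trials(g$session)
  for (i in 1:2) {
    m <- rfMap(spikeTimes(units(g$session)[[i]]), tt)
    truthRate <- g$truth$amplitude[i] *
      exp(-((m$x - g$truth$center_x[i])^2 +
              (m$y - g$truth$center_y[i])^2) / (2 * g$truth$sigma[i]^2))
    expect_gt(cor(m$rate, truthRate), 0.9)
  }
  # an unresponsive unit maps to approximately zero everywhere
  set.seed(84)
  flat <- poissonTrain(3, sessionDuration(g$session))
  m0 <- rfMap(flat, tt)
  expect_lt(max(abs(m0$rate)), 5)   # ~3.5 SE of a 3 Hz baseline estimate
})

test_that("Gaussian RF fits recover center, size and eccentricity exactly", {
  grid <- expand.grid(x = seq(-2, 8, 1), y = seq(-7, 3, 1))
  grid$rate <- 20 * exp(-((grid$x - 3)^2 + (grid$y + 2)^2) / (2 * 0.8^2))
  f <- rfFit(grid)
  expect_true(f$fitOk)
  expect_lt(sqrt(sum((f$center - c(3, -2))^2)), 0.1)
  expect_equal(f$size, 1.6, tolerance = 1e-4)
  expect_equal(f$eccentricity, sqrt(13), tolerance = 1e-4)
  # isotropic scaling of the grid scales the size estimate linearly
  k <- 2.5
  g2 <- grid; g2$x <- k * g2$x; g2$y <- k * g2$y
  f2 <- rfFit(g2)
  expect_equal(f2$size, k * f$size, tolerance = 1e-3)
  # degenerate grids are flagged
  flat <- grid; flat$rate <- 0
  expect_false(rfFit(flat)$fitOk)
})

test_that("depth model recovers a common slope and flags singular fits", {
  set.seed(85)
  depths <- rep(seq(0.1, 1.2, length.out = 12), 4)
  shank <- rep(c("A", "B", "C", "D"), each = 12)
  sizes <- 0.8 + 0.9 * depths          # one exact slope, no noise
  m <- rfDepthModel(sizes, depths, shank)
  expect_equal(m$slope, 0.9, tolerance = 1e-6)
  expect_true(m$singular)              # no between-shank variance
  expect_error(rfDepthModel(sizes, depths, rep("A", 48)), "2 shanks")
})

test_that("depth model detects a positive depth trend in noisy data", {
  set.seed(86)
  nPer <- 15
  shank <- rep(paste0("s", 1:6), each = nPer)
  depths <- rep(seq(0.1, 1.5, length.out = nPer), 6)
  slopes <- 0.6 + rnorm(6, 0, 0.15)
  sizes <- unlist(lapply(1:6, function(k)
    0.5 + rnorm(1, 0, 0.1) + slopes[k] * depths[shank == paste0("s", k)] +
      rnorm(nPer, 0, 0.15)))
  m <- rfDepthModel(sizes, depths, shank)
  expect_lt(abs(m$slope - 0.6), 0.25)
  expect_lt(m$p, 0.05)
  expect_true(m$ci[1] < 0.6 && m$ci[2] > 0.6)
})
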