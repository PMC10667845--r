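test_that("orientation generator hits its target rate at the preferred angle", {
  # b=2, a=18: lambda at the preferred orientation is exactly b + a = 20 Hz
  nTr <- 50
  g <- genOrientationSession(nUnits = 1, orientations = c(0, 90),
                             nTrialsPerOrientation = nTr, trialDur = 1,
                             params = list(baseline = 2, amplitude = 18,
                                           kappa = 2, prefOrientation = 0),
                             seed = 21)
  tt <- trials(g$session)
  r <- trialRates(spikeTimes(units(g$session)[[1]]), tt)
  atPref <- r[tt$condition == 0]
  se <- sqrt(20 / nTr)                     # Poisson SE of the mean rate
  expect_lt(abs(mean(atPref) - 20), 3 * se)
})

test_that("kappa -> 0 removes orientation tuning", {
  g <- genOrientationSession(nUnits = 1, orientations = seq(0, 157.5, 22.5),
                             nTrialsPerOrientation = 25, trialDur = 1,
                             params = list(baseline = 2, amplitude = 18,
                                           kappa = 0, prefOrientation = 30),
                             seed = 22)
  tt <- trials(g$session)
  r <- trialRates(spikeTimes(units(g$session)[[1]]), tt)
  cv <- orientationCurve(r, tt$condition)
  # every condition has expectation b + a = 20 Hz
  se <- sqrt(20 / 25)
  expect_true(all(abs(cv$mean_rate - 20) < 4 * se))
})

test_that("coupled-pair excess coincidences match the thinning expectation", {
  p <- 0.3
  pr <- genCoupledPair(rateLeader = 10, rateFollowerBase = 0, p = p,
                       lagMs = 2, jitterMs = 0, duration = 600, seed = 31)
  cc <- ccg(pr$leader, pr$follower)
  expected <- p * length(pr$leader)
  inPeak <- cc$counts[cc$lags == 2]
  expect_lt(abs(inPeak - expected), 3 * sqrt(expected))
})

test_that("p = 1, no jitter, no base rate makes the follower a pure shift", {
  pr <- genCoupledPair(rateLeader = 5, rateFollowerBase = 0, p = 1,
                       lagMs = 3, jitterMs = 0, duration = 60, seed = 32)
  expect_equal(pr$follower, pr$leader + 0.003)
})

test_that("p = 0 gives a flat CCG at the Poisson chance level", {
  pr <- genCoupledPair(rateLeader = 10, rateFollowerBase = 10, p = 0,
                       duration = 600, seed = 33)
  cc <- ccg(pr$leader, pr$follower)
  chance <- length(pr$leader) * length(pr$follower) * 0.0004 / 600
  expect_true(all(abs(cc$counts - chance) < 5 * sqrt(chance)))
})

test_that("noiseless raw traces are zero outside template windows", {
  tpl <- biphasicTemplate(20000, 80)
  tr <- genRawTrace(list(list(spikeTimes = c(0.05, 0.10), template = tpl,
                              channel = 1)),
                    duration = 0.2, samplingRate = 20000, noiseSd = 0,
                    seed = 1)
  expect_identical(nrow(tr), 1L)
  nz <- which(tr[1, ] != 0)
  expect_true(all(abs(nz - 0.05 * 20000) < 40 | abs(nz - 0.10 * 20000) < 40))
  expect_gt(length(nz), 0)
})

test_that("generators are pure functions of (params, seed)", {
  a <- genOrientationSession(nUnits = 2, nTrialsPerOrientation = 2, seed = 9)
  b <- genOrientationSession(nUnits = 2, nTrialsPerOrientation = 2, seed = 9)
  expect_identical(spikeTimes(units(a$session)[[2]]),
                   spikeTimes(units(b$session)[[2]]))
  c1 <- genCursorTrials(5, seed = 4)
  c2 <- genCursorTrials(5, seed = 4)
  expect_identical(c1[[3]]@positions, c2[[3]]@positions)
  # generators do not disturb the global RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(genCoupledPair(seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("adding units never perturbs existing units' spikes", {
  a <- genOrientationSession(nUnits = 2, nTrialsPerOrientation = 3,
                             params = list(baseline = 2, amplitude = 18,
                                           kappa = 2, prefOrientation = 10),
                             seed = 13)
  b <- genOrientationSession(nUnits = 4, nTrialsPerOrientation = 3,
                             params = list(baseline = 2, amplitude = 18,
                                           kappa = 2, prefOrientation = 10),
                             seed = 13)
  expect_identical(spikeTimes(units(a$session)[[1]]),
                   spikeTimes(units(b$session)[[1]]))
})

test_that("noise-free cursor trials fly straight; heavy noise causes misses", {
  straight <- genCursorTrials(8, noiseLevel = 0, seed = 2)
  for (t in straight) {
    expect_true(t@success)
    expect_equal(pathEfficiency(t), 1, tolerance = 1e-12)
  }
  noisy <- genCursorTrials(60, noiseLevel = 2.2, speed = 3, seed = 2)
  acc <- mean(vapply(noisy, function(t) t@success, logical(1)))
  expect_lt(acc, 1)
})

test_that("multisession drift scales the template as specified", {
  tpl <- biphasicTemplate()
  ms <- genMultisessionDrift(tpl, nSessions = 3, driftPerSession = 0.5,
                             noiseSd = 0, nSnippets = 5, seed = 1)
  expect_equal(colMeans(ms[[1]]), tpl)
  expect_equal(colMeans(ms[[3]]), 2 * tpl)
})
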