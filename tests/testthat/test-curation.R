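test_that("firing rate and its strict acceptance boundary", {
  expect_identical(firingRate(numeric(0), 600), 0)
  expect_equal(firingRate(seq_len(30), 600), 0.05)
  expect_equal(firingRate(seq_len(31), 600), 31 / 600)
  # exactly 0.05 Hz fails the strict > 0.05 gate; one more spike passes
  set.seed(50)
  u30 <- SortedUnit("at", sort(runif(30, 0, 600)))
  u31 <- SortedUnit("above", sort(runif(31, 0, 600)))
  rep <- curateUnits(list(u30, u31), 600)
  expect_false(rep$accepted[1])
  expect_match(rep$reasons[1], "firing_rate")
  expect_true(rep$accepted[2])
})

test_that("ISI violation fraction counts short intervals over spikes", {
  # times 0, 1.0, 10 ms: ISIs {1.0, 9.0}, one violation, three spikes
  expect_equal(isiViolationFraction(c(0, 0.001, 0.010)), 1 / 3)
  expect_equal(isiViolationFraction(c(0, 0.001, 0.010),
                                    denominator = "isis"), 1 / 2)
  expect_identical(isiViolationFraction(0.5), 0)
  expect_identical(isiViolationFraction(numeric(0)), 0)
})

test_that("Poisson trains violate at the exponential-law rate", {
  set.seed(51)
  st <- poissonTrain(50, 600)
  expected <- 1 - exp(-50 * 0.0016)   # P(ISI < 1.6 ms) at 50 Hz
  n <- length(st)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(isiViolationFraction(st) - expected), 3 * se)
})

test_that("peak-to-trough amplitude", {
  expect_equal(peakToTrough(c(-60, 0, 25)), 85)
  expect_equal(peakToTrough(rep(3, 10)), 0)
  w <- biphasicTemplate()
  expect_equal(peakToTrough(3 * w), 3 * peakToTrough(w))
})

test_that("SNR converges to template amplitude over twice the noise SD", {
  set.seed(52)
  tpl <- biphasicTemplate(20000, 60 / peakToTrough(biphasicTemplate(20000, 1)))
  expect_equal(peakToTrough(tpl), 60)
  snips <- sweep(matrix(rnorm(1000 * 32, 0, 10), ncol = 32), 2, tpl, "+")
  expect_lt(abs(waveformSnr(snips) - 3) / 3, 0.05)
  expect_identical(waveformSnr(rbind(tpl, tpl)), Inf)
  # pure noise: SNR shrinks toward 0 as the mean waveform flattens
  noise <- matrix(rnorm(2000 * 32, 0, 10), ncol = 32)
  expect_lt(waveformSnr(noise), 0.5)
})

test_that("GESD flags a single gross outlier snippet and only it", {
  set.seed(53)
  tpl <- biphasicTemplate()
  snips <- sweep(matrix(rnorm(100 * 32, 0, 3), ncol = 32), 2, tpl, "+")
  snips <- rbind(snips, 10 * tpl)
  out <- gesdOutliers(snips)
  expect_identical(out, 101L)
})

test_that("GESD keeps homogeneous snippet sets intact (null behavior)", {
  set.seed(54)
  falseAlarms <- vapply(1:40, function(i) {
    snips <- matrix(rnorm(60 * 16), ncol = 16)
    length(gesdOutliers(snips)) > 0
  }, logical(1))
  expect_lte(mean(falseAlarms), 0.15)
  expect_warning(gesdOutliers(matrix(rnorm(5 * 16), ncol = 16)), "skipped")
})

test_that("GESD matches the literal Rosner oracle on scalar sets", {
  # the Rosner 1983 benchmark pattern: mostly normal scalars with gross
  # contamination flags exactly the contaminated values
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(15:50, 1)
    x <- rnorm(n)
    nOut <- sample(0:3, 1)
    if (nOut) x[seq_len(nOut)] <- x[seq_len(nOut)] + 6 + 2 * seq_len(nOut)
    maxOut <- max(1L, floor(n * 0.2))
    got <- gesdTest(x, alpha = 0.05, maxOutliers = maxOut)
    want <- rosnerOracle(x, alpha = 0.05, maxOutliers = maxOut)
    expect_identical(sort(got), sort(want))
  }
})

test_that("curation gates fire individually and report their reasons", {
  set.seed(56)
  dur <- 600
  tpl <- biphasicTemplate()
  goodTimes <- seq(1, 599, by = 0.7)
  mkUnit <- function(id, times, noiseSd) {
    snips <- sweep(matrix(rnorm(length(times) * 32, 0, noiseSd), ncol = 32),
                   2, tpl, "+")
    SortedUnit(id, times, 1L, snips)
  }
  okUnit <- mkUnit("ok", goodTimes, 5)
  lowSnr <- mkUnit("lowsnr", goodTimes, 60)
  burst <- mkUnit("burst", sort(c(goodTimes, goodTimes + 0.001)), 5)
  rep <- curateUnits(list(okUnit, lowSnr, burst), dur)
  expect_true(rep$accepted[rep$unit_id == "ok"])
  expect_identical(rep$reasons[rep$unit_id == "lowsnr"], "snr")
  expect_match(rep$reasons[rep$unit_id == "burst"], "isi_violation")
  # external metrics gate only when supplied
  ext <- SortedUnit("ext", goodTimes, 1L,
                    waveforms(okUnit), isolation = 0.90,
                    noiseOverlap = 0.01)
  rep2 <- curateUnits(list(ext), dur)
  expect_identical(rep2$reasons, "isolation")
})

test_that("relaxing thresholds never shrinks the accepted set", {
  set.seed(57)
  dur <- 300
  unitsList <- lapply(1:12, function(i) {
    n <- sample(c(10, 40, 400), 1)
    tpl <- biphasicTemplate(20000, sample(c(20, 80), 1))
    times <- sort(runif(n, 0, dur))
    times <- unique(round(times, 4))
    snips <- sweep(matrix(rnorm(length(times) * 32, 0, 8), ncol = 32),
                   2, tpl, "+")
    SortedUnit(paste0("u", i), times, 1L, snips)
  })
  strict <- curateUnits(unitsList, dur)
  lax <- curateUnits(unitsList, dur,
                     criteria = list(minFiringRate = 0.01, minSnr = 0.5,
                                     maxIsiViolation = 0.10))
  expect_true(all(lax$accepted[strict$accepted]))
})

test_that("duplicate units merge only within the adjacency radius", {
  set.seed(58)
  st <- poissonTrain(5, 100)
  near <- data.frame(channel_id = c(1L, 2L), x = 0, y = c(0, 60))
  far <- data.frame(channel_id = c(1L, 2L), x = 0, y = c(0, 150))
  dup <- list(SortedUnit("a", st, 1L), SortedUnit("b", st, 2L))
  expect_length(mergeDuplicateUnits(dup, near), 1L)
  expect_length(mergeDuplicateUnits(dup, far), 2L)   # outside 100 um
  indep <- list(SortedUnit("a", st, 1L),
                SortedUnit("b", poissonTrain(5, 100), 2L))
  expect_length(mergeDuplicateUnits(indep, near), 2L)
})
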