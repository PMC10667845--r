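fs <- 20000
rms <- function(x) sqrt(mean(x^2))

test_that("the 50 Hz notch removes mains and spares the passband", {
  t <- seq(0, 2, by = 1 / fs)
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(rms(notchFilter(s50, fs)) / rms(s50), 0.01)
  s10 <- sin(2 * pi * 10 * t)
  expect_lt(abs(rms(notchFilter(s10, fs)) / rms(s10) - 1), 0.05)
  for (f in c(40, 60))   # passband within 1% at notch +/- 10 Hz
    expect_lt(abs(rms(notchFilter(sin(2 * pi * f * t), fs)) /
                    rms(sin(2 * pi * f * t)) - 1), 0.01)
  dc <- rep(2.5, length(t))
  expect_lt(max(abs(notchFilter(dc, fs) - 2.5)), 0.01)
  expect_error(notchFilter(s50, fs, freq = fs), "Nyquist")
})

test_that("band-pass filtering suppresses out-of-band power (zero phase)", {
  set.seed(7)
  wn <- rnorm(2^16)
  bp <- bandpassFilter(wn, fs, 300, 9000)
  sp0 <- spec.pgram(ts(wn, frequency = fs), plot = FALSE)
  sp1 <- spec.pgram(ts(bp, frequency = fs), plot = FALSE)
  lowReduction <- 10 * log10(mean(sp0$spec[sp0$freq < 100]) /
                               mean(sp1$spec[sp1$freq < 100]))
  expect_gt(lowReduction, 20)
  # zero-phase: impulse response is symmetric
  imp <- numeric(4001); imp[2001] <- 1
  h <- bandpassFilter(imp, 1000, 30, 200)
  expect_lt(max(abs(h - rev(h))), 1e-10)
  # LFP band (0.3-300 Hz) runs without degenerate output
  lf <- bandpassFilter(wn[1:40000], fs, 0.3, 300)
  expect_true(all(is.finite(lf)))
  expect_lt(rms(lf), rms(wn[1:40000]))
  expect_error(bandpassFilter(wn, fs, 300, fs), "edges")
})

test_that("filters are linear operators", {
  set.seed(8)
  x <- rnorm(5000); y <- rnorm(5000)
  fx <- bandpassFilter(x, fs, 500, 5000)
  fy <- bandpassFilter(y, fs, 500, 5000)
  fxy <- bandpassFilter(2 * x - 3 * y, fs, 500, 5000)
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
})

test_that("common median reference subtracts the per-sample median", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
  expect_equal(commonMedianReference(m),
               matrix(c(-2, -2, 0, 0, 2, 2), nrow = 3, byrow = TRUE))
  same <- matrix(rep(rnorm(100), each = 4), nrow = 4)
  expect_equal(commonMedianReference(same), matrix(0, 4, 100),
               ignore_attr = TRUE)
  set.seed(3)
  r <- commonMedianReference(matrix(rnorm(500), nrow = 5))
  expect_equal(apply(r, 2, median), rep(0, 100))
  expect_warning(commonMedianReference(matrix(1:4, nrow = 1)), "2 channels")
})

test_that("artifact blanking zeroes exactly the offending 0.1 s chunks", {
  set.seed(9)
  clean <- rnorm(2 * fs)   # 2 s of Gaussian noise: no sample reaches 6 SD
  r0 <- removeArtifacts(clean, fs)
  expect_identical(nrow(r0$intervals), 0L)
  expect_identical(r0$trace, clean)

  pulse <- clean
  pulse[25000] <- 100   # 100 SD outlier at t = 1.25 s
  r1 <- removeArtifacts(pulse, fs)
  expect_identical(nrow(r1$intervals), 1L)
  expect_true(r1$intervals$start <= 25000 / fs &
                r1$intervals$end >= 25000 / fs)
  blanked <- seq(r1$intervals$start * fs + 1, r1$intervals$end * fs)
  expect_true(all(r1$trace[blanked] == 0))
  expect_identical(r1$trace[-blanked], pulse[-blanked])

  z <- numeric(1000)
  rz <- removeArtifacts(z, fs)
  expect_identical(rz$trace, z)
})

test_that("artifact blanking is idempotent", {
  set.seed(10)
  x <- rnorm(2 * fs)
  x[c(10000, 30000)] <- c(80, -120)
  r1 <- removeArtifacts(x, fs)
  expect_identical(nrow(r1$intervals), 2L)
  r2 <- removeArtifacts(r1$trace, fs)
  expect_identical(r2$trace, r1$trace)
  expect_identical(nrow(r2$intervals), 0L)   # nothing left to blank
})

test_that("spike detection finds inserted templates at absolute threshold", {
  tpl <- biphasicTemplate(fs, 90)   # -90 uV trough
  truth <- seq(0.05, 9.95, length.out = 200)
  tr <- genRawTrace(list(list(spikeTimes = truth, template = tpl,
                              channel = 1)),
                    duration = 10, samplingRate = fs, noiseSd = 5,
                    seed = 41)[1, ]
  ev <- detectSpikes(tr, fs, mode = "absolute", threshold = -70)
  expect_identical(length(ev), 200L)
  err <- vapply(truth, function(t) min(abs(ev - t)), numeric(1))
  expect_true(all(err <= 1.5 / fs))
})

test_that("flat traces yield no events; sd mode ignores DC offsets", {
  expect_identical(detectSpikes(numeric(1000), fs), numeric(0))
  tpl <- biphasicTemplate(fs, 90)
  truth <- seq(0.05, 1.95, length.out = 40)
  tr <- genRawTrace(list(list(spikeTimes = truth, template = tpl,
                              channel = 1)),
                    duration = 2, samplingRate = fs, noiseSd = 6,
                    seed = 42)[1, ]
  e1 <- detectSpikes(tr, fs, mode = "sd", threshold = 4.5)
  e2 <- detectSpikes(tr + 50, fs, mode = "sd", threshold = 4.5)
  expect_identical(e1, e2)
  expect_error(detectSpikes(tr, fs, mode = "sd", threshold = -1), "> 0")
})

test_that("waveform extraction uses the 0.4 + 1.2 ms window", {
  # 32 samples at 20 kHz
  tpl <- biphasicTemplate(fs, 90)
  expect_identical(length(tpl), 32L)
  tr <- genRawTrace(list(list(spikeTimes = c(0.0001, 0.05, 0.0998),
                              template = tpl, channel = 1)),
                    duration = 0.1, samplingRate = fs, noiseSd = 0,
                    seed = 1)[1, ]
  w <- extractWaveforms(tr, fs, c(0.0001, 0.05, 0.0998))
  expect_identical(ncol(w$snippets), 32L)
  # events at the very edges are dropped and reported
  expect_identical(w$times, 0.05)
  expect_identical(sort(w$dropped), c(0.0001, 0.0998))
  # noiseless insertion is recovered exactly
  expect_equal(as.numeric(w$snippets[1, ]), tpl, tolerance = 1e-12)
})

test_that("binned spike counts conserve the total", {
  expect_identical(binnedSpikeCounts(c(0.1, 0.2, 0.3), bin = 1,
                                     duration = 1), 3L)
  expect_identical(binnedSpikeCounts(numeric(0), bin = 0.1, duration = 1),
                   rep(0L, 10))
  set.seed(11)
  st <- sort(runif(500, 0, 60))
  expect_identical(sum(binnedSpikeCounts(st, 0.05, 60)), 500L)
})
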