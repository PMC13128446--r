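test_that("preprocessing passes slow components and rejects fast ones", {
  fs <- 400
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.05 * tt)
  fast <- sin(2 * pi * 50 * tt)
  rec <- PhotometryRecording(slow + fast, slow, fs = fs, time = tt,
                             baselineWindow = c(0, 60), injectionTime = 60)
  out <- preprocessRecording(rec)
  expect_equal(out@fs, 40)
  # 0.05 Hz sinusoid passes with < 1% amplitude loss
  mid <- out@time > 20 & out@time < 100  # avoid filter edges
  ref <- sin(2 * pi * 0.05 * out@time[mid])
  expect_lt(max(abs(out@f405[mid] - ref)), 0.01)
  # 50 Hz tone attenuated > 90%
  expect_lt(max(abs(out@f465[mid] - ref)), 0.1)
  # constant trace unchanged
  recC <- PhotometryRecording(rep(2, length(tt)), rep(1, length(tt)),
                              fs = fs, time = tt,
                              baselineWindow = c(0, 60),
                              injectionTime = 60)
  outC <- preprocessRecording(recC)
  expect_equal(outC@f465, rep(2, length(outC@time)), tolerance = 1e-10)
  # precondition checks
  expect_error(preprocessRecording(rec, cutoffHz = 30), "20x")
  expect_error(preprocessRecording(rec, factor = 25L), "Nyquist")
})

test_that("baseline rescaling recovers affine channel relations exactly", {
  fs <- 50
  tt <- seq(0, 200 - 1 / fs, by = 1 / fs)
  shared <- exp(-tt / 500) + 0.02 * sin(2 * pi * tt / 60)
  # identical channels: F0 equals the signal, dF/F is 0
  rec1 <- PhotometryRecording(shared, shared, fs = fs, time = tt,
                              baselineWindow = c(0, 100),
                              injectionTime = 100)
  f0 <- fitBaseline(rec1)
  expect_equal(f0, shared, tolerance = 1e-10)
  expect_lt(max(abs(computeDff(shared, f0))), 1e-10)
  # signal = 2 * isosbestic + 1: the affine map recovers it
  rec2 <- PhotometryRecording(2 * shared + 1, shared, fs = fs, time = tt,
                              baselineWindow = c(0, 100),
                              injectionTime = 100)
  f02 <- fitBaseline(rec2)
  expect_lt(max(abs(computeDff(rec2@f465, f02))), 1e-10)
  # bumps outside the baseline window do not bias F0
  bump <- 0.5 * exp(-(tt - 150)^2 / 8)
  rec3 <- PhotometryRecording(2 * shared + 1 + bump, shared, fs = fs,
                              time = tt, baselineWindow = c(0, 100),
                              injectionTime = 100)
  f03 <- fitBaseline(rec3)
  expect_equal(f03, f02, tolerance = 1e-10)
  # degenerate isosbestic with non-constant signal is an error
  rec4 <- PhotometryRecording(shared, rep(1, length(tt)), fs = fs,
                              time = tt, baselineWindow = c(0, 100),
                              injectionTime = 100)
  expect_error(fitBaseline(rec4), "degenerate")
})

test_that("dF/F is the pointwise fractional change with F0 masking", {
  expect_equal(computeDff(1.0, 1.0), 0)
  expect_equal(computeDff(2.0, 1.0), 1.0)
  expect_equal(computeDff(1.1, 1.0), 0.1)
  expect_warning(out <- computeDff(c(1, 2), c(1, 0)), "masked")
  expect_true(is.na(out[2]))
})

test_that("the prominence threshold is the baseline median plus k MADs", {
  set.seed(21)
  sigma <- 0.01
  noise <- rnorm(120 * 40, 0, sigma)  # 120 s at 40 Hz
  thr <- setTransientThreshold(noise, fs = 40)
  expect_equal(thr, median(noise) + 2.5 * mad(noise))
  # for Gaussian noise, approximately 2.5 * 1.4826 * sigma above median
  expect_equal(thr - median(noise), 2.5 * 1.4826 * sigma,
               tolerance = 0.05)
  # scale equivariance: doubling the trace doubles the threshold
  expect_equal(setTransientThreshold(2 * noise, fs = 40), 2 * thr)
  # determinism
  expect_identical(setTransientThreshold(noise, fs = 40), thr)
  expect_error(setTransientThreshold(noise[1:100], fs = 40), "60 s")
})

test_that("transient detection finds injected bumps and ignores sub-threshold ones", {
  fs <- 40
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  thr <- 0.05
  centers <- c(60, 150, 240)
  dff <- rowSums(vapply(centers, function(m)
    2 * thr * exp(-(tt - m)^2 / (2 * 1.5^2)), numeric(length(tt))))
  ts <- detectTransients(dff, thr, time = tt)
  ev <- transients(ts)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peak_time_s, centers, tolerance = 0.05)
  expect_true(all(ev$amplitude >= thr))
  # amplitude is the prominence; isolated bump prominence equals height
  expect_equal(ev$amplitude, rep(2 * thr, 3), tolerance = 1e-3)
  # duration is the full width at half prominence of a Gaussian bump
  expect_equal(ev$duration_s, rep(2 * sqrt(2 * log(2)) * 1.5, 3),
               tolerance = 0.05)
  # frequency in events per minute over the analysis window
  expect_equal(ts@frequencyPerMin, 3 / (300 / 60), tolerance = 1e-3)
  # a bump at half the threshold is not detected
  small <- 0.5 * thr * exp(-(tt - 150)^2 / (2 * 1.5^2))
  expect_equal(nrow(transients(detectTransients(small, thr, time = tt))),
               0)
  # a flat trace has no events
  expect_equal(nrow(transients(detectTransients(rep(0, 100), thr,
                                                fs = 40))), 0)
  expect_error(detectTransients(numeric(0), thr, fs = 40), "empty")
})

test_that("slow AUC is the rectangle value on constant traces and additive over bins", {
  fs <- 10
  tt <- seq(0, 900 - 1 / fs, by = 1 / fs)
  auc <- slowAuc(rep(0.2, length(tt)), fs = fs, time = tt)
  # dff == c over a 5-min bin integrates to c * 300
  expect_equal(auc$auc[1], 0.2 * 300, tolerance = 1e-6)
  expect_equal(nrow(auc), 3)
  # additivity: two adjacent bins sum to the AUC over their union
  dff <- 0.1 + 0.05 * sin(2 * pi * tt / 700)
  a5 <- slowAuc(dff, fs = fs, time = tt, binSec = 300)
  a10 <- slowAuc(dff, fs = fs, time = tt, binSec = 600)
  expect_equal(a5$auc[1] + a5$auc[2], a10$auc[1], tolerance = 1e-9)
  # linearity in dff
  a2 <- slowAuc(2 * dff, fs = fs, time = tt, binSec = 300)
  expect_equal(a2$auc, 2 * a5$auc, tolerance = 1e-9)
  # a zero-mean fast oscillation is suppressed by the 0.1 Hz filter
  fast <- 0.3 * sin(2 * pi * 1 * tt)
  af <- slowAuc(fast, fs = fs, time = tt)
  expect_lt(max(abs(af$auc)), 0.3 * 300 * 0.01)
})

test_that("thresholds fixed per animal give reproducible transient sets", {
  sim <- simulatePhotometry(5, durationSec = 900, baselineSec = 300,
                            transientTimes = seq(330, 870, by = 90))
  rec <- preprocessRecording(sim$rec)
  f0 <- fitBaseline(rec)
  dff <- computeDff(rec@f465, f0)
  ib <- rec@time <= 300
  thr <- setTransientThreshold(dff[ib], rec@fs)
  t1 <- detectTransients(dff, thr, time = rec@time)
  t2 <- detectTransients(dff, thr, time = rec@time)
  expect_identical(transients(t1), transients(t2))
})
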