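test_that("the ECG filter chain meets its band specification", {
  expect_gt(tone_attenuation_db(50), 87)    # notch: -90 dB within 3 dB
  expect_gt(tone_attenuation_db(0.5), 40)   # baseline drift
  for (f in c(5, 10, 20)) {                 # passband unity within 0.1x
    expect_lt(abs(tone_attenuation_db(f)), 20 * log10(1 / 0.9))
  }
  expect_gt(tone_attenuation_db(30), 40)    # myoelectric band
  # group delay compensated: cross-correlation peak at lag 0
  tt <- (0:3999) / 200
  x <- sin(2 * pi * 10 * tt)
  y <- filter_ecg(bio_signal(x, 200, kind = "ecg"))$value
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # zero in, zero out; fs mismatch rejected
  expect_equal(max(abs(filter_ecg(bio_signal(rep(0, 500), 200,
                                             kind = "ecg"))$value)), 0)
  expect_error(filter_ecg(bio_signal(rnorm(100), 100, kind = "ecg")),
               "sampling rate")
})

test_that("filtering is linear", {
  set.seed(21)
  x <- rnorm(1000); y <- rnorm(1000)
  fx <- filter_ecg(bio_signal(x, 200, kind = "ecg"))$value
  fy <- filter_ecg(bio_signal(y, 200, kind = "ecg"))$value
  fxy <- filter_ecg(bio_signal(2 * x - 3 * y, 200, kind = "ecg"))$value
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)
})

test_that("R peaks are the per-cycle maxima with the stated tie-break", {
  fs <- 200
  v <- rep(0, 10 * fs)
  at <- seq(1, 9, by = 1) * fs
  v[at] <- 1
  tm <- detect_r_peaks(bio_signal(v, fs, kind = "ecg"))
  expect_equal(nrow(tm), 9L)
  expect_equal(unique(round(tm$rr[-1], 6)), 1)
  # one short beat: RR = 0.87 s reported
  v2 <- rep(0, 10 * fs)
  beats <- cumsum(c(1, 1, 0.87, 1, 1))
  v2[round(beats * fs)] <- 1
  tm2 <- detect_r_peaks(bio_signal(v2, fs, kind = "ecg"))
  expect_true(any(abs(tm2$rr - 0.87) < 1e-6, na.rm = TRUE))
  # two equal maxima 50 ms apart: the earlier is kept
  v3 <- rep(0, 3 * fs)
  v3[fs] <- 1; v3[fs + 10] <- 1
  tm3 <- detect_r_peaks(bio_signal(v3, fs, kind = "ecg"))
  expect_equal(nrow(tm3), 1L)
  expect_equal(tm3$t_peak, (fs - 1) / fs)
  expect_warning(detect_r_peaks(bio_signal(rep(0.5, 400), fs, kind = "ecg")),
                 "flat")
})

test_that("PPG normalisation is the affine map onto [0, 1]", {
  r <- normalize_ppg(bio_signal(seq(2, 4, length.out = 100), 200))
  expect_equal(range(r$value), c(0, 1))
  expect_equal(normalize_ppg(r)$value, r$value)  # idempotent
  s <- bio_signal(10 + 3 * sin(2 * pi * (0:199) / 50), 200)
  ns <- normalize_ppg(s)
  expect_equal(min(ns$value), 0)
  expect_equal(max(ns$value), 1)
  expect_equal(cor(ns$value, s$value), 1)
  expect_error(normalize_ppg(bio_signal(rep(1, 10), 200)), "constant")
})

test_that("pressure calibration spans the cuff values", {
  tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1])
  p <- calibrate_pressure(bio_signal(tri, 200),
                          pressure_calibration(120, 80))
  expect_equal(range(p$value), c(80, 120))
  # symmetric triangle with (100, 60): mean 80 mmHg
  p2 <- calibrate_pressure(bio_signal(tri[-1], 200),
                           pressure_calibration(100, 60))
  expect_equal(mean(p2$value), 80, tolerance = 1e-2)
  expect_error(pressure_calibration(80, 120), "systolic")
  expect_error(calibrate_pressure(bio_signal(tri * 3, 200)), "normalised")
  # calibrate-after-normalise is idempotent under re-application
  pn <- normalize_ppg(p)
  p3 <- calibrate_pressure(pn, pressure_calibration(120, 80))
  expect_equal(p3$value, p$value, tolerance = 1e-12)
})

test_that("watershed area extraction recovers programmed lumen areas", {
  area <- 2500 * (1 + 0.1 * sin(2 * pi * (0:11) / 12))
  stk <- render_bmode(area, 96, 96, fs = 34.394, speckle_sd = 0, seed = 2)
  ip <- extract_image_pulse(stk, fs = 34.394)
  prog <- attr(stk, "programmed_area")
  expect_lt(mean(abs(ip$value - prog) / prog), 0.02)
  # constant-area stack gives a constant series
  stc <- render_bmode(rep(2000, 5), 96, 96, fs = 34.394, seed = 2)
  ipc <- extract_image_pulse(stc, fs = 34.394)
  expect_equal(diff(range(ipc$value)), 0)
})

test_that("least-squares scaling inverts an exact affine relation", {
  set.seed(3)
  ppg <- bio_signal(runif(200), 200)
  img <- bio_signal(2 * ppg$value + 5, 200)
  sc <- scale_to_reference(img, ppg)
  expect_equal(attr(sc, "scale_a"), 0.5, tolerance = 1e-10)
  expect_equal(attr(sc, "scale_b"), -2.5, tolerance = 1e-10)
  expect_lt(max(abs(sc$value - ppg$value)), 1e-10)
  # identical signals: identity scaling
  sid <- scale_to_reference(ppg, ppg)
  expect_equal(attr(sid, "scale_a"), 1, tolerance = 1e-10)
  expect_equal(attr(sid, "scale_b"), 0, tolerance = 1e-10)
  # uncorrelated noise: compare against the normal-equations oracle
  x <- bio_signal(rnorm(500), 200)
  y <- bio_signal(rnorm(500), 200)
  sn <- scale_to_reference(x, y)
  X <- cbind(1, x$value)
  beta <- solve(t(X) %*% X, t(X) %*% y$value)
  expect_equal(attr(sn, "scale_b"), beta[1], tolerance = 1e-8)
  expect_equal(attr(sn, "scale_a"), beta[2], tolerance = 1e-8)
})

test_that("clock synchronization recovers offsets exactly on noiseless peaks", {
  pp <- 0.5 + cumsum(c(0, 0.9, 0.88, 0.92, 0.86, 0.95, 0.9))
  expect_equal(synchronize_clocks(pp, pp), 0)
  expect_equal(synchronize_clocks(pp, pp + 0.029), 0.029, tolerance = 1e-9)
  # unbiased across the +/-500 ms range (1-ms grid)
  for (off in c(-0.5, -0.211, -0.037, 0.143, 0.5)) {
    expect_equal(synchronize_clocks(pp, pp + off), off, tolerance = 1e-9)
  }
  expect_error(synchronize_clocks(pp[1:3], pp), "at least")
})

test_that("pulse transit time matches a programmed foot lag", {
  fs <- 500
  tt <- (0:(3 * fs - 1)) / fs
  beats <- c(0.5, 1.5, 2.5)
  # ramp pulse whose foot (upstroke onset) lags each R peak by exactly 180 ms
  pulse <- rowSums(sapply(beats, function(tb) {
    pmax(0, pmin(1, (tt - tb - 0.18) / 0.1))
  }))
  timing <- tibble::tibble(beat = 1:3, t_peak = beats,
                           rr = c(NA, diff(beats)))
  class(timing) <- c("cardiac_timing", class(timing))
  ptt <- compute_ptt(timing, bio_signal(pulse, fs))
  expect_true(all(abs(ptt$ptt[1:2] - 0.180) < 0.005))
  # a beat with no upstroke yields a missing value
  flat <- bio_signal(rep(0, 3 * fs), fs)
  ptt2 <- compute_ptt(timing, flat)
  expect_true(all(is.na(ptt2$ptt)))
})
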