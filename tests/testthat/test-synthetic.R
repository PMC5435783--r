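test_that("generators are bit-reproducible under a fixed seed", {
  area <- 2000 * (1 + 0.1 * sin((0:9) / 3))
  s1 <- render_bmode(area, 96, 96, seed = 7, speckle_sd = 0.2)
  s2 <- render_bmode(area, 96, 96, seed = 7, speckle_sd = 0.2)
  expect_identical(s1, s2)
  e1 <- generate_ecg(1:5, powerline_amp = 0.5, broadband_sd = 0.1, seed = 3)
  e2 <- generate_ecg(1:5, powerline_amp = 0.5, broadband_sd = 0.1, seed = 3)
  expect_identical(e1$value, e2$value)
})

test_that("a steady scenario reproduces Poiseuille and imposes the inlet flux", {
  sc <- twin_scenario(n_frames = 3, u_mean = 0.1, u_amplitudes = numeric(0),
                      u_phases = numeric(0))
  tr <- generate_truth(sc, settings = solver_settings(residual_tol = 1e-5))
  g <- tr$grid
  props <- fluid_props()
  h <- (g$jhi[1] - g$jlo[1] + 1) * g$dy
  fld <- tr$fields[[3]]
  # steady truth equals plane Poiseuille within solver tolerance
  w <- compute_wss(fld, props, "lower")
  tau_exact <- 6 * props$mu * 0.1 / h
  expect_lt(abs(w$tau[18] - tau_exact) / tau_exact, 0.03)
  # the prescribed inlet flux is imposed exactly at the inlet faces
  for (k in seq_along(tr$fields)) {
    influx <- sum(tr$fields[[k]]$u[1, ] * g$dy)
    expect_equal(influx / h, tr$inlet$u_inlet[k], tolerance = 1e-12)
  }
  # zero-inlet scenario gives zero truth
  sc0 <- twin_scenario(n_frames = 2, u_mean = 0, u_amplitudes = numeric(0),
                       u_phases = numeric(0))
  tr0 <- generate_truth(sc0)
  expect_equal(max(abs(tr0$fields[[2]]$u)), 0)
})

test_that("Doppler sampling adds calibrated Gaussian noise on valid points", {
  tw <- skewed_twin()
  sc <- tw$scenario
  scn <- twin_scenario(inlet_shape = "skewed", n_frames = 10,
                       noise_sd = 0.02, seed = 5)
  # reuse the cached truth fields (same scenario geometry/waveform)
  truth <- tw$truth
  truth$scenario <- scn
  truth$fields <- truth$fields[1:10]
  truth$times <- truth$times[1:10]
  frames_noisy <- sample_doppler(truth, scn)
  resid <- unlist(lapply(seq_along(frames_noisy), function(k) {
    Vc <- project_doppler(truth$fields[[k]], scenario_beam(scn))
    (frames_noisy[[k]]$V_m - Vc)[truth$grid$fluid]
  }))
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.1)
  # sigma = 0, offset = 0: V_m equals the projected truth exactly
  fr0 <- sample_doppler(tw$truth)
  Vc1 <- project_doppler(tw$truth$fields[[1]], scenario_beam(sc))
  expect_equal(fr0[[1]]$V_m[tw$truth$grid$fluid],
               Vc1[tw$truth$grid$fluid])
  # beam orthogonal to the axial flow measures only the small cross-stream
  # velocity left over from profile relaxation
  sc_orth <- twin_scenario(inlet_shape = "skewed", n_frames = 10,
                           beam_angle_deg = 0)
  fr_orth <- sample_doppler(truth, sc_orth)
  expect_lt(max(abs(fr_orth[[5]]$V_m)), 0.05 * max(abs(fr0[[5]]$V_m)))
})

test_that("Beer-Lambert photoplethysmography follows the exponential law", {
  opt <- ppg_optics(I0 = 1, epsilon = 1000, C = 1e-3)
  # constant path: I = I0 exp(-eps C l)
  p <- generate_ppg(rep(0.5, 100), opt, invert = FALSE)
  expect_equal(unique(round(p$value, 12)),
               round(exp(-1000 * 1e-3 * 0.5), 12))
  # eps C l = 1 -> I/I0 = exp(-1)
  p1 <- generate_ppg(rep(1, 10), ppg_optics(I0 = 2, epsilon = 1000, C = 1e-3),
                     invert = FALSE)
  expect_equal(p1$value[1] / 2, exp(-1), tolerance = 1e-12)
  # small sinusoidal path modulation: intensity is anti-phase with the path
  ell <- 0.5 + 0.01 * sin(2 * pi * (0:499) / 100)
  pa <- generate_ppg(ell, opt, invert = FALSE)
  expect_lte(cor(pa$value, ell), -0.99)
  expect_error(generate_ppg(c(0.5, -0.1), opt), "positive")
})

test_that("R peaks survive the contaminated ECG end to end", {
  beats <- cumsum(c(1, rep(c(0.9, 0.95, 0.85), 20)))  # 61 beats
  for (contam in list(list(powerline_amp = 2), list(drift_amp = 0.5))) {
    args <- utils::modifyList(list(beat_times = beats, seed = 11), contam)
    raw <- do.call(generate_ecg, args)
    tm <- detect_r_peaks(filter_ecg(raw), min_rr = 0.5)
    expect_equal(nrow(tm), length(beats))
    expect_lt(max(abs(tm$t_peak - beats)), 0.02)
  }
})

test_that("clock offsets are injected exactly and recovered", {
  s <- bio_signal(sin((0:99) / 5), 50)
  expect_equal(inject_offset(s, 0)$t, s$t)
  expect_equal(inject_offset(s, 0.029)$t, s$t + 0.029)
  expect_error(inject_offset(s, 3), "2 s")
  # 29-ms offset recovered from noiseless pulse peaks
  tr <- sync_twin_trial(offset = 0.029, jitter_sd = 0, seed = 2)
  expect_equal(tr$recovered, 0.029, tolerance = 1e-9)
  # end-to-end: -10 ms residual refined on a water-hammer pair
  tr2 <- sync_twin_trial(offset = -0.010, jitter_sd = 0, seed = 3)
  expect_lte(abs(tr2$recovered - (-0.010)), 5e-3)
})
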