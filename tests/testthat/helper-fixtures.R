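# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# carotid-scale grid matching the reference acquisition (36 x 86)
paper_grid <- function() {
  cached("paper_grid", {
    geo <- channel_geometry(diameter = 6.4e-3, length = 36 * 163e-6,
                            pitch_x = 163e-6, pitch_y = 173e-6,
                            depth_extent = 86 * 173e-6)
    build_grid(geo, 163e-6, 173e-6)
  })
}

# small fast channel for solver unit tests (12 x 16, 10-cell lumen)
small_grid <- function() {
  cached("small_grid", {
    geo <- channel_geometry(diameter = 2e-3, length = 3e-3,
                            pitch_x = 2.5e-4, pitch_y = 2e-4,
                            depth_extent = 3.2e-3)
    build_grid(geo, 2.5e-4, 2e-4)
  })
}

# noiseless skewed-profile twin at full scale (35 frames) + both runs
skewed_twin <- function() {
  cached("skewed_twin", {
    sc <- twin_scenario(inlet_shape = "skewed", n_frames = 35, noise_sd = 0)
    truth <- generate_truth(sc)
    list(scenario = sc, truth = truth, frames = sample_doppler(truth))
  })
}

umi_run_500 <- function() {
  cached("umi_run_500", {
    tw <- skewed_twin()
    run_simulation(tw$frames, tw$truth$grid, mode = "umi")
  })
}

ordinary_run <- function() {
  cached("ordinary_run", {
    tw <- skewed_twin()
    run_simulation(tw$frames, tw$truth$grid, mode = "ordinary")
  })
}

# hand-built parabolic flow field on a grid (no solver involved)
parabolic_field <- function(grid, u_max, t = 0) {
  fld <- flow_field(grid, t)
  h <- (grid$jhi[1] - grid$jlo[1] + 1) * grid$dy
  yc <- (grid$jlo[1] - 1) * grid$dy + h / 2
  for (i in seq_len(grid$nx + 1)) {
    js <- grid$jlo[min(i, grid$nx)]:grid$jhi[min(i, grid$nx)]
    y <- (js - 0.5) * grid$dy
    fld$u[i, js] <- u_max * (1 - ((y - yc) / (h / 2))^2)
  }
  fld
}

# steady-state amplitude attenuation of the ECG filter chain at one frequency
tone_attenuation_db <- function(f_hz, fs = 200, n = 4000) {
  tt <- (0:(n - 1)) / fs
  y <- filter_ecg(bio_signal(sin(2 * pi * f_hz * tt), fs, kind = "ecg"))$value
  mid <- (n %/% 4):(3 * n %/% 4)
  a <- 2 * abs(mean(y[mid] * exp(-2i * pi * f_hz * tt[mid])))
  -20 * log10(max(a, 1e-15))
}

# water-hammer beat: exactly linear P-U relation, asymmetric systolic pulse
water_hammer_beat <- function(fs = 200, shift_p = 0) {
  tb <- seq(0, 0.9, by = 1 / fs)
  uf <- function(tau) {
    0.10 + 0.35 * exp(-((tau - 0.28) / 0.07)^2) * (tau <= 0.28) +
      0.35 * exp(-((tau - 0.28) / 0.16)^2) * (tau > 0.28)
  }
  list(P = bio_signal(80 + 100 * (uf(tb - shift_p) - 0.1), fs, 0,
                      kind = "pressure"),
       U = bio_signal(uf(tb), fs, 0, kind = "velocity"))
}
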