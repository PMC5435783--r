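#' Twin-experiment scenario
#'
#' Describes a synthetic acquisition mirroring the clinical setup: a
#' carotid-like channel (6.4 mm upstream diameter), Doppler/B-mode frame
#' rate 34.394 Hz, measurement pitch equal to the computational grid
#' spacing (163 x 173 um), and a pulsatile inlet waveform (mean + three
#' harmonics) spanning roughly 0.1-0.5 m/s. Everything downstream of the
#' scenario is bit-reproducible under the scenario seed.
#'
#' @param shape `"straight"`, `"tapered"` or `"stenosed"`.
#' @param diameter Upstream lumen diameter (m).
#' @param length Axial domain length (m).
#' @param dx,dy Grid/measurement pitch (m).
#' @param depth_extent Raster depth (m).
#' @param n_frames Number of Doppler frames.
#' @param rate Frame rate (Hz).
#' @param period Cardiac period (s).
#' @param u_mean Mean inlet velocity (m/s).
#' @param u_amplitudes,u_phases Harmonic amplitudes (m/s) and phases (rad)
#'   of the inlet waveform.
#' @param inlet_shape `"parabolic"` or `"skewed"` (a non-parabolic profile
#'   `eta (1-eta)^2`, peaked toward the shallow wall).
#' @param beam_angle_deg Beam angle from the depth axis (degrees).
#' @param noise_sd Gaussian Doppler noise s.d. (m/s).
#' @param clock_offset Injected clock offset of the measurement channel (s).
#' @param seed RNG seed.
#' @return A `twin_scenario` object.
#' @export
twin_scenario <- function(shape = c("straight", "tapered", "stenosed"),
                          diameter = 6.4e-3, length = 36 * 163e-6,
                          dx = 163e-6, dy = 173e-6,
                          depth_extent = 86 * 173e-6,
                          n_frames = 35, rate = 34.394, period = 0.9,
                          u_mean = 0.3,
                          u_amplitudes = c(0.12, 0.05, 0.025),
                          u_phases = c(-pi / 2, pi / 4, pi / 2),
                          inlet_shape = c("parabolic", "skewed"),
                          beam_angle_deg = 20, noise_sd = 0,
                          clock_offset = 0, seed = 1L) {
  shape <- match.arg(shape)
  inlet_shape <- match.arg(inlet_shape)
  stopifnot(period > 0, rate > 0, noise_sd >= 0, diameter > 0)
  structure(list(shape = shape, diameter = diameter, length = length,
                 dx = dx, dy = dy, depth_extent = depth_extent,
                 n_frames = as.integer(n_frames), rate = rate,
                 period = period, u_mean = u_mean,
                 u_amplitudes = u_amplitudes, u_phases = u_phases,
                 inlet_shape = inlet_shape,
                 beam_angle_deg = beam_angle_deg, noise_sd = noise_sd,
                 clock_offset = clock_offset, seed = as.integer(seed)),
            class = "twin_scenario")
}

#' Inlet velocity waveform of a scenario
#'
#' `U(t) = u_mean + sum_k A_k sin(2 pi k t / T + phi_k)`.
#'
#' @param scenario A [twin_scenario()].
#' @param t Time (s), vectorised.
#' @return Mean inlet velocity at `t` (m/s).
#' @export
inlet_waveform <- function(scenario, t) {
  out <- rep(scenario$u_mean, length(t))
  for (k in seq_along(scenario$u_amplitudes)) {
    out <- out + scenario$u_amplitudes[k] *
      sin(2 * pi * k * t / scenario$period + scenario$u_phases[k])
  }
  out
}

# Geometry of a scenario: per-column half-width profile on a raster.
scenario_geometry <- function(scenario) {
  und <- 0
  half_fn <- switch(scenario$shape,
    straight = function(s) rep(scenario$diameter / 2, length(s)),
    tapered = function(s) scenario$diameter / 2 * (1 - 0.2 * s),
    stenosed = function(s) scenario$diameter / 2 *
      (1 - 0.3 * exp(-((s - 0.5) / 0.15)^2))
  )
  px <- scenario$dx; py <- scenario$dy
  nc <- max(4L, round(scenario$length / px))
  nr <- max(4L, round(scenario$depth_extent / py))
  yc <- scenario$depth_extent / 2
  s <- ((seq_len(nc) - 0.5) * px) / scenario$length
  half <- half_fn(s)
  yrow <- (seq_len(nr) - 0.5) * py
  mask <- matrix(0, nr, nc)
  for (i in seq_len(nc)) mask[abs(yrow - yc) <= half[i], i] <- 1
  vessel_geometry(mask, px, py)
}

#' Scenario beam unit vector
#' @param scenario A [twin_scenario()].
#' @return Length-2 unit vector `c(ex, ey)`.
#' @export
scenario_beam <- function(scenario) {
  th <- scenario$beam_angle_deg * pi / 180
  c(sin(th), cos(th))
}

skewed_profile <- function(eta) eta * (1 - eta)^2

#' Generate the ground-truth flow of a twin experiment
#'
#' Runs the flow solver with the scenario's prescribed inlet waveform (no
#' feedback): a steady solve at U(0) initialises the field, then one
#' implicit step per frame interval. The result is the "truth" against
#' which assimilation accuracy is measured exactly.
#'
#' @param scenario A [twin_scenario()].
#' @param props [fluid_props()].
#' @param settings Optional [solver_settings()]; `dt` is forced to the frame
#'   interval.
#' @return A `twin_truth` list: `fields`, `inlet` (tibble frame/t/u_inlet),
#'   `wss` (lower wall), `grid`, `times`, `scenario`.
#' @export
generate_truth <- function(scenario, props = fluid_props(),
                           settings = NULL) {
  if (is.null(settings)) settings <- solver_settings()
  settings$dt <- 1 / scenario$rate
  grid <- build_grid(scenario_geometry(scenario), scenario$dx, scenario$dy)
  profile <- if (scenario$inlet_shape == "skewed") skewed_profile
  else "parabolic"
  u0 <- inlet_waveform(scenario, 0)
  # the initial steady state is converged tightly regardless of the marching
  # tolerance, so the truth starts from a clean fully developed field
  init_settings <- settings
  init_settings$residual_tol <- min(settings$residual_tol, 1e-4)
  fld <- steady_state(flow_field(grid, t = 0), boundary_condition(u0, profile),
                      props, settings = init_settings, max_outer = 2000L)
  n <- scenario$n_frames
  times <- seq_len(n) / scenario$rate
  fields <- vector("list", n)
  wss_list <- vector("list", n)
  u_in <- inlet_waveform(scenario, times)
  for (k in seq_len(n)) {
    fld <- step(fld, boundary_condition(u_in[k], profile), props,
                settings = settings)
    fields[[k]] <- fld
    w <- compute_wss(fld, props, "lower")
    wss_list[[k]] <- tibble::tibble(frame = k, t = times[k], x = w$x,
                                    tau = w$tau)
  }
  structure(list(fields = fields,
                 inlet = tibble::tibble(frame = seq_len(n), t = times,
                                        u_inlet = u_in),
                 wss = dplyr::bind_rows(wss_list),
                 grid = grid, times = times, scenario = scenario),
            class = "twin_truth")
}

#' Sample Doppler frames from a truth run
#'
#' Projects each truth field onto the scenario beam at the measurement grid
#' (the computational cell centres), adds i.i.d. Gaussian noise of s.d.
#' `scenario$noise_sd` on valid (lumen) points, and stamps frames at the
#' measurement rate shifted by the scenario clock offset. Bit-reproducible
#' under the scenario seed.
#'
#' @param truth A `twin_truth` from [generate_truth()].
#' @param scenario Defaults to `truth$scenario`.
#' @return List of [doppler_frame()]s.
#' @export
sample_doppler <- function(truth, scenario = truth$scenario) {
  beam <- scenario_beam(scenario)
  grid <- truth$grid
  mgrid <- meas_grid_from_flow(grid)
  valid <- grid$fluid
  with_seed(scenario$seed + 1L, {
    lapply(seq_along(truth$fields), function(k) {
      Vc <- project_doppler(truth$fields[[k]], beam, mgrid)
      Vm <- Vc
      if (scenario$noise_sd > 0) {
        Vm[valid] <- Vm[valid] + rnorm(sum(valid), 0, scenario$noise_sd)
      }
      Vm[!valid] <- 0
      doppler_frame(Vm, beam, truth$times[k] + scenario$clock_offset,
                    valid, mgrid)
    })
  })
}

#' Render a B-mode-like image stack with a programmed lumen area
#'
#' Each frame shows a dark elliptical lumen (axis ratio `aspect`) of the
#' programmed pixel area on a bright background with multiplicative
#' log-normal speckle. The realised (rasterised) pixel areas are stored as
#' the ground truth in attribute `programmed_area`.
#'
#' @param area_px Vector of target lumen areas per frame (pixels).
#' @param width,height Frame size (pixels).
#' @param fs Frame rate (Hz).
#' @param speckle_sd Log-normal speckle sigma (0 = none).
#' @param aspect Ellipse major/minor axis ratio.
#' @param tissue,lumen Mean intensities of tissue and lumen.
#' @param seed RNG seed.
#' @return Array `height x width x n` in [0, 1] with attributes
#'   `programmed_area` and `fs`.
#' @export
render_bmode <- function(area_px, width = 128, height = 128, fs = 34.394,
                         speckle_sd = 0, aspect = 2, tissue = 0.8,
                         lumen = 0.12, seed = 1L) {
  n <- length(area_px)
  cy <- height / 2; cx <- width / 2
  bmax <- sqrt(max(area_px) / (pi * aspect))
  if (aspect * bmax * 2 >= width || 2 * bmax >= height) {
    stop("programmed area exceeds the frame size")
  }
  X <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  Y <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  out <- array(0, dim = c(height, width, n))
  realised <- numeric(n)
  with_seed(seed, {
    for (k in seq_len(n)) {
      b <- sqrt(area_px[k] / (pi * aspect))
      a <- aspect * b
      inside <- ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
      realised[k] <- sum(inside)
      img <- matrix(tissue, height, width)
      img[inside] <- lumen
      if (speckle_sd > 0) {
        img <- img * exp(matrix(rnorm(height * width, 0, speckle_sd),
                                height, width))
      }
      out[, , k] <- pmin(pmax(img, 0), 1)
    }
  })
  attr(out, "programmed_area") <- realised
  attr(out, "fs") <- fs
  out
}

#' Optical parameters for Beer-Lambert photoplethysmography
#'
#' @param I0 Incident light intensity (arbitrary units).
#' @param epsilon Molar absorption coefficient of haemoglobin at the sensor
#'   wavelength (L / (mol cm)).
#' @param C Molar haemoglobin concentration (mol/L), constant for vessels
#'   larger than ~128 um.
#' @param lambda Wavelength (m); 940 nm for the near-infrared sensor.
#' @return A `ppg_optics` object.
#' @export
ppg_optics <- function(I0 = 1, epsilon = 1.0e3, C = 2.3e-3,
                       lambda = 940e-9) {
  stopifnot(I0 > 0, epsilon > 0, C > 0, lambda > 0)
  structure(list(I0 = I0, epsilon = epsilon, C = C, lambda = lambda),
            class = "ppg_optics")
}

#' Synthesise a PPG signal from an optical path-length waveform
#'
#' Beer-Lambert law: `I(t) = I0 exp(-epsilon C l(t))` with the path length
#' `l(t)` (cm) tied to the lumen size, so a larger lumen yields a smaller
#' detected intensity (the raw PPG is anti-phase with the vessel area).
#' With `invert = TRUE` (default) the waveform is mirrored about its mid
#' level so the pulse is positive-going like a clinical PPG display.
#'
#' @param path_cm Path length waveform in cm: a `bio_signal` or a numeric
#'   vector (then `fs` and `t0` apply).
#' @param optics A [ppg_optics()].
#' @param fs,t0 Sampling rate / origin when `path_cm` is numeric.
#' @param invert Mirror the intensity so the pulse is positive-going.
#' @return `bio_signal` of kind `"ppg"`.
#' @export
generate_ppg <- function(path_cm, optics = ppg_optics(), fs = 200, t0 = 0,
                         invert = TRUE) {
  if (inherits(path_cm, "bio_signal")) {
    ell <- path_cm$value
    out0 <- path_cm
  } else {
    out0 <- bio_signal(path_cm, fs, t0)
    ell <- out0$value
  }
  if (any(ell <= 0)) stop("path length must be positive")
  I <- optics$I0 * exp(-optics$epsilon * optics$C * ell)
  if (invert) I <- max(I) + min(I) - I
  bs_update(out0, value = I, kind = "ppg")
}

#' Synthesise an ECG with controlled contaminants
#'
#' Template QRS complexes (plus small Q/S/T deflections) at the given beat
#' times, with optional 50 Hz power-line tone, sinusoidal baseline drift and
#' broadband Gaussian noise, all seeded.
#'
#' @param beat_times Strictly increasing R-peak times (s).
#' @param fs Sampling rate (Hz).
#' @param duration Record length (s); default covers the last beat + 0.8 s.
#' @param powerline_amp,drift_amp,drift_hz,broadband_sd Contaminant levels
#'   (template R amplitude is 1).
#' @param seed RNG seed.
#' @return `bio_signal` of kind `"ecg"` with attribute `beat_times`.
#' @export
generate_ecg <- function(beat_times, fs = 200, duration = NULL,
                         powerline_amp = 0, drift_amp = 0, drift_hz = 0.5,
                         broadband_sd = 0, seed = 1L) {
  if (is.unsorted(beat_times, strictly = TRUE)) {
    stop("beat_times must be strictly increasing")
  }
  if (is.null(duration)) duration <- max(beat_times) + 0.8
  tt <- seq(0, duration, by = 1 / fs)
  v <- numeric(length(tt))
  for (tb in beat_times) {
    v <- v + exp(-((tt - tb) / 0.012)^2) -
      0.15 * exp(-((tt - tb + 0.04) / 0.008)^2) -
      0.20 * exp(-((tt - tb - 0.03) / 0.008)^2) +
      0.25 * exp(-((tt - tb - 0.25) / 0.060)^2)
  }
  with_seed(seed, {
    if (powerline_amp > 0) v <- v + powerline_amp * sin(2 * pi * 50 * tt)
    if (drift_amp > 0) v <- v + drift_amp * sin(2 * pi * drift_hz * tt)
    if (broadband_sd > 0) v <- v + rnorm(length(tt), 0, broadband_sd)
  })
  out <- bio_signal(v, fs, 0, kind = "ecg")
  attr(out, "beat_times") <- beat_times
  out
}

#' Shift the clock of a signal or frame stack
#'
#' Timestamps are shifted by exactly `offset`; the data are unchanged.
#'
#' @param x A `bio_signal`, a list of [doppler_frame()]s, or a numeric
#'   vector of event times.
#' @param offset Clock offset (s), |offset| <= 2 s.
#' @return Shifted copy of `x`.
#' @export
inject_offset <- function(x, offset) {
  if (abs(offset) > 2) stop("offset outside +/-2 s")
  if (inherits(x, "bio_signal")) {
    return(bs_update(x, t = x$t + offset))
  }
  if (is.list(x) && length(x) && inherits(x[[1]], "doppler_frame")) {
    return(lapply(x, function(f) {
      f$timestamp <- f$timestamp + offset
      f
    }))
  }
  if (is.numeric(x)) return(x + offset)
  stop("unsupported input to inject_offset()")
}
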