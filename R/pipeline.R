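#' Default pipeline configuration
#'
#' All physical quantities carry unit suffixes in their key names. The
#' defaults reproduce the reference acquisition: gain K_v* = 500, time step
#' 29.075 ms (34.394 Hz), typical carotid velocity 0.39 m/s, cuff
#' calibration 120/80 mmHg.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "umi",
    gain = 500,
    dt_s = NULL,                 # derived from frame_rate_hz when NULL
    frame_rate_hz = 34.394,
    v_type_m_s = 0.39,
    u_char_m_s = 0.1,
    l_char_m = 6.4e-3,
    rho_kg_m3 = 1.0e3,
    mu_pa_s = 4.0e-3,
    feedback_xmin = 1 / 36,
    feedback_xmax = 29 / 36,
    residual_tol = 1.0e-2,
    inlet_tol = 1.0e-3,
    systolic_mmhg = 120,
    diastolic_mmhg = 80,
    sync_n_cycles = 6,
    sync_step_s = 1e-3,
    refine_step_s = 5e-3,
    refine_range_s = 30e-3,
    scenario = list(),           # twin_scenario() overrides
    frames_stem = NULL,          # read frames instead of generating a twin
    grid_json = NULL,
    out_dir = "umiflow_out",
    seed = 1L
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are an error
#' (strict mode), missing keys are filled from [default_config()], and
#' `dt_s` is derived from `frame_rate_hz` when omitted. Basic unit/sanity
#' coherence is enforced (non-negative gain, systolic > diastolic, positive
#' rates).
#'
#' @param config Path to a YAML file, a named list, or `NULL` (defaults).
#' @return A validated `umiflow_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a file path or a named list")
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(def, config)
  if (!cfg$mode %in% c("umi", "ordinary")) {
    stop("mode must be 'umi' or 'ordinary'")
  }
  if (cfg$gain < 0) stop("gain must be non-negative")
  if (cfg$frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (is.null(cfg$dt_s)) cfg$dt_s <- 1 / cfg$frame_rate_hz
  if (cfg$dt_s <= 0) stop("dt_s must be positive")
  if (cfg$systolic_mmhg <= cfg$diastolic_mmhg) {
    stop("systolic_mmhg must exceed diastolic_mmhg")
  }
  if (!is.null(cfg$frames_stem) &&
      !file.exists(paste0(cfg$frames_stem, "_frames.csv"))) {
    stop("frames_stem: file not found: ", paste0(cfg$frames_stem,
                                                 "_frames.csv"))
  }
  if (!is.null(cfg$grid_json) && !file.exists(cfg$grid_json)) {
    stop("grid_json: file not found: ", cfg$grid_json)
  }
  structure(cfg, class = c("umiflow_config", "list"))
}

log_stage <- function(log_path, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE)
  message(sprintf("[%s] %s", stage,
                  paste(names(list(...)), unlist(list(...)),
                        sep = "=", collapse = " ")))
}

#' Run the full analysis pipeline on a twin experiment
#'
#' Executes the complete chain of the simultaneous pressure-measurement /
#' flow-analysis system on a synthetic twin: (1) twin generation (truth
#' flow, Doppler frames, PPG and image-pulse waveforms from a common lumen
#' waveform, synthetic ECG, injected clock offset); (2) clock
#' synchronization (1-ms peak alignment of PPG vs image pulse, applied to
#' the frame timestamps); (3) measurement-integrated (or ordinary) flow
#' simulation with golden-section inlet estimation; (4) wave-intensity and
#' PU-loop analysis with 5-ms refinement; (5) report outputs: CSV tables, a
#' JSON summary, a seven-panel aligned figure and a JSONL stage log.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return Invisibly, a list with all stage outputs (`truth`, `frames`,
#'   `signals`, `sync`, `run`, `wi`, `pu`, `summary`, `paths`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)

  stage <- "configure"
  result <- tryCatch({
    props <- fluid_props(cfg$rho_kg_m3, cfg$mu_pa_s)
    fb <- feedback_config(K_v_star = cfg$gain,
                          feedback_xmin = cfg$feedback_xmin,
                          feedback_xmax = cfg$feedback_xmax,
                          U_char = cfg$u_char_m_s, L_char = cfg$l_char_m,
                          rho = cfg$rho_kg_m3, V_type = cfg$v_type_m_s)
    settings <- solver_settings(dt = cfg$dt_s,
                                residual_tol = cfg$residual_tol)
    log_stage(log_path, stage, mode = cfg$mode, gain = cfg$gain)

    stage <- "twin-gen"
    sargs <- utils::modifyList(list(seed = cfg$seed), cfg$scenario)
    scenario <- do.call(twin_scenario, sargs)
    if (is.null(cfg$frames_stem)) {
      truth <- generate_truth(scenario, props)
      frames <- sample_doppler(truth)
      grid <- truth$grid
    } else {
      truth <- NULL
      frames <- read_doppler_frames(cfg$frames_stem)
      grid <- if (!is.null(cfg$grid_json)) read_grid_json(cfg$grid_json)
      else build_grid(scenario_geometry(scenario), scenario$dx, scenario$dy)
    }
    log_stage(log_path, stage, n_frames = length(frames),
              offset_injected_s = scenario$clock_offset)

    stage <- "biosignals"
    dur <- max(vapply(frames, function(f) f$timestamp, numeric(1))) + 1.5
    beat_times <- seq(0.02, dur, by = scenario$period)
    fs <- 200
    tt <- seq(0, dur, by = 1 / fs)
    uwave <- inlet_waveform(scenario, tt)
    un <- (uwave - min(uwave)) / (max(uwave) - min(uwave))
    ell <- 0.5 + 0.05 * un
    ppg <- normalize_ppg(generate_ppg(bio_signal(ell, fs, 0), invert = TRUE))
    pressure <- calibrate_pressure(ppg,
                                   pressure_calibration(cfg$systolic_mmhg,
                                                        cfg$diastolic_mmhg))
    ecg_raw <- generate_ecg(beat_times, fs, duration = dur,
                            powerline_amp = 0.5, drift_amp = 0.3,
                            broadband_sd = 0.02, seed = cfg$seed + 2L)
    ecg <- filter_ecg(ecg_raw)
    timing <- detect_r_peaks(ecg)
    ti <- seq(0, dur, by = 1 / scenario$rate)
    img <- inject_offset(
      bio_signal(3000 * (1 + 0.1 * stats::approx(tt, un, xout = ti,
                                                 rule = 2)$y),
                 scenario$rate, 0, kind = "image_pulse"),
      scenario$clock_offset)
    log_stage(log_path, stage, n_beats = nrow(timing))

    stage <- "sync"
    ppg_peaks <- find_pulse_peaks(ppg, min_separation = 0.5 * scenario$period)
    img_peaks <- find_pulse_peaks(img, min_separation = 0.5 * scenario$period)
    coarse <- synchronize_clocks(ppg_peaks, img_peaks,
                                 shift_step = cfg$sync_step_s,
                                 n_cycles = min(cfg$sync_n_cycles,
                                                length(ppg_peaks) - 1,
                                                length(img_peaks) - 1))
    frames_sync <- inject_offset(frames, -coarse)
    log_stage(log_path, stage, coarse_shift_ms = coarse * 1e3)

    stage <- "flow"
    run <- run_simulation(frames_sync, grid, props, fb, settings,
                          mode = cfg$mode, inlet_tol = cfg$inlet_tol)
    log_stage(log_path, stage, e_mean = mean(run$results$e),
              feedback = cfg$mode == "umi" && cfg$gain > 0)

    stage <- "wave"
    usig <- bio_signal(stats::approx(run$results$t, run$results$u_inlet,
                                     xout = tt, rule = 2)$y,
                       fs, 0, kind = "velocity")
    wi <- compute_wi(pressure, usig)
    # PU loop over the beat best covered by the frames
    bt <- beat_times[beat_times > min(run$results$t) &
                       beat_times + scenario$period < max(run$results$t)]
    t0b <- if (length(bt)) bt[1] else beat_times[1]
    selb <- tt >= t0b & tt <= t0b + scenario$period
    Pb <- bs_update(pressure, value = pressure$value[selb], t = tt[selb],
                    kind = "pressure")
    Ub <- bs_update(usig, value = usig$value[selb], t = tt[selb],
                    kind = "velocity")
    refined <- tryCatch(as.numeric(refine_sync(Pb, Ub,
                                               shift_step = cfg$refine_step_s,
                                               search_range = cfg$refine_range_s)),
                        error = function(e) NA_real_)
    Ub_ref <- if (is.finite(refined)) {
      bs_update(Ub, value = stats::approx(Ub$t - refined, Ub$value,
                                          xout = Ub$t, rule = 2)$y)
    } else Ub
    # a record too short to cover a systolic upstroke yields no PU loop
    pu <- tryCatch(build_pu_loop(Pb, Ub_ref), error = function(e) {
      warning("PU loop not computable: ", conditionMessage(e))
      NULL
    })
    log_stage(log_path, stage, refined_shift_ms = refined * 1e3,
              pu_r_squared = if (is.null(pu)) NA else pu$r_squared)

    stage <- "report"
    paths <- list(
      results_csv = file.path(cfg$out_dir, "results.csv"),
      wss_csv = file.path(cfg$out_dir, "wss.csv"),
      wi_csv = file.path(cfg$out_dir, "wave_intensity.csv"),
      summary_json = file.path(cfg$out_dir, "summary.json"),
      panels_pdf = file.path(cfg$out_dir, "panels.pdf"),
      log_jsonl = log_path
    )
    utils::write.csv(tidy(run), paths$results_csv, row.names = FALSE)
    utils::write.csv(run$wss, paths$wss_csv, row.names = FALSE)
    utils::write.csv(as.data.frame(wi), paths$wi_csv, row.names = FALSE)
    summary <- list(
      mode = cfg$mode, gain = cfg$gain,
      feedback = cfg$mode == "umi" && cfg$gain > 0,
      coarse_shift_ms = coarse * 1e3,
      refined_shift_ms = refined * 1e3,
      offset_injected_ms = scenario$clock_offset * 1e3,
      e_time_averaged = mean(run$results$e),
      pu_r_squared = if (is.null(pu)) NA else pu$r_squared,
      pu_classification = if (is.null(pu)) NA else pu$classification,
      wi_peaks = as.list(glance(wi))
    )
    jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                         digits = NA)
    panels <- plot_report_panels(ecg, pressure, usig, run, wi)
    ggplot2::ggsave(paths$panels_pdf, panels, width = 7, height = 12)
    log_stage(log_path, stage, out_dir = cfg$out_dir)

    list(truth = truth, frames = frames_sync,
         signals = list(ecg = ecg, ppg = ppg, pressure = pressure,
                        image_pulse = img, timing = timing),
         sync = list(coarse = coarse, refined = refined),
         run = run, wi = wi, pu = pu, summary = summary, paths = paths)
  }, error = function(e) {
    log_stage(log_path, paste0(stage, ":error"),
              message = conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Seven-panel aligned report figure
#'
#' Stacks ECG, blood pressure, dP/dt, inflow velocity U, dU/dt,
#' space-averaged WSS and wave intensity on a common time axis.
#'
#' @param ecg,pressure,usig `bio_signal`s (ECG, mmHg pressure, m/s inflow).
#' @param run A `umi_run`.
#' @param wi A `wave_intensity`.
#' @return A patchwork object of 7 aligned panels.
#' @export
plot_report_panels <- function(ecg, pressure, usig, run, wi) {
  xlim <- range(run$results$t)
  panel <- function(d, y, lab) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = {{ y }})) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::coord_cartesian(xlim = xlim) +
      ggplot2::labs(x = NULL, y = lab) +
      ggplot2::theme_minimal(base_size = 9)
  }
  dP <- derivative(pressure)
  dU <- derivative(usig)
  wbar <- tidy(run)
  p <- list(
    panel(ecg, .data$value, "ECG [mV]"),
    panel(pressure, .data$value, "P [mmHg]"),
    panel(dP, .data$value, "dP/dt [mmHg/s]"),
    panel(usig, .data$value, "U [m/s]"),
    panel(dU, .data$value, "dU/dt [m/s²]"),
    panel(wbar, .data$wss_mean, "WSS [Pa]"),
    panel(wi, .data$wi, "WI [Pa m/s³]") +
      ggplot2::labs(x = "time [s]")
  )
  patchwork::wrap_plots(p, ncol = 1)
}
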