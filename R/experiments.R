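#' Carotid-like pulse waveform on a beat grid
#'
#' Unit-amplitude pulse shape per beat: a systolic bump with a dicrotic
#' shoulder, summed over beats. Used as the common lumen-area driver for
#' synchronization twin experiments.
#'
#' @param t Time (s), vectorised.
#' @param beat_times R-wave (cycle start) times (s).
#' @return Numeric waveform, baseline 0, systolic peak approximately 1.
#' @export
carotid_pulse_shape <- function(t, beat_times) {
  v <- numeric(length(t))
  for (tb in beat_times) {
    v <- v + exp(-((t - tb - 0.18) / 0.09)^2) +
      0.30 * exp(-((t - tb - 0.45) / 0.12)^2)
  }
  v
}

#' One synchronization twin trial
#'
#' Generates a PPG waveform (Beer-Lambert, 200 Hz) and an image-pulse
#' waveform (34.394 Hz) from one common lumen-area waveform over
#' `n_cycles + 1` cardiac cycles, injects a known clock offset into the
#' image channel plus Gaussian jitter on its detected peak times, then runs
#' the two-stage synchronization: coarse 1-ms peak-time alignment over
#' `n_cycles` cycles, followed by 5-ms PU-loop linearity refinement on a
#' water-hammer beat carrying the residual misalignment. The recovered
#' offset is `coarse + refined`.
#'
#' @param offset Injected clock offset (s); drawn uniformly from
#'   `+/-offset_range` when `NULL`.
#' @param jitter_sd Gaussian s.d. of the image-channel peak-time jitter (s).
#' @param n_cycles Cycles used for the coarse alignment (default 6).
#' @param seed Trial seed (controls offset and jitter).
#' @param offset_range Half-range of the offset draw (s).
#' @param image_rate Image-pulse frame rate (Hz).
#' @param fs Pressure-channel sampling rate (Hz).
#' @return One-row tibble: `seed`, `offset`, `coarse`, `refined`,
#'   `recovered`, `error` (s).
#' @export
sync_twin_trial <- function(offset = NULL, jitter_sd = 5e-3, n_cycles = 6,
                            seed = 1L, offset_range = 0.3,
                            image_rate = 34.394, fs = 200) {
  rr <- c(0.88, 0.92, 0.86, 0.95, 0.90, 0.87, 0.91, 0.89)
  beat_times <- 0.4 + cumsum(c(0, rr[seq_len(n_cycles + 1)]))
  duration <- max(beat_times) + 0.8
  res <- with_seed(seed, {
    if (is.null(offset)) offset <- runif(1, -offset_range, offset_range)
    # common lumen-area waveform, and the two channels derived from it
    tt_p <- seq(0, duration, by = 1 / fs)
    pulse_p <- carotid_pulse_shape(tt_p, beat_times)
    ell <- 0.5 + 0.05 * pulse_p  # optical path (cm) follows the lumen
    ppg <- normalize_ppg(generate_ppg(bio_signal(ell, fs, 0), invert = TRUE))

    tt_i <- seq(0, duration, by = 1 / image_rate)
    area <- 3000 * (1 + 0.10 * carotid_pulse_shape(tt_i, beat_times))
    image_pulse <- inject_offset(bio_signal(area, image_rate, 0,
                                            kind = "image_pulse"), offset)

    ppg_peaks <- find_pulse_peaks(ppg, min_separation = 0.5)
    image_peaks <- find_pulse_peaks(image_pulse, min_separation = 0.5)
    image_peaks <- image_peaks + rnorm(length(image_peaks), 0, jitter_sd)

    coarse <- synchronize_clocks(ppg_peaks, image_peaks,
                                 n_cycles = n_cycles)
    resid <- offset - coarse  # residual lead of the flow channel

    # water-hammer beat: P = a + b U exactly; U carries the residual shift
    tb <- seq(0, 0.9, by = 1 / fs)
    u_true <- function(tau) {
      0.10 + 0.35 * exp(-((tau - 0.30) / 0.10)^2) +
        0.08 * exp(-((tau - 0.55) / 0.12)^2)
    }
    P <- bio_signal(80 + 100 * (u_true(tb) - 0.1), fs, 0, kind = "pressure")
    U <- bio_signal(u_true(tb - resid), fs, 0, kind = "velocity")
    refined <- as.numeric(refine_sync(P, U))
    recovered <- coarse + refined
    tibble::tibble(seed = seed, offset = offset, coarse = coarse,
                   refined = refined, recovered = recovered,
                   error = recovered - offset)
  })
  res
}

#' Monte-Carlo synchronization recovery study
#'
#' Repeats [sync_twin_trial()] over independent seeds with offsets drawn
#' uniformly from `+/-offset_range` and summarises the absolute recovery
#' error.
#'
#' @param n_trials Number of trials (default 100).
#' @param seed Base seed; trial k uses `seed * 1000 + k`.
#' @param jitter_sd,offset_range,n_cycles Passed to [sync_twin_trial()].
#' @return Tibble of per-trial results with attribute `summary` (one-row
#'   tibble: `p90_error_ms`, `max_error_ms`, `frac_within_10ms`).
#' @export
sync_recovery_study <- function(n_trials = 100, seed = 1L, jitter_sd = 5e-3,
                                offset_range = 0.3, n_cycles = 6) {
  base <- (as.integer(seed) %% 1000000L) * 1000L
  out <- purrr::map_dfr(seq_len(n_trials), function(k) {
    sync_twin_trial(offset = NULL, jitter_sd = jitter_sd,
                    n_cycles = n_cycles, seed = base + k,
                    offset_range = offset_range)
  })
  err_ms <- abs(out$error) * 1000
  attr(out, "summary") <- tibble::tibble(
    p90_error_ms = as.numeric(quantile(err_ms, 0.9, type = 7)),
    max_error_ms = max(err_ms),
    frac_within_10ms = mean(err_ms <= 10)
  )
  out
}
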