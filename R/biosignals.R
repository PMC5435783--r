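#' Uniformly sampled biological signal
#'
#' A tibble with columns `t` (s) and `value`, carrying the sampling rate,
#' clock origin and signal kind as attributes. All signal-chain verbs take
#' and return these tibbles.
#'
#' @param samples Numeric amplitude vector.
#' @param fs Sampling rate (Hz).
#' @param t0 Clock origin of the first sample (s).
#' @param kind One of `"ecg"`, `"ppg"`, `"image_pulse"`, `"pressure"`,
#'   `"velocity"`, `"generic"`.
#' @return A `bio_signal` tibble.
#' @export
bio_signal <- function(samples, fs, t0 = 0,
                       kind = c("generic", "ecg", "ppg", "image_pulse",
                                "pressure", "velocity")) {
  kind <- match.arg(kind)
  if (fs <= 0) stop("fs must be positive")
  if (any(!is.finite(samples))) stop("samples must be finite")
  out <- tibble::tibble(t = t0 + (seq_along(samples) - 1) / fs,
                        value = as.numeric(samples))
  structure(out, fs = fs, t0 = t0, kind = kind,
            class = c("bio_signal", class(out)))
}

#' @rdname bio_signal
#' @param x A `bio_signal` (or any tibble with a `t` column).
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) return(fs)
  1 / stats::median(diff(x$t))
}

#' @rdname bio_signal
#' @export
signal_kind <- function(x) attr(x, "kind") %||% "generic"

# rebuild a bio_signal from an existing one with new values / metadata
bs_update <- function(x, value = x$value, t = x$t, kind = signal_kind(x)) {
  out <- tibble::tibble(t = t, value = value)
  structure(out, fs = signal_fs(x), t0 = t[1], kind = kind,
            class = c("bio_signal", class(out)))
}

#' ECG filter-chain specification
#'
#' Defaults follow the acquisition chain of the measurement system: a 50 Hz
#' notch (10 Hz bandwidth, -90 dB target) against power-supply noise, a
#' 250th-order FIR high-pass (stop-band 2 Hz, pass-band 5 Hz) against
#' baseline drift, and a 200th-order FIR low-pass (stop-band 30 Hz,
#' pass-band 20 Hz) against myoelectric noise, all at 200 Hz sampling. All
#' filters are linear-phase FIR; the group delay is compensated exactly.
#'
#' @param fs Sampling rate (Hz).
#' @param notch_hz,notch_bw Notch centre and bandwidth (Hz).
#' @param notch_order FIR order of the notch (even).
#' @param notch_atten_db Target attenuation at the notch centre (dB).
#' @param hp_order,hp_stop,hp_pass High-pass FIR order and band edges (Hz).
#' @param lp_order,lp_stop,lp_pass Low-pass FIR order and band edges (Hz).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(fs = 200, notch_hz = 50, notch_bw = 10,
                        notch_order = 400, notch_atten_db = 90,
                        hp_order = 250, hp_stop = 2, hp_pass = 5,
                        lp_order = 200, lp_stop = 30, lp_pass = 20) {
  stopifnot(hp_stop < hp_pass, lp_pass < lp_stop,
            notch_order %% 2 == 0, hp_order %% 2 == 0, lp_order %% 2 == 0)
  structure(list(fs = fs, notch_hz = notch_hz, notch_bw = notch_bw,
                 notch_order = notch_order, notch_atten_db = notch_atten_db,
                 hp_order = hp_order, hp_stop = hp_stop, hp_pass = hp_pass,
                 lp_order = lp_order, lp_stop = lp_stop, lp_pass = lp_pass),
            class = "filter_spec")
}

# Kaiser-window FIR designs for the three stages.
make_filter_bank <- function(spec) {
  nyq <- spec$fs / 2
  notch <- signal::fir1(spec$notch_order,
                        c(spec$notch_hz - spec$notch_bw / 2,
                          spec$notch_hz + spec$notch_bw / 2) / nyq,
                        type = "stop",
                        window = signal::kaiser(spec$notch_order + 1, 9))
  hp_cut <- (spec$hp_stop + spec$hp_pass) / 2
  hp <- signal::fir1(spec$hp_order, hp_cut / nyq, type = "high",
                     window = signal::kaiser(spec$hp_order + 1, 5.65))
  lp_cut <- (spec$lp_stop + spec$lp_pass) / 2
  lp <- signal::fir1(spec$lp_order, lp_cut / nyq, type = "low",
                     window = signal::kaiser(spec$lp_order + 1, 8))
  list(notch = as.numeric(notch), hp = as.numeric(hp), lp = as.numeric(lp))
}

# Zero-delay linear-phase FIR application with reflection padding.
apply_fir <- function(x, h) {
  n <- length(h)
  stopifnot(n %% 2 == 1)
  half <- (n - 1) / 2
  np <- length(x)
  pad <- min(half, np - 1)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[np] - x[seq(np - 1, np - pad)]
  xp <- c(left, x, right)
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(pad + 1):(pad + np)])
}

#' Filter an ECG signal
#'
#' Applies the notch, high-pass and low-pass stages of a [filter_spec()] in
#' sequence. All stages are linear-phase FIR filters applied with exact
#' group-delay compensation, so the output stays aligned with the input
#' clock.
#'
#' @param raw A `bio_signal` (ECG).
#' @param spec A [filter_spec()]; its `fs` must match the signal.
#' @return Filtered `bio_signal`.
#' @export
filter_ecg <- function(raw, spec = filter_spec()) {
  fs <- signal_fs(raw)
  if (abs(fs - spec$fs) > 1e-9 * spec$fs) {
    stop("signal sampling rate (", fs, " Hz) does not match the filter spec (",
         spec$fs, " Hz)")
  }
  bank <- make_filter_bank(spec)
  v <- raw$value
  for (h in bank) v <- apply_fir(v, h)
  bs_update(raw, value = v, kind = "ecg")
}

#' Detect R-wave peaks
#'
#' The R peak is taken as the maximum of the ECG in each cardiac cycle:
#' candidate samples above `threshold_frac` of the record maximum are
#' accepted greedily in order of decreasing amplitude (earlier sample wins a
#' tie) with a refractory separation of `min_rr`.
#'
#' @param ecg Filtered ECG `bio_signal`.
#' @param min_rr Minimum RR interval (s).
#' @param threshold_frac Acceptance threshold as a fraction of the record
#'   maximum amplitude.
#' @return A `cardiac_timing` tibble: `beat`, `t_peak` (s), `rr` (s, NA for
#'   the first beat). A flat signal yields zero rows with a warning.
#' @export
detect_r_peaks <- function(ecg, min_rr = 0.4, threshold_frac = 0.4) {
  v <- ecg$value; tt <- ecg$t
  rng <- max(v) - min(v)
  if (rng < .Machine$double.eps^0.5) {
    warning("flat ECG signal: no R peaks detected")
    out <- tibble::tibble(beat = integer(0), t_peak = numeric(0),
                          rr = numeric(0))
    class(out) <- c("cardiac_timing", class(out))
    return(out)
  }
  thr <- min(v) + threshold_frac * rng
  cand <- which(v > thr)
  ord <- cand[order(-v[cand], tt[cand])]
  acc <- numeric(0)
  for (i in ord) {
    if (all(abs(tt[i] - acc) >= min_rr)) acc <- c(acc, tt[i])
  }
  acc <- sort(acc)
  out <- tibble::tibble(beat = seq_along(acc), t_peak = acc,
                        rr = c(NA_real_, diff(acc)))
  class(out) <- c("cardiac_timing", class(out))
  out
}

#' Normalise a PPG signal to [0, 1]
#'
#' Affine map sending the record minimum to 0 and maximum to 1 (per
#' measurement record).
#'
#' @param ppg A `bio_signal`.
#' @return Normalised `bio_signal` (kind `"ppg"`).
#' @export
normalize_ppg <- function(ppg) {
  v <- ppg$value
  rng <- max(v) - min(v)
  if (rng < .Machine$double.eps^0.5) stop("constant signal cannot be normalised")
  bs_update(ppg, value = (v - min(v)) / rng, kind = "ppg")
}

#' Systolic/diastolic cuff calibration
#'
#' @param systolic,diastolic Cuff pressures (mmHg), `systolic > diastolic > 0`.
#' @return A `pressure_calibration` object.
#' @export
pressure_calibration <- function(systolic = 120, diastolic = 80) {
  if (!(systolic > diastolic && diastolic > 0)) {
    stop("require systolic > diastolic > 0")
  }
  structure(list(systolic = systolic, diastolic = diastolic),
            class = "pressure_calibration")
}

#' Calibrate a normalised PPG signal to pressure
#'
#' Maps the [0, 1] pulse waveform affinely so its minimum equals the
#' diastolic and its maximum the systolic cuff pressure, giving the blood
#' pressure pulse P0(t) in mmHg.
#'
#' @param ppg_norm Normalised `bio_signal` in [0, 1] ([normalize_ppg()]).
#' @param cal A [pressure_calibration()].
#' @return `bio_signal` of kind `"pressure"` (mmHg).
#' @export
calibrate_pressure <- function(ppg_norm, cal = pressure_calibration()) {
  v <- ppg_norm$value
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    stop("input must be normalised to [0, 1]; run normalize_ppg() first")
  }
  bs_update(ppg_norm, value = cal$diastolic + v * (cal$systolic - cal$diastolic),
            kind = "pressure")
}

#' Extract the image pulse (vessel area) from a B-mode-like image stack
#'
#' Each frame is binarised with Otsu's threshold (the lumen is darker than
#' the surrounding tissue), split with a watershed on the distance map, and
#' the pixel count of the largest lumen object is recorded. Frames where no
#' component is found are linearly interpolated with a warning.
#'
#' @param frames Grayscale stack: array `h x w x n` or list of matrices,
#'   values in any range.
#' @param fs Frame rate (Hz).
#' @param t0 Timestamp of the first frame (s).
#' @return `bio_signal` of kind `"image_pulse"` (lumen area in pixels).
#' @export
extract_image_pulse <- function(frames, fs, t0 = 0) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  area <- vapply(frames, function(img) {
    rng <- range(img)
    if (diff(rng) < .Machine$double.eps^0.5) return(NA_real_)
    imgn <- (img - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(imgn), range = c(0, 1))
    mask <- EBImage::Image((imgn < th) * 1)
    if (sum(mask) == 0) return(NA_real_)
    labs <- EBImage::watershed(EBImage::distmap(mask))
    tab <- tabulate(as.integer(labs[labs > 0]))
    if (length(tab) == 0) return(NA_real_)
    max(tab)
  }, numeric(1))
  if (any(is.na(area))) {
    warning(sum(is.na(area)), " frame(s) without a detectable lumen; ",
            "interpolated")
    ok <- which(!is.na(area))
    area <- stats::approx(ok, area[ok], xout = seq_along(area),
                          rule = 2)$y
  }
  bio_signal(area, fs, t0, kind = "image_pulse")
}

#' Scale the image pulse to a reference PPG waveform
#'
#' Least-squares affine scaling `a x + b` of the image pulse minimising the
#' squared error against the normalised PPG waveform; the image pulse is
#' resampled to the PPG sampling instants by linear interpolation over the
#' overlapping support.
#'
#' @param image_pulse,ppg_norm `bio_signal`s with overlapping time support.
#' @return The scaled image pulse (at its original timestamps) with
#'   attributes `scale_a`, `scale_b`.
#' @export
scale_to_reference <- function(image_pulse, ppg_norm) {
  lo <- max(min(image_pulse$t), min(ppg_norm$t))
  hi <- min(max(image_pulse$t), max(ppg_norm$t))
  sel <- ppg_norm$t >= lo & ppg_norm$t <= hi
  if (sum(sel) < 2) stop("fewer than 2 overlapping samples")
  xi <- stats::approx(image_pulse$t, image_pulse$value,
                      xout = ppg_norm$t[sel])$y
  fit <- stats::lm.fit(cbind(1, xi), ppg_norm$value[sel])
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  if (!is.finite(a)) { a <- 0; b <- mean(ppg_norm$value[sel]) }
  out <- bs_update(image_pulse, value = a * image_pulse$value + b)
  attr(out, "scale_a") <- unname(a)
  attr(out, "scale_b") <- unname(b)
  out
}

#' Per-cycle pulse peak times
#'
#' Greedy local-maximum detection with a refractory separation, optionally
#' refined to sub-sample resolution by a 3-point parabolic fit around each
#' sampled maximum (important at the 34.394 Hz image-pulse rate, where the
#' raw sample grid would quantise peak times to ~29 ms).
#'
#' @param x A `bio_signal`.
#' @param min_separation Minimum peak separation (s).
#' @param threshold_frac Acceptance threshold as a fraction of the record
#'   amplitude range.
#' @param refine Parabolic sub-sample refinement (default TRUE).
#' @return Numeric vector of peak times (s).
#' @export
find_pulse_peaks <- function(x, min_separation = 0.4, threshold_frac = 0.5,
                             refine = TRUE) {
  v <- x$value; tt <- x$t
  n <- length(v)
  rng <- max(v) - min(v)
  if (rng < .Machine$double.eps^0.5) return(numeric(0))
  thr <- min(v) + threshold_frac * rng
  isloc <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
               v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(isloc & v > thr)
  ord <- cand[order(-v[cand], tt[cand])]
  acc <- integer(0)
  for (i in ord) {
    if (length(acc) == 0 || all(abs(tt[i] - tt[acc]) >= min_separation)) {
      acc <- c(acc, i)
    }
  }
  acc <- sort(acc)
  pk <- tt[acc]
  if (refine) {
    dt <- 1 / signal_fs(x)
    for (k in seq_along(acc)) {
      i <- acc[k]
      if (i > 1 && i < n) {
        den <- v[i - 1] - 2 * v[i] + v[i + 1]
        if (den < 0) {
          delta <- 0.5 * (v[i - 1] - v[i + 1]) / den
          pk[k] <- tt[i] + max(-0.5, min(0.5, delta)) * dt
        }
      }
    }
  }
  pk
}

#' Coarse clock synchronization from pulse peak times
#'
#' Finds the integer-millisecond clock shift of the image-pulse channel
#' relative to the PPG channel that minimises the mean squared difference of
#' peak times over `n_cycles` cardiac cycles: the recovered shift `s`
#' satisfies `image_peaks - s ~ ppg_peaks`. Peaks are paired by nearest
#' neighbour at each candidate shift; a candidate whose pairing is ambiguous
#' (two PPG peaks claiming one image peak) is discarded. Ties prefer the
#' smaller |shift|.
#'
#' @param ppg_peaks,image_peaks Peak-time vectors (s).
#' @param shift_step Shift quantum (s), default 1 ms.
#' @param n_cycles Number of cycles used (default 6).
#' @param search_range Maximum |shift| searched (s).
#' @return Recovered shift (s).
#' @export
synchronize_clocks <- function(ppg_peaks, image_peaks, shift_step = 1e-3,
                               n_cycles = 6, search_range = 0.5) {
  if (length(ppg_peaks) < n_cycles || length(image_peaks) < n_cycles) {
    stop("need at least ", n_cycles, " peaks in each channel")
  }
  pp <- sort(ppg_peaks)[seq_len(n_cycles)]
  ip <- sort(image_peaks)
  shifts <- seq(-search_range, search_range, by = shift_step)
  obj <- vapply(shifts, function(s) {
    shifted <- ip - s
    idx <- vapply(pp, function(p) which.min(abs(shifted - p)), integer(1))
    if (anyDuplicated(idx)) return(Inf)
    mean((shifted[idx] - pp)^2)
  }, numeric(1))
  if (all(!is.finite(obj))) {
    stop("peak pairing is ambiguous at every candidate shift")
  }
  best <- min(obj[is.finite(obj)])
  cand <- shifts[which(obj <= best + .Machine$double.eps)]
  cand[which.min(abs(cand))]
}

#' Pulse transit time per beat
#'
#' PTT is the time from the ECG R-wave peak to the foot ("standing up"
#' point) of the pulse wave in the same beat. The foot is located by the
#' intersecting-tangents method: the tangent at the maximum-upslope point of
#' the systolic upstroke is intersected with the horizontal baseline through
#' the pre-upstroke minimum.
#'
#' @param timing A `cardiac_timing` from [detect_r_peaks()].
#' @param pulse A `bio_signal` pulse waveform covering the beats.
#' @param search_window Fraction of the beat interval after the R peak
#'   searched for the upstroke.
#' @return Tibble `beat`, `t_r`, `t_foot`, `ptt` (s; NA when no upstroke is
#'   found in a beat).
#' @export
compute_ptt <- function(timing, pulse, search_window = 0.6) {
  v <- pulse$value; tt <- pulse$t
  dt <- 1 / signal_fs(pulse)
  dv <- c(diff(v) / dt, NA)
  res <- purrr::map_dfr(seq_len(nrow(timing)), function(k) {
    tr <- timing$t_peak[k]
    tend <- if (k < nrow(timing)) {
      tr + search_window * (timing$t_peak[k + 1] - tr)
    } else {
      tr + search_window * stats::median(diff(timing$t_peak))
    }
    win <- which(tt >= tr & tt <= tend)
    if (length(win) < 4) {
      return(tibble::tibble(beat = timing$beat[k], t_r = tr,
                            t_foot = NA_real_, ptt = NA_real_))
    }
    im <- win[which.max(dv[win[-length(win)]])]
    slope <- dv[im]
    if (!is.finite(slope) || slope <= 0) {
      return(tibble::tibble(beat = timing$beat[k], t_r = tr,
                            t_foot = NA_real_, ptt = NA_real_))
    }
    base <- min(v[win[win <= im]])
    t_foot <- tt[im] - (v[im] - base) / slope
    tibble::tibble(beat = timing$beat[k], t_r = tr, t_foot = t_foot,
                   ptt = t_foot - tr)
  })
  res
}
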