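#' Smoothed first derivative of a uniformly sampled signal
#'
#' Local-polynomial (Savitzky-Golay) first derivative; endpoints use the
#' one-sided fits of the same local polynomial.
#'
#' @param series A `bio_signal`.
#' @param window Odd window length in samples (default 5).
#' @param order Polynomial order (default 2).
#' @return A `bio_signal` holding d(value)/dt in (units of value)/s.
#' @export
derivative <- function(series, window = 5, order = 2) {
  n <- nrow(series)
  if (window > n) stop("smoothing window larger than the series")
  dt <- 1 / signal_fs(series)
  d <- signal::sgolayfilt(series$value, p = order, n = window, m = 1, ts = dt)
  bs_update(series, value = as.numeric(d), kind = "generic")
}

# Intersecting-tangents foot of the first upstroke of a pulse waveform:
# tangent at the maximum-upslope point crossed with the horizontal baseline
# through the pre-upstroke minimum. Returns NA when there is no upstroke.
pulse_foot <- function(tt, v, fs) {
  ipk <- which.max(v)
  if (ipk < 3) return(NA_real_)
  dv <- diff(v[1:ipk]) * fs
  im <- which.max(dv)
  slope <- dv[im]
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  base <- min(v[1:im])
  tm <- 0.5 * (tt[im] + tt[im + 1])
  vm <- 0.5 * (v[im] + v[im + 1])
  tm - (vm - base) / slope
}

#' Wave intensity from synchronized pressure and velocity
#'
#' WI(t) = dP/dt * dU/dt, computed from Savitzky-Golay smoothed derivatives
#' after resampling `U` to the pressure sampling instants (linear
#' interpolation). Pressure in mmHg is converted to Pa for the product, so
#' WI is in (Pa/s)(m/s^2) = W/m^2/s^2... reported as Pa m / s^3. Samples are
#' labelled: `forward` when both derivatives are positive and WI exceeds the
#' significance threshold, `backward` when WI is below minus the threshold,
#' `absorption` when both derivatives are negative yet WI exceeds the
#' threshold (the late-systolic forward-running wave that decelerates the
#' flow), otherwise `none`. The threshold is `threshold_frac` of the record
#' maximum |WI|.
#'
#' @param P `bio_signal` of kind `"pressure"` (mmHg).
#' @param U `bio_signal` of velocity (m/s).
#' @param threshold_frac Label-significance threshold (default 0.05).
#' @param window,order Derivative smoothing parameters (see [derivative()]).
#' @return A `wave_intensity` tibble: `t`, `dPdt` (Pa/s), `dUdt` (m/s^2),
#'   `wi`, `label`.
#' @export
compute_wi <- function(P, U, threshold_frac = 0.05, window = 5, order = 2) {
  if (!isTRUE(all.equal(signal_fs(P), signal_fs(U))) ||
      nrow(P) != nrow(U) || max(abs(P$t - U$t)) > 1e-9) {
    lo <- max(min(P$t), min(U$t)); hi <- min(max(P$t), max(U$t))
    sel <- P$t >= lo & P$t <= hi
    if (sum(sel) < window) stop("pressure and velocity supports do not overlap")
    uv <- stats::approx(U$t, U$value, xout = P$t[sel])$y
    P <- bs_update(P, value = P$value[sel], t = P$t[sel], kind = "pressure")
    U <- bs_update(P, value = uv, kind = "velocity")
  }
  dP <- derivative(bs_update(P, value = P$value * MMHG_PA), window, order)
  dU <- derivative(U, window, order)
  wi <- dP$value * dU$value
  # absolute floor keeps numerically-zero records unlabelled
  thr <- max(threshold_frac * max(abs(wi)), 1e-9)
  label <- rep("none", length(wi))
  label[dP$value > 0 & dU$value > 0 & wi > thr] <- "forward"
  label[wi < -thr] <- "backward"
  label[dP$value < 0 & dU$value < 0 & wi > thr] <- "absorption"
  out <- tibble::tibble(t = P$t, dPdt = dP$value, dUdt = dU$value,
                        wi = wi, label = label)
  structure(out, threshold = thr,
            class = c("wave_intensity", class(out)))
}

#' Per-beat wave-intensity peak summary
#'
#' @param x A `wave_intensity`.
#' @param ... Unused.
#' @return One-row tibble: time and magnitude of the first forward peak
#'   (WI1), the negative (backward) peak, and the absorption-type positive
#'   peaks ordered by time (WI2 and, when present, a second one).
#' @export
glance.wave_intensity <- function(x, ...) {
  seg_peak <- function(lab, f = which.max) {
    sel <- x$label == lab
    if (!any(sel)) return(c(NA_real_, NA_real_))
    i <- which(sel)[f(x$wi[sel])]
    c(x$t[i], x$wi[i])
  }
  fwd <- seg_peak("forward")
  bwd <- seg_peak("backward", which.min)
  abs_idx <- which(x$label == "absorption")
  ab <- if (length(abs_idx)) {
    # split into contiguous runs, peak per run, ordered by time
    runs <- split(abs_idx, cumsum(c(1, diff(abs_idx) != 1)))
    pk <- vapply(runs, function(ii) ii[which.max(x$wi[ii])], numeric(1))
    pk <- sort(pk)
    rbind(x$t[pk], x$wi[pk])
  } else matrix(numeric(0), 2, 0)
  tibble::tibble(
    wi1_t = fwd[1], wi1 = fwd[2],
    neg_t = bwd[1], neg = bwd[2],
    wi2_t = if (ncol(ab) >= 1) ab[1, 1] else NA_real_,
    wi2 = if (ncol(ab) >= 1) ab[2, 1] else NA_real_,
    wi2b_t = if (ncol(ab) >= 2) ab[1, 2] else NA_real_,
    wi2b = if (ncol(ab) >= 2) ab[2, 2] else NA_real_
  )
}

#' @export
autoplot.wave_intensity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$wi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object[object$label != "none", ],
                        ggplot2::aes(colour = .data$label), size = 1) +
    ggplot2::labs(x = "time [s]", y = "wave intensity [Pa m / s^3]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Build a PU loop over one beat
#'
#' Pairs pressure P (vertical axis) with velocity U (horizontal axis) over
#' one beat, detects the systolic window from the foot of the U upstroke
#' (intersecting tangents) to the U peak, and quantifies how straight the
#' loop is there: `r_squared` of a linear fit, and the quadratic coefficient
#' of a least-squares parabola on range-normalised axes. With pressure on
#' the vertical axis, a loop bulging below its chord (positive quadratic
#' coefficient) is classified `concave` — delayed pressure; bulging above
#' (`convex`) — advanced pressure; |coefficient| below `straight_tol` is
#' `straight`, the exactly synchronized case of the water-hammer relation
#' P = rho c U.
#'
#' @param P,U `bio_signal`s covering one beat (resampled internally to the
#'   pressure instants).
#' @param straight_tol Tolerance on the normalised quadratic coefficient.
#' @return A `pu_loop` object; see [tidy.pu_loop()] / [glance.pu_loop()].
#' @export
build_pu_loop <- function(P, U, straight_tol = 0.05) {
  lo <- max(min(P$t), min(U$t)); hi <- min(max(P$t), max(U$t))
  sel <- P$t >= lo & P$t <= hi
  if (sum(sel) < 8) stop("pressure and velocity supports do not overlap")
  tt <- P$t[sel]
  pv <- P$value[sel]
  uv <- stats::approx(U$t, U$value, xout = tt)$y
  fs <- signal_fs(P)
  t_foot <- pulse_foot(tt, uv, fs)
  if (is.na(t_foot)) stop("no systolic upstroke found in U")
  t_peak <- tt[which.max(uv)]
  win <- tt >= t_foot & tt <= t_peak
  if (sum(win) < 4) {
    win <- tt >= (t_foot - 2 / fs) & tt <= t_peak
  }
  if (sum(win) < 4) stop("systolic window too short")
  pw <- pv[win]; uw <- uv[win]
  r2 <- suppressWarnings(stats::cor(uw, pw)^2)
  if (!is.finite(r2)) r2 <- 0
  u01 <- (uw - min(uw)) / max(max(uw) - min(uw), .Machine$double.eps)
  p01 <- (pw - min(pw)) / max(max(pw) - min(pw), .Machine$double.eps)
  qfit <- stats::lm.fit(cbind(1, u01, u01^2), p01)
  a2 <- unname(qfit$coefficients[3])
  classification <- if (!is.finite(a2) || abs(a2) <= straight_tol) "straight"
  else if (a2 > 0) "concave" else "convex"
  structure(
    list(data = tibble::tibble(t = tt, P = pv, U = uv, systolic = win),
         window = c(foot = t_foot, peak = t_peak),
         r_squared = r2, quad_coef = a2, classification = classification),
    class = "pu_loop"
  )
}

#' @export
print.pu_loop <- function(x, ...) {
  cat(sprintf("<pu_loop> systolic window %.3f-%.3f s, R^2 = %.4f, %s\n",
              x$window[1], x$window[2], x$r_squared, x$classification))
  invisible(x)
}

#' @rdname build_pu_loop
#' @param x A `pu_loop`.
#' @param ... Unused.
#' @export
tidy.pu_loop <- function(x, ...) x$data

#' @rdname build_pu_loop
#' @export
glance.pu_loop <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, quad_coef = x$quad_coef,
                 classification = x$classification,
                 t_foot = x$window[1], t_peak = x$window[2])
}

#' @export
autoplot.pu_loop <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$U, y = .data$P)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_path(data = d[d$systolic, ], colour = "red") +
    ggplot2::labs(x = "U [m/s]", y = "P [mmHg]",
                  title = sprintf("PU loop: R^2 = %.3f (%s)",
                                  object$r_squared, object$classification)) +
    ggplot2::theme_minimal()
}

#' Refine channel synchronization with the PU-loop linearity criterion
#'
#' Shifts the velocity channel in 5-ms steps over a +/-30 ms range and picks
#' the shift maximising the systolic-window R^2 of the PU loop; a straight
#' systolic limb indicates exact synchronization (water-hammer relation).
#' Ties prefer the smaller |shift|. Positive return value means the velocity
#' channel must be advanced by that amount.
#'
#' @param P Pressure `bio_signal` (mmHg).
#' @param U Velocity `bio_signal` (m/s).
#' @param shift_step Shift quantum (s), default 5 ms.
#' @param search_range Maximum |shift| (s), default 30 ms.
#' @return Refined shift (s) with attribute `r_squared` (the profile over
#'   candidates). Warns if the R^2 profile is not unimodal.
#' @export
refine_sync <- function(P, U, shift_step = 5e-3, search_range = 30e-3) {
  shifts <- seq(-search_range, search_range, by = shift_step)
  r2 <- vapply(shifts, function(s) {
    us <- bs_update(U, value = stats::approx(U$t - s, U$value, xout = U$t,
                                             rule = 2)$y)
    tryCatch(build_pu_loop(P, us)$r_squared, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(r2))) stop("PU loop not computable at any candidate shift")
  best <- max(r2, na.rm = TRUE)
  cand <- shifts[which(r2 >= best - 1e-12)]
  out <- cand[which.min(abs(cand))]
  ok <- which(!is.na(r2))
  dirs <- sign(diff(r2[ok]))
  dirs <- dirs[dirs != 0]
  if (length(rle(dirs)$values) > 2) {
    warning("systolic R^2 profile is not unimodal over the search range; ",
            "returning its argmax")
  }
  structure(out, r_squared = stats::setNames(r2, signif(shifts, 6)))
}
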