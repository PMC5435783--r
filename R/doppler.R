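#' Measurement grid
#'
#' Rectangular lattice of Doppler measurement points (cell centres at
#' `x0 + (i - 0.5) dx`, `y0 + (j - 0.5) dy`).
#'
#' @param nx,ny Number of measurement points in x and y.
#' @param dx,dy Measurement pitch (m).
#' @param x0,y0 Origin offset (m) relative to the computational domain.
#' @return A `meas_grid` object.
#' @export
meas_grid <- function(nx, ny, dx, dy, x0 = 0, y0 = 0) {
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, dy = dy, x0 = x0, y0 = y0),
            class = "meas_grid")
}

#' Measurement grid coincident with the computational cell centres
#' @param grid A `flow_grid`.
#' @return A [meas_grid()].
#' @export
meas_grid_from_flow <- function(grid) {
  meas_grid(grid$nx, grid$ny, grid$dx, grid$dy)
}

#' A single color-Doppler frame
#'
#' Beam-projected velocity samples on the measurement grid at one timestamp.
#' Positive values mean motion along `+beam`.
#'
#' @param V_m Matrix (nx x ny of the measurement grid) of Doppler velocities
#'   (m/s).
#' @param beam Length-2 unit vector of the ultrasound beam direction
#'   `c(ex, ey)`.
#' @param timestamp Acquisition time (s).
#' @param valid Logical matrix marking points where a measurement exists
#'   (default: all finite entries of `V_m`).
#' @param mgrid A [meas_grid()].
#' @return A `doppler_frame` object.
#' @export
doppler_frame <- function(V_m, beam, timestamp, valid = NULL, mgrid) {
  if (abs(sqrt(sum(beam^2)) - 1) > 1e-8) stop("beam must be a unit vector")
  if (is.null(valid)) valid <- is.finite(V_m)
  if (!all(dim(V_m) == c(mgrid$nx, mgrid$ny))) {
    stop("V_m dimensions do not match the measurement grid")
  }
  if (any(!is.finite(V_m[valid]))) stop("V_m must be finite on valid points")
  structure(list(V_m = V_m, beam = beam, timestamp = timestamp,
                 valid = valid, mgrid = mgrid),
            class = "doppler_frame")
}

#' Feedback configuration for measurement-integrated simulation
#'
#' @param K_v_star Non-dimensional feedback gain (>= 0); 0 reproduces an
#'   ordinary simulation. Default 500.
#' @param feedback_xmin,feedback_xmax Fractional x-extent of the feedback
#'   domain (defaults 1/36 and 29/36 of the domain from the upstream
#'   boundary).
#' @param U_char Characteristic velocity (m/s), default 0.1.
#' @param L_char Characteristic length (m), default the 6.4 mm upstream
#'   vessel diameter.
#' @param rho Density used for non-dimensionalisation (kg/m^3).
#' @param V_type Typical carotid blood velocity used to normalise the error
#'   norm (m/s), default 0.39.
#' @return A `feedback_config` object.
#' @export
feedback_config <- function(K_v_star = 500, feedback_xmin = 1 / 36,
                            feedback_xmax = 29 / 36, U_char = 0.1,
                            L_char = 6.4e-3, rho = 1.0e3, V_type = 0.39) {
  stopifnot(K_v_star >= 0, feedback_xmin >= 0, feedback_xmax <= 1,
            feedback_xmin <= feedback_xmax,
            U_char > 0, L_char > 0, rho > 0, V_type > 0)
  structure(list(K_v_star = K_v_star, feedback_xmin = feedback_xmin,
                 feedback_xmax = feedback_xmax, U_char = U_char,
                 L_char = L_char, rho = rho, V_type = V_type),
            class = "feedback_config")
}

# Bilinear interpolation of a cell-centred matrix at query points (m).
# Values are clamped to the boundary cell centres.
bilinear_interp <- function(M, dx, dy, xq, yq, x0 = 0, y0 = 0) {
  nx <- nrow(M); ny <- ncol(M)
  gx <- (xq - x0) / dx + 0.5
  gy <- (yq - y0) / dy + 0.5
  i0 <- pmin(pmax(floor(gx), 1), nx - 1)
  j0 <- pmin(pmax(floor(gy), 1), ny - 1)
  tx <- pmin(pmax(gx - i0, 0), 1)
  ty <- pmin(pmax(gy - j0, 0), 1)
  M00 <- M[cbind(i0, j0)]; M10 <- M[cbind(i0 + 1, j0)]
  M01 <- M[cbind(i0, j0 + 1)]; M11 <- M[cbind(i0 + 1, j0 + 1)]
  (1 - tx) * (1 - ty) * M00 + tx * (1 - ty) * M10 +
    (1 - tx) * ty * M01 + tx * ty * M11
}

#' Project a computed flow field onto the Doppler beam
#'
#' Interpolates the staggered velocity components to the measurement points
#' and projects onto the beam: `V_c = u ex + v ey`. When the measurement
#' grid coincides with the computational cell centres the interpolation
#' reduces to the staggered-to-centre average.
#'
#' @param field A [flow_field()].
#' @param beam Length-2 unit beam vector.
#' @param target A [meas_grid()]; default the computational cell centres.
#' @return Matrix of computed Doppler velocities on the measurement grid.
#' @export
project_doppler <- function(field, beam, target = NULL) {
  if (abs(sqrt(sum(beam^2)) - 1) > 1e-8) stop("beam must be a unit vector")
  grid <- field$grid
  if (is.null(target)) target <- meas_grid_from_flow(grid)
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (field$u[1:nx, , drop = FALSE] +
                 field$u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (field$v[, 1:ny, drop = FALSE] +
                 field$v[, 2:(ny + 1), drop = FALSE])
  same <- target$nx == nx && target$ny == ny &&
    isTRUE(all.equal(target$dx, grid$dx)) &&
    isTRUE(all.equal(target$dy, grid$dy)) &&
    target$x0 == 0 && target$y0 == 0
  if (same) {
    return(uc * beam[1] + vc * beam[2])
  }
  xq <- target$x0 + (seq_len(target$nx) - 0.5) * target$dx
  yq <- target$y0 + (seq_len(target$ny) - 0.5) * target$dy
  X <- matrix(rep(xq, times = target$ny), target$nx, target$ny)
  Y <- matrix(rep(yq, each = target$nx), target$nx, target$ny)
  uq <- bilinear_interp(uc, grid$dx, grid$dy, X, Y)
  vq <- bilinear_interp(vc, grid$dx, grid$dy, X, Y)
  matrix(uq * beam[1] + vq * beam[2], target$nx, target$ny)
}

# Logical mask of computational columns inside the feedback domain.
feedback_columns <- function(grid, cfg) {
  xfrac <- ((seq_len(grid$nx)) - 0.5) / grid$nx
  xfrac >= cfg$feedback_xmin & xfrac <= cfg$feedback_xmax
}

# Feedback-domain mask on a measurement grid (relative to the computational
# domain extent).
feedback_mask_meas <- function(mgrid, grid, cfg) {
  xq <- mgrid$x0 + (seq_len(mgrid$nx) - 0.5) * mgrid$dx
  Lx <- grid$nx * grid$dx
  inx <- xq / Lx >= cfg$feedback_xmin & xq / Lx <= cfg$feedback_xmax
  matrix(rep(inx, times = mgrid$ny), mgrid$nx, mgrid$ny)
}

#' Feedback body force from the Doppler velocity mismatch
#'
#' `f = -K_v* (rho U / L) (V_c - V_m) e_beam` on valid measurement points
#' inside the feedback domain, zero elsewhere; the sign drives the computed
#' Doppler velocity toward the measured one. The mismatch is transferred to
#' the computational cell centres by bilinear interpolation (identity when
#' the grids coincide). The returned list also carries the diagonal source
#' linearisation (`sp_u`, `sp_v` <= 0, N/m^3 per m/s) so the solver can
#' treat the self-coupling implicitly, which keeps high gains stable.
#'
#' @param V_c Computed Doppler raster (measurement grid).
#' @param V_m Measured Doppler raster (same grid).
#' @param cfg A [feedback_config()].
#' @param grid The computational `flow_grid`.
#' @param beam Unit beam vector.
#' @param mgrid Measurement grid; default the computational cell centres.
#' @param valid Logical matrix of valid measurement points.
#' @return List `fx`, `fy` (N/m^3, nx x ny) and `sp_u`, `sp_v`.
#' @export
feedback_force <- function(V_c, V_m, cfg, grid, beam, mgrid = NULL,
                           valid = NULL) {
  if (is.null(mgrid)) mgrid <- meas_grid_from_flow(grid)
  if (!all(dim(V_c) == dim(V_m))) stop("V_c and V_m rasters are misaligned")
  if (!all(dim(V_m) == c(mgrid$nx, mgrid$ny))) {
    stop("rasters are misaligned with the measurement grid")
  }
  if (is.null(valid)) valid <- matrix(TRUE, mgrid$nx, mgrid$ny)
  gain <- cfg$K_v_star * cfg$rho * cfg$U_char / cfg$L_char
  dV <- V_c - V_m
  dV[!valid] <- 0
  dV[!(feedback_mask_meas(mgrid, grid, cfg))] <- 0
  same <- mgrid$nx == grid$nx && mgrid$ny == grid$ny &&
    isTRUE(all.equal(mgrid$dx, grid$dx)) &&
    isTRUE(all.equal(mgrid$dy, grid$dy)) && mgrid$x0 == 0 && mgrid$y0 == 0
  if (same) {
    dVc <- dV
    active <- valid & feedback_mask_meas(mgrid, grid, cfg)
  } else {
    xq <- (seq_len(grid$nx) - 0.5) * grid$dx
    yq <- (seq_len(grid$ny) - 0.5) * grid$dy
    X <- matrix(rep(xq, times = grid$ny), grid$nx, grid$ny)
    Y <- matrix(rep(yq, each = grid$nx), grid$nx, grid$ny)
    dVc <- matrix(bilinear_interp(dV, mgrid$dx, mgrid$dy, X, Y,
                                  mgrid$x0, mgrid$y0),
                  grid$nx, grid$ny)
    active <- matrix(bilinear_interp((valid &
                                        feedback_mask_meas(mgrid, grid, cfg)) * 1,
                                     mgrid$dx, mgrid$dy, X, Y,
                                     mgrid$x0, mgrid$y0) > 0.5,
                     grid$nx, grid$ny)
  }
  fb_cols <- feedback_columns(grid, cfg)
  dVc[!fb_cols, ] <- 0
  active[!fb_cols, ] <- FALSE
  dVc[!grid$fluid] <- 0
  active <- active & grid$fluid
  f <- -gain * dVc
  sp <- matrix(0, grid$nx, grid$ny)
  sp[active] <- -gain
  list(fx = f * beam[1], fy = f * beam[2],
       sp_u = sp * beam[1]^2, sp_v = sp * beam[2]^2)
}

#' Doppler-velocity error norm
#'
#' Mean absolute difference between computed and measured Doppler velocities
#' over the feedback-domain measurement points with valid data, normalised
#' by the typical carotid velocity `V_type`:
#' `e(t) = (1/N_e) sum |V_c - V_m| / V_type`.
#'
#' @param V_c,V_m Doppler rasters on the measurement grid.
#' @param valid Logical matrix of valid points.
#' @param V_type Normalising velocity (m/s).
#' @param domain Optional logical matrix restricting to the feedback domain
#'   (default: all valid points).
#' @return Non-negative scalar error norm (non-dimensional), with attribute
#'   `N_e` (number of points summed).
#' @export
error_norm <- function(V_c, V_m, valid = NULL, V_type = 0.39, domain = NULL) {
  if (!all(dim(V_c) == dim(V_m))) stop("V_c and V_m rasters are misaligned")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(V_m), ncol(V_m))
  sel <- valid
  if (!is.null(domain)) sel <- sel & domain
  n <- sum(sel)
  if (n < 1) stop("no valid feedback-domain points (N_e = 0)")
  e <- mean(abs(V_c[sel] - V_m[sel])) / V_type
  attr(e, "N_e") <- n
  e
}

#' Golden-section minimisation on a bracket
#'
#' Pure golden-section search: the bracket is shrunk by the inverse golden
#' ratio each iteration until its width falls below `tol`; assumes the
#' objective is unimodal on the bracket.
#'
#' @param f Objective function of a scalar.
#' @param lower,upper Bracket (lower < upper).
#' @param tol Absolute bracket-width termination tolerance.
#' @param max_iter Safety cap on iterations.
#' @return List with `minimum`, `objective`, `evals`.
#' @export
golden_section <- function(f, lower, upper, tol = 1e-4, max_iter = 200L) {
  if (lower >= upper) stop("bracket inverted: lower must be < upper")
  invphi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - invphi * (b - a)
  c2 <- a + invphi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  evals <- 2L
  while ((b - a) > tol && evals < max_iter) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - invphi * (b - a)
      f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + invphi * (b - a)
      f2 <- f(c2)
    }
    evals <- evals + 1L
  }
  if ((b - a) > tol) {
    warning("golden-section search did not reach the bracket tolerance; ",
            "returning the best point found")
  }
  if (f1 <= f2) list(minimum = c1, objective = f1, evals = evals)
  else list(minimum = c2, objective = f2, evals = evals)
}
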