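#' Fluid properties
#'
#' @param rho Density (kg/m^3), default 1.0e3 (blood).
#' @param mu Dynamic viscosity (Pa s), default 4.0e-3 (blood, Newtonian).
#' @return A `fluid_props` object.
#' @export
fluid_props <- function(rho = 1.0e3, mu = 4.0e-3) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_props")
}

#' Inlet/outlet/wall boundary condition
#'
#' A parabolic (or user-shaped) velocity profile with a prescribed mean is
#' imposed across the local lumen at the upstream boundary; the downstream
#' boundary is free-flow (zero streamwise gradient with a global mass
#' correction) and the vessel walls are no-slip.
#'
#' @param inlet_mean_velocity Cross-sectional mean inlet velocity (m/s).
#' @param profile `"parabolic"` or a function of the normalised cross-stream
#'   coordinate eta in (0, 1) giving the profile shape (it is renormalised to
#'   discrete mean 1, so only the shape matters).
#' @return A `boundary_condition` object.
#' @export
boundary_condition <- function(inlet_mean_velocity, profile = "parabolic") {
  structure(list(inlet_mean_velocity = inlet_mean_velocity, profile = profile),
            class = "boundary_condition")
}

#' Solver settings
#'
#' @param dt Time step (s). Default 29.075 ms, the Doppler frame interval at
#'   34.394 Hz.
#' @param residual_tol Non-dimensional residual convergence criterion for the
#'   outer (pressure-velocity coupling) iterations; default 1.0e-2.
#' @param max_outer Maximum outer iterations per time step.
#' @param relax_u,relax_p Under-relaxation factors for momentum (0.7) and the
#'   pressure update (0.3).
#' @param time_scheme `"bdf2"` (second-order implicit; first step falls back
#'   to backward Euler) or `"euler"`.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(dt = 29.075e-3, residual_tol = 1.0e-2,
                            max_outer = 200L, relax_u = 0.7, relax_p = 0.3,
                            time_scheme = c("bdf2", "euler")) {
  stopifnot(dt > 0, residual_tol > 0)
  time_scheme <- match.arg(time_scheme)
  structure(list(dt = dt, residual_tol = residual_tol,
                 max_outer = as.integer(max_outer),
                 relax_u = relax_u, relax_p = relax_p,
                 time_scheme = time_scheme),
            class = "solver_settings")
}

#' Flow field state
#'
#' Staggered arrangement: `u` ((nx+1) x ny) on x-faces, `v` (nx x (ny+1)) on
#' y-faces, `p` (nx x ny, Pa, relative) at cell centres; all zero outside the
#' lumen. `u[1, ]` is the inlet face, `u[nx+1, ]` the outlet face.
#'
#' @param grid A [build_grid()] result.
#' @param t Time (s).
#' @return A `flow_field` object.
#' @export
flow_field <- function(grid, t = 0) {
  structure(list(u = matrix(0, grid$nx + 1, grid$ny),
                 v = matrix(0, grid$nx, grid$ny + 1),
                 p = matrix(0, grid$nx, grid$ny),
                 t = t, grid = grid, prev = NULL),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> t = %.4f s, max |u| = %.4g m/s, max |v| = %.4g m/s\n",
              x$t, max(abs(x$u)), max(abs(x$v))))
  invisible(x)
}

# Discrete inlet profile: vector over ny, zero outside the inlet lumen span,
# renormalised so its discrete mean over the span equals the prescribed mean.
inlet_profile <- function(grid, bc) {
  js <- grid$jlo[1]:grid$jhi[1]
  eta <- (seq_along(js) - 0.5) / length(js)
  shape <- if (is.function(bc$profile)) bc$profile(eta) else 6 * eta * (1 - eta)
  if (any(!is.finite(shape))) stop("invalid inlet profile shape")
  prof <- numeric(grid$ny)
  m <- mean(shape)
  prof[js] <- if (abs(m) > 0) shape / m * bc$inlet_mean_velocity else 0
  prof
}

# matrix shift: entries M[i+di, j+dj], out-of-range filled with `fill`
shiftm <- function(M, di, dj, fill = 0) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  ci <- max(1, 1 - dj):min(nc, nc - dj)
  out[ri, ci] <- M[ri + di, ci + dj]
  out
}

# Existence masks for staggered faces.
face_masks <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; f <- grid$fluid
  ufex <- matrix(FALSE, nx + 1, ny)
  ufex[1, ] <- f[1, ]
  ufex[nx + 1, ] <- f[nx, ]
  if (nx >= 2) ufex[2:nx, ] <- f[1:(nx - 1), ] & f[2:nx, ]
  u_unk <- matrix(FALSE, nx + 1, ny)
  if (nx >= 2) u_unk[2:nx, ] <- ufex[2:nx, ]
  vfex <- matrix(FALSE, nx, ny + 1)  # v faces with fluid on both sides
  if (ny >= 2) vfex[, 2:ny] <- f[, 1:(ny - 1)] & f[, 2:ny]
  v_unk <- vfex
  list(ufex = ufex, u_unk = u_unk, v_unk = v_unk)
}

# QUICK deferred correction for one velocity component on its own lattice.
# phi: component matrix; F*: mass-flux matrices on the CV faces (same dims as
# phi, meaningful at unknowns); ex: existence mask used to decide fallback.
quick_correction <- function(phi, Fe, Fw, Fn, Fs, ex) {
  f_e_u <- shiftm(phi, 0, 0);  f_e_d <- shiftm(phi, 1, 0)
  f_e_uu <- shiftm(phi, -1, 0); f_e_dd <- shiftm(phi, 2, 0)
  ok_pos <- shiftm(ex, -1, 0) & ex & shiftm(ex, 1, 0)
  ok_neg <- ex & shiftm(ex, 1, 0) & shiftm(ex, 2, 0)
  q_e <- ifelse(Fe >= 0,
                ifelse(ok_pos, 0.75 * f_e_u + 0.375 * f_e_d - 0.125 * f_e_uu,
                       f_e_u),
                ifelse(ok_neg, 0.75 * f_e_d + 0.375 * f_e_u - 0.125 * f_e_dd,
                       f_e_d))
  up_e <- ifelse(Fe >= 0, f_e_u, f_e_d)

  f_w_u <- shiftm(phi, -1, 0); f_w_d <- phi
  f_w_uu <- shiftm(phi, -2, 0); f_w_dd <- shiftm(phi, 1, 0)
  ok_pos <- shiftm(ex, -2, 0) & shiftm(ex, -1, 0) & ex
  ok_neg <- shiftm(ex, -1, 0) & ex & shiftm(ex, 1, 0)
  q_w <- ifelse(Fw >= 0,
                ifelse(ok_pos, 0.75 * f_w_u + 0.375 * f_w_d - 0.125 * f_w_uu,
                       f_w_u),
                ifelse(ok_neg, 0.75 * f_w_d + 0.375 * f_w_u - 0.125 * f_w_dd,
                       f_w_d))
  up_w <- ifelse(Fw >= 0, f_w_u, f_w_d)

  f_n_u <- phi; f_n_d <- shiftm(phi, 0, 1)
  f_n_uu <- shiftm(phi, 0, -1); f_n_dd <- shiftm(phi, 0, 2)
  ok_pos <- shiftm(ex, 0, -1) & ex & shiftm(ex, 0, 1)
  ok_neg <- ex & shiftm(ex, 0, 1) & shiftm(ex, 0, 2)
  q_n <- ifelse(Fn >= 0,
                ifelse(ok_pos, 0.75 * f_n_u + 0.375 * f_n_d - 0.125 * f_n_uu,
                       f_n_u),
                ifelse(ok_neg, 0.75 * f_n_d + 0.375 * f_n_u - 0.125 * f_n_dd,
                       f_n_d))
  up_n <- ifelse(Fn >= 0, f_n_u, f_n_d)

  f_s_u <- shiftm(phi, 0, -1); f_s_d <- phi
  f_s_uu <- shiftm(phi, 0, -2); f_s_dd <- shiftm(phi, 0, 1)
  ok_pos <- shiftm(ex, 0, -2) & shiftm(ex, 0, -1) & ex
  ok_neg <- shiftm(ex, 0, -1) & ex & shiftm(ex, 0, 1)
  q_s <- ifelse(Fs >= 0,
                ifelse(ok_pos, 0.75 * f_s_u + 0.375 * f_s_d - 0.125 * f_s_uu,
                       f_s_u),
                ifelse(ok_neg, 0.75 * f_s_d + 0.375 * f_s_u - 0.125 * f_s_dd,
                       f_s_d))
  up_s <- ifelse(Fs >= 0, f_s_u, f_s_d)

  (Fe * up_e - Fw * up_w + Fn * up_n - Fs * up_s) -
    (Fe * q_e - Fw * q_w + Fn * q_n - Fs * q_s)
}

# Assemble u-momentum coefficients on the (nx+1) x ny lattice. Returns full
# matrices (meaningful at unknowns) of neighbour coefficients, unrelaxed aP,
# and the source without the pressure-gradient term or relaxation.
assemble_u <- function(grid, u, v, u_n, u_nm1, props, dt_coef, fx_face, msk,
                       sp_face = NULL) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  rho <- props$rho; mu <- props$mu
  nxp <- nx + 1
  ufex <- msk$ufex

  Fe <- matrix(0, nxp, ny); Fw <- Fe; Fn <- Fe; Fs <- Fe
  if (nx >= 2) {
    I <- 2:nx
    Fe[I, ] <- rho * dy * 0.5 * (u[I, ] + u[I + 1, ])
    Fw[I, ] <- rho * dy * 0.5 * (u[I - 1, ] + u[I, ])
    Fn[I, ] <- rho * dx * 0.5 * (v[I - 1, 2:(ny + 1)] + v[I, 2:(ny + 1)])
    Fs[I, ] <- rho * dx * 0.5 * (v[I - 1, 1:ny] + v[I, 1:ny])
  }
  De <- mu * dy / dx; Dn <- mu * dx / dy

  aE <- De + pmax(-Fe, 0); aW <- De + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0); aS <- Dn + pmax(Fs, 0)

  # lateral stair-step walls at dy/2: one-sided quadratic diffusive flux
  # aP_extra compensates so the wall contributes exactly +3c to aP even
  # though the quadratic cross-term c/3 is carried inside aS/aN (which are
  # also summed into aP below).
  wallN <- msk$u_unk & !shiftm(ufex, 0, 1, fill = FALSE)
  wallS <- msk$u_unk & !shiftm(ufex, 0, -1, fill = FALSE)
  cwall <- mu * dx / dy
  aP_extra <- matrix(0, nxp, ny)
  aN[wallN] <- 0; aP_extra[wallN] <- aP_extra[wallN] + 3 * cwall - cwall / 3
  aS[wallN] <- aS[wallN] + cwall / 3
  aS[wallS] <- 0; aP_extra[wallS] <- aP_extra[wallS] + 3 * cwall - cwall / 3
  aN[wallS] <- aN[wallS] + cwall / 3

  vol <- dx * dy
  aT <- rho * vol * dt_coef$c0
  b <- rho * vol * (dt_coef$c1 * u_n + dt_coef$c2 * u_nm1) +
    fx_face * vol +
    quick_correction(u, Fe, Fw, Fn, Fs, ufex)
  # implicit (linearised) part of the body force: f = fx + sp (u - u_cur)
  if (!is.null(sp_face)) {
    aP_extra <- aP_extra - sp_face * vol
    b <- b - sp_face * vol * u
  }

  aP0 <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs) + aT + aP_extra
  list(aE = aE, aW = aW, aN = aN, aS = aS, aP0 = aP0, b = b)
}

assemble_v <- function(grid, u, v, v_n, v_nm1, props, dt_coef, fy_face, msk,
                       sp_face = NULL) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  rho <- props$rho; mu <- props$mu
  nyp <- ny + 1
  vfex <- msk$v_unk  # v faces that are actual fluid unknowns

  Fe <- matrix(0, nx, nyp); Fw <- Fe; Fn <- Fe; Fs <- Fe
  J <- 2:ny
  Fe[, J] <- rho * dy * 0.5 * (u[2:(nx + 1), J - 1] + u[2:(nx + 1), J])
  Fw[, J] <- rho * dy * 0.5 * (u[1:nx, J - 1] + u[1:nx, J])
  Fn[, J] <- rho * dx * 0.5 * (v[, J] + v[, J + 1])
  Fs[, J] <- rho * dx * 0.5 * (v[, J - 1] + v[, J])
  De <- mu * dy / dx; Dn <- mu * dx / dy

  aE <- De + pmax(-Fe, 0); aW <- De + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0); aS <- Dn + pmax(Fs, 0)

  # inlet plane at dx/2 (v = 0 there); outlet: zero-gradient, drop diffusion.
  # Under outlet inflow (Fe < 0) the zero-gradient flux Fe*v_P is split as
  # max(-Fe,0)*(v_P - v_P_old) implicit/deferred to keep the diagonal
  # positive; identical at convergence.
  aW[1, ] <- 2 * De + pmax(Fw[1, ], 0)
  aE[nx, ] <- 0
  out_in <- pmax(-Fe[nx, ], 0)

  vol <- dx * dy
  aT <- rho * vol * dt_coef$c0
  b <- rho * vol * (dt_coef$c1 * v_n + dt_coef$c2 * v_nm1) +
    fy_face * vol +
    quick_correction(v, Fe, Fw, Fn, Fs, vfex)
  aP_extra <- matrix(0, nx, nyp)
  aP_extra[nx, ] <- out_in
  b[nx, ] <- b[nx, ] + out_in * v[nx, ]
  if (!is.null(sp_face)) {
    aP_extra <- aP_extra - sp_face * vol
    b <- b - sp_face * vol * v
  }

  aP0 <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs) + aT + aP_extra
  list(aE = aE, aW = aW, aN = aN, aS = aS, aP0 = aP0, b = b)
}

# Sum over neighbours of a_nb * value_nb, using matrix shifts (known
# neighbours contribute their stored values; walls are zero).
neighbour_sum <- function(co, phi) {
  co$aE * shiftm(phi, 1, 0) + co$aW * shiftm(phi, -1, 0) +
    co$aN * shiftm(phi, 0, 1) + co$aS * shiftm(phi, 0, -1)
}

# Build and solve the sparse system for one velocity component. Neighbours
# outside the lattice contribute their boundary value (0 by construction of
# the stored field matrices).
solve_component <- function(co, phi, unk, b_total, aP_r) {
  nr <- nrow(phi); nc <- ncol(phi)
  idx <- which(unk)
  n <- length(idx)
  id_map <- matrix(0L, nr, nc)
  id_map[idx] <- seq_len(n)
  ai <- ((idx - 1L) %% nr) + 1L
  aj <- ((idx - 1L) %/% nr) + 1L
  i_list <- list(seq_len(n)); j_list <- list(seq_len(n))
  x_list <- list(aP_r[idx])
  bb <- b_total[idx]
  dirs <- list(c(1L, 0L, "aE"), c(-1L, 0L, "aW"), c(0L, 1L, "aN"),
               c(0L, -1L, "aS"))
  for (d in dirs) {
    di <- as.integer(d[1]); dj <- as.integer(d[2])
    a <- co[[d[3]]][idx]
    ni <- ai + di; nj <- aj + dj
    inb <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    nidx <- (nj - 1L) * nr + ni
    nid <- integer(n)
    nid[inb] <- id_map[nidx[inb]]
    link <- nid > 0L
    i_list[[length(i_list) + 1]] <- which(link)
    j_list[[length(j_list) + 1]] <- nid[link]
    x_list[[length(x_list) + 1]] <- -a[link]
    fold <- inb & !link
    bb[fold] <- bb[fold] + a[fold] * phi[nidx[fold]]
  }
  A <- Matrix::sparseMatrix(i = unlist(i_list), j = unlist(j_list),
                            x = unlist(x_list), dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, bb))
  phi[idx] <- sol
  phi
}

# Pressure(-correction) equation: coefficients from momentum aP, source from
# face velocities. Returns solved cell-centred field (0 outside fluid).
solve_pressure <- function(grid, dE, dW, dN, dS, src, props) {
  nx <- grid$nx; ny <- grid$ny
  rho <- props$rho
  fl <- grid$fluid
  idx <- which(fl)
  n <- length(idx)
  id_map <- matrix(0L, nx, ny)
  id_map[idx] <- seq_len(n)
  aE <- rho * dE; aW <- rho * dW; aN <- rho * dN; aS <- rho * dS
  aP <- aE + aW + aN + aS
  # pin the reference cell
  ref <- id_map[1, grid$jlo[1]]
  i_list <- list(seq_len(n)); j_list <- list(seq_len(n))
  aPv <- aP[idx]; aPv[ref] <- aPv[ref] + max(aPv)  # strengthen diagonal at ref
  x_list <- list(aPv)
  bb <- src[idx]
  dirs <- list(list(1L, 0L, aE), list(-1L, 0L, aW), list(0L, 1L, aN),
               list(0L, -1L, aS))
  for (d in dirs) {
    nidx <- idx + d[[1]] + d[[2]] * nx
    inb <- nidx >= 1 & nidx <= nx * ny
    nid <- integer(n); nid[inb] <- id_map[nidx[inb]]
    a <- d[[3]][idx]
    link <- nid > 0L & a > 0
    i_list[[length(i_list) + 1]] <- which(link)
    j_list[[length(j_list) + 1]] <- nid[link]
    x_list[[length(x_list) + 1]] <- -a[link]
  }
  A <- Matrix::sparseMatrix(i = unlist(i_list), j = unlist(j_list),
                            x = unlist(x_list), dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, bb))
  out <- matrix(0, nx, ny)
  out[idx] <- sol - sol[ref]
  out
}

#' Advance the flow field by one time step
#'
#' One implicit time step of the incompressible 2D Navier-Stokes equations,
#' solved with SIMPLER-style pressure-velocity coupling on the staggered grid:
#' QUICK convection by deferred correction (first-order upwind implicit),
#' second-order implicit (BDF2) time discretisation, an arbitrary body-force
#' field entering both the momentum equations and the pressure-equation
#' source, a parabolic inlet, free-flow outlet with global mass correction,
#' and no-slip stair-step walls. Outer iterations run until the
#' non-dimensional mass and momentum residuals drop below
#' `settings$residual_tol`.
#'
#' @param field A [flow_field()] at time level n.
#' @param bc A [boundary_condition()].
#' @param props A [fluid_props()].
#' @param body_force `NULL`, a list `list(fx, fy)` of cell-centred force
#'   densities (N/m^3, nx x ny matrices), or a function of the current
#'   iterate (a `flow_field`) returning such a list (re-evaluated every outer
#'   iteration, which tightly couples measurement feedback to the solve).
#' @param settings A [solver_settings()].
#' @param steady If `TRUE`, drop the transient term and iterate to a steady
#'   state (time is not advanced).
#' @param init Optional list with elements `u`, `v`, `p` used as the initial
#'   outer-iteration iterate (warm start); the time-level-n state is always
#'   taken from `field`.
#' @return A `flow_field` at time n+1 with attributes `outer_iters` and
#'   `residuals`.
#' @export
step <- function(field, bc, props, body_force = NULL,
                 settings = solver_settings(), steady = FALSE, init = NULL) {
  grid <- field$grid
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  nxp <- nx + 1
  msk <- face_masks(grid)
  dt <- settings$dt

  u_n <- field$u; v_n <- field$v
  bdf2 <- !steady && settings$time_scheme == "bdf2" && !is.null(field$prev)
  if (steady) {
    dt_coef <- list(c0 = 0, c1 = 0, c2 = 0)
    u_nm1 <- u_n * 0; v_nm1 <- v_n * 0
  } else if (bdf2) {
    dt_coef <- list(c0 = 1.5 / dt, c1 = 2 / dt, c2 = -0.5 / dt)
    u_nm1 <- field$prev$u; v_nm1 <- field$prev$v
  } else {
    dt_coef <- list(c0 = 1 / dt, c1 = 1 / dt, c2 = 0)
    u_nm1 <- u_n * 0; v_nm1 <- v_n * 0
  }

  if (is.null(init)) {
    u <- field$u; v <- field$v; p <- field$p
  } else {
    u <- init$u; v <- init$v; p <- init$p
  }
  u_in <- inlet_profile(grid, bc)
  u[1, ] <- u_in
  influx <- sum(u[1, ] * dy)
  # initial outlet guess: zero-gradient + mass correction
  out_f <- msk$ufex[nxp, ]
  u[nxp, ] <- 0
  u[nxp, out_f] <- u[nx, out_f] +
    (influx - sum(u[nx, out_f] * dy)) / (sum(out_f) * dy)

  h_in <- (grid$jhi[1] - grid$jlo[1] + 1) * dy
  relax_u <- settings$relax_u; relax_p <- settings$relax_p
  mass_res <- Inf; mom_res <- Inf
  res_hist <- numeric(0)
  iters <- 0L

  for (it in seq_len(settings$max_outer)) {
    iters <- it
    cur <- structure(list(u = u, v = v, p = p, t = field$t, grid = grid),
                     class = "flow_field")
    bf <- if (is.function(body_force)) body_force(cur) else body_force
    fx <- if (is.null(bf)) matrix(0, nx, ny) else bf$fx
    fy <- if (is.null(bf)) matrix(0, nx, ny) else bf$fy
    fx_face <- matrix(0, nxp, ny)
    if (nx >= 2) fx_face[2:nx, ] <- 0.5 * (fx[1:(nx - 1), ] + fx[2:nx, ])
    fy_face <- matrix(0, nx, ny + 1)
    fy_face[, 2:ny] <- 0.5 * (fy[, 1:(ny - 1)] + fy[, 2:ny])
    spu_face <- NULL; spv_face <- NULL
    if (!is.null(bf) && !is.null(bf$sp_u)) {
      spu_face <- matrix(0, nxp, ny)
      if (nx >= 2) spu_face[2:nx, ] <- 0.5 * (bf$sp_u[1:(nx - 1), ] +
                                                bf$sp_u[2:nx, ])
      spv_face <- matrix(0, nx, ny + 1)
      spv_face[, 2:ny] <- 0.5 * (bf$sp_v[, 1:(ny - 1)] + bf$sp_v[, 2:ny])
    }

    au <- assemble_u(grid, u, v, u_n, u_nm1, props, dt_coef, fx_face, msk,
                     spu_face)
    av <- assemble_v(grid, u, v, v_n, v_nm1, props, dt_coef, fy_face, msk,
                     spv_face)

    # pressure-gradient source terms at faces
    bPu <- matrix(0, nxp, ny)
    if (nx >= 2) bPu[2:nx, ] <- dy * (p[1:(nx - 1), ] - p[2:nx, ])
    bPv <- matrix(0, nx, ny + 1)
    bPv[, 2:ny] <- dx * (p[, 1:(ny - 1)] - p[, 2:ny])

    # nonlinear residuals of the previous iterate (unrelaxed), scaled by the
    # total momentum content sum(|aP phi|) as is standard for FV codes
    Uref <- max(abs(bc$inlet_mean_velocity), max(abs(u)), 1e-2)
    imb_u <- au$aP0 * u - neighbour_sum(au, u) - au$b - bPu
    imb_v <- av$aP0 * v - neighbour_sum(av, v) - av$b - bPv
    mdenom <- max(sum(abs((au$aP0 * u)[msk$u_unk])) +
                    sum(abs((av$aP0 * v)[msk$v_unk])),
                  props$rho * Uref^2 * h_in * 1e-3)
    mom_res <- (sum(abs(imb_u[msk$u_unk])) + sum(abs(imb_v[msk$v_unk]))) /
      mdenom
    if (it > 1 && mass_res < settings$residual_tol &&
        mom_res < settings$residual_tol) {
      iters <- it - 1L
      break
    }

    aPu_r <- au$aP0 / relax_u
    aPv_r <- av$aP0 / relax_u
    relax_bu <- (1 - relax_u) * aPu_r * u
    relax_bv <- (1 - relax_u) * aPv_r * v

    # SIMPLER: pressure from pseudo-velocities
    uh <- u; vh <- v
    uh[msk$u_unk] <- ((neighbour_sum(au, u) + au$b + relax_bu)[msk$u_unk]) /
      aPu_r[msk$u_unk]
    vh[msk$v_unk] <- ((neighbour_sum(av, v) + av$b + relax_bv)[msk$v_unk]) /
      aPv_r[msk$v_unk]

    dE <- matrix(0, nx, ny); dW <- dE; dN <- dE; dS <- dE
    de_face <- matrix(0, nxp, ny)
    de_face[msk$u_unk] <- dy^2 / aPu_r[msk$u_unk]
    dn_face <- matrix(0, nx, ny + 1)
    dn_face[msk$v_unk] <- dx^2 / aPv_r[msk$v_unk]
    dE <- de_face[2:nxp, , drop = FALSE]
    dW <- de_face[1:nx, , drop = FALSE]
    dN <- dn_face[, 2:(ny + 1), drop = FALSE]
    dS <- dn_face[, 1:ny, drop = FALSE]

    src_p <- props$rho * ((uh[1:nx, ] - uh[2:nxp, ]) * dy +
                            (vh[, 1:ny] - vh[, 2:(ny + 1)]) * dx)
    p_new <- solve_pressure(grid, dE, dW, dN, dS, src_p, props)
    p <- p + relax_p * (p_new - p)

    # momentum solves with the updated pressure
    bPu <- matrix(0, nxp, ny)
    if (nx >= 2) bPu[2:nx, ] <- dy * (p[1:(nx - 1), ] - p[2:nx, ])
    bPv <- matrix(0, nx, ny + 1)
    bPv[, 2:ny] <- dx * (p[, 1:(ny - 1)] - p[, 2:ny])
    u <- solve_component(au, u, msk$u_unk, au$b + bPu + relax_bu, aPu_r)
    v <- solve_component(av, v, msk$v_unk, av$b + bPv + relax_bv, aPv_r)

    # outlet: zero-gradient + additive global mass correction
    u[nxp, ] <- 0
    u[nxp, out_f] <- u[nx, out_f] +
      (influx - sum(u[nx, out_f] * dy)) / (sum(out_f) * dy)

    # pressure correction to restore continuity
    src_pc <- props$rho * ((u[1:nx, ] - u[2:nxp, ]) * dy +
                             (v[, 1:ny] - v[, 2:(ny + 1)]) * dx)
    mass_res <- sum(abs(src_pc[grid$fluid])) / (props$rho * Uref * h_in)
    pc <- solve_pressure(grid, dE, dW, dN, dS, src_pc, props)
    gradx <- matrix(0, nxp, ny)
    if (nx >= 2) gradx[2:nx, ] <- pc[1:(nx - 1), ] - pc[2:nx, ]
    u[msk$u_unk] <- u[msk$u_unk] +
      (de_face * gradx / dy)[msk$u_unk]
    grady <- matrix(0, nx, ny + 1)
    grady[, 2:ny] <- pc[, 1:(ny - 1)] - pc[, 2:ny]
    v[msk$v_unk] <- v[msk$v_unk] +
      (dn_face * grady / dx)[msk$v_unk]
    # re-apply outlet mass closure after the correction
    u[nxp, out_f] <- u[nx, out_f] +
      (influx - sum(u[nx, out_f] * dy)) / (sum(out_f) * dy)

    if (any(!is.finite(u)) || any(!is.finite(v)) || any(!is.finite(p))) {
      stop("flow solver produced non-finite values at t = ", field$t)
    }
    res_hist <- c(res_hist, max(mass_res, mom_res))
  }

  if (iters >= settings$max_outer &&
      (mass_res >= settings$residual_tol || mom_res >= settings$residual_tol)) {
    stop(sprintf(paste0("flow solver did not converge in %d outer iterations",
                        " (final residuals: mass %.3g, momentum %.3g;",
                        " history: %s)"),
                 settings$max_outer, mass_res, mom_res,
                 paste(signif(utils::tail(res_hist, 8), 3), collapse = ", ")))
  }

  structure(list(u = u, v = v, p = p,
                 t = if (steady) field$t else field$t + dt,
                 grid = grid,
                 prev = if (steady) NULL else list(u = u_n, v = v_n)),
            class = "flow_field",
            outer_iters = iters,
            residuals = c(mass = mass_res, momentum = mom_res))
}

#' Solve directly for a steady state
#'
#' Convenience wrapper around [step()] with the transient term dropped.
#'
#' @inheritParams step
#' @param max_outer Outer-iteration budget for the steady solve.
#' @export
steady_state <- function(field, bc, props, body_force = NULL,
                         settings = solver_settings(), max_outer = 600L) {
  settings$max_outer <- as.integer(max_outer)
  step(field, bc, props, body_force, settings, steady = TRUE)
}

#' Wall shear stress along a wall
#'
#' One-sided evaluation of tau = mu du/dy at the stair-step wall using a
#' quadratic fit through the first two cell-centre velocities (exact for a
#' parabolic profile). Positive tau means the fluid drags the wall
#' downstream.
#'
#' @param field A converged [flow_field()].
#' @param props [fluid_props()].
#' @param wall `"lower"` (the deeper wall, larger y; ultrasound display
#'   convention) or `"upper"`.
#' @return A tibble with columns `x` (m, column centre), `tau` (Pa).
#' @export
compute_wss <- function(field, props, wall = c("lower", "upper")) {
  wall <- match.arg(wall)
  grid <- field$grid
  nx <- grid$nx; dy <- grid$dy
  uc <- 0.5 * (field$u[1:nx, , drop = FALSE] +
                 field$u[2:(nx + 1), , drop = FALSE])
  tau <- numeric(nx)
  for (i in seq_len(nx)) {
    if (wall == "lower") {
      j1 <- grid$jhi[i]; j2 <- j1 - 1L
    } else {
      j1 <- grid$jlo[i]; j2 <- j1 + 1L
    }
    tau[i] <- props$mu * (9 * uc[i, j1] - uc[i, j2]) / (3 * dy)
  }
  tibble::tibble(x = (seq_len(nx) - 0.5) * grid$dx, tau = tau, wall = wall)
}

#' Space-averaged wall shear stress
#'
#' Arithmetic mean of the per-column WSS over an axial range.
#'
#' @param series Tibble from [compute_wss()].
#' @param x_range Length-2 numeric `c(xmin, xmax)` in metres.
#' @return Scalar mean WSS (Pa).
#' @export
space_average_wss <- function(series, x_range) {
  sel <- series$x >= x_range[1] & series$x <= x_range[2]
  if (!any(sel)) stop("empty x_range: no WSS columns selected")
  mean(series$tau[sel])
}
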