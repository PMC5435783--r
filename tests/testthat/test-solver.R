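props_blood <- fluid_props()

test_that("zero inlet, zero force, zero field is a fixed point", {
  g <- small_grid()
  fld <- step(flow_field(g), boundary_condition(0), props_blood,
              settings = solver_settings())
  expect_equal(max(abs(fld$u)), 0)
  expect_equal(max(abs(fld$v)), 0)
  expect_lt(max(abs(fld$p)), 1e-12)
})

test_that("steady plane Poiseuille reproduces the analytic shear and centreline", {
  g <- small_grid()
  s <- solver_settings(residual_tol = 1e-5, relax_p = 0.5)
  fld <- steady_state(flow_field(g), boundary_condition(0.1), props_blood,
                      settings = s, max_outer = 800)
  h <- (g$jhi[1] - g$jlo[1] + 1) * g$dy
  w <- compute_wss(fld, props_blood, "lower")
  tau_exact <- 6 * props_blood$mu * 0.1 / h
  expect_lt(abs(w$tau[g$nx %/% 2] - tau_exact) / tau_exact, 0.02)
  uc <- 0.5 * (fld$u[1:g$nx, ] + fld$u[2:(g$nx + 1), ])
  expect_lt(abs(max(uc) - 1.5 * 0.1) / (1.5 * 0.1), 0.02)
  # global mass conservation at the converged state
  influx <- sum(fld$u[1, ] * g$dy)
  outflux <- sum(fld$u[g$nx + 1, ] * g$dy)
  expect_lt(abs(influx - outflux) / influx, 1e-10)
  # upper-wall shear matches by symmetry
  wu <- compute_wss(fld, props_blood, "upper")
  expect_lt(abs(wu$tau[g$nx %/% 2] - tau_exact) / tau_exact, 0.02)
})

test_that("impulsively started flow approaches 1.5 U monotonically at the centreline", {
  g <- small_grid()
  s <- solver_settings(dt = 0.05, residual_tol = 1e-6)
  fld <- flow_field(g)
  jc <- (g$jlo[1] + g$jhi[1]) %/% 2
  im <- g$nx %/% 2
  cl <- numeric(0)
  for (k in 1:25) {
    fld <- step(fld, boundary_condition(0.05), props_blood, settings = s)
    cl <- c(cl, 0.5 * (fld$u[im, jc] + fld$u[im + 1, jc]))
  }
  # monotone rise up to a small startup transient of the implicit scheme
  u_inf <- 1.5 * 0.05
  expect_true(all(diff(cl) > -0.01 * u_inf))
  expect_lt(abs(cl[length(cl)] - u_inf) / u_inf, 0.02)
})

test_that("the implicit time scheme converges at second order in dt", {
  g <- small_grid()
  Ufun <- function(t) 0.2 + 0.1 * sin(2 * pi * t / 0.4)
  run_dt <- function(dt, Tend = 0.116) {
    s <- solver_settings(dt = dt, residual_tol = 1e-6, max_outer = 400)
    fld <- steady_state(flow_field(g), boundary_condition(Ufun(0)),
                        props_blood, settings = s, max_outer = 800)
    for (k in seq_len(round(Tend / dt))) {
      fld <- step(fld, boundary_condition(Ufun(k * dt)), props_blood,
                  settings = s)
    }
    fld
  }
  ref <- run_dt(0.029 / 8)
  e1 <- max(abs(run_dt(0.029)$u - ref$u))
  e2 <- max(abs(run_dt(0.029 / 2)$u - ref$u))
  expect_gt(e1 / e2, 2.5)
})

test_that("non-convergence raises with a residual history", {
  g <- small_grid()
  s <- solver_settings(residual_tol = 1e-12, max_outer = 3L)
  expect_error(step(flow_field(g), boundary_condition(0.3), props_blood,
                    settings = s),
               "did not converge")
})

test_that("wall shear extraction is exact for an imposed parabolic profile", {
  g <- small_grid()
  h <- (g$jhi[1] - g$jlo[1] + 1) * g$dy
  u_max <- 0.15
  fld <- parabolic_field(g, u_max)
  tau_exact <- 4 * props_blood$mu * u_max / h
  w <- compute_wss(fld, props_blood, "lower")
  expect_lt(max(abs(w$tau - tau_exact)) / tau_exact, 0.01)
  # zero field and antisymmetry
  expect_equal(compute_wss(flow_field(g), props_blood, "lower")$tau,
               rep(0, g$nx))
  wneg <- compute_wss(parabolic_field(g, -u_max), props_blood, "lower")
  expect_equal(wneg$tau, -w$tau)
})

test_that("space-averaged WSS is the arithmetic mean over the range", {
  ser <- tibble::tibble(x = (1:10 - 0.5) * 1e-3,
                        tau = rep(2, 10), wall = "lower")
  expect_equal(space_average_wss(ser, c(0, 1)), 2)
  ser$tau <- seq(0, 4, length.out = 10)
  expect_equal(space_average_wss(ser, c(0, 1)), 2)
  set.seed(7)
  ser$tau <- rnorm(10)
  expect_equal(space_average_wss(ser, c(0, 5e-3)),
               sum(ser$tau[1:5]) / 5)  # direct-sum oracle
  expect_error(space_average_wss(ser, c(1, 2)), "empty")
})
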