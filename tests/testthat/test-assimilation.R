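props_blood <- fluid_props()

test_that("golden-section inlet estimation recovers a known steady inlet", {
  g <- small_grid()
  s <- solver_settings(residual_tol = 1e-4)
  truth <- steady_state(flow_field(g), boundary_condition(0.25), props_blood,
                        settings = s, max_outer = 800)
  beam <- scenario_beam(twin_scenario())
  mg <- meas_grid_from_flow(g)
  frame <- doppler_frame(project_doppler(truth, beam, mg), beam,
                         timestamp = s$dt, valid = g$fluid, mgrid = mg)
  cfg <- feedback_config(L_char = 2e-3)
  est <- estimate_inlet_velocity(frame, truth, bracket = c(-0.2, 1.5),
                                 tol = 1e-3, props_blood, cfg, s,
                                 mode = "ordinary")
  expect_lt(abs(est$u_inlet - 0.25), 5e-3)
  expect_lt(est$e, 1e-3)
})

test_that("a zero frame with a zero-flow prior estimates a zero inlet", {
  g <- small_grid()
  s <- solver_settings(residual_tol = 1e-3)
  beam <- c(0, 1)
  mg <- meas_grid_from_flow(g)
  frame <- doppler_frame(matrix(0, g$nx, g$ny), beam, s$dt,
                         valid = g$fluid, mgrid = mg)
  est <- estimate_inlet_velocity(frame, flow_field(g), bracket = c(-0.1, 0.1),
                                 tol = 1e-3, props_blood,
                                 feedback_config(L_char = 2e-3), s,
                                 mode = "ordinary")
  expect_lt(abs(est$u_inlet), 2e-4)
})

test_that("feedback with V_m equal to the unforced solution reproduces it", {
  g <- small_grid()
  s <- solver_settings(residual_tol = 1e-5)
  prev <- steady_state(flow_field(g), boundary_condition(0.2), props_blood,
                       settings = s, max_outer = 800)
  bc <- boundary_condition(0.3)
  unforced <- step(prev, bc, props_blood, settings = s)
  beam <- scenario_beam(twin_scenario())
  mg <- meas_grid_from_flow(g)
  Vm <- project_doppler(unforced, beam, mg)
  cfg <- feedback_config(K_v_star = 500, L_char = 2e-3)
  force_fn <- function(cur) {
    feedback_force(project_doppler(cur, beam, mg), Vm, cfg, g, beam, mg,
                   g$fluid)
  }
  forced <- step(prev, bc, props_blood, force_fn, s)
  expect_lt(max(abs(forced$u - unforced$u)), 2e-3 * max(abs(unforced$u)))
  expect_lt(max(abs(forced$v - unforced$v)), 2e-3 * max(abs(unforced$u)))
})

test_that("zero-flow frames give zero fields and zero error in both modes", {
  g <- small_grid()
  s <- solver_settings(residual_tol = 1e-3)
  beam <- c(0, 1)
  mg <- meas_grid_from_flow(g)
  frames <- lapply(1:2, function(k) {
    doppler_frame(matrix(0, g$nx, g$ny), beam, k * s$dt, g$fluid, mg)
  })
  for (mode in c("umi", "ordinary")) {
    run <- run_simulation(frames, g, props_blood,
                          feedback_config(L_char = 2e-3), s, mode = mode,
                          bracket_width = 0.2, bracket_init = c(-0.1, 0.1))
    expect_lt(max(run$results$e), 1e-3)
    expect_lt(max(abs(run$fields[[2]]$u)), 1e-3)
  }
})

test_that("run_simulation validates frame ordering and exposes tidy output", {
  g <- small_grid()
  beam <- c(0, 1)
  mg <- meas_grid_from_flow(g)
  frames <- lapply(c(2, 1), function(k) {
    doppler_frame(matrix(0, g$nx, g$ny), beam, k * 0.029, g$fluid, mg)
  })
  expect_error(run_simulation(frames, g), "time-ordered")

  run <- umi_run_500()
  td <- tidy(run)
  expect_true(all(c("frame", "t", "e", "u_inlet", "wss_mean") %in% names(td)))
  expect_equal(nrow(td), 35L)
  gl <- glance(run)
  expect_equal(gl$mode, "umi")
  expect_equal(gl$K_v_star, 500)
  expect_s3_class(autoplot(run), "ggplot")
})
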