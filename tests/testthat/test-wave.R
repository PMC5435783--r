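test_that("the smoothed derivative matches analytic derivatives", {
  fs <- 200
  tt <- (0:(2 * fs - 1)) / fs
  ramp <- bio_signal(3 * tt, fs)
  expect_equal(derivative(ramp)$value, rep(3, length(tt)), tolerance = 1e-9)
  s <- bio_signal(sin(2 * pi * tt), fs)
  d <- derivative(s)
  expect_lt(max(abs(d$value - 2 * pi * cos(2 * pi * tt))), 0.01 * 2 * pi)
  expect_equal(max(abs(derivative(bio_signal(rep(4, 100), fs))$value)), 0)
  expect_error(derivative(bio_signal(1:3, fs), window = 5), "window")
})

test_that("wave intensity signs and labels follow the forward/backward rule", {
  wh <- water_hammer_beat()
  wi <- compute_wi(wh$P, wh$U)
  # pointwise sign identity
  expect_true(all(sign(wi$wi) == sign(wi$dPdt) * sign(wi$dUdt) |
                    wi$wi == 0))
  # water hammer: the global WI maximum is a forward wave in early systole
  imax <- which.max(wi$wi)
  expect_equal(wi$label[imax], "forward")
  expect_lt(wi$t[imax], wh$U$t[which.max(wh$U$value)])
  # exactly one contiguous forward-labelled episode
  runs <- rle(wi$label == "forward")
  expect_equal(sum(runs$values), 1L)
  # P rising while U falling: backward labels
  fs <- 200; tt <- (0:199) / fs
  P2 <- bio_signal(90 + 10 * tt, fs, kind = "pressure")
  U2 <- bio_signal(0.4 - 0.2 * tt, fs, kind = "velocity")
  wi2 <- compute_wi(P2, U2)
  expect_true(all(wi2$wi <= 0))
  expect_true("backward" %in% wi2$label)
  expect_false("forward" %in% wi2$label)
  # constant pressure: identically zero WI and no labels
  wi3 <- compute_wi(bio_signal(rep(100, 200), fs, kind = "pressure"), U2)
  expect_equal(max(abs(wi3$wi)), 0)
  expect_true(all(wi3$label == "none"))
})

test_that("negating the velocity flips wave intensity pointwise", {
  wh <- water_hammer_beat()
  wi <- compute_wi(wh$P, wh$U)
  Uneg <- wh$U
  Uneg$value <- -Uneg$value
  wineg <- compute_wi(wh$P, Uneg)
  expect_equal(wineg$wi, -wi$wi, tolerance = 1e-12)
})

test_that("labels partition the samples", {
  wh <- water_hammer_beat()
  wi <- compute_wi(wh$P, wh$U)
  expect_true(all(wi$label %in% c("forward", "backward", "absorption",
                                  "none")))
  expect_equal(length(wi$label), nrow(wi))
})

test_that("PU loop of an exact water-hammer relation is straight with R^2 = 1", {
  wh <- water_hammer_beat()
  pl <- build_pu_loop(wh$P, wh$U)
  expect_gte(pl$r_squared, 0.9999)
  expect_equal(pl$classification, "straight")
  expect_true(all(c("r_squared", "quad_coef", "classification") %in%
                    names(glance(pl))))
  expect_s3_class(autoplot(pl), "ggplot")
  # no systolic upstroke
  flatU <- bio_signal(rep(0.2, nrow(wh$P)), 200, kind = "velocity")
  expect_error(build_pu_loop(wh$P, flatU), "upstroke")
})

test_that("delayed pressure is concave and advanced pressure convex", {
  delayed <- water_hammer_beat(shift_p = +15e-3)
  expect_equal(build_pu_loop(delayed$P, delayed$U)$classification, "concave")
  advanced <- water_hammer_beat(shift_p = -15e-3)
  expect_equal(build_pu_loop(advanced$P, advanced$U)$classification, "convex")
})

test_that("PU-loop refinement recovers misalignments at the 5-ms grid", {
  wh <- water_hammer_beat()
  expect_equal(as.numeric(refine_sync(wh$P, wh$U)), 0)
  # 10-ms misalignment: U delayed -> refined shift +10 ms (within one step)
  sh <- water_hammer_beat()
  sh$U$value <- stats::approx(sh$U$t + 10e-3, sh$U$value, xout = sh$U$t,
                              rule = 2)$y
  r10 <- as.numeric(refine_sync(wh$P, bio_signal(sh$U$value, 200,
                                                 kind = "velocity")))
  expect_lte(abs(r10 - 10e-3), 5e-3)
  # off-grid 7 ms: forced onto {5, 10} ms by quantisation
  sh7 <- water_hammer_beat()
  u7 <- stats::approx(sh7$U$t + 7e-3, sh7$U$value, xout = sh7$U$t,
                      rule = 2)$y
  r7 <- as.numeric(refine_sync(wh$P, bio_signal(u7, 200, kind = "velocity")))
  expect_true(any(abs(r7 - c(5e-3, 10e-3)) < 1e-9))
  # R^2 is maximal at the true offset and lower one step either side
  prof <- attr(refine_sync(wh$P, bio_signal(sh$U$value, 200,
                                            kind = "velocity")),
               "r_squared")
  i10 <- which(abs(as.numeric(names(prof)) - 10e-3) < 1e-9)
  expect_gte(prof[i10], prof[i10 - 1])
  expect_gte(prof[i10], prof[i10 + 1])
})
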