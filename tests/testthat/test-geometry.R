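test_that("carotid-scale mask yields the 36 x 86 grid with a ~6.4 mm fluid band", {
  g <- paper_grid()
  expect_equal(g$nx, 36L)
  expect_equal(g$ny, 86L)
  band <- g$jhi - g$jlo + 1L
  expect_true(all(band %in% c(36L, 37L)))
  # round trip: reconstructed height within one dy of the requested 6.4 mm
  expect_lt(abs(band[1] * g$dy - 6.4e-3), g$dy)
})

test_that("a full-rectangle mask gives walls on the raster edges", {
  geo <- vessel_geometry(matrix(1, 20, 10), 1e-4, 1e-4)
  g <- build_grid(geo, 1e-4, 1e-4)
  expect_true(all(g$jlo == 1L))
  expect_true(all(g$jhi == g$ny))
})

test_that("sinusoidally undulating walls are traced at the analytic positions", {
  d <- 4e-3; L <- 8e-3; p <- 1e-4
  geo <- channel_geometry(diameter = d, length = L, pitch_x = p, pitch_y = p,
                          depth_extent = 8e-3, undulation = 0.10,
                          undulation_periods = 2)
  g <- build_grid(geo, p, p)
  # independent brute-force oracle: evaluate the analytic wall at each column
  yc <- 8e-3 / 2
  x <- (seq_len(g$nx) - 0.5) * p
  half <- d / 2 * (1 + 0.10 * sin(2 * pi * 2 * x / L))
  yrow <- (seq_len(g$ny) - 0.5) * p
  for (i in seq_len(g$nx)) {
    inside <- which(abs(yrow - yc) <= half[i])
    expect_equal(g$jlo[i], inside[1])
    expect_equal(g$jhi[i], inside[length(inside)])
  }
})

test_that("degenerate lumens are rejected", {
  # thinner than 3 cells
  m <- matrix(0, 20, 10); m[10:11, ] <- 1
  expect_error(build_grid(vessel_geometry(m, 1e-4, 1e-4), 1e-4, 1e-4),
               "thinner")
  # two disconnected bands fail at construction
  m2 <- matrix(0, 20, 10); m2[3:7, ] <- 1; m2[12:16, ] <- 1
  expect_error(vessel_geometry(m2, 1e-4, 1e-4), "4-connected")
  # empty mask
  expect_error(vessel_geometry(matrix(0, 5, 5), 1e-4, 1e-4), "foreground")
})

make_rotated_channel <- function(angle_deg, nr = 120, nc = 120, hw = 8) {
  th <- angle_deg * pi / 180
  m <- matrix(0, nr, nc)
  cx <- nc / 2; cy <- nr / 2
  for (ci in seq_len(nc)) {
    for (ri in seq_len(nr)) {
      # distance from the channel axis through the centre at angle th
      dist <- -(ci - cx) * sin(th) + (ri - cy) * cos(th)
      along <- (ci - cx) * cos(th) + (ri - cy) * sin(th)
      if (abs(dist) <= hw && abs(along) <= 50) m[ri, ci] <- 1
    }
  }
  m
}

test_that("principal-axis rotation aligns a tilted channel with the x-axis", {
  horiz <- make_rotated_channel(0)
  geo0 <- rotate_and_extract(horiz, c(1e-4, 1e-4))
  expect_lt(abs(geo0$rotation_angle), 1 * pi / 180)

  tilted <- make_rotated_channel(10)
  geo <- rotate_and_extract(tilted, c(1e-4, 1e-4))
  expect_lt(abs(geo$rotation_angle - (-10 * pi / 180)), 1 * pi / 180)

  # a circular blob has no dominant axis
  blob <- matrix(0, 60, 60)
  for (ci in 1:60) for (ri in 1:60) {
    if ((ci - 30)^2 + (ri - 30)^2 <= 20^2) blob[ri, ci] <- 1
  }
  expect_error(rotate_and_extract(blob, c(1e-4, 1e-4)), "dominant axis")
})

test_that("extraction of a rotated channel reproduces the unrotated grid", {
  p <- 1e-4
  # crop the ragged rotated end columns before gridding
  crop_ends <- function(geo, margin = 12) {
    m <- geo$lumen_mask
    vessel_geometry(m[, (margin + 1):(ncol(m) - margin)],
                    geo$pixel_pitch_x, geo$pixel_pitch_y,
                    geo$rotation_angle)
  }
  g0 <- build_grid(crop_ends(rotate_and_extract(make_rotated_channel(0),
                                                c(p, p))), p, p)
  g1 <- build_grid(crop_ends(rotate_and_extract(make_rotated_channel(12),
                                                c(p, p))), p, p)
  band0 <- round(stats::median(g0$jhi - g0$jlo + 1))
  band1 <- round(stats::median(g1$jhi - g1$jlo + 1))
  expect_lte(abs(band0 - band1), 1)
})
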