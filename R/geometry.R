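#' Vessel lumen geometry
#'
#' Bundles a binary lumen raster with its pixel pitch and the rotation that
#' was applied to align the vessel axis with the x-axis. The raster follows
#' ultrasound display convention: rows are depth (y, increasing downward),
#' columns are the axial direction (x, downstream).
#'
#' @param lumen_mask Binary matrix (0/1 or logical); rows = depth y,
#'   columns = axial x. Must contain exactly one 4-connected foreground
#'   component spanning the full x extent.
#' @param pixel_pitch_x,pixel_pitch_y Pixel pitch in metres (> 0).
#' @param rotation_angle Rotation (radians) that was applied so that the
#'   vessel axis is horizontal; purely informative here.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(lumen_mask, pixel_pitch_x, pixel_pitch_y,
                            rotation_angle = 0) {
  mask <- as.matrix(lumen_mask)
  storage.mode(mask) <- "double"
  mask <- (mask > 0.5) * 1
  if (!is.numeric(pixel_pitch_x) || !is.numeric(pixel_pitch_y) ||
      pixel_pitch_x <= 0 || pixel_pitch_y <= 0) {
    stop("pixel pitches must be positive lengths (metres)")
  }
  if (sum(mask) == 0) stop("lumen_mask has no foreground pixels")
  if (n_components4(mask) != 1L) {
    stop("lumen_mask must contain exactly one 4-connected component")
  }
  if (any(colSums(mask) == 0)) {
    stop("lumen must span the full x extent of the mask")
  }
  structure(
    list(lumen_mask = mask,
         pixel_pitch_x = pixel_pitch_x,
         pixel_pitch_y = pixel_pitch_y,
         rotation_angle = rotation_angle),
    class = "vessel_geometry"
  )
}

# Number of 4-connected foreground components, by iterative label propagation
# (masks are small; O(diameter) vectorised sweeps).
n_components4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- mask > 0.5
  lab[fg] <- seq_len(sum(fg))
  repeat {
    nb <- lab
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    for (m in list(up, dn, lf, rt)) {
      take <- fg & m > 0L & (nb == 0L | m < nb)
      nb[take] <- m[take]
    }
    if (all(nb == lab)) break
    lab <- nb
  }
  length(unique(lab[fg]))
}

#' Rotate a raw mask so the vessel axis is horizontal
#'
#' Estimates the principal axis of the dominant elongated component from the
#' second moments of the foreground pixel coordinates (in physical units, so
#' anisotropic pitch is handled), rotates the mask by the negative of that
#' angle about the foreground centroid, and returns an axis-aligned
#' [vessel_geometry()]. The rotated raster is resampled on a lattice with the
#' same pixel pitches using nearest-neighbour sampling and cropped to the
#' foreground bounding box.
#'
#' @param raw_mask Binary matrix, rows = depth, cols = axial.
#' @param pitch Numeric length-2 vector `c(pitch_x, pitch_y)` in metres.
#' @param eccentricity_min Minimum eccentricity of the pixel cloud for a
#'   "dominant axis" to exist; blobs below this are rejected.
#' @return A [vessel_geometry()] whose `rotation_angle` is the applied angle
#'   (radians); a channel drawn at +10 degrees yields approximately -10
#'   degrees.
#' @export
rotate_and_extract <- function(raw_mask, pitch, eccentricity_min = 0.9) {
  mask <- (as.matrix(raw_mask) > 0.5) * 1
  if (sum(mask) == 0) stop("raw_mask has no foreground pixels")
  px <- pitch[1]; py <- pitch[2]
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * px
  y <- (idx[, 1] - 0.5) * py
  mx <- mean(x); my <- mean(y)
  mu20 <- mean((x - mx)^2); mu02 <- mean((y - my)^2)
  mu11 <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)
  ecc <- sqrt(1 - ev$values[2] / ev$values[1])
  if (!is.finite(ecc) || ecc < eccentricity_min) {
    stop("no dominant axis: component eccentricity ", signif(ecc, 3),
         " below threshold ", eccentricity_min)
  }
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  ang <- -theta  # rotation applied to make the axis horizontal

  # Inverse-map target lattice points through the rotation and sample.
  nr <- nrow(mask); nc <- ncol(mask)
  half <- sqrt((nr * py)^2 + (nc * px)^2) / 2  # metres
  nxt <- ceiling(2 * half / px); nyt <- ceiling(2 * half / py)
  # the 1e-3-pixel offset breaks exact half-pixel ties at band edges
  xt <- ((seq_len(nxt) - 0.5 + 1e-3) * px) - (nxt * px) / 2
  yt <- ((seq_len(nyt) - 0.5 + 1e-3) * py) - (nyt * py) / 2
  Xt <- matrix(rep(xt, each = nyt), nyt, nxt)
  Yt <- matrix(rep(yt, times = nxt), nyt, nxt)
  ca <- cos(-ang); sa <- sin(-ang)  # inverse rotation
  Xs <- ca * Xt - sa * Yt + mx
  Ys <- sa * Xt + ca * Yt + my
  # bilinear sampling of the binary mask, thresholded at 0.5, preserves the
  # channel thickness to within half a pixel
  gx <- as.vector(Xs / px + 0.5); gy <- as.vector(Ys / py + 0.5)
  ok <- gx >= 1 & gx <= nc & gy >= 1 & gy <= nr
  c0 <- pmin(pmax(floor(gx), 1), nc - 1)
  r0 <- pmin(pmax(floor(gy), 1), nr - 1)
  tx <- pmin(pmax(gx - c0, 0), 1); ty <- pmin(pmax(gy - r0, 0), 1)
  val <- (1 - tx) * (1 - ty) * mask[cbind(r0, c0)] +
    tx * (1 - ty) * mask[cbind(r0, c0 + 1)] +
    (1 - tx) * ty * mask[cbind(r0 + 1, c0)] +
    tx * ty * mask[cbind(r0 + 1, c0 + 1)]
  out <- matrix(as.numeric(ok & val >= 0.5), nyt, nxt)

  rows <- which(rowSums(out) > 0); cols <- which(colSums(out) > 0)
  out <- out[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  # Nearest-neighbour resampling can leave isolated pixels; keep the largest
  # 4-connected component.
  out <- keep_largest_component(out)
  vessel_geometry(out, px, py, rotation_angle = ang)
}

keep_largest_component <- function(mask) {
  fg <- mask > 0.5
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[fg] <- seq_len(sum(fg))
  repeat {
    nb <- lab
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    for (m in list(up, dn, lf, rt)) {
      take <- fg & m > 0L & (nb == 0L | m < nb)
      nb[take] <- m[take]
    }
    if (all(nb == lab)) break
    lab <- nb
  }
  tab <- table(lab[fg])
  keep <- as.integer(names(tab)[which.max(tab)])
  (lab == keep) * 1
}

#' Build the staggered computational grid from a vessel geometry
#'
#' Resamples the lumen mask onto an orthogonal equidistant grid with spacing
#' `dx`, `dy` and traces the stair-step wall position in every column. Scalar
#' quantities (pressure) live at cell centres; velocity components live on
#' cell faces (staggered arrangement). The coordinate convention is 0-based
#' physical x downstream and y increasing with depth; the "lower" wall is the
#' deeper one (larger y), matching ultrasound display convention.
#'
#' @param geometry A [vessel_geometry()].
#' @param dx,dy Grid spacing in metres (> 0); typically the spatial
#'   resolution of the Doppler measurement.
#' @return An object of class `flow_grid` with fields `nx`, `ny`, `dx`, `dy`,
#'   `fluid` (`nx` x `ny` logical, x-by-depth), `jlo`, `jhi` (first/last
#'   fluid cell index per column; `jlo` is the shallow wall side, `jhi` the
#'   deep "lower" wall side).
#' @export
build_grid <- function(geometry, dx, dy) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (dx <= 0 || dy <= 0) stop("dx and dy must be positive")
  mask <- geometry$lumen_mask
  px <- geometry$pixel_pitch_x; py <- geometry$pixel_pitch_y
  W <- ncol(mask) * px; H <- nrow(mask) * py
  nx <- max(1L, round(W / dx)); ny <- max(1L, round(H / dy))
  if (nx < 4L || ny < 4L) stop("grid too small: nx, ny must be >= 4")
  xq <- (seq_len(nx) - 0.5) * dx
  yq <- (seq_len(ny) - 0.5) * dy
  ci <- pmin(ncol(mask), pmax(1L, round(xq / px + 0.5)))
  ri <- pmin(nrow(mask), pmax(1L, round(yq / py + 0.5)))
  fluid <- t(mask[ri, ci, drop = FALSE] > 0.5)  # nx x ny

  jlo <- integer(nx); jhi <- integer(nx)
  for (i in seq_len(nx)) {
    js <- which(fluid[i, ])
    if (length(js) == 0) stop("lumen does not span the full x extent at column ", i)
    if (any(diff(js) != 1L)) stop("lumen cross-section not contiguous at column ", i)
    if (length(js) < 3L) stop("lumen thinner than 3 cells at column ", i)
    jlo[i] <- js[1]; jhi[i] <- js[length(js)]
  }
  structure(
    list(nx = nx, ny = ny, dx = dx, dy = dy,
         fluid = fluid, jlo = jlo, jhi = jhi),
    class = "flow_grid"
  )
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("<flow_grid> %d x %d cells, dx = %.3g m, dy = %.3g m\n",
              x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  fluid band: %d-%d cells per column (%d fluid cells)\n",
              min(x$jhi - x$jlo + 1L), max(x$jhi - x$jlo + 1L), sum(x$fluid)))
  invisible(x)
}

#' Serialize a grid to JSON / read it back
#'
#' @param grid A `flow_grid`.
#' @param path Output file.
#' @return `write_grid_json` returns `path` invisibly; `read_grid_json`
#'   returns a `flow_grid`.
#' @export
write_grid_json <- function(grid, path) {
  obj <- list(nx = grid$nx, ny = grid$ny, dx = grid$dx, dy = grid$dy,
              jlo = grid$jlo, jhi = grid$jhi)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fluid <- matrix(FALSE, obj$nx, obj$ny)
  for (i in seq_len(obj$nx)) fluid[i, obj$jlo[i]:obj$jhi[i]] <- TRUE
  structure(
    list(nx = as.integer(obj$nx), ny = as.integer(obj$ny),
         dx = obj$dx, dy = obj$dy, fluid = fluid,
         jlo = as.integer(obj$jlo), jhi = as.integer(obj$jhi)),
    class = "flow_grid"
  )
}

#' Convenience constructor: straight (optionally undulating) channel geometry
#'
#' Builds a raster mask of a horizontal channel of height `diameter` centred
#' in a domain of height `depth_extent`, with an optional sinusoidal wall
#' undulation, and wraps it in a [vessel_geometry()].
#'
#' @param diameter Channel height (m).
#' @param length Axial extent (m).
#' @param pitch_x,pitch_y Raster pitch (m).
#' @param depth_extent Total raster depth (m); default twice the diameter
#'   plus margin.
#' @param undulation Relative amplitude of a sinusoidal wall undulation
#'   (0 = straight walls).
#' @param undulation_periods Number of undulation periods along the axis.
#' @return A [vessel_geometry()].
#' @export
channel_geometry <- function(diameter, length, pitch_x, pitch_y,
                             depth_extent = NULL, undulation = 0,
                             undulation_periods = 2) {
  if (is.null(depth_extent)) depth_extent <- 2.3 * diameter
  nc <- max(4L, round(length / pitch_x))
  nr <- max(4L, round(depth_extent / pitch_y))
  yc <- depth_extent / 2
  x <- (seq_len(nc) - 0.5) * pitch_x
  half <- diameter / 2 * (1 + undulation * sin(2 * pi * undulation_periods * x / length))
  mask <- matrix(0, nr, nc)
  yrow <- (seq_len(nr) - 0.5) * pitch_y
  for (i in seq_len(nc)) {
    mask[abs(yrow - yc) <= half[i], i] <- 1
  }
  vessel_geometry(mask, pitch_x, pitch_y)
}
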