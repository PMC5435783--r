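#' Read and write signals as annotated CSV
#'
#' Signals are stored as two-column CSV (`t`, `value`) preceded by comment
#' headers `# fs:`, `# t0:`, `# kind:`.
#'
#' @param x A `bio_signal`.
#' @param path File path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns a `bio_signal`.
#' @export
write_signal_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.10g", signal_fs(x)),
               sprintf("# t0: %.10g", x$t[1]),
               sprintf("# kind: %s", signal_kind(x))), con)
  utils::write.csv(data.frame(t = x$t, value = x$value), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- list(fs = NA_real_, t0 = 0, kind = "generic")
  for (h in hdr[startsWith(hdr, "#")]) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (kv[1] %in% c("fs", "t0")) meta[[kv[1]]] <- as.numeric(kv[2])
    if (kv[1] == "kind") meta$kind <- kv[2]
  }
  d <- utils::read.csv(path, comment.char = "#")
  bio_signal(d$value, meta$fs, meta$t0, kind = meta$kind)
}

#' Read and write Doppler frame stacks
#'
#' A frame stack is stored as a pair of plain-text files sharing a stem:
#' `<stem>_frames.csv` in long format (`frame`, `t`, `i`, `j`, `Vm`,
#' `valid`) and `<stem>_meta.json` (beam vector and measurement-grid
#' parameters).
#'
#' @param frames List of [doppler_frame()]s.
#' @param stem Path stem (without suffix).
#' @return `write_doppler_frames` returns `stem` invisibly;
#'   `read_doppler_frames` returns the frame list.
#' @export
write_doppler_frames <- function(frames, stem) {
  mg <- frames[[1]]$mgrid
  meta <- list(beam = frames[[1]]$beam,
               mgrid = list(nx = mg$nx, ny = mg$ny, dx = mg$dx, dy = mg$dy,
                            x0 = mg$x0, y0 = mg$y0),
               timestamps = vapply(frames, function(f) f$timestamp,
                                   numeric(1)))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  rows <- purrr::map_dfr(seq_along(frames), function(k) {
    f <- frames[[k]]
    idx <- which(f$valid | f$V_m != 0, arr.ind = TRUE)
    tibble::tibble(frame = k, t = f$timestamp, i = idx[, 1], j = idx[, 2],
                   Vm = f$V_m[idx], valid = f$valid[idx])
  })
  utils::write.csv(rows, paste0(stem, "_frames.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_doppler_frames
#' @export
read_doppler_frames <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  mg <- do.call(meas_grid, as.list(meta$mgrid))
  d <- utils::read.csv(paste0(stem, "_frames.csv"))
  lapply(seq_along(meta$timestamps), function(k) {
    dk <- d[d$frame == k, ]
    Vm <- matrix(0, mg$nx, mg$ny)
    valid <- matrix(FALSE, mg$nx, mg$ny)
    Vm[cbind(dk$i, dk$j)] <- dk$Vm
    valid[cbind(dk$i, dk$j)] <- as.logical(dk$valid)
    doppler_frame(Vm, as.numeric(meta$beam), meta$timestamps[k], valid, mg)
  })
}

#' Read and write B-mode image stacks as multi-page TIFF
#'
#' @param stack Array `h x w x n` in [0, 1].
#' @param path TIFF file path.
#' @return `write_bmode_tiff` returns `path` invisibly; `read_bmode_tiff`
#'   returns the array (attribute `fs` is not stored in the TIFF and must be
#'   supplied on read).
#' @export
write_bmode_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' @rdname write_bmode_tiff
#' @param fs Frame rate (Hz) to attach on read.
#' @export
read_bmode_tiff <- function(path, fs = 34.394) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    out[, , k] <- pg
  }
  attr(out, "fs") <- fs
  out
}
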