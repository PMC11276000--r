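# Readers/writers for the interchange formats: CSV (trajectories, curves,
# profiles), TIFF (images), JSON (results, ground truth, config).

.write_csv_exact <- function(df, path) {
  # %.17g preserves doubles bit-exactly through a text round trip
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a trajectory CSV
#'
#' Schema: `particle_id, frame, t_s, x_um, y_um`; doubles are written with 17
#' significant digits so the round trip is exact.
#'
#' @param traj a [trajectory_set()].
#' @param path file path.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  .write_csv_exact(as.data.frame(traj), path)
  invisible(path)
}

#' @rdname write_trajectories
#' @param dt_s frame interval; default inferred from the `t_s` column.
#' @export
read_trajectories <- function(path, dt_s = NULL) {
  df <- utils::read.csv(path)
  if (is.null(dt_s)) {
    ts <- sort(unique(df$t_s))
    dt_s <- if (length(ts) > 1L) min(diff(ts)) else 1
  }
  trajectory_set(df, dt_s = dt_s)
}

#' Write / read an MSD profile CSV
#'
#' Schema: `lag_s, msd_um2, n_obs`.
#'
#' @param profile an `msd_profile`.
#' @param path file path.
#' @export
write_msd <- function(profile, path) {
  stopifnot(inherits(profile, "msd_profile"))
  .write_csv_exact(as.data.frame(profile), path)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  df <- utils::read.csv(path)
  ts <- df$lag_s
  dt <- if (length(ts) > 1L) min(diff(sort(ts))) else ts[1L]
  structure(df, dt_s = dt, mode = "ensemble_of_time_averages",
            class = c("msd_profile", "data.frame"))
}

#' Write / read a generic curve CSV (FRAP, ramp, force)
#'
#' @param df data.frame with the module's schema (`t_s, roi, reference,
#'   background` for FRAP; `temperature_C, signal, leg` for ramps;
#'   `t_ms, force` for fusion traces).
#' @param path file path.
#' @export
write_curve <- function(df, path) {
  .write_csv_exact(as.data.frame(df), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) utils::read.csv(path)

# TIFF values must be in [0, 1]; a fixed scale of 65535 a.u. per unit is
# used so typical photon-count images survive the trip at float32 precision.
.TIFF_SCALE <- 65535

#' Write / read an image (or multi-page stack) as 32-bit float TIFF
#'
#' Intensities are divided by a fixed scale of 65535 on write and multiplied
#' back on read; the round trip is exact to single precision.
#'
#' @param img 2D matrix, 3D array (pages = 3rd dim) or list of matrices.
#' @param path file path.
#' @export
write_image_tiff <- function(img, path) {
  pages <- if (is.list(img)) img
    else if (length(dim(img)) == 3L)
      lapply(seq_len(dim(img)[3L]), function(k) img[, , k])
    else list(img)
  pages <- lapply(pages, function(m) pmin(pmax(m / .TIFF_SCALE, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @return `read_image_tiff` returns a list of 2D matrices (one per page).
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) m * .TIFF_SCALE)
}

#' Write an analysis result or ground truth as JSON
#'
#' @param x a list (result object components are coerced).
#' @param path file path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) jsonlite::read_json(path,
                                                       simplifyVector = TRUE)
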