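# Video particle tracking: localization, linking, drift correction, MSD.

#' Detect particles in a single frame
#'
#' Local maxima above `min_intensity`, refined to sub-pixel precision by an
#' intensity-weighted centroid within a window of `expected_diameter_um`.
#' Detections closer than half the expected diameter are merged, keeping the
#' brighter one.
#'
#' @param frame 2D numeric matrix (rows = y, cols = x).
#' @param pixel_size_um um per pixel.
#' @param expected_diameter_um expected spot diameter (>= 2 pixels).
#' @param min_intensity detection threshold (a.u.).
#' @return data.frame `(x_um, y_um, mass)`; empty for an empty frame.
#' @export
detect_particles <- function(frame, pixel_size_um, expected_diameter_um,
                             min_intensity) {
  stopifnot(is.matrix(frame))
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  d_px <- expected_diameter_um / pixel_size_um
  if (d_px < 2) stop("expected_diameter_um must be at least 2 pixels")
  nr <- nrow(frame); nc <- ncol(frame)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), mass = numeric(0))

  # strict local maxima over the 8-neighborhood, via shifted comparisons
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- frame
  is_max <- frame > min_intensity
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    is_max <- is_max & (frame >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)

  w <- max(1L, round(d_px / 2))
  res <- matrix(NA_real_, nrow(idx), 3L)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    ii <- max(1L, i - w):min(nr, i + w)
    jj <- max(1L, j - w):min(nc, j + w)
    win <- frame[ii, jj, drop = FALSE]
    win <- win - min(win) # local background before centroiding
    m <- sum(win)
    if (m <= 0) next
    cy <- sum(win * (ii - 1L)) / m        # row sums weight y
    cx <- sum(t(win) * (jj - 1L)) / m
    res[k, ] <- c(cx * pixel_size_um, cy * pixel_size_um, m)
  }
  res <- res[stats::complete.cases(res), , drop = FALSE]
  if (nrow(res) == 0L) return(empty)
  out <- data.frame(x_um = res[, 1L], y_um = res[, 2L], mass = res[, 3L])

  # merge duplicates closer than d/2, keep the brighter
  out <- out[order(-out$mass), ]
  keep <- rep(TRUE, nrow(out))
  min_sep <- expected_diameter_um / 2
  for (a in seq_len(nrow(out))) {
    if (!keep[a]) next
    if (a < nrow(out)) {
      b <- (a + 1L):nrow(out)
      dd <- sqrt((out$x_um[b] - out$x_um[a])^2 +
                 (out$y_um[b] - out$y_um[a])^2)
      keep[b[dd < min_sep]] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-frame localizations into trajectories
#'
#' Frame-to-frame assignment by greedy nearest-neighbour matching with global
#' conflict resolution: all candidate (track, detection) pairs within
#' `max_disp_um` are sorted by squared displacement and accepted in order,
#' each track and each detection at most once. Tracks unmatched for up to
#' `memory` frames remain eligible (gap bridging); unmatched detections start
#' new ids.
#'
#' @param detections list of per-frame data.frames `(x_um, y_um, mass)`, or a
#'   single data.frame with a `frame` column.
#' @param max_disp_um maximum displacement per frame interval.
#' @param memory frames a lost track stays eligible.
#' @param dt_s frame interval (for the `t_s` column).
#' @return a [trajectory_set()] with a `linking_report` attribute
#'   (`n_tracks`, `n_gaps_bridged`, `n_new_after_first_frame`).
#' @export
link_trajectories <- function(detections, max_disp_um, memory = 0L,
                              dt_s = 1) {
  .assert_scalar_pos(max_disp_um, "max_disp_um")
  if (is.data.frame(detections)) {
    stopifnot("frame" %in% names(detections))
    fr <- sort(unique(detections$frame))
    detections <- lapply(fr, function(f)
      detections[detections$frame == f, c("x_um", "y_um", "mass")])
  }
  n_frames <- length(detections)
  # active track state
  tr_x <- numeric(0); tr_y <- numeric(0); tr_last <- integer(0)
  tr_id <- integer(0)
  next_id <- 1L
  rows <- vector("list", n_frames)
  n_gaps <- 0L; n_new_later <- 0L

  for (f in seq_len(n_frames)) {
    det <- detections[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    assigned_det <- integer(0)
    if (nd > 0L && length(tr_id) > 0L) {
      eligible <- which((f - tr_last) <= (memory + 1L))
      if (length(eligible) > 0L) {
        # candidate pairs within max_disp per elapsed frame
        cand <- expand.grid(ti = eligible, di = seq_len(nd))
        gapn <- f - tr_last[cand$ti]
        d2 <- (tr_x[cand$ti] - det$x_um[cand$di])^2 +
              (tr_y[cand$ti] - det$y_um[cand$di])^2
        ok <- d2 <= (max_disp_um * gapn)^2
        cand <- cand[ok, , drop = FALSE]; d2 <- d2[ok]; gapn <- gapn[ok]
        if (nrow(cand) > 0L) {
          ord <- order(d2)
          used_t <- logical(length(tr_id)); used_d <- logical(nd)
          for (r in ord) {
            ti <- cand$ti[r]; di <- cand$di[r]
            if (used_t[ti] || used_d[di]) next
            used_t[ti] <- TRUE; used_d[di] <- TRUE
            if (f - tr_last[ti] > 1L) n_gaps <- n_gaps + 1L
            tr_x[ti] <- det$x_um[di]; tr_y[ti] <- det$y_um[di]
            tr_last[ti] <- f
            rows[[f]] <- rbind(rows[[f]],
              data.frame(particle_id = tr_id[ti], frame = f,
                         x_um = det$x_um[di], y_um = det$y_um[di]))
            assigned_det <- c(assigned_det, di)
          }
        }
      }
    }
    if (nd > 0L) {
      new_d <- setdiff(seq_len(nd), assigned_det)
      for (di in new_d) {
        tr_x <- c(tr_x, det$x_um[di]); tr_y <- c(tr_y, det$y_um[di])
        tr_last <- c(tr_last, f); tr_id <- c(tr_id, next_id)
        if (f > 1L) n_new_later <- n_new_later + 1L
        rows[[f]] <- rbind(rows[[f]],
          data.frame(particle_id = next_id, frame = f,
                     x_um = det$x_um[di], y_um = det$y_um[di]))
        next_id <- next_id + 1L
      }
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L)
    stop("no detections to link")
  df <- df[order(df$particle_id, df$frame), ]
  df$t_s <- (df$frame - 1L) * dt_s
  df <- df[, c("particle_id", "frame", "t_s", "x_um", "y_um")]
  rownames(df) <- NULL
  out <- trajectory_set(df, dt_s = dt_s)
  attr(out, "linking_report") <- list(
    n_tracks = next_id - 1L, n_gaps_bridged = n_gaps,
    n_new_after_first_frame = n_new_later)
  out
}

#' Subtract common drift from a trajectory set
#'
#' The per-frame ensemble-median displacement (over particles present in both
#' of two consecutive frames) is accumulated and subtracted from all
#' positions, leaving relative inter-particle displacements unchanged. With a
#' single particle this removes all of its motion; a warning is emitted.
#'
#' @param traj a [trajectory_set()].
#' @return drift-corrected [trajectory_set()] with attribute `drift_um`
#'   (per-frame cumulative correction).
#' @export
correct_drift <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (length(unique(traj$particle_id)) < 2L)
    warning("drift correction with a single particle removes all motion")
  frames <- sort(unique(traj$frame))
  step_x <- numeric(length(frames)); step_y <- numeric(length(frames))
  for (k in seq_along(frames)[-1L]) {
    a <- traj[traj$frame == frames[k - 1L], ]
    b <- traj[traj$frame == frames[k], ]
    common <- intersect(a$particle_id, b$particle_id)
    if (length(common) == 0L) next
    ia <- match(common, a$particle_id); ib <- match(common, b$particle_id)
    step_x[k] <- stats::median(b$x_um[ib] - a$x_um[ia])
    step_y[k] <- stats::median(b$y_um[ib] - a$y_um[ia])
  }
  cum_x <- cumsum(step_x); cum_y <- cumsum(step_y)
  ix <- match(traj$frame, frames)
  out <- traj
  out$x_um <- traj$x_um - cum_x[ix]
  out$y_um <- traj$y_um - cum_y[ix]
  attr(out, "drift_um") <- data.frame(frame = frames, dx_um = cum_x,
                                      dy_um = cum_y)
  out
}

#' Compute time- and ensemble-averaged MSD
#'
#' For each trajectory, the time-averaged MSD over all start points at each
#' lag up to `max_lag_fraction` of the trajectory length; the ensemble value
#' per lag is the unweighted mean over trajectories contributing to that lag
#' (mode `"ensemble_of_time_averages"`, the default) or the pair-count
#' weighted mean over all displacements (mode `"all_displacements"`).
#' Trajectories shorter than `min_length` frames are dropped.
#'
#' @param traj a [trajectory_set()].
#' @param max_lag_fraction maximum lag as a fraction of trajectory length,
#'   in `(0, 0.5]`. Short relative to the record to limit estimator variance.
#' @param mode averaging mode, see above.
#' @param min_length minimum trajectory length in frames.
#' @return an `msd_profile`: data.frame `(lag_s, msd_um2, n_obs)` sorted by
#'   lag, with attributes `dt_s` and `mode`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25,
                        mode = c("ensemble_of_time_averages",
                                 "all_displacements"),
                        min_length = 10L) {
  stopifnot(inherits(traj, "trajectory_set"))
  mode <- match.arg(mode)
  if (max_lag_fraction <= 0 || max_lag_fraction > 0.5)
    stop("max_lag_fraction must be in (0, 0.5]")
  dt <- attr(traj, "dt_s")
  ids <- unique(traj$particle_id)
  acc_sum <- list(); acc_n <- list(); acc_pairs <- list()
  max_k_all <- 0L
  kept <- 0L
  for (id in ids) {
    tr <- traj[traj$particle_id == id, ]
    f0 <- min(tr$frame); f1 <- max(tr$frame)
    L <- f1 - f0 + 1L
    if (L < min_length) next
    kept <- kept + 1L
    x <- rep(NA_real_, L); y <- rep(NA_real_, L)
    x[tr$frame - f0 + 1L] <- tr$x_um
    y[tr$frame - f0 + 1L] <- tr$y_um
    max_k <- max(1L, floor(max_lag_fraction * L))
    max_k_all <- max(max_k_all, max_k)
    s <- numeric(max_k); np <- integer(max_k)
    for (k in seq_len(max_k)) {
      dx <- x[(k + 1L):L] - x[1:(L - k)]
      dy <- y[(k + 1L):L] - y[1:(L - k)]
      sq <- dx * dx + dy * dy
      np[k] <- sum(!is.na(sq))
      s[k] <- if (np[k] > 0L) sum(sq, na.rm = TRUE) else NA_real_
    }
    acc_sum[[length(acc_sum) + 1L]] <- s
    acc_n[[length(acc_n) + 1L]] <- np
    acc_pairs[[length(acc_pairs) + 1L]] <- max_k
  }
  if (kept == 0L)
    stop("no trajectory of at least ", min_length, " frames: empty profile")
  msd <- numeric(max_k_all); n_obs <- integer(max_k_all)
  for (k in seq_len(max_k_all)) {
    if (mode == "ensemble_of_time_averages") {
      vals <- vapply(seq_along(acc_sum), function(i) {
        if (acc_pairs[[i]] >= k && acc_n[[i]][k] > 0L)
          acc_sum[[i]][k] / acc_n[[i]][k] else NA_real_
      }, numeric(1))
      n_obs[k] <- sum(!is.na(vals))
      msd[k] <- mean(vals, na.rm = TRUE)
    } else {
      tot <- 0; nn <- 0L
      for (i in seq_along(acc_sum)) {
        if (acc_pairs[[i]] >= k && acc_n[[i]][k] > 0L) {
          tot <- tot + acc_sum[[i]][k]; nn <- nn + acc_n[[i]][k]
        }
      }
      n_obs[k] <- nn
      msd[k] <- if (nn > 0L) tot / nn else NA_real_
    }
  }
  ok <- n_obs >= 1L
  out <- data.frame(lag_s = seq_len(max_k_all)[ok] * dt,
                    msd_um2 = msd[ok], n_obs = n_obs[ok])
  structure(out, dt_s = dt, mode = mode,
            class = c("msd_profile", "data.frame"))
}
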