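# Independent oracles and shared fixture builders.

# Brute-force double-loop MSD (ensemble of per-trajectory time averages),
# deliberately naive: the reference the FFT-free production path must match.
msd_brute_force <- function(traj, max_lag_fraction = 0.25) {
  dt <- attr(traj, "dt_s")
  ids <- unique(traj$particle_id)
  per_traj <- list()
  max_k_all <- 0L
  for (id in ids) {
    tr <- traj[traj$particle_id == id, ]
    L <- nrow(tr)
    max_k <- max(1L, floor(max_lag_fraction * L))
    max_k_all <- max(max_k_all, max_k)
    m <- rep(NA_real_, max_k)
    for (k in seq_len(max_k)) {
      vals <- numeric(0)
      for (i in seq_len(L - k)) {
        vals <- c(vals, (tr$x_um[i + k] - tr$x_um[i])^2 +
                        (tr$y_um[i + k] - tr$y_um[i])^2)
      }
      m[k] <- mean(vals)
    }
    per_traj[[length(per_traj) + 1L]] <- m
  }
  vapply(seq_len(max_k_all), function(k) {
    vals <- vapply(per_traj, function(m)
      if (length(m) >= k) m[k] else NA_real_, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
}

# Build an msd_profile object from closed-form values.
make_msd_profile <- function(lag_s, msd_um2) {
  structure(data.frame(lag_s = lag_s, msd_um2 = msd_um2,
                       n_obs = rep(100L, length(lag_s))),
            dt_s = min(diff(c(0, lag_s))), mode = "ensemble_of_time_averages",
            class = c("msd_profile", "data.frame"))
}

# Single Gaussian blob image (peak amplitude `amp`) centered in an n x n
# frame; physical coordinates via pixel size px.
gaussian_blob_image <- function(n, sigma_um, px, amp = 100) {
  xg <- (0:(n - 1)) * px
  cx <- (n - 1) / 2 * px
  g <- exp(-(xg - cx)^2 / (2 * sigma_um^2))
  amp * outer(g, g)
}

# Materials for the 4-class classification suite (conditions fixed with the
# acquisition: dt = 0.1 s, 400 frames, 5 nm localization noise).
class_suite_model <- function(kind) {
  switch(kind,
    newtonian = material_model("newtonian", viscosity_Pa_s = 1),
    maxwell = material_model("maxwell", viscosity_Pa_s = 2,
                             confinement_sd_um = 0.05,
                             relaxation_time_s = 0.15),
    kelvin_voigt = material_model("kelvin_voigt", confinement_sd_um = 0.05,
                                  relaxation_time_s = 0.3),
    arrested = material_model("arrested"))
}

class_suite_expected <- c(newtonian = "newtonian",
                          maxwell = "viscoelastic_fluid",
                          kelvin_voigt = "kelvin_voigt_solid",
                          arrested = "arrested")

# Per-bead terminal viscosity estimates; the median over beads is the robust
# recovery statistic. The fit uses the first 10 lags, where time averaging
# is effective (a Newtonian bead is diffusive at every lag, and localization
# noise only contributes to the intercept).
per_bead_eta <- function(traj, bead_radius_um = 0.1, temperature_K = 298) {
  dt <- attr(traj, "dt_s")
  vapply(unique(traj$particle_id), function(id) {
    one <- trajectory_set(traj[traj$particle_id == id, ], dt_s = dt)
    p <- compute_msd(one)
    sel <- seq_len(min(10L, nrow(p)))
    slope <- unname(stats::coef(stats::lm(msd_um2 ~ lag_s,
                                          data = p[sel, ]))[2L])
    if (slope <= 0) return(NA_real_)
    stokes_einstein_eta(slope / 4, bead_radius_um, temperature_K)
  }, numeric(1))
}
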