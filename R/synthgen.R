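# Synthetic-data generators with known ground truth. Every analysis stage in
# the package can be validated by parameter recovery against these objects.

#' Describe a viscoelastic medium for trajectory simulation
#'
#' The four material regimes observed for aging condensates by passive bead
#' nanorheology: a Newtonian liquid (free diffusion), a Maxwell-like
#' viscoelastic fluid (confined motion at short times crossing over to free
#' diffusion at long times), a Kelvin-Voigt solid (fully caged tracers with an
#' MSD plateau), and complete dynamical arrest (no motion beyond localization
#' noise).
#'
#' @param kind one of `"newtonian"`, `"maxwell"`, `"kelvin_voigt"`,
#'   `"arrested"`.
#' @param viscosity_Pa_s terminal viscosity (newtonian/maxwell).
#' @param confinement_sd_um per-axis stationary SD of the confined component
#'   in um (maxwell/kelvin_voigt). The long-lag 2D MSD plateau of a pure
#'   confined process is `4 * confinement_sd_um^2`.
#' @param relaxation_time_s relaxation time of the confined component in s.
#' @param temperature_K absolute temperature (default 298 K, room temperature).
#' @param bead_radius_um tracer radius in um; default 0.1 um (200 nm diameter
#'   fluorescent beads).
#' @return a `material_model` object.
#' @export
material_model <- function(kind = c("newtonian", "maxwell", "kelvin_voigt",
                                    "arrested"),
                           viscosity_Pa_s = NULL,
                           confinement_sd_um = NULL,
                           relaxation_time_s = NULL,
                           temperature_K = 298,
                           bead_radius_um = 0.1) {
  kind <- match.arg(kind)
  .assert_scalar_pos(temperature_K, "temperature_K")
  .assert_scalar_pos(bead_radius_um, "bead_radius_um")
  if (kind %in% c("newtonian", "maxwell"))
    .assert_scalar_pos(viscosity_Pa_s, "viscosity_Pa_s")
  if (kind %in% c("maxwell", "kelvin_voigt")) {
    .assert_scalar_pos(confinement_sd_um, "confinement_sd_um")
    .assert_scalar_pos(relaxation_time_s, "relaxation_time_s")
  }
  structure(list(kind = kind,
                 viscosity_Pa_s = viscosity_Pa_s,
                 confinement_sd_um = confinement_sd_um,
                 relaxation_time_s = relaxation_time_s,
                 temperature_K = temperature_K,
                 bead_radius_um = bead_radius_um),
            class = "material_model")
}

#' Simulate 2D tracer-bead trajectories in a viscoelastic medium
#'
#' Generates per-particle in-plane positions under the model in `model`,
#' with i.i.d. Gaussian localization noise added per frame and an optional
#' common drift accumulated across frames. Conventions: 2D tracking, so free
#' diffusion has `MSD(tau) = 4*D*tau` with `D` from [stokes_einstein_D()].
#'
#' @param model a [material_model()].
#' @param n_particles,n_frames counts (`n_frames >= 2`).
#' @param dt_s frame interval in s.
#' @param loc_noise_sd_um localization noise SD per axis, um.
#' @param drift_per_frame_um length-2 vector, common drift added per frame.
#' @param seed integer seed; output is deterministic given all arguments.
#' @return a `trajectory_set`: data.frame `(particle_id, frame, t_s, x_um,
#'   y_um)` with attributes `dt_s`, `model` (ground truth).
#' @export
gen_trajectories <- function(model, n_particles, n_frames, dt_s,
                             loc_noise_sd_um = 0,
                             drift_per_frame_um = c(0, 0),
                             seed = 1L) {
  stopifnot(inherits(model, "material_model"))
  n_particles <- .assert_count(n_particles, "n_particles")
  n_frames <- .assert_count(n_frames, "n_frames", min = 2L)
  .assert_scalar_pos(dt_s, "dt_s")
  if (loc_noise_sd_um < 0) stop("invalid parameter: loc_noise_sd_um < 0")
  stopifnot(length(drift_per_frame_um) == 2L)
  set.seed(seed)

  one_axis <- switch(model$kind,
    newtonian = function() {
      D <- stokes_einstein_D(model$viscosity_Pa_s, model$bead_radius_um,
                             model$temperature_K)
      cumsum(c(0, stats::rnorm(n_frames - 1L, 0, sqrt(2 * D * dt_s))))
    },
    kelvin_voigt = function() {
      .ou_path(n_frames, dt_s, model$confinement_sd_um,
               model$relaxation_time_s)
    },
    maxwell = function() {
      D <- stokes_einstein_D(model$viscosity_Pa_s, model$bead_radius_um,
                             model$temperature_K)
      .ou_path(n_frames, dt_s, model$confinement_sd_um,
               model$relaxation_time_s) +
        cumsum(c(0, stats::rnorm(n_frames - 1L, 0, sqrt(2 * D * dt_s))))
    },
    arrested = function() rep(0, n_frames)
  )

  drift_x <- (seq_len(n_frames) - 1L) * drift_per_frame_um[1L]
  drift_y <- (seq_len(n_frames) - 1L) * drift_per_frame_um[2L]

  xs <- vector("list", n_particles)
  ys <- vector("list", n_particles)
  for (p in seq_len(n_particles)) {
    x0 <- stats::runif(1, -5, 5)
    y0 <- stats::runif(1, -5, 5)
    x <- x0 + one_axis() + drift_x
    y <- y0 + one_axis() + drift_y
    if (loc_noise_sd_um > 0) {
      x <- x + stats::rnorm(n_frames, 0, loc_noise_sd_um)
      y <- y + stats::rnorm(n_frames, 0, loc_noise_sd_um)
    }
    xs[[p]] <- x
    ys[[p]] <- y
  }
  df <- data.frame(
    particle_id = rep(seq_len(n_particles), each = n_frames),
    frame = rep(seq_len(n_frames), n_particles),
    t_s = rep((seq_len(n_frames) - 1L) * dt_s, n_particles),
    x_um = unlist(xs),
    y_um = unlist(ys)
  )
  trajectory_set(df, dt_s = dt_s, model = model)
}

#' Construct a trajectory set
#'
#' @param df data.frame with columns `particle_id, frame, t_s, x_um, y_um`.
#' @param dt_s frame interval in s.
#' @param pixel_size_um optional provenance.
#' @param model optional ground-truth [material_model()].
#' @return the data.frame with class `trajectory_set` and metadata attributes.
#' @export
trajectory_set <- function(df, dt_s, pixel_size_um = NA_real_, model = NULL) {
  need <- c("particle_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory set needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("trajectory coordinates must be finite")
  ok <- tapply(df$frame, df$particle_id,
               function(f) all(diff(f) > 0))
  if (!all(unlist(ok)))
    stop("frame indices must strictly increase within each particle")
  structure(df, dt_s = dt_s, pixel_size_um = pixel_size_um, model = model,
            class = c("trajectory_set", "data.frame"))
}

#' Describe the synthetic imaging scene
#'
#' Imaging geometry for synthetic condensate images: a circular condensate of
#' uniform baseline intensity containing Gaussian intra-condensate clusters,
#' blurred by a Gaussian PSF, with optional Poisson or Gaussian noise.
#' Pixel convention: 0-based pixel centers, physical coordinate = index *
#' `pixel_size_um`.
#'
#' @param image_shape_px length-2 `(rows, cols)`.
#' @param pixel_size_um um per pixel; confocal presets in this package are
#'   0.2196 and 0.09765 um.
#' @param condensate_center_um length-2 `(x, y)` or `NULL` for image center.
#' @param condensate_radius_um disk radius.
#' @param baseline intensity of the condensate body (a.u.).
#' @param psf_sigma_um Gaussian PSF sigma.
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_sd SD for `"gaussian"` noise.
#' @param seed integer seed.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(image_shape_px = c(128L, 128L),
                       pixel_size_um = 0.2196,
                       condensate_center_um = NULL,
                       condensate_radius_um = 10,
                       baseline = 100,
                       psf_sigma_um = 0.2,
                       noise = c("poisson", "gaussian", "none"),
                       noise_sd = 0,
                       seed = 1L) {
  noise <- match.arg(noise)
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  .assert_scalar_pos(condensate_radius_um, "condensate_radius_um")
  if (is.null(condensate_center_um))
    condensate_center_um <- (rev(image_shape_px) - 1) / 2 * pixel_size_um
  structure(list(image_shape_px = as.integer(image_shape_px),
                 pixel_size_um = pixel_size_um,
                 condensate_center_um = condensate_center_um,
                 condensate_radius_um = condensate_radius_um,
                 baseline = baseline,
                 psf_sigma_um = psf_sigma_um,
                 noise = noise, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Age-dependence law for intra-condensate RNA clusters
#'
#' Saturating-exponential growth of cluster size and brightness with sample
#' age, emulating the age-dependent demixing of RNA into fractal-like
#' clusters inside condensates. `sigma(age) = sigma_final * (1 -
#' exp(-age/timescale))` (plus `sigma_initial`), and similarly for amplitude.
#' The spatial-autocorrelation size of a Gaussian cluster of width `sigma` is
#' `2*sigma` under the 1/e convention used by [cluster_size()].
#'
#' @param sigma_initial_um,sigma_final_um cluster Gaussian sigma at age 0 and
#'   at late age (um); the law is non-decreasing in age.
#' @param timescale_h growth timescale in hours.
#' @param n_clusters number of clusters per condensate.
#' @param amp_final peak cluster amplitude above baseline at late age (a.u.).
#' @param amp_timescale_h amplitude growth timescale.
#' @return an `aging_law` object with functions `sigma_um(age_h)` and
#'   `amplitude(age_h)`.
#' @export
aging_law <- function(sigma_initial_um = 0, sigma_final_um = 0.45,
                      timescale_h = 1.5, n_clusters = 20L,
                      amp_final = 300, amp_timescale_h = 1.5) {
  stopifnot(sigma_final_um >= sigma_initial_um, sigma_initial_um >= 0)
  structure(list(
    sigma_um = function(age_h)
      sigma_initial_um + (sigma_final_um - sigma_initial_um) *
        (1 - exp(-age_h / timescale_h)),
    amplitude = function(age_h) amp_final * (1 - exp(-age_h / amp_timescale_h)),
    n_clusters = as.integer(n_clusters),
    params = list(sigma_initial_um = sigma_initial_um,
                  sigma_final_um = sigma_final_um,
                  timescale_h = timescale_h,
                  n_clusters = n_clusters,
                  amp_final = amp_final,
                  amp_timescale_h = amp_timescale_h)),
    class = "aging_law")
}

# FFT circular convolution with a normalized Gaussian kernel; preserves the
# image sum exactly (kernel sums to 1).
.gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 1e-6) return(img)
  EBImage::gblur(img, sigma = sigma_px)
}

.disk_mask <- function(shape, center_um, radius_um, pixel_size_um) {
  x <- (seq_len(shape[2L]) - 1L) * pixel_size_um
  y <- (seq_len(shape[1L]) - 1L) * pixel_size_um
  dx2 <- outer(rep(1, shape[1L]), (x - center_um[1L])^2)
  dy2 <- outer((y - center_um[2L])^2, rep(1, shape[2L]))
  (dx2 + dy2) <= radius_um^2
}

#' Generate a multi-channel, multi-age synthetic condensate image stack
#'
#' One frame per age. The RNA channel is the condensate baseline plus
#' Gaussian clusters drawn from the aging law, convolved with the PSF, plus
#' noise. When `anti_correlated = TRUE` the scaffold channel is depleted
#' where the clusters are bright (`scaffold = baseline - kappa * clusters`,
#' clipped at zero before blurring), emulating the core-shell architecture in
#' which the scaffold protein is excluded from the RNA-rich cores.
#'
#' @param spec a [scene_spec()].
#' @param aging an [aging_law()].
#' @param ages_h ascending vector of sample ages in hours.
#' @param channels channel names; first is the RNA (cluster) channel.
#' @param anti_correlated deplete scaffold under clusters?
#' @param kappa depletion coefficient in `[0, 1]`.
#' @return an `image_stack`: list with `ages_h`, `channels`, `frames` (list of
#'   `[rows, cols, channel]` arrays) and `ground_truth` (per-age cluster
#'   parameters incl. a `subresolution` warning flag when cluster sigma <
#'   half a pixel).
#' @export
gen_condensate_stack <- function(spec, aging, ages_h,
                                 channels = c("rna", "scaffold"),
                                 anti_correlated = TRUE, kappa = 0.8) {
  stopifnot(inherits(spec, "scene_spec"), inherits(aging, "aging_law"))
  if (is.unsorted(ages_h)) stop("ages must be sorted ascending")
  set.seed(spec$seed)
  shape <- spec$image_shape_px
  px <- spec$pixel_size_um
  disk <- .disk_mask(shape, spec$condensate_center_um,
                     spec$condensate_radius_um, px)
  xg <- (seq_len(shape[2L]) - 1L) * px
  yg <- (seq_len(shape[1L]) - 1L) * px

  frames <- vector("list", length(ages_h))
  truth <- vector("list", length(ages_h))
  for (i in seq_along(ages_h)) {
    age <- ages_h[i]
    sig <- aging$sigma_um(age)
    amp <- aging$amplitude(age)
    k <- if (sig > 0 && amp > 0) aging$n_clusters else 0L
    centers <- NULL
    clusters <- matrix(0, shape[1L], shape[2L])
    if (k > 0L) {
      # place cluster centers uniformly inside the condensate, margin 3 sigma
      rmax <- max(spec$condensate_radius_um - 3 * sig, 0.5)
      th <- stats::runif(k, 0, 2 * pi)
      rr <- rmax * sqrt(stats::runif(k))
      cx <- spec$condensate_center_um[1L] + rr * cos(th)
      cy <- spec$condensate_center_um[2L] + rr * sin(th)
      centers <- cbind(x_um = cx, y_um = cy)
      for (j in seq_len(k)) {
        gx <- exp(-(xg - cx[j])^2 / (2 * sig^2))
        gy <- exp(-(yg - cy[j])^2 / (2 * sig^2))
        clusters <- clusters + amp * outer(gy, gx)
      }
    }
    rna <- spec$baseline * disk + clusters * disk
    arr <- array(0, c(shape, length(channels)))
    psf_px <- spec$psf_sigma_um / px
    arr[, , 1L] <- .gaussian_blur(rna, psf_px)
    if (length(channels) > 1L) {
      scaf <- if (anti_correlated)
        pmax(spec$baseline - kappa * clusters, 0) * disk
      else spec$baseline * disk
      for (c2 in 2:length(channels))
        arr[, , c2] <- .gaussian_blur(scaf, psf_px)
    }
    if (spec$noise == "poisson") {
      arr[] <- stats::rpois(length(arr), pmax(arr, 0))
    } else if (spec$noise == "gaussian") {
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
    }
    frames[[i]] <- arr
    truth[[i]] <- list(age_h = age, sigma_um = sig, amplitude = amp,
                       n_clusters = k, centers_um = centers,
                       subresolution = (sig > 0 && sig < px / 2))
  }
  structure(list(ages_h = ages_h, channels = channels, frames = frames,
                 ground_truth = truth, spec = spec, aging = aging,
                 mask = disk),
            class = "image_stack")
}

#' Generate a synthetic FRAP record
#'
#' Pre-bleach plateau at 1 for `t < 0`; after the bleach at `t = 0` the
#' model intensity is `(1 - bleach_depth) + bleach_depth * mobile_fraction *
#' (1 - exp(-t/tau))`. Raw ROI/reference/background columns are emitted so
#' the normalization stage can be exercised: the reference channel decays
#' linearly by `reference_decay` over the record (acquisition
#' photobleaching) and `background` is a constant offset added to all
#' channels.
#'
#' @param mobile_fraction in `[0, 1]`.
#' @param tau_s recovery time constant (s); half-time is `tau_s * log(2)`.
#' @param bleach_depth fraction of intensity removed by the bleach.
#' @param n_points post-bleach samples; `n_prebleach` samples precede t = 0.
#' @param dt_s sampling interval.
#' @param noise_sd Gaussian noise SD on the normalized scale.
#' @param reference_decay total fractional linear decay of the reference.
#' @param background constant background level (a.u.).
#' @param seed integer seed.
#' @return a `frap_curve` data.frame `(t_s, roi, reference, background)` with
#'   ground truth in attributes.
#' @export
gen_frap_curve <- function(mobile_fraction, tau_s, bleach_depth = 0.8,
                           n_points = 200L, dt_s = 0.5, noise_sd = 0.01,
                           reference_decay = 0, background = 0,
                           n_prebleach = 10L, seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("invalid parameter: mobile_fraction must be in [0, 1]")
  .assert_scalar_pos(tau_s, "tau_s")
  n_points <- .assert_count(n_points, "n_points", 2L)
  n_prebleach <- .assert_count(n_prebleach, "n_prebleach", 3L)
  set.seed(seed)
  t_s <- c(-(rev(seq_len(n_prebleach))) * dt_s,
           (seq_len(n_points) - 1L) * dt_s)
  model <- ifelse(t_s < 0, 1,
                  (1 - bleach_depth) +
                    bleach_depth * mobile_fraction * (1 - exp(-t_s / tau_s)))
  ref <- 1 - reference_decay * (t_s - t_s[1L]) / (max(t_s) - t_s[1L])
  roi <- model * ref + background +
    stats::rnorm(length(t_s), 0, noise_sd)
  reference <- ref + background + stats::rnorm(length(t_s), 0, noise_sd / 2)
  out <- data.frame(t_s = t_s, roi = roi, reference = reference,
                    background = rep(background, length(t_s)))
  structure(out,
            truth = list(mobile_fraction = mobile_fraction, tau_s = tau_s,
                         bleach_depth = bleach_depth),
            class = c("frap_curve", "data.frame"))
}

#' Generate a heating/cooling temperature-ramp trace
#'
#' The heating leg is a logistic step of unit amplitude centered at the true
#' lower cloud-point temperature (LCPT); the cooling leg returns to baseline
#' if the transition is reversible, otherwise it stays elevated at
#' `hysteresis_offset` (irreversible percolation). If `true_lcpt_C` lies
#' outside `t_range_C` the heating leg is flat (no transition: soluble).
#'
#' @param true_lcpt_C true cloud point (deg C), or a value outside
#'   `t_range_C` for "no transition".
#' @param reversible logical.
#' @param t_range_C length-2 temperature range of both legs.
#' @param n_points samples per leg (>= 8).
#' @param noise_sd Gaussian noise SD (signal amplitude is 1).
#' @param hysteresis_offset residual cooling-leg signal when irreversible.
#' @param width_C logistic transition width (deg C).
#' @param seed integer seed.
#' @return a `ramp_trace` data.frame `(temperature_C, signal, leg)` with
#'   ground truth in attributes.
#' @export
gen_ramp_trace <- function(true_lcpt_C, reversible = FALSE,
                           t_range_C = c(20, 80), n_points = 121L,
                           noise_sd = 0.05, hysteresis_offset = 1,
                           width_C = 0.25, seed = 1L) {
  n_points <- .assert_count(n_points, "n_points", 8L)
  set.seed(seed)
  temps <- seq(t_range_C[1L], t_range_C[2L], length.out = n_points)
  in_range <- true_lcpt_C >= t_range_C[1L] && true_lcpt_C <= t_range_C[2L]
  sigmoid <- function(T) {
    if (!in_range) rep(0, length(T))
    else stats::plogis((T - true_lcpt_C) / width_C)
  }
  heat <- sigmoid(temps) + stats::rnorm(n_points, 0, noise_sd)
  cool_temps <- rev(temps)
  cool <- if (!in_range) {
    stats::rnorm(n_points, 0, noise_sd)
  } else if (reversible) {
    sigmoid(cool_temps) + stats::rnorm(n_points, 0, noise_sd)
  } else {
    hysteresis_offset + stats::rnorm(n_points, 0, noise_sd)
  }
  out <- data.frame(
    temperature_C = c(temps, cool_temps),
    signal = c(heat, cool),
    leg = rep(c("heating", "cooling"), each = n_points)
  )
  structure(out,
            truth = list(true_lcpt_C = if (in_range) true_lcpt_C else NA_real_,
                         reversible = reversible),
            class = c("ramp_trace", "data.frame"))
}

#' Generate a droplet-fusion force relaxation trace
#'
#' Optical-tweezer force during coalescence of two droplets relaxes
#' exponentially: `F(t) = F0 * exp(-t/tau) + noise`. The fusion relaxation
#' time is conventionally reported normalized by droplet size (ms/um).
#'
#' @param tau_ms relaxation time in ms.
#' @param diameters_um diameters of the two fusing droplets.
#' @param n_points,dt_ms sampling.
#' @param noise_sd Gaussian noise SD (F0 = 1).
#' @param F0 initial force amplitude.
#' @param seed integer seed.
#' @return a `force_trace` data.frame `(t_ms, force)` with ground truth in
#'   attributes.
#' @export
gen_fusion_trace <- function(tau_ms, diameters_um = c(3, 3), n_points = 400L,
                             dt_ms = 1, noise_sd = 0, F0 = 1, seed = 1L) {
  .assert_scalar_pos(tau_ms, "tau_ms")
  stopifnot(length(diameters_um) == 2L, all(diameters_um > 0))
  n_points <- .assert_count(n_points, "n_points", 4L)
  set.seed(seed)
  t_ms <- (seq_len(n_points) - 1L) * dt_ms
  force <- F0 * exp(-t_ms / tau_ms) + stats::rnorm(n_points, 0, noise_sd)
  structure(data.frame(t_ms = t_ms, force = force),
            truth = list(tau_ms = tau_ms, diameters_um = diameters_um,
                         F0 = F0),
            class = c("force_trace", "data.frame"))
}
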