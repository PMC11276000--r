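# Viscoelastic interpretation of MSD profiles: log-log slopes, material
# classification, Stokes-Einstein terminal viscosity.

#' Log-log slope of an MSD profile over a lag window
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` restricted to the
#' window. The slope `alpha` is the local scaling exponent: 1 for free
#' diffusion, 0 for a plateau, 2 for ballistic motion.
#'
#' @param profile an `msd_profile`.
#' @param lag_window length-2 `(s, s)` inclusive lag range.
#' @return list `(alpha, prefactor, stderr, n)`.
#' @export
fit_loglog_slope <- function(profile, lag_window) {
  stopifnot(inherits(profile, "msd_profile"), length(lag_window) == 2L)
  sel <- profile$lag_s >= lag_window[1L] & profile$lag_s <= lag_window[2L]
  if (sum(sel) < 4L)
    stop("need at least 4 lags in the fit window")
  if (any(profile$msd_um2[sel] <= 0))
    stop("fit-domain error: msd <= 0 in window, log-log slope undefined")
  fit <- stats::lm(log(msd_um2) ~ log(lag_s), data = profile[sel, ])
  co <- suppressWarnings(summary(fit))$coefficients
  list(alpha = unname(co[2L, 1L]),
       prefactor = exp(unname(co[1L, 1L])),
       stderr = unname(co[2L, 2L]),
       n = sum(sel))
}

.default_windows <- function(profile) {
  lmin <- min(profile$lag_s); lmax <- max(profile$lag_s)
  list(short = c(lmin, min(10 * lmin, lmax)),
       long = c(max(lmax / 10, lmin), lmax))
}

#' Terminal viscosity from the diffusive regime of an MSD profile
#'
#' Checks that the terminal window is diffusive (log-log slope in
#' `[0.8, 1.2]`), fits `msd ~ lag` by ordinary least squares (the intercept
#' absorbs the static localization-error offset), and converts
#' `D = slope / 4` (2D tracking) to viscosity by Stokes-Einstein.
#'
#' @param profile an `msd_profile`.
#' @param bead_radius_um tracer radius (default 0.1 um).
#' @param temperature_K temperature (default 298 K).
#' @param terminal_window lag window (s); default last decade of lags.
#' @return list `(D_um2_s, eta_Pa_s, alpha, window_s, slope_stderr)`.
#' @seealso [classify_material()] for profiles without a terminal regime.
#' @export
terminal_viscosity <- function(profile, bead_radius_um = 0.1,
                               temperature_K = 298,
                               terminal_window = NULL) {
  stopifnot(inherits(profile, "msd_profile"))
  terminal_window <- terminal_window %||% .default_windows(profile)$long
  a <- fit_loglog_slope(profile, terminal_window)
  if (a$alpha < 0.8 || a$alpha > 1.2) {
    stop(structure(class = c("no_terminal_viscosity", "error", "condition"),
                   list(message = sprintf(
                     paste0("no terminal viscosity: log-log slope %.2f in the",
                            " terminal window is not diffusive;",
                            " consider classify_material()"), a$alpha),
                     call = sys.call(-1))))
  }
  sel <- profile$lag_s >= terminal_window[1L] &
         profile$lag_s <= terminal_window[2L]
  fit <- stats::lm(msd_um2 ~ lag_s, data = profile[sel, ])
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("non-positive terminal slope")
  D <- slope / 4
  list(D_um2_s = D,
       eta_Pa_s = stokes_einstein_eta(D, bead_radius_um, temperature_K),
       alpha = a$alpha,
       window_s = terminal_window,
       slope_stderr = suppressWarnings(summary(fit))$coefficients[2L, 2L])
}

#' Classification thresholds for material state
#'
#' @param alpha_fluid slope at/above which a window is called diffusive.
#' @param alpha_solid slope below which a window is called a plateau.
#' @param static_floor_um2 static localization-error MSD floor (um^2),
#'   typically estimated as the shortest-lag MSD of arrested control beads
#'   (`4 * sigma_loc^2`); `NULL` enables a flat-profile fallback.
#' @param floor_mult multiple of the floor below which motion is "arrested".
#' @return a list of thresholds for [classify_material()].
#' @export
material_thresholds <- function(alpha_fluid = 0.8, alpha_solid = 0.2,
                                static_floor_um2 = NULL, floor_mult = 3) {
  list(alpha_fluid = alpha_fluid, alpha_solid = alpha_solid,
       static_floor_um2 = static_floor_um2, floor_mult = floor_mult)
}

#' Classify the material state from an MSD profile
#'
#' Decision rule on the short-window and long-window log-log slopes
#' (defaults: first and last decade of available lags):
#' both slopes >= `alpha_fluid` -> `newtonian`; long slope >= `alpha_fluid`
#' but short slope below it -> `viscoelastic_fluid` (Maxwell-like); long
#' slope < `alpha_solid` with a plateau above the static-error floor ->
#' `kelvin_voigt_solid`; MSD everywhere at the floor -> `arrested`.
#' Intermediate long-window slopes give `viscoelastic_fluid` with a
#' low-confidence flag.
#'
#' @param profile an `msd_profile` spanning at least one decade of lags.
#' @param thresholds see [material_thresholds()].
#' @param windows optional list with `short` and `long` lag windows (s).
#' @return a `rheology_result` list: `material_class`, `alpha_short`,
#'   `alpha_long`, `plateau_um2` (reported for Kelvin-Voigt solids, else NA),
#'   `low_confidence`, `windows_s`.
#' @export
classify_material <- function(profile, thresholds = material_thresholds(),
                              windows = NULL) {
  stopifnot(inherits(profile, "msd_profile"))
  if (max(profile$lag_s) / min(profile$lag_s) < 10)
    stop("profile must span at least one decade of lags")
  windows <- windows %||% .default_windows(profile)
  floor_est <- thresholds$static_floor_um2
  mult <- thresholds$floor_mult

  res <- function(cls, a_s = NA_real_, a_l = NA_real_, plateau = NA_real_,
                  low = FALSE) {
    structure(list(material_class = cls, alpha_short = a_s, alpha_long = a_l,
                   plateau_um2 = plateau, low_confidence = low,
                   windows_s = windows),
              class = "rheology_result")
  }

  # arrested gate before any log fit (MSD may be ~0)
  if (!is.null(floor_est)) {
    if (max(profile$msd_um2) <= mult * floor_est) return(res("arrested"))
  } else if (max(profile$msd_um2) <= 0) {
    return(res("arrested"))
  }

  a_short <- fit_loglog_slope(profile, windows$short)$alpha
  a_long <- fit_loglog_slope(profile, windows$long)$alpha
  sel_long <- profile$lag_s >= windows$long[1L] &
              profile$lag_s <= windows$long[2L]
  plateau <- mean(profile$msd_um2[sel_long])

  if (a_long < thresholds$alpha_solid) {
    floor_eff <- floor_est %||% profile$msd_um2[1L]
    if (plateau > mult * floor_eff)
      return(res("kelvin_voigt_solid", a_short, a_long, plateau))
    return(res("arrested", a_short, a_long))
  }
  if (a_long >= thresholds$alpha_fluid) {
    if (a_short >= thresholds$alpha_fluid)
      return(res("newtonian", a_short, a_long))
    return(res("viscoelastic_fluid", a_short, a_long))
  }
  res("viscoelastic_fluid", a_short, a_long, low = TRUE)
}

#' Full rheological characterization of an MSD profile
#'
#' Classification plus, for fluid classes, the terminal viscosity; for
#' Kelvin-Voigt solids, the plateau. Arrested/solid profiles carry no
#' viscosity (the terminal regime does not exist).
#'
#' @inheritParams classify_material
#' @inheritParams terminal_viscosity
#' @return a `rheology_result` augmented with `D_um2_s` and `eta_Pa_s`
#'   (NA where undefined).
#' @export
analyze_rheology <- function(profile, bead_radius_um = 0.1,
                             temperature_K = 298,
                             thresholds = material_thresholds(),
                             windows = NULL) {
  cls <- classify_material(profile, thresholds, windows)
  cls$D_um2_s <- NA_real_
  cls$eta_Pa_s <- NA_real_
  if (cls$material_class %in% c("newtonian", "viscoelastic_fluid")) {
    tv <- tryCatch(
      terminal_viscosity(profile, bead_radius_um, temperature_K,
                         terminal_window = (windows %||%
                           .default_windows(profile))$long),
      no_terminal_viscosity = function(e) NULL)
    if (!is.null(tv)) {
      cls$D_um2_s <- tv$D_um2_s
      cls$eta_Pa_s <- tv$eta_Pa_s
    }
  }
  cls
}

#' @export
print.rheology_result <- function(x, ...) {
  cat("Material classification:", x$material_class,
      if (isTRUE(x$low_confidence)) "(low confidence)" else "", "\n")
  cat(sprintf("  alpha short/long: %.3f / %.3f\n", x$alpha_short,
              x$alpha_long))
  if (!is.na(x$plateau_um2))
    cat(sprintf("  plateau: %.4g um^2\n", x$plateau_um2))
  if (!is.null(x$eta_Pa_s) && !is.na(x$eta_Pa_s))
    cat(sprintf("  terminal viscosity: %.3g Pa.s (D = %.3g um^2/s)\n",
                x$eta_Pa_s, x$D_um2_s))
  invisible(x)
}
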