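# Physical constants and small shared helpers.

.kB <- 1.380649e-23 # Boltzmann constant, J/K

#' Stokes-Einstein diffusion coefficient
#'
#' Translational diffusion coefficient of a sphere in a Newtonian fluid,
#' `D = kB*T / (6*pi*eta*R)`, returned in um^2/s for inputs in lab units.
#'
#' @param eta_Pa_s dynamic viscosity in Pa*s.
#' @param radius_um bead radius in um (note: radius, not diameter).
#' @param temperature_K absolute temperature in K.
#' @return diffusion coefficient in um^2/s.
#' @examples
#' stokes_einstein_D(35.2, 0.1, 298) # ~6.2e-5 um^2/s
#' @export
stokes_einstein_D <- function(eta_Pa_s, radius_um, temperature_K = 298) {
  stopifnot(eta_Pa_s > 0, radius_um > 0, temperature_K > 0)
  # 1e18 converts m^2/s -> um^2/s after expressing R in m (R_um * 1e-6)
  .kB * temperature_K * 1e18 / (6 * pi * eta_Pa_s * radius_um)
}

#' Stokes-Einstein viscosity from a diffusion coefficient
#'
#' Inverse of [stokes_einstein_D()]: terminal viscosity implied by a measured
#' diffusion coefficient of a tracer bead.
#'
#' @param D_um2_s diffusion coefficient in um^2/s.
#' @inheritParams stokes_einstein_D
#' @return viscosity in Pa*s.
#' @export
stokes_einstein_eta <- function(D_um2_s, radius_um, temperature_K = 298) {
  stopifnot(D_um2_s > 0, radius_um > 0, temperature_K > 0)
  .kB * temperature_K * 1e18 / (6 * pi * D_um2_s * radius_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("invalid parameter: `%s` must be a positive finite scalar", name),
         call. = FALSE)
  invisible(x)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("invalid parameter: `%s` must be an integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Bounded Levenberg-Marquardt least squares on a residual function.
# Returns par, residuals and a convergence flag; robust to the degenerate
# (flat-trace) cases where the nls object construction of nlsLM fails.
.lm_exp_fit <- function(resid_fn, start, lower) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4 || any(!is.finite(fit$par)))
    return(list(par = rep(NaN, length(start)), residuals = NaN,
                converged = FALSE))
  list(par = fit$par, residuals = fit$fvec, converged = TRUE)
}

# Stationary Ornstein-Uhlenbeck sample path (exact discretization).
# sd: stationary standard deviation; tau: relaxation time; n points at step dt.
.ou_path <- function(n, dt, sd, tau) {
  rho <- exp(-dt / tau)
  innov <- c(stats::rnorm(1L, 0, sd),
             stats::rnorm(n - 1L, 0, sd * sqrt(1 - rho^2)))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}
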