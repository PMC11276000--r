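# FRAP normalization and single-exponential recovery fitting.

#' Normalize a FRAP record (double normalization)
#'
#' Background-subtracts all traces, divides the bleached ROI by the reference
#' region (correcting acquisition photobleaching), and rescales so the
#' pre-bleach mean is 1. If the reference channel is absent, single
#' normalization is applied and flagged.
#'
#' @param curve data.frame `(t_s, roi, reference, background)`; bleach at
#'   `t_s = 0`, at least 3 pre-bleach samples (`t_s < 0`).
#' @return data.frame `(t_s, intensity)` with attribute
#'   `normalization` (`"double"` or `"single"`).
#' @export
normalize_frap <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("t_s", "roi") %in% names(curve)))
  pre <- curve$t_s < 0
  if (sum(pre) < 3L) stop("need at least 3 pre-bleach samples (t_s < 0)")
  bg <- if ("background" %in% names(curve)) curve$background else 0
  roi <- curve$roi - bg
  if ("reference" %in% names(curve)) {
    ref <- curve$reference - bg
    if (any(ref <= 0))
      stop("normalization error: reference intensity <= 0 after background subtraction")
    ratio <- roi / ref
    mode <- "double"
  } else {
    ratio <- roi
    mode <- "single"
  }
  out <- data.frame(t_s = curve$t_s, intensity = ratio / mean(ratio[pre]))
  attr(out, "normalization") <- mode
  out
}

#' Fit single-exponential FRAP recovery kinetics
#'
#' Least-squares fit of `I(t) = I0 + A * (1 - exp(-t/tau))` to the
#' post-bleach portion of a normalized trace. The mobile fraction uses the
#' convention `(I0 + A - I_bleach) / (1 - I_bleach)` with `I_bleach` the
#' fitted post-bleach intercept `I0` (pre-bleach level is 1 after
#' normalization), i.e. `A / (1 - I0)`. The half-time is `tau * log(2)`.
#'
#' @param normalized data.frame `(t_s, intensity)` from [normalize_frap()]
#'   (or any normalized trace with bleach at t = 0 and pre-bleach level 1).
#' @return a `frap_fit` list: `mobile_fraction`, `tau_s`, `t_half_s`,
#'   `bleach_depth`, `I0`, `A`, `residual_sd`, `converged`, `clipped`
#'   (TRUE when the mobile fraction was clipped into `[0, 1]`).
#'   Non-convergence yields NaN parameters with `converged = FALSE`.
#' @export
fit_frap <- function(normalized) {
  stopifnot(is.data.frame(normalized),
            all(c("t_s", "intensity") %in% names(normalized)))
  post <- normalized[normalized$t_s >= 0, ]
  if (nrow(post) < 5L) stop("too few post-bleach samples")
  t <- post$t_s; I <- post$intensity
  I0g <- I[1L]
  plateau <- mean(utils::tail(I, max(3L, round(length(I) / 10))))
  Ag <- max(plateau - I0g, 1e-3)
  # tau guess: 63% crossing of the recovery
  cross <- which(I >= I0g + 0.632 * Ag)
  taug <- if (length(cross) > 0L) max(t[cross[1L]], diff(range(t)) / 50)
          else diff(range(t)) / 5
  fit <- .lm_exp_fit(function(p) p[1L] + p[2L] * (1 - exp(-t / p[3L])) - I,
                     start = c(I0g, Ag, taug), lower = c(-Inf, 0, 1e-9))
  if (!fit$converged) {
    return(structure(list(mobile_fraction = NaN, tau_s = NaN, t_half_s = NaN,
                          bleach_depth = NaN, I0 = NaN, A = NaN,
                          residual_sd = NaN, converged = FALSE,
                          clipped = FALSE),
                     class = "frap_fit"))
  }
  I0 <- fit$par[1L]; A <- fit$par[2L]; tau <- fit$par[3L]
  mob_raw <- if (1 - I0 > 1e-9) A / (1 - I0) else NaN
  clipped <- is.finite(mob_raw) && (mob_raw < 0 || mob_raw > 1)
  mob <- min(max(mob_raw, 0), 1)
  structure(list(mobile_fraction = mob, tau_s = tau,
                 t_half_s = tau * log(2), bleach_depth = 1 - I0,
                 I0 = I0, A = A,
                 residual_sd = stats::sd(fit$residuals),
                 converged = TRUE, clipped = clipped),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit: mobile fraction %.3f, tau %.3g s (t1/2 %.3g s)%s\n",
    x$mobile_fraction, x$tau_s, x$t_half_s,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}
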