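# RNA state diagrams: cloud-point detection, reversibility, percolation
# boundary; droplet fusion relaxation fitting.

.leg <- function(ramp, which) {
  if (is.data.frame(ramp) && "leg" %in% names(ramp))
    ramp[ramp$leg == which, c("temperature_C", "signal")]
  else ramp
}

#' Detect the lower cloud-point temperature on a heating leg
#'
#' The LCPT is the temperature at which the signal first crosses
#' `baseline_mean + k * baseline_sd`, where the baseline is the first 20% of
#' the heating leg, refined by linear interpolation between the bracketing
#' samples. The baseline SD is floored at 1e-3 of the signal range so the
#' statistic is defined for noiseless traces. Returns `NA` (no transition:
#' soluble) when the threshold is never crossed, including for flat traces.
#'
#' @param heating data.frame `(temperature_C, signal)` or a full
#'   `ramp_trace` (the heating leg is extracted).
#' @param k threshold multiplier (default 5).
#' @return LCPT in deg C, or `NA_real_`.
#' @export
detect_cloud_point <- function(heating, k = 5) {
  h <- .leg(heating, "heating")
  if (nrow(h) < 8L) stop("need at least 8 points on the heating leg")
  h <- h[order(h$temperature_C), ]
  nb <- max(3L, floor(0.2 * nrow(h)))
  base <- h$signal[seq_len(nb)]
  rng <- diff(range(h$signal))
  sd_eff <- max(stats::sd(base), 1e-3 * rng, .Machine$double.eps)
  thr <- mean(base) + k * sd_eff
  above <- which(h$signal > thr)
  above <- above[above > nb] # crossing must occur beyond the baseline window
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(h$temperature_C[1L])
  t0 <- h$temperature_C[i - 1L]; t1 <- h$temperature_C[i]
  s0 <- h$signal[i - 1L]; s1 <- h$signal[i]
  if (s1 == s0) return(t1)
  t0 + (thr - s0) / (s1 - s0) * (t1 - t0)
}

#' Classify reversibility of a heating/cooling cycle
#'
#' The transition is irreversible if, after cooling back to (at or below)
#' the heating start temperature, the signal stays elevated above the
#' heating baseline by strictly more than `tol` (hysteresis); exactly `tol`
#' counts as reversible.
#'
#' @param heating,cooling data.frames `(temperature_C, signal)`, or a single
#'   `ramp_trace` passed as `heating` (legs are extracted).
#' @param tol hysteresis tolerance in signal units (default 0.1).
#' @return list `(classification, hysteresis)` with classification
#'   `"reversible"` or `"irreversible"`.
#' @export
assess_reversibility <- function(heating, cooling = NULL, tol = 0.1) {
  if (is.null(cooling)) {
    cooling <- .leg(heating, "cooling")
    heating <- .leg(heating, "heating")
  } else {
    heating <- .leg(heating, "heating")
    cooling <- .leg(cooling, "cooling")
  }
  if (nrow(heating) == 0L || nrow(cooling) == 0L)
    stop("both heating and cooling legs are required")
  if (min(cooling$temperature_C) > min(heating$temperature_C) + 1e-9)
    stop("invalid input: cooling must end at or below the heating start temperature")
  ov <- max(heating$temperature_C) >= min(cooling$temperature_C) &&
        max(cooling$temperature_C) >= min(heating$temperature_C)
  if (!ov) stop("invalid input: legs on disjoint temperature ranges")
  heating <- heating[order(heating$temperature_C), ]
  nb <- max(3L, floor(0.2 * nrow(heating)))
  baseline <- mean(heating$signal[seq_len(nb)])
  # end of cooling = the coolest 10% of the cooling leg
  cooling <- cooling[order(cooling$temperature_C), ]
  ne <- max(3L, floor(0.1 * nrow(cooling)))
  end_sig <- mean(cooling$signal[seq_len(ne)])
  hyst <- end_sig - baseline
  list(classification = if (hyst > tol) "irreversible" else "reversible",
       hysteresis = hyst)
}

#' Classify one condition into a state-diagram point
#'
#' Combines cloud-point detection and reversibility: no transition ->
#' `soluble`; transition + reversible cooling -> `reversible_ps`
#' (thermoresponsive phase separation); transition + hysteresis, or clusters
#' already present at the start (`pre_percolated`) -> `percolated`.
#'
#' @param ramp a `ramp_trace` with both legs.
#' @param condition free-form condition descriptor (e.g.
#'   `list(mg_mM = 6, rna = "wt")`).
#' @param pre_percolated clusters present at the lowest temperature? Supplied
#'   as a flag on the condition rather than inferred from the trace.
#' @param k,tol see [detect_cloud_point()] and [assess_reversibility()].
#' @return a `state_point` list: `condition`, `classification`, `lcpt_C`,
#'   `hysteresis`.
#' @export
classify_state_point <- function(ramp, condition = list(),
                                 pre_percolated = FALSE, k = 5, tol = 0.1) {
  lcpt <- detect_cloud_point(ramp, k = k)
  if (pre_percolated) {
    cls <- "percolated"; hyst <- NA_real_
  } else if (is.na(lcpt)) {
    cls <- "soluble"; hyst <- NA_real_
  } else {
    rev <- assess_reversibility(ramp, tol = tol)
    hyst <- rev$hysteresis
    cls <- if (rev$classification == "irreversible") "percolated"
           else "reversible_ps"
  }
  structure(list(condition = condition, classification = cls,
                 lcpt_C = lcpt, hysteresis = hyst),
            class = "state_point")
}

#' Build an RNA state diagram over a Mg2+ titration
#'
#' Orders the classified conditions by Mg2+ concentration, locates the
#' percolation boundary as the midpoint between the highest Mg2+ classified
#' soluble/reversible and the lowest classified percolated, and reports the
#' reversible window. A non-monotone classification sequence (percolated
#' below reversible) is flagged but the diagram is still built.
#'
#' @param points list of `state_point` objects whose conditions carry
#'   `mg_mM`, or a data.frame `(mg_mM, classification)`.
#' @return a `state_diagram` list: `table` (mg_mM, classification, lcpt_C),
#'   `percolation_boundary_mM` (NA when no percolated point),
#'   `reversible_window_mM` (NULL when empty), `monotone`.
#' @export
build_state_diagram <- function(points) {
  if (is.data.frame(points)) {
    tab <- points
    if (!"lcpt_C" %in% names(tab)) tab$lcpt_C <- NA_real_
  } else {
    tab <- do.call(rbind, lapply(points, function(p)
      data.frame(mg_mM = p$condition$mg_mM,
                 classification = p$classification,
                 lcpt_C = p$lcpt_C)))
  }
  if (length(unique(tab$mg_mM)) < 2L)
    stop("need at least 2 distinct Mg2+ values")
  tab <- tab[order(tab$mg_mM), ]
  rownames(tab) <- NULL
  perc <- tab$mg_mM[tab$classification == "percolated"]
  nonp <- tab$mg_mM[tab$classification != "percolated"]
  boundary <- if (length(perc) > 0L && length(nonp) > 0L) {
    lo <- suppressWarnings(max(nonp[nonp < min(perc)]))
    if (is.finite(lo)) (lo + min(perc)) / 2 else min(perc)
  } else NA_real_
  monotone <- !(length(perc) > 0L && length(nonp) > 0L &&
                any(nonp > min(perc)))
  revs <- tab$mg_mM[tab$classification == "reversible_ps"]
  window <- if (length(revs) > 0L) range(revs) else NULL
  structure(list(table = tab, percolation_boundary_mM = boundary,
                 reversible_window_mM = window, monotone = monotone),
            class = "state_diagram")
}

#' @export
print.state_diagram <- function(x, ...) {
  print(x$table)
  if (!is.na(x$percolation_boundary_mM))
    cat(sprintf("Percolation boundary: %.3g mM Mg2+\n",
                x$percolation_boundary_mM))
  else cat("No percolated region.\n")
  if (!is.null(x$reversible_window_mM))
    cat(sprintf("Reversible window: %.3g-%.3g mM\n",
                x$reversible_window_mM[1L], x$reversible_window_mM[2L]))
  if (!x$monotone) cat("WARNING: classification not monotone in Mg2+\n")
  invisible(x)
}

#' Fit a droplet-fusion force relaxation
#'
#' Least-squares fit of `F(t) = F_inf + dF * exp(-t/tau)` to an
#' optical-tweezer force trace during droplet coalescence. The
#' size-normalized relaxation time is `tau / mean(diameters)` (arithmetic
#' mean of the two droplet diameters), in ms/um. The fit is flagged
#' unreliable (no normalized value) when it does not converge or when the
#' fitted `tau` exceeds a third of the trace span.
#'
#' @param trace data.frame `(t_ms, force)`.
#' @param diameters_um diameters of the two fusing droplets (um).
#' @return a `fusion_fit` list: `tau_ms`, `F_inf`, `dF`,
#'   `normalized_tau_ms_per_um`, `diameters_um`, `converged`, `reliable`.
#' @export
fit_fusion_relaxation <- function(trace, diameters_um) {
  stopifnot(is.data.frame(trace), all(c("t_ms", "force") %in% names(trace)),
            length(diameters_um) == 2L, all(diameters_um > 0))
  t <- trace$t_ms; F <- trace$force
  span <- diff(range(t))
  Finf_g <- mean(utils::tail(F, max(3L, round(length(F) / 10))))
  dF_g <- F[1L] - Finf_g
  cross <- which(F - Finf_g <= dF_g * exp(-1))
  tau_g <- if (length(cross) > 0L && dF_g > 0) max(t[cross[1L]], span / 100)
           else span / 5
  fit <- .lm_exp_fit(function(p) p[1L] + p[2L] * exp(-t / p[3L]) - F,
                     start = c(Finf_g, dF_g, tau_g),
                     lower = c(-Inf, -Inf, 1e-9))
  d_mean <- mean(diameters_um)
  if (!fit$converged) {
    return(structure(list(tau_ms = NaN, F_inf = NaN, dF = NaN,
                          normalized_tau_ms_per_um = NA_real_,
                          diameters_um = diameters_um,
                          converged = FALSE, reliable = FALSE),
                     class = "fusion_fit"))
  }
  tau <- fit$par[3L]
  reliable <- is.finite(tau) && tau <= span / 3 && fit$par[2L] > 0
  structure(list(tau_ms = tau, F_inf = fit$par[1L],
                 dF = fit$par[2L],
                 normalized_tau_ms_per_um =
                   if (reliable) tau / d_mean else NA_real_,
                 diameters_um = diameters_um,
                 converged = TRUE, reliable = reliable),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  if (x$reliable)
    cat(sprintf("Fusion relaxation: tau %.3g ms, %.3g ms/um (d = %.3g um)\n",
                x$tau_ms, x$normalized_tau_ms_per_um,
                mean(x$diameters_um)))
  else cat("Fusion relaxation: fit not reliable (flat trace or tau beyond trace span)\n")
  invisible(x)
}
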