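# End-to-end aging time-course driver: compose image SAC, line-profile
# anti-correlation, cluster fraction, VPT rheology and FRAP per sample age.

#' Pipeline configuration
#'
#' All stage parameters with their package defaults; every pipeline report
#' embeds the fully resolved configuration and the package version
#' (reproducibility contract).
#'
#' @param scenario `"wt"` (aging: growing clusters, rising viscosity,
#'   eventual arrest, dropping RNA mobility) or `"mut"` (non-aging control:
#'   no clusters, constant material, constant mobility).
#' @param ages_h sample ages in hours.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_particles,n_frames VPT simulation size per age.
#' @param loc_noise_sd_um localization noise (um).
#' @param bead_radius_um,temperature_K Stokes-Einstein parameters.
#' @param pixel_size_um imaging pixel size.
#' @param image_shape_px image size.
#' @param condensate_radius_um condensate radius.
#' @param include_frap run FRAP fits per age?
#' @param out_dir optional output directory for the JSON/CSV report.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = c("wt", "mut"),
                       ages_h = c(0.5, 1, 1.5, 5),
                       seed = 1L,
                       n_particles = 40L, n_frames = 300L,
                       loc_noise_sd_um = 0.005,
                       bead_radius_um = 0.1, temperature_K = 298,
                       pixel_size_um = 0.2196,
                       image_shape_px = c(128L, 128L),
                       condensate_radius_um = 10,
                       include_frap = TRUE,
                       out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (length(ages_h) == 0L) stop("validation error: empty age list")
  if (is.unsorted(ages_h)) stop("validation error: ages must be ascending")
  structure(list(scenario = scenario, ages_h = ages_h, seed = as.integer(seed),
                 n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames),
                 loc_noise_sd_um = loc_noise_sd_um,
                 bead_radius_um = bead_radius_um,
                 temperature_K = temperature_K,
                 pixel_size_um = pixel_size_um,
                 image_shape_px = as.integer(image_shape_px),
                 condensate_radius_um = condensate_radius_um,
                 include_frap = include_frap,
                 out_dir = out_dir),
            class = "run_config")
}

# Study-condition presets per scenario: material state and RNA mobility as a
# function of age, mirroring the measured progression of aging condensates
# (fresh Newtonian liquid ~35 Pa.s, order-of-magnitude stiffening, then
# complete arrest) versus the non-aging control (constant ~35 Pa.s).
.scenario_material <- function(scenario, age_h, cfg) {
  if (scenario == "mut")
    return(material_model("newtonian", viscosity_Pa_s = 35.2,
                          temperature_K = cfg$temperature_K,
                          bead_radius_um = cfg$bead_radius_um))
  eta_stages <- c(35.2, 150, 489)
  breaks <- c(0.75, 1.25, 2.5) # age boundaries (h) between stages
  if (age_h >= breaks[3L])
    return(material_model("arrested", temperature_K = cfg$temperature_K,
                          bead_radius_um = cfg$bead_radius_um))
  stage <- findInterval(age_h, breaks) + 1L
  material_model("newtonian", viscosity_Pa_s = eta_stages[stage],
                 temperature_K = cfg$temperature_K,
                 bead_radius_um = cfg$bead_radius_um)
}

.scenario_aging_law <- function(scenario) {
  if (scenario == "wt")
    aging_law(sigma_final_um = 0.45, timescale_h = 1.5, n_clusters = 20L,
              amp_final = 300, amp_timescale_h = 3)
  else
    aging_law(sigma_initial_um = 0, sigma_final_um = 0, amp_final = 0)
}

.scenario_mobile <- function(scenario, age_h) {
  if (scenario == "wt") max(0.9 * exp(-age_h / 3), 0.2) else 0.9
}

# Line through the brightest in-mask pixel, oriented tangentially so both
# endpoints stay inside the condensate.
.bright_line <- function(img, mask, px, center_um, half_len_um = 3) {
  tmp <- img
  tmp[!mask] <- -Inf
  ij <- which(tmp == max(tmp), arr.ind = TRUE)[1L, ]
  p <- c((ij[2L] - 1L) * px, (ij[1L] - 1L) * px)
  v <- p - center_um
  if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0)
  tangent <- c(-v[2L], v[1L]) / sqrt(sum(v^2))
  list(p0 = p - half_len_um * tangent, p1 = p + half_len_um * tangent)
}

#' Run the aging time-course pipeline on simulated study conditions
#'
#' For each age: synthetic condensate image -> SAC cluster size (with
#' detection-floor flag), intensity-based cluster fraction, RNA/scaffold
#' line-profile Pearson r; synthetic bead trajectories -> MSD -> material
#' classification and terminal viscosity where the terminal regime exists;
#' optional FRAP fit of the RNA channel. Stage failures are recorded per age
#' and the pipeline continues. The acquisition interval for tracking is
#' scaled with the expected viscosity so the displacement signal per lag
#' stays resolvable across the full stiffness range.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list: `config`, `package_version`, `per_age`
#'   (data.frame with one row per age), `trends` (Kendall taus and the
#'   viscosity series), `errors`.
#' @export
run_aging_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  law <- .scenario_aging_law(cfg$scenario)
  spec <- scene_spec(image_shape_px = cfg$image_shape_px,
                     pixel_size_um = cfg$pixel_size_um,
                     condensate_radius_um = cfg$condensate_radius_um,
                     noise = "poisson", seed = cfg$seed)
  stack <- gen_condensate_stack(spec, law, cfg$ages_h,
                                anti_correlated = TRUE)
  errors <- list()
  rows <- vector("list", length(cfg$ages_h))
  frap_fits <- list()
  for (i in seq_along(cfg$ages_h)) {
    age <- cfg$ages_h[i]
    row <- data.frame(age_h = age, cluster_size_um = NA_real_,
                      at_floor = NA, cluster_fraction = NA_real_,
                      pearson_r = NA_real_, material_class = NA_character_,
                      eta_Pa_s = NA_real_, frap_mobile = NA_real_)
    rna <- stack$frames[[i]][, , 1L]
    scaf <- stack$frames[[i]][, , 2L]
    res <- tryCatch({
      cs <- cluster_size(spatial_autocorrelation(rna, cfg$pixel_size_um,
                                                 mask = stack$mask))
      row$cluster_size_um <- cs$size_um
      row$at_floor <- cs$at_floor
      row$cluster_fraction <- cluster_fraction(rna, stack$mask)
      ln <- .bright_line(rna, stack$mask, cfg$pixel_size_um,
                         spec$condensate_center_um)
      row$pearson_r <- pairwise_line_profile(rna, scaf, cfg$pixel_size_um,
                                             ln$p0, ln$p1,
                                             width_px = 3L)$pearson_r
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[paste0("imaging_age_", age)]] <- res

    res <- tryCatch({
      model <- .scenario_material(cfg$scenario, age, cfg)
      dt <- if (model$kind == "newtonian") 0.1 * model$viscosity_Pa_s else 5
      traj <- gen_trajectories(model, cfg$n_particles, cfg$n_frames, dt,
                               loc_noise_sd_um = cfg$loc_noise_sd_um,
                               seed = cfg$seed + 97L * i)
      prof <- compute_msd(traj)
      floor_est <- 4 * cfg$loc_noise_sd_um^2
      rr <- analyze_rheology(prof, cfg$bead_radius_um, cfg$temperature_K,
                             material_thresholds(static_floor_um2 = floor_est))
      row$material_class <- rr$material_class
      row$eta_Pa_s <- rr$eta_Pa_s
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[paste0("rheology_age_", age)]] <- res

    if (cfg$include_frap) {
      res <- tryCatch({
        mob <- .scenario_mobile(cfg$scenario, age)
        curve <- gen_frap_curve(mob, tau_s = 10, noise_sd = 0.01,
                                seed = cfg$seed + 131L * i)
        ft <- fit_frap(normalize_frap(curve))
        row$frap_mobile <- ft$mobile_fraction
        frap_fits[[as.character(age)]] <- ft
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) errors[[paste0("frap_age_", age)]] <- res
    }
    rows[[i]] <- row
  }
  per_age <- do.call(rbind, rows)

  ktau <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 2L || stats::sd(y[ok]) == 0) return(0)
    suppressWarnings(stats::cor(x[ok], y[ok], method = "kendall"))
  }
  trends <- list(
    cluster_size_kendall_tau = ktau(per_age$age_h, per_age$cluster_size_um),
    pearson_r_kendall_tau = ktau(per_age$age_h, per_age$pearson_r),
    eta_series_Pa_s = per_age$eta_Pa_s,
    arrested_at_final_age =
      identical(per_age$material_class[nrow(per_age)], "arrested"))

  report <- structure(list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("condaging")),
    per_age = per_age, trends = trends, frap_fits = frap_fits,
    errors = errors), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_json(report[c("config", "package_version", "trends",
                               "errors")],
                      file.path(cfg$out_dir, "report.json"))
    .write_csv_exact(per_age, file.path(cfg$out_dir, "per_age.csv"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Aging pipeline (%s scenario), %d ages\n",
              x$config$scenario, nrow(x$per_age)))
  print(x$per_age, digits = 3)
  cat(sprintf("cluster-size trend tau = %.2f; line-profile r trend tau = %.2f\n",
              x$trends$cluster_size_kendall_tau,
              x$trends$pearson_r_kendall_tau))
  if (length(x$errors) > 0L)
    cat("stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
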