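# Localization, linking, drift correction and MSD estimation.

test_that("a symmetric Gaussian spot is localized at its center", {
  px <- 0.5
  n <- 32
  xg <- (0:(n - 1)) * px
  img <- 10 * outer(exp(-(xg - 7)^2 / (2 * 1^2)),   # rows = y, center y = 7
                    exp(-(xg - 5)^2 / (2 * 1^2)))   # cols = x, center x = 5
  det <- detect_particles(img, px, expected_diameter_um = 2,
                          min_intensity = 1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_um - 5), 0.02)
  expect_lt(abs(det$y_um - 7), 0.02)
})

test_that("uniform frames yield no detections; separated spots both found", {
  px <- 0.5
  expect_equal(nrow(detect_particles(matrix(1, 32, 32), px, 2, 2)), 0L)
  n <- 48
  xg <- (0:(n - 1)) * px
  img <- 10 * outer(exp(-(xg - 6)^2 / 2), exp(-(xg - 6)^2 / 2)) +
         10 * outer(exp(-(xg - 15)^2 / 2), exp(-(xg - 15)^2 / 2))
  det <- detect_particles(img, px, 2, 1) # separation 9*sqrt(2) um >> 3 * 2 um
  expect_equal(nrow(det), 2L)
  # near-duplicate maxima within half a diameter merge into the brighter
  img2 <- img * 0
  img2[10, 10] <- 5; img2[10, 11] <- 6
  det2 <- detect_particles(img2, px, 2, 1)
  expect_equal(nrow(det2), 1L)
})

test_that("linking spans frames, bridges gaps, and preserves identities", {
  # one particle, small steps
  det <- lapply(1:10, function(f)
    data.frame(x_um = 0.05 * f, y_um = 0, mass = 1))
  tr <- link_trajectories(det, max_disp_um = 0.5)
  expect_equal(length(unique(tr$particle_id)), 1L)
  expect_equal(nrow(tr), 10L)

  # gap of one frame bridged with memory = 2
  det_gap <- det
  det_gap[[5]] <- det_gap[[5]][0, ]
  tr2 <- link_trajectories(det_gap, max_disp_um = 0.5, memory = 2)
  expect_equal(length(unique(tr2$particle_id)), 1L)
  expect_equal(attr(tr2, "linking_report")$n_gaps_bridged, 1L)
  # without memory the track breaks in two
  tr3 <- link_trajectories(det_gap, max_disp_um = 0.5, memory = 0)
  expect_equal(length(unique(tr3$particle_id)), 2L)

  # two approaching particles: swapping would need steps beyond max_disp,
  # and the chosen assignment has the lower total squared cost (enumerated)
  det_sw <- list(
    data.frame(x_um = c(0, 1), y_um = c(0, 0), mass = c(1, 1)),
    data.frame(x_um = c(0.2, 0.8), y_um = c(0, 0), mass = c(1, 1)))
  cost_keep <- (0.2 - 0)^2 + (0.8 - 1)^2
  cost_swap <- (0.8 - 0)^2 + (0.2 - 1)^2
  expect_lt(cost_keep, cost_swap)
  tr4 <- link_trajectories(det_sw, max_disp_um = 0.5)
  a <- tr4[tr4$particle_id == tr4$particle_id[tr4$frame == 1 &
                                              tr4$x_um == 0], ]
  expect_equal(a$x_um[a$frame == 2], 0.2)
})

test_that("drift correction removes common motion, keeps relative motion", {
  m <- material_model("arrested")
  tr <- gen_trajectories(m, 5, 50, 0.1, loc_noise_sd_um = 0,
                         drift_per_frame_um = c(0.05, -0.02), seed = 2)
  cor1 <- correct_drift(tr)
  expect_true(all(abs(compute_msd(cor1)$msd_um2) < 1e-24))
  expect_warning(
    correct_drift(trajectory_set(tr[tr$particle_id == 1, ], dt_s = 0.1)),
    "single particle")

  # drift + diffusion: corrected ensemble MSD matches the paired no-drift
  # simulation (same seed, drift is deterministic so draws are identical)
  mn <- material_model("newtonian", viscosity_Pa_s = 1)
  with_dr <- gen_trajectories(mn, 60, 200, 0.1,
                              drift_per_frame_um = c(0.08, 0.05), seed = 7)
  no_dr <- gen_trajectories(mn, 60, 200, 0.1, seed = 7)
  p_corr <- compute_msd(correct_drift(with_dr))
  p_ref <- compute_msd(no_dr)
  expect_equal(p_corr$msd_um2, p_ref$msd_um2, tolerance = 0.05)
})

test_that("MSD closed forms: ballistic exact, static-noise plateau", {
  # deterministic stepper x = v*t -> MSD = v^2 tau^2 exactly
  v <- 0.3
  df <- data.frame(particle_id = 1L, frame = 1:40,
                   t_s = (0:39) * 0.5, x_um = v * (0:39) * 0.5, y_um = 1)
  p <- compute_msd(trajectory_set(df, dt_s = 0.5))
  expect_equal(p$msd_um2, v^2 * p$lag_s^2, tolerance = 1e-12)

  # arrested + localization noise sigma -> flat at 4 sigma^2
  m <- material_model("arrested")
  tr <- gen_trajectories(m, 200, 100, 0.1, loc_noise_sd_um = 0.03, seed = 3)
  p2 <- compute_msd(tr)
  expect_equal(mean(p2$msd_um2), 4 * 0.03^2, tolerance = 0.05)
  expect_lt(diff(range(p2$msd_um2)) / mean(p2$msd_um2), 0.2)
})

test_that("pipeline MSD equals the brute-force double loop", {
  m <- material_model("maxwell", viscosity_Pa_s = 2,
                      confinement_sd_um = 0.05, relaxation_time_s = 0.2)
  tr <- gen_trajectories(m, 5, 50, 0.1, loc_noise_sd_um = 0.01, seed = 13)
  p <- compute_msd(tr)
  oracle <- msd_brute_force(tr)
  expect_equal(p$msd_um2, oracle, tolerance = 1e-10)
})

test_that("MSD is invariant under global translation and rotation", {
  m <- material_model("newtonian", viscosity_Pa_s = 5)
  tr <- gen_trajectories(m, 4, 60, 0.2, seed = 17)
  p0 <- compute_msd(tr)
  th <- 0.7
  tr2 <- tr
  tr2$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 12.3
  tr2$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 4.56
  p1 <- compute_msd(trajectory_set(as.data.frame(tr2), dt_s = 0.2))
  expect_equal(p1$msd_um2, p0$msd_um2, tolerance = 1e-12)
})

test_that("ensemble MSD sampling spread shrinks roughly as 1/sqrt(N)", {
  m <- material_model("newtonian", viscosity_Pa_s = 1)
  spread_at <- function(n) {
    vals <- vapply(1:10, function(s) {
      p <- compute_msd(gen_trajectories(m, n, 100, 0.1, seed = 400 + s))
      p$msd_um2[10]
    }, numeric(1))
    sd(vals)
  }
  ratio <- spread_at(10) / spread_at(100)
  expect_gt(ratio, sqrt(10) / 2)
  expect_lt(ratio, sqrt(10) * 2)
})

test_that("an image sequence tracks end to end", {
  # three beads stepping deterministically; detect + link recovers them
  px <- 0.5
  n <- 64
  xg <- (0:(n - 1)) * px
  mk_frame <- function(centers) {
    img <- matrix(0, n, n)
    for (k in seq_len(nrow(centers)))
      img <- img + 50 * outer(exp(-(xg - centers[k, 2])^2 / 2),
                              exp(-(xg - centers[k, 1])^2 / 2))
    img
  }
  start <- cbind(c(6, 15, 24), c(8, 20, 10))
  frames <- lapply(0:9, function(f) mk_frame(start + 0.1 * f))
  dets <- lapply(frames, detect_particles, pixel_size_um = px,
                 expected_diameter_um = 2, min_intensity = 5)
  tr <- link_trajectories(dets, max_disp_um = 0.5, dt_s = 0.1)
  expect_equal(length(unique(tr$particle_id)), 3L)
  expect_equal(nrow(tr), 30L)
})
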