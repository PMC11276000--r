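# Cloud-point detection, reversibility, state diagrams, fusion relaxation.

test_that("cloud-point detection: flat traces give none, sigmoids their
           center", {
  flat <- gen_ramp_trace(150, t_range_C = c(20, 80), noise_sd = 0.02,
                         seed = 1)
  expect_true(is.na(detect_cloud_point(flat)))

  hi <- gen_ramp_trace(60.2, reversible = FALSE, t_range_C = c(20, 80),
                       noise_sd = 0.05, seed = 2)
  expect_lt(abs(detect_cloud_point(hi) - 60.2), 0.5)

  lo <- gen_ramp_trace(28.8, reversible = TRUE, t_range_C = c(20, 60),
                       noise_sd = 0.05, seed = 3)
  expect_lt(abs(detect_cloud_point(lo) - 28.8), 0.5)
})

test_that("cloud-point error stays below 1 degree at SNR >= 10", {
  for (lcpt in c(25, 40, 60)) {
    errs <- vapply(1:20, function(s) {
      tr <- gen_ramp_trace(lcpt, t_range_C = c(lcpt - 12, lcpt + 27),
                           noise_sd = 0.1, seed = 200 + s)
      abs(detect_cloud_point(tr) - lcpt)
    }, numeric(1))
    expect_lt(max(errs), 1)
  }
})

test_that("reversibility classification and its strict tie-break", {
  rev <- gen_ramp_trace(60.2, reversible = TRUE, noise_sd = 0.05, seed = 4)
  expect_equal(assess_reversibility(rev)$classification, "reversible")
  irr <- gen_ramp_trace(60.2, reversible = FALSE, noise_sd = 0.05, seed = 5)
  expect_equal(assess_reversibility(irr)$classification, "irreversible")

  # hysteresis exactly at tol counts as reversible (strict inequality)
  heat <- data.frame(temperature_C = seq(20, 80, 1),
                     signal = c(rep(0, 40), rep(1, 21)))
  cool <- data.frame(temperature_C = seq(80, 20, -1),
                     signal = rep(0.1, 61))
  expect_equal(assess_reversibility(heat, cool, tol = 0.1)$classification,
               "reversible")
  cool$signal <- rep(0.1000001, 61)
  expect_equal(assess_reversibility(heat, cool, tol = 0.1)$classification,
               "irreversible")
  # disjoint temperature ranges are rejected
  cool_far <- data.frame(temperature_C = seq(10, 5, -1), signal = rep(0, 6))
  expect_error(assess_reversibility(heat, cool_far), "disjoint|cooling")
})

test_that("reversibility is >= 95% accurate at SNR 10", {
  calls <- vapply(1:40, function(s) {
    truth <- s %% 2 == 0
    tr <- gen_ramp_trace(60, reversible = truth, noise_sd = 0.1,
                         seed = 300 + s)
    assess_reversibility(tr)$classification ==
      (if (truth) "reversible" else "irreversible")
  }, logical(1))
  expect_gte(mean(calls), 0.95)
})

test_that("state points classify into soluble / reversible / percolated", {
  sol <- classify_state_point(gen_ramp_trace(150, t_range_C = c(20, 80),
                                             noise_sd = 0.05, seed = 6),
                              condition = list(mg_mM = 5))
  expect_equal(sol$classification, "soluble")
  rev <- classify_state_point(gen_ramp_trace(60.2, TRUE, noise_sd = 0.05,
                                             seed = 7),
                              condition = list(mg_mM = 6))
  expect_equal(rev$classification, "reversible_ps")
  expect_lt(abs(rev$lcpt_C - 60.2), 1)
  per <- classify_state_point(gen_ramp_trace(60.2, FALSE, noise_sd = 0.05,
                                             seed = 8),
                              condition = list(mg_mM = 7))
  expect_equal(per$classification, "percolated")
  pre <- classify_state_point(gen_ramp_trace(150, t_range_C = c(20, 80),
                                             noise_sd = 0.05, seed = 9),
                              condition = list(mg_mM = 10),
                              pre_percolated = TRUE)
  expect_equal(pre$classification, "percolated")
})

test_that("state diagram: narrow reversible window flanked by soluble and
           percolated regions", {
  # Mg titration emulating a thermoresponsive RNA with a narrow reversible
  # window (5.75-6.5 mM) and percolation above it
  mg <- c(5, 5.75, 6.1, 6.5, 7, 8)
  pts <- lapply(seq_along(mg), function(i) {
    kind <- if (mg[i] < 5.75) "soluble"
            else if (mg[i] <= 6.5) "reversible" else "percolated"
    tr <- switch(kind,
      soluble = gen_ramp_trace(150, t_range_C = c(20, 80), noise_sd = 0.05,
                               seed = 400 + i),
      reversible = gen_ramp_trace(60, TRUE, noise_sd = 0.05, seed = 400 + i),
      percolated = gen_ramp_trace(58, FALSE, noise_sd = 0.05,
                                  seed = 400 + i))
    classify_state_point(tr, condition = list(mg_mM = mg[i]))
  })
  sd1 <- build_state_diagram(pts)
  expect_equal(sd1$reversible_window_mM, c(5.75, 6.5))
  expect_equal(sd1$percolation_boundary_mM, (6.5 + 7) / 2)
  expect_true(sd1$monotone)

  # control RNA: reversible everywhere probed, no percolation
  mg2 <- c(10, 25)
  pts2 <- lapply(seq_along(mg2), function(i)
    classify_state_point(gen_ramp_trace(40, TRUE, noise_sd = 0.05,
                                        seed = 500 + i),
                         condition = list(mg_mM = mg2[i])))
  sd2 <- build_state_diagram(pts2)
  expect_true(is.na(sd2$percolation_boundary_mM))
  expect_equal(sd2$reversible_window_mM, c(10, 25))

  # all-soluble panel: no boundary, empty window
  sd3 <- build_state_diagram(data.frame(mg_mM = c(1, 2),
                                        classification = "soluble"))
  expect_true(is.na(sd3$percolation_boundary_mM))
  expect_null(sd3$reversible_window_mM)

  # non-monotone classification is flagged but still built
  sd4 <- build_state_diagram(data.frame(
    mg_mM = c(1, 2, 3),
    classification = c("percolated", "reversible_ps", "percolated")))
  expect_false(sd4$monotone)
})

test_that("fusion relaxation: exact normalization, size scaling, recovery", {
  tr <- gen_fusion_trace(54, c(3, 3), noise_sd = 0, seed = 1)
  ft <- fit_fusion_relaxation(tr, c(3, 3))
  expect_equal(ft$tau_ms, 54, tolerance = 1e-6)
  expect_equal(ft$normalized_tau_ms_per_um, 18, tolerance = 1e-6)
  # halving the diameters doubles the normalized time
  ft2 <- fit_fusion_relaxation(tr, c(1.5, 1.5))
  expect_equal(ft2$normalized_tau_ms_per_um, 36, tolerance = 1e-6)

  # noisy recovery: 20 seeds at SNR 20, mean tau within 5%
  taus <- vapply(1:20, function(s)
    fit_fusion_relaxation(gen_fusion_trace(50, c(3, 4), noise_sd = 0.05,
                                           seed = 600 + s),
                          c(3, 4))$tau_ms, numeric(1))
  expect_lt(abs(mean(taus) / 50 - 1), 0.05)

  # a flat trace (tau far beyond the window) is flagged, no normalized value
  flat <- gen_fusion_trace(1e6, c(3, 3), n_points = 100, noise_sd = 0.01,
                           seed = 2)
  ff <- fit_fusion_relaxation(flat, c(3, 3))
  expect_false(ff$reliable)
  expect_true(is.na(ff$normalized_tau_ms_per_um))
})
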