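# Spatial autocorrelation, cluster sizing, line profiles, cluster fraction.

test_that("FFT autocovariance equals direct summation with a mask", {
  set.seed(7)
  img <- matrix(runif(48 * 48), 48, 48)
  mask <- condaging:::.disk_mask(c(48L, 48L), c(5, 5), 4.5, 0.2196)
  sac <- spatial_autocorrelation(img, 0.2196, mask)
  lags <- as.matrix(expand.grid(di = -8:8, dj = -8:8))
  direct <- condaging:::.sac_direct(img, mask, lags)
  c0 <- direct[lags[, 1] == 0 & lags[, 2] == 0]
  fft_vals <- sac$corr_map[cbind(lags[, 1] + 48, lags[, 2] + 48)]
  expect_lt(max(abs(fft_vals - direct / c0), na.rm = TRUE), 1e-6)
  expect_equal(sac$radial_corr[sac$radial_lag_um == 0], 1, tolerance = 1e-12)
})

test_that("constant images give an undefined-correlation error", {
  expect_error(spatial_autocorrelation(matrix(5, 32, 32), 0.2),
               "zero intensity variance")
  expect_error(spatial_autocorrelation(matrix(1, 8, 8), 0.2),
               "at least 100 pixels")
})

test_that("white noise decorrelates within one pixel", {
  set.seed(11)
  img <- matrix(100 + rnorm(128^2, 0, 10), 128, 128)
  sac <- spatial_autocorrelation(img, 0.2196)
  far <- sac$radial_corr[sac$radial_lag_um >= 2 * 0.2196 &
                         sac$radial_lag_um <= 64 * 0.2196]
  expect_true(all(abs(far) <= 0.1))
  cs <- cluster_size(sac)
  expect_true(cs$at_floor)
})

test_that("Gaussian blob autocorrelation matches exp(-r^2/4sigma^2)", {
  px <- 0.2196
  sig <- 0.45
  img <- gaussian_blob_image(128, sig, px)
  sac <- spatial_autocorrelation(img, px)
  sel <- sac$radial_lag_um <= 3 * sig
  expected <- exp(-sac$radial_lag_um[sel]^2 / (4 * sig^2))
  expect_lt(max(abs(sac$radial_corr[sel] - expected)), 0.02)
  # 1/e convention: size = 2 sigma = 0.90 um
  expect_equal(cluster_size(sac)$size_um, 0.90, tolerance = 0.02)
})

test_that("cluster size is invariant to intensity scaling and offset, and
           scales with the blob", {
  px <- 0.2196
  img <- gaussian_blob_image(128, 0.5, px)
  base <- cluster_size(spatial_autocorrelation(img, px))$size_um
  scaled <- cluster_size(spatial_autocorrelation(7.3 * img + 40, px))$size_um
  expect_equal(scaled, base, tolerance = 1e-9)
  doubled <- cluster_size(spatial_autocorrelation(
    gaussian_blob_image(192, 1.0, px), px))$size_um
  expect_equal(doubled, 2 * base, tolerance = 0.05)
})

test_that("cluster size recovers 2*sigma within 10% at SNR 10", {
  px <- 0.2196
  set.seed(19)
  for (sig in c(0.3, 0.5, 1.0, 2.0)) {
    n <- if (sig >= 1.5) 192 else 128
    img <- gaussian_blob_image(n, sig, px)
    noisy <- img + rnorm(n^2, 0, sd(img) / 10)
    cs <- cluster_size(spatial_autocorrelation(noisy, px))
    expect_lt(abs(cs$size_um / (2 * sig) - 1), 0.10)
    expect_false(cs$at_floor)
  }
})

test_that("a correlation length beyond half the field is censored", {
  px <- 0.2196
  lag <- (0:63) * px
  # decay so slow it stays above 1/e throughout the trusted half-field range
  sac <- structure(list(radial_lag_um = lag,
                        radial_corr = exp(-lag^2 / (4 * (20 * px)^2)),
                        pixel_size_um = px),
                   class = "sac_result")
  cs <- cluster_size(sac)
  expect_true(cs$censored)
  expect_true(is.na(cs$size_um))
  # the same shape with a short correlation length is measured normally
  sac2 <- structure(list(radial_lag_um = lag,
                         radial_corr = exp(-lag^2 / (4 * (2 * px)^2)),
                         pixel_size_um = px),
                    class = "sac_result")
  cs2 <- cluster_size(sac2)
  expect_false(cs2$censored)
  expect_equal(cs2$size_um, 4 * px, tolerance = 0.05)
})

test_that("line profiles: self-correlation 1, inversion -1, degenerate error", {
  set.seed(23)
  img <- matrix(runif(64 * 64, 10, 50), 64, 64)
  px <- 0.2196
  p0 <- c(2, 5); p1 <- c(11, 7)
  same <- pairwise_line_profile(img, img, px, p0, p1)
  expect_equal(same$pearson_r, 1, tolerance = 1e-12)
  inv <- pairwise_line_profile(img, 60 - img, px, p0, p1)
  expect_equal(inv$pearson_r, -1, tolerance = 1e-12)
  expect_true(all(same$profile_a >= 0 & same$profile_a <= 1))
  expect_equal(min(same$profile_a), 0)
  expect_equal(max(same$profile_a), 1)
  expect_error(pairwise_line_profile(img, img, px, p0, p0), "degenerate")
})

test_that("anti-correlation deepens as clusters brighten with age", {
  spec <- scene_spec(noise = "gaussian", noise_sd = 8, seed = 31)
  law <- aging_law(sigma_final_um = 0.45, timescale_h = 3, amp_final = 300,
                   amp_timescale_h = 6)
  st <- gen_condensate_stack(spec, law, ages_h = c(0.5, 6),
                             anti_correlated = TRUE)
  px <- spec$pixel_size_um
  rs <- vapply(1:2, function(i) {
    rna <- st$frames[[i]][, , 1]
    ctr <- st$ground_truth[[i]]$centers_um[1, ]
    pairwise_line_profile(rna, st$frames[[i]][, , 2], px,
                          ctr - c(2, 0), ctr + c(2, 0),
                          width_px = 3)$pearson_r
  }, numeric(1))
  expect_lt(rs[2], -0.5)
  expect_lt(rs[2], rs[1])
})

test_that("cluster fraction: homogeneous 0, shell-at-background ~1,
           known 10% recovered, scale invariant", {
  px <- 0.2196
  n <- 128
  set.seed(37)
  mask <- condaging:::.disk_mask(c(n, n), c(14, 14), 9, px)
  # homogeneous condensate: exactly 0 noiseless, negligible with noise
  # (with Gaussian noise a ~0.1% tail clears any k-sigma threshold)
  img0 <- matrix(0, n, n); img0[mask] <- 100
  expect_equal(cluster_fraction(img0, mask), 0)
  expect_lt(cluster_fraction(img0 + rnorm(n^2, 0, 1), mask), 0.02)

  # cluster component: 6 Gaussians inside the disk
  xg <- (0:(n - 1)) * px
  comp <- matrix(0, n, n)
  set.seed(41)
  th <- runif(6, 0, 2 * pi); rr <- 6 * sqrt(runif(6))
  cxs <- 14 + rr * cos(th); cys <- 14 + rr * sin(th)
  truth_mask <- matrix(FALSE, n, n)
  sig <- 1.5 * px
  for (k in 1:6) {
    comp <- comp + outer(exp(-(xg - cys[k])^2 / (2 * sig^2)),
                         exp(-(xg - cxs[k])^2 / (2 * sig^2)))
    truth_mask <- truth_mask |
      (outer((xg - cys[k])^2, rep(1, n)) +
       outer(rep(1, n), (xg - cxs[k])^2)) <= (2.5 * sig)^2
  }
  truth_mask <- truth_mask & mask

  # all condensate intensity inside clusters (shell at background)
  img1 <- 200 * comp * mask + rnorm(n^2, 0, 2)
  expect_gt(cluster_fraction(img1, mask), 0.9)

  # clusters carrying a known 10% of the total condensate intensity:
  # solve the amplitude s with the ground-truth cluster mask as the oracle
  B <- matrix(0, n, n); B[mask] <- 100
  s <- (0.1 * sum(B[mask]) - sum(B[truth_mask])) /
       (sum(comp[truth_mask] * mask[truth_mask]) - 0.1 * sum(comp[mask]))
  expect_gt(s, 0)
  img2 <- B + s * comp * mask + rnorm(n^2, 0, 3)
  frac <- cluster_fraction(img2, mask)
  expect_lt(abs(frac - 0.10), 0.02)
  expect_equal(cluster_fraction(img2 * 3.7, mask, background = NULL), frac,
               tolerance = 0.01)
})

test_that("cluster size grows monotonically across an aging time course", {
  spec <- scene_spec(noise = "poisson", seed = 43)
  st <- gen_condensate_stack(spec, aging_law(amp_timescale_h = 3),
                             ages_h = c(0.5, 1, 1.5, 5))
  tc <- cluster_size_timecourse(st)
  expect_true(all(diff(tc$cluster_size_um) > -1e-9))
  expect_gt(attr(tc, "kendall_tau"), 0)
  expect_true(tc$at_floor[1])   # early age at the resolution floor
  expect_false(tc$at_floor[4])  # late age resolvable
  # flat (cluster-free) law: every age at the floor
  st0 <- gen_condensate_stack(spec, aging_law(sigma_final_um = 0,
                                              amp_final = 0),
                              ages_h = c(1, 5))
  tc0 <- cluster_size_timecourse(st0)
  expect_true(all(tc0$at_floor))
})
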