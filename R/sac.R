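# Spatial autocorrelation (SAC) analysis of intra-condensate clustering,
# line-profile anti-correlation, and intensity-based cluster fraction.

.fft2_xcorr <- function(a, b, P, Q) {
  # zero-padded circular cross-correlation sum_r a(r) * b(r + d)
  A <- matrix(0, P, Q); B <- matrix(0, P, Q)
  A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  B[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) /
    (P * Q)
}

#' Mask-aware normalized spatial autocovariance of an image
#'
#' Mean-subtracted autocovariance restricted to a mask (typically the
#' condensate region), computed with FFTs and normalized lag-by-lag by the
#' mask's own autocorrelation (the number of in-mask pixel pairs at each
#' lag), which removes the edge bias of a finite condensate. The map is
#' normalized so the zero-lag value is 1, and radially averaged over annular
#' bins of one pixel width.
#'
#' @param image 2D numeric matrix.
#' @param pixel_size_um um per pixel.
#' @param mask logical matrix of the same shape; `NULL` uses all pixels.
#' @param min_pixels minimum mask size.
#' @return a `sac_result`: list with `corr_map` (centered lag map,
#'   `(2*nr-1) x (2*nc-1)`), `radial_lag_um`, `radial_corr`, `pixel_size_um`,
#'   `variance`.
#' @export
spatial_autocorrelation <- function(image, pixel_size_um, mask = NULL,
                                    min_pixels = 100L) {
  stopifnot(is.matrix(image))
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(dim(mask) == dim(image))
  W <- mask * 1
  n_in <- sum(W)
  if (n_in < min_pixels)
    stop("mask must contain at least ", min_pixels, " pixels")
  mu <- sum(image * W) / n_in
  v <- sum(((image - mu) * W)^2) / n_in
  if (v <= 0)
    stop("undefined correlation: zero intensity variance within mask")

  P <- 2L * nr; Q <- 2L * nc
  dI <- (image - mu) * W
  num <- .fft2_xcorr(dI, dI, P, Q)
  den <- .fft2_xcorr(W, W, P, Q)

  # rearrange wrap-around lags into a centered (2nr-1) x (2nc-1) map
  ri <- c((P - nr + 2L):P, 1L:nr)   # lags -(nr-1) .. (nr-1)
  ci <- c((Q - nc + 2L):Q, 1L:nc)
  num_c <- num[ri, ci]
  den_c <- den[ri, ci]
  cov_map <- ifelse(den_c > 0.5, num_c / pmax(den_c, 0.5), NA_real_)
  c0 <- cov_map[nr, nc]
  corr_map <- cov_map / c0

  # radial average, 1-pixel annuli
  di <- (-(nr - 1L)):(nr - 1L)
  dj <- (-(nc - 1L)):(nc - 1L)
  r_px <- sqrt(outer(di^2, dj^2, "+"))
  bin <- round(r_px)
  max_bin <- floor(min(nr, nc) - 1L)
  keep <- bin <= max_bin & !is.na(corr_map)
  sums <- tapply(corr_map[keep], bin[keep], mean)
  bins <- as.integer(names(sums))
  structure(list(corr_map = corr_map,
                 radial_lag_um = bins * pixel_size_um,
                 radial_corr = as.numeric(sums),
                 pixel_size_um = pixel_size_um,
                 variance = v),
            class = "sac_result")
}

# Direct O(N^2) summation oracle for the mask-normalized autocovariance at
# the given pixel lags; used by tests to validate the FFT path.
.sac_direct <- function(image, mask, lags) {
  W <- mask * 1
  mu <- sum(image * W) / sum(W)
  dI <- (image - mu) * W
  nr <- nrow(image); nc <- ncol(image)
  out <- numeric(nrow(lags))
  for (k in seq_len(nrow(lags))) {
    di <- lags[k, 1L]; dj <- lags[k, 2L]
    i1 <- max(1L, 1L - di):min(nr, nr - di)
    j1 <- max(1L, 1L - dj):min(nc, nc - dj)
    a <- dI[i1, j1, drop = FALSE]
    b <- dI[i1 + di, j1 + dj, drop = FALSE]
    wa <- W[i1, j1, drop = FALSE]
    wb <- W[i1 + di, j1 + dj, drop = FALSE]
    npair <- sum(wa * wb)
    out[k] <- if (npair > 0) sum(a * b) / npair else NA_real_
  }
  out
}

#' Cluster size from a SAC radial profile (1/e convention)
#'
#' The characteristic cluster size is the smallest lag at which the radial
#' normalized autocovariance first falls to 1/e, found by linear
#' interpolation between annuli. The search starts at a lag of one pixel so
#' the zero-lag white-noise spike is excluded; the result is floored at one
#' pixel, and sizes at or below 1.5 pixels are flagged `at_floor` (the
#' detection limit: spatial fluctuations at the image resolution). For a
#' noiseless Gaussian cluster of width `sigma` the size is `2*sigma`.
#'
#' @param sac a `sac_result`.
#' @return list `(size_um, at_floor, censored)`; `censored = TRUE` with
#'   `size_um = NA` when the profile never falls below 1/e within half the
#'   image (size >= max lag).
#' @export
cluster_size <- function(sac) {
  stopifnot(inherits(sac, "sac_result"))
  px <- sac$pixel_size_um
  lag <- sac$radial_lag_um
  corr <- sac$radial_corr
  thr <- exp(-1)
  start <- which(lag >= px)[1L]
  if (is.na(start)) stop("radial profile has no lag >= 1 pixel")
  # sizes are only trusted up to half the field of view: beyond that the
  # profile is dominated by the finite window, so a non-crossing is censored
  half <- max(lag) / 2
  corr <- corr[lag <= half]
  lag <- lag[lag <= half]
  below <- which(corr[start:length(corr)] < thr)
  if (length(below) == 0L)
    return(list(size_um = NA_real_, at_floor = FALSE, censored = TRUE))
  k <- start + below[1L] - 1L
  if (k == start) {
    size <- px # already below 1/e at the first off-center annulus: floor
  } else {
    l0 <- lag[k - 1L]; l1 <- lag[k]
    c0 <- corr[k - 1L]; c1 <- corr[k]
    size <- l0 + (c0 - thr) / (c0 - c1) * (l1 - l0)
    size <- max(size, px)
  }
  list(size_um = size, at_floor = size <= 1.5 * px, censored = FALSE)
}

.bilinear <- function(image, x_px, y_px) {
  nr <- nrow(image); nc <- ncol(image)
  x_px <- pmin(pmax(x_px, 0), nc - 1L)
  y_px <- pmin(pmax(y_px, 0), nr - 1L)
  j0 <- pmin(floor(x_px), nc - 2L); i0 <- pmin(floor(y_px), nr - 2L)
  fx <- x_px - j0; fy <- y_px - i0
  v00 <- image[cbind(i0 + 1L, j0 + 1L)]
  v01 <- image[cbind(i0 + 1L, j0 + 2L)]
  v10 <- image[cbind(i0 + 2L, j0 + 1L)]
  v11 <- image[cbind(i0 + 2L, j0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Pairwise line-profile analysis of two co-registered channels
#'
#' Intensities are sampled along the line (bilinear interpolation, averaged
#' across `width_px` parallel offsets), each channel normalized by first
#' offsetting by its minimum and then dividing by its maximum, and the
#' Pearson correlation of the two normalized profiles is reported. Negative
#' values quantify anti-correlation, e.g. scaffold depletion at RNA cluster
#' positions.
#'
#' @param image_a,image_b 2D matrices of the two channels.
#' @param pixel_size_um um per pixel.
#' @param p0_um,p1_um line endpoints `(x, y)` in um, inside both images.
#' @param width_px number of parallel 1-pixel-spaced lines to average.
#' @return a `line_profile_pair`: list with `position_um`, `profile_a`,
#'   `profile_b` (both normalized to `[0, 1]`), `pearson_r`.
#' @export
pairwise_line_profile <- function(image_a, image_b, pixel_size_um,
                                  p0_um, p1_um, width_px = 1L) {
  stopifnot(is.matrix(image_a), is.matrix(image_b),
            all(dim(image_a) == dim(image_b)))
  len <- sqrt(sum((p1_um - p0_um)^2))
  if (len == 0) stop("invalid parameter: degenerate line (p0 == p1)")
  n <- max(2L, ceiling(len / (pixel_size_um / 2)) + 1L)
  tseq <- seq(0, 1, length.out = n)
  x <- p0_um[1L] + tseq * (p1_um[1L] - p0_um[1L])
  y <- p0_um[2L] + tseq * (p1_um[2L] - p0_um[2L])
  # unit normal for width averaging
  nx <- -(p1_um[2L] - p0_um[2L]) / len
  ny <- (p1_um[1L] - p0_um[1L]) / len
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pixel_size_um
  sample_chan <- function(img) {
    acc <- 0
    for (o in offs)
      acc <- acc + .bilinear(img, (x + o * nx) / pixel_size_um,
                             (y + o * ny) / pixel_size_um)
    acc / length(offs)
  }
  a <- sample_chan(image_a)
  b <- sample_chan(image_b)
  norm01 <- function(v) {
    v <- v - min(v)
    m <- max(v)
    if (m > 0) v / m else v
  }
  a <- norm01(a); b <- norm01(b)
  structure(list(position_um = tseq * len, profile_a = a, profile_b = b,
                 pearson_r = stats::cor(a, b)),
            class = "line_profile_pair")
}

#' Fraction of intensity residing in intra-condensate clusters
#'
#' Cluster pixels are those exceeding the robust threshold `median +
#' k_sigma * sigma_MAD` of the within-condensate intensity; the fraction is
#' the background-subtracted intensity summed over cluster pixels divided by
#' the background-subtracted intensity over the whole condensate. Robust
#' statistics (median/MAD) make the threshold insensitive to the bright
#' cluster tail itself. Invariant to uniform intensity scaling.
#'
#' @param image 2D matrix.
#' @param mask logical condensate mask (non-empty).
#' @param k_sigma threshold multiplier (default 3).
#' @param background background level; default the median intensity outside
#'   the mask (0 if the mask covers the image).
#' @return fraction in `[0, 1]`; 0 when no pixel exceeds the threshold
#'   (homogeneous condensate).
#' @export
cluster_fraction <- function(image, mask, k_sigma = 3, background = NULL) {
  stopifnot(is.matrix(image), all(dim(mask) == dim(image)))
  if (!any(mask)) stop("condensate mask is empty")
  vals <- image[mask]
  if (is.null(background)) {
    background <- if (any(!mask)) stats::median(image[!mask]) else 0
  }
  thr <- stats::median(vals) + k_sigma * stats::mad(vals)
  cl <- mask & (image > thr)
  if (!any(cl)) return(0)
  num <- sum(image[cl] - background)
  den <- sum(image[mask] - background)
  if (den <= 0) return(0)
  max(min(num / den, 1), 0)
}

#' SAC cluster size across an aging time course
#'
#' Applies [spatial_autocorrelation()] + [cluster_size()] to the RNA channel
#' of each age in an image stack and reports the size trend (Kendall tau of
#' size versus age).
#'
#' @param stack an `image_stack` from [gen_condensate_stack()], or a list of
#'   2D matrices with an `ages_h` argument.
#' @param masks optional list of logical masks (default: the stack's
#'   condensate mask, or Otsu threshold + fill).
#' @param ages_h ages when `stack` is a plain list of matrices.
#' @param channel channel index holding the RNA signal.
#' @return data.frame `(age_h, cluster_size_um, at_floor, censored)` with
#'   attribute `kendall_tau`.
#' @export
cluster_size_timecourse <- function(stack, masks = NULL, ages_h = NULL,
                                    channel = 1L) {
  if (inherits(stack, "image_stack")) {
    imgs <- lapply(stack$frames, function(a) a[, , channel])
    ages_h <- stack$ages_h
    if (is.null(masks)) masks <- rep(list(stack$mask), length(imgs))
    px <- stack$spec$pixel_size_um
  } else {
    imgs <- stack
    stopifnot(!is.null(ages_h), length(ages_h) == length(imgs))
    px <- attr(stack, "pixel_size_um")
    if (is.null(masks))
      masks <- lapply(imgs, function(im) {
        m <- im > EBImage::otsu(EBImage::Image(im / max(im))) * max(im)
        as.matrix(EBImage::fillHull(EBImage::Image(m * 1)) > 0.5)
      })
  }
  if (length(ages_h) < 2L) stop("need at least 2 ages")
  rows <- lapply(seq_along(imgs), function(i) {
    cs <- cluster_size(spatial_autocorrelation(imgs[[i]], px,
                                               mask = masks[[i]]))
    data.frame(age_h = ages_h[i], cluster_size_um = cs$size_um,
               at_floor = cs$at_floor, censored = cs$censored)
  })
  out <- do.call(rbind, rows)
  tau <- if (stats::sd(out$cluster_size_um, na.rm = TRUE) > 0)
    suppressWarnings(stats::cor(out$age_h, out$cluster_size_um,
                                method = "kendall",
                                use = "complete.obs"))
  else 0
  attr(out, "kendall_tau") <- tau
  out
}
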