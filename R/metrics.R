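#' Peak signal-to-noise ratio against the mean image
#'
#' `PSNR = 10 log10( max(mean)^2 / MSE )` in dB, with the MSE taken over
#' all pixels of the vectorized images — masked-out pixels contribute their
#' stored 0, matching the vectorized formulation.
#'
#' @param mean_image numeric matrix.
#' @param warped a `warped_image`, or a plain numeric matrix (treated as
#'   fully in-support).
#' @return PSNR in dB; `Inf` when the images are pixelwise identical.
#' @export
psnr <- function(mean_image, warped) {
  mean_image <- as.matrix(mean_image)
  v <- if (inherits(warped, "warped_image")) warped$values else as.matrix(warped)
  if (!all(dim(mean_image) == dim(v))) stop("images must share a shape")
  mse <- mean((mean_image - v)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(mean_image)^2 / mse)
}

#' Global structural similarity against the mean image
#'
#' A single whole-image SSIM statistic (no sliding window) computed from
#' global means, variances and covariance:
#' \deqn{SSIM = \frac{(2\mu_0\mu_n + c_1)(2\sigma_{0n} + c_2)}
#'   {(\mu_0^2 + \mu_n^2 + c_1)(\sigma_0^2 + \sigma_n^2 + c_2)}}
#' with `c1 = 0.01 max(mean_image)` and `c2 = 0.03 max(mean_image)` —
#' the constants enter linearly in the intensity maximum, and the
#' covariance term in the numerator is `2*cov + c2`. `windowed = TRUE`
#' instead computes the conventional locally windowed SSIM (Gaussian
#' window, squared stabilization constants) and returns its average, for
#' comparison with mainstream implementations.
#'
#' @inheritParams psnr
#' @param windowed use the conventional windowed SSIM instead of the global
#'   statistic (default `FALSE`).
#' @param window_sigma Gaussian window standard deviation in pixels for the
#'   windowed variant (default 1.5).
#' @return a similarity value; 1 for an image with itself.
#' @export
ssim_global <- function(mean_image, warped, windowed = FALSE,
                        window_sigma = 1.5) {
  mean_image <- as.matrix(mean_image)
  v <- if (inherits(warped, "warped_image")) warped$values else as.matrix(warped)
  if (!all(dim(mean_image) == dim(v))) stop("images must share a shape")
  L <- max(mean_image)
  if (windowed) {
    c1 <- (0.01 * L)^2
    c2 <- (0.03 * L)^2
    m0 <- gaussian_smooth(mean_image, window_sigma)
    mn <- gaussian_smooth(v, window_sigma)
    s00 <- gaussian_smooth(mean_image^2, window_sigma) - m0^2
    snn <- gaussian_smooth(v^2, window_sigma) - mn^2
    s0n <- gaussian_smooth(mean_image * v, window_sigma) - m0 * mn
    num <- (2 * m0 * mn + c1) * (2 * s0n + c2)
    den <- (m0^2 + mn^2 + c1) * (s00 + snn + c2)
    return(mean(num / den))
  }
  c1 <- 0.01 * L
  c2 <- 0.03 * L
  a <- as.vector(mean_image); b <- as.vector(v)
  m0 <- mean(a); mn <- mean(b)
  npx <- length(a)
  s00 <- sum((a - m0)^2) / npx
  snn <- sum((b - mn)^2) / npx
  s0n <- sum((a - m0) * (b - mn)) / npx
  ((2 * m0 * mn + c1) * (2 * s0n + c2)) /
    ((m0^2 + mn^2 + c1) * (s00 + snn + c2))
}

#' Ensemble alignment quality report
#'
#' Computes per-image PSNR and global SSIM of every warped image against
#' the final mean image, plus their ensemble means (mPSNR, mSSIM). Images
#' pixelwise identical to the mean yield infinite PSNR and are excluded
#' from mPSNR with a warning.
#'
#' @param state a finalized `congeal_state` from [congeal()].
#' @param stack the [image_stack] the metrics are evaluated on (typically
#'   the original-intensity stack).
#' @param on_sqi evaluate against the working (SQI) mean instead — only
#'   meaningful when the state was fitted with `use_sqi` (default `FALSE`).
#' @return a `metrics_report`: list with `psnr_per_image`, `ssim_per_image`,
#'   `mpsnr`, `mssim`.
#' @export
ensemble_metrics <- function(state, stack, on_sqi = FALSE) {
  N <- length(stack$images)
  mimg <- if (on_sqi) state$mean_image else state$mean_original
  if (is.null(mimg)) mimg <- state$mean_image
  ps <- numeric(N); ss <- numeric(N)
  for (n in seq_len(N)) {
    # full-frame resampling (edge replication): the vectorized MSE then
    # measures residual misalignment, not the area lost to resampling
    w <- warp_image(stack$images[[n]], state$params[[n]], fill = "edge")
    ps[n] <- psnr(mimg, w)
    ss[n] <- ssim_global(mimg, w)
  }
  fin <- is.finite(ps)
  if (!all(fin))
    warning(sum(!fin), " image(s) identical to the mean excluded from mPSNR")
  structure(list(psnr_per_image = ps, ssim_per_image = ss,
                 mpsnr = mean(ps[fin]), mssim = mean(ss)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ensemble metrics over %d images:\n  mPSNR = %.3f dB\n  mSSIM = %.4f\n",
              length(x$psnr_per_image), x$mpsnr, x$mssim))
  invisible(x)
}
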