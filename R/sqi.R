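#' Self Quotient Image configuration
#'
#' @param sigma standard deviation, in pixels, of the isotropic Gaussian
#'   kernel used for the smoothed denominator image. Controls the width of
#'   the edges retained in the quotient. Default 2.
#' @param mu hard-threshold factor in (0, 1): quotient deviations from the
#'   mean smaller than `mu` standard deviations are suppressed. Default 0.5.
#' @param epsilon denominator guard added to the smoothed image before
#'   division, as a fraction of the image maximum. Default 1e-3.
#' @return an object of class `sqi_config`.
#' @export
sqi_config <- function(sigma = 2, mu = 0.5, epsilon = 1e-3) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu >= 1)
    stop("mu must lie strictly between 0 and 1")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be positive")
  structure(list(sigma = sigma, mu = mu, epsilon = epsilon),
            class = "sqi_config")
}

# sampled, truncated, renormalized 1-D Gaussian kernel
gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# 1-D convolution along the rows of m with reflective padding
conv_cols_reflect <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m)
  idx <- c(rev(seq_len(min(r, nr))), seq_len(nr),
           nr + 1 - seq_len(min(r, nr)))
  # if r > nr the reflection repeats; extend by cycling the reflection
  while (length(idx) < nr + 2 * r) {
    idx <- c(idx[1], idx, idx[length(idx)])
  }
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nr, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[j:(j + nr - 1), , drop = FALSE]
  }
  out
}

#' Isotropic Gaussian smoothing
#'
#' Separable Gaussian filtering with reflective boundary handling and a
#' kernel truncated at 4 sigma and renormalized to unit mass, so constants
#' are preserved exactly.
#'
#' @param image numeric matrix.
#' @param sigma positive kernel standard deviation in pixels.
#' @return smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  image <- as.matrix(image)
  k <- gaussian_kernel_1d(sigma)
  t(conv_cols_reflect(t(conv_cols_reflect(image, k)), k))
}

#' Compute the Self Quotient Image
#'
#' The quotient of an image to its Gaussian-smoothed version,
#' `Q = I / (I_sigma + eps)`, with `eps = cfg$epsilon * max(I)` guarding
#' against division by near-zero in dark regions. The quotient is invariant
#' to multiplicative intensity scaling and approximately invariant to any
#' shading field that is smooth at the kernel scale, leaving edge structure.
#'
#' @param image numeric matrix with nonnegative intensities.
#' @param cfg an [sqi_config].
#' @return an `sq_image`: list with `values` (the quotient) and
#'   `source_shape`.
#' @export
compute_sqi <- function(image, cfg = sqi_config()) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must be finite")
  if (any(image < 0))
    stop("image has negative intensities; shift or rescale before SQI")
  sm <- gaussian_smooth(image, cfg$sigma)
  eps <- cfg$epsilon * max(image)
  if (eps <= 0) eps <- cfg$epsilon  # all-zero image
  q <- image / (sm + eps)
  structure(list(values = q, source_shape = dim(image)), class = "sq_image")
}

#' Hard-threshold a Self Quotient Image
#'
#' Centers the quotient at its mean and suppresses deviations below
#' `T = mu * sd(Q)`: the output is `Q - mean(Q)` where
#' `|Q - mean(Q)| > T` and 0 elsewhere. Small quotient fluctuations
#' (noise, residual shading) vanish while strong edges survive; the output
#' is zero-mean up to the suppressed mass, which removes the DC offset that
#' would otherwise dominate a least-squares alignment cost.
#'
#' @param q an `sq_image` from [compute_sqi()].
#' @param cfg an [sqi_config]; only `mu` is used.
#' @return an `sq_image` with thresholded values. A constant quotient
#'   (zero standard deviation) yields an all-zero image.
#' @export
threshold_sqi <- function(q, cfg = sqi_config()) {
  v <- q$values
  if (!all(is.finite(v))) stop("quotient image must be finite")
  m <- mean(v)
  s <- stats::sd(as.vector(v))
  out <- matrix(0, nrow(v), ncol(v))
  if (is.finite(s) && s > 0) {
    dev <- v - m
    keep <- abs(dev) > cfg$mu * s
    out[keep] <- dev[keep]
  }
  structure(list(values = out, source_shape = q$source_shape),
            class = "sq_image")
}

#' Full SQI preprocessing of one image
#'
#' Convenience wrapper: quotient then hard threshold.
#'
#' @inheritParams compute_sqi
#' @return numeric matrix of thresholded quotient values, same shape as the
#'   input.
#' @export
sqi_preprocess <- function(image, cfg = sqi_config()) {
  threshold_sqi(compute_sqi(image, cfg), cfg)$values
}

#' Polarity-insensitive SQI edge map
#'
#' The thresholded quotient is signed: a bright-to-dark edge and its
#' contrast-inverted counterpart produce deviations of opposite sign whose
#' dominant ridge sits on opposite sides of the edge. For ensembles that
#' mix inverted contrasts (e.g. T1- against T2-like images) this biases a
#' least-squares alignment systematically. This variant instead thresholds
#' the gradient magnitude of the (lightly smoothed) quotient, which peaks
#' at the edge crossing regardless of contrast polarity: edges are kept as
#' positive outliers above `mu` standard deviations, everything else is
#' suppressed, mirroring the hard-threshold denoising of the signed map.
#'
#' @inheritParams compute_sqi
#' @param presmooth standard deviation, in pixels, of the light Gaussian
#'   smoothing applied to the quotient before differentiation (default 1).
#' @return numeric matrix of thresholded edge strengths (nonnegative).
#' @export
sqi_edge_map <- function(image, cfg = sqi_config(), presmooth = 1) {
  q <- compute_sqi(image, cfg)$values
  g <- image_gradients(gaussian_smooth(q, presmooth))
  e <- sqrt(g$gx^2 + g$gy^2)
  m <- mean(e)
  s <- stats::sd(as.vector(e))
  out <- matrix(0, nrow(e), ncol(e))
  if (is.finite(s) && s > 0) {
    keep <- e - m > cfg$mu * s
    out[keep] <- e[keep] - m
  }
  out
}
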