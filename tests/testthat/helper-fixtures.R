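# shared fixtures: all generated in code, seeded for reproducibility

# smooth textured image with gradient energy everywhere
smooth_texture <- function(n = 48, seed = 7, sigma = 2) {
  set.seed(seed)
  m <- gaussian_smooth(matrix(runif(n * n), n, n), sigma)
  (m - min(m)) / (max(m) - min(m))
}

# dense direct 2-D convolution with a truncated sampled Gaussian kernel and
# reflective padding: the independent oracle for gaussian_smooth
dense_gaussian_conv <- function(im, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k1 <- dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nr <- nrow(im); nc <- ncol(im)
  ri <- c(rev(seq_len(r)), seq_len(nr), nr + 1 - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(nc), nc + 1 - seq_len(r))
  pad <- im[ri, ci]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- sum(K * pad[i:(i + 2 * r), j:(j + 2 * r)])
    }
  }
  out
}

# translation-only SSD grid search: the independent oracle for the
# Gauss-Newton translation estimate
grid_search_translation <- function(target, image, span = 1, step = 0.01) {
  offs <- seq(-span, span, by = step)
  best <- c(NA, NA); best_ssd <- Inf
  for (tx in offs) {
    for (ty in offs) {
      w <- warp_image(image, affine_params(c(0, 0, 0, 0, tx, ty)))
      ssd <- sum(((target - w$values)[w$mask])^2)
      if (ssd < best_ssd) { best_ssd <- ssd; best <- c(tx, ty) }
    }
  }
  best
}
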