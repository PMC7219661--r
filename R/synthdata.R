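# run expr under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic distortion settings
#'
#' Describes how an ensemble of distorted copies of a base image is
#' generated: geometric strength, photometric shading, occlusions and
#' pseudo-modality intensity remaps.
#'
#' @param sigma2 geometric distortion strength: the variance, in squared
#'   pixels, of the i.i.d. Gaussian displacements applied to three corners
#'   of the image rectangle (1 = mild, 10 = strong; 0 = no warp).
#' @param shading `"none"`, `"ramp"` (multiplicative linear ramp from 0.2
#'   to 1.0 in a random direction, per image), or `"field"` (smooth
#'   low-frequency multiplicative field in \[0.4, 1.2\]).
#' @param occlusion_frac area fraction (0 to 0.4) of a single opaque
#'   rectangle pasted onto an occluded image; 0 disables occlusion.
#' @param occlusion_prob fraction of images that carry an occlusion.
#' @param modality `"identity"`, `"gamma"` (power-law remap with exponent
#'   drawn from `gamma`), `"remap"` (random monotone piecewise-linear remap
#'   with 5 knots), or `"mixed"` (cycles identity/gamma/remap across the
#'   ensemble, emulating T1/T2/PD-style contrast differences).
#' @param gamma candidate exponents for the gamma remap.
#' @param seed integer seed; a fixed seed reproduces the ensemble exactly.
#' @return an object of class `distortion_spec`.
#' @export
distortion_spec <- function(sigma2 = 2,
                            shading = c("none", "ramp", "field"),
                            occlusion_frac = 0, occlusion_prob = 0,
                            modality = c("identity", "gamma", "remap", "mixed"),
                            gamma = c(0.5, 2), seed = 1) {
  shading <- match.arg(shading)
  modality <- match.arg(modality)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (occlusion_frac < 0 || occlusion_frac > 0.4)
    stop("occlusion_frac must lie in [0, 0.4]")
  structure(list(sigma2 = sigma2, shading = shading,
                 occlusion_frac = occlusion_frac,
                 occlusion_prob = occlusion_prob,
                 modality = modality, gamma = gamma,
                 seed = as.integer(seed)),
            class = "distortion_spec")
}

#' Generate a base image
#'
#' Produces a smooth, textured, non-periodic image in \[0, 1\] with gradient
#' energy spread over the support, so that the alignment normal equations
#' are well conditioned.
#'
#' @param kind `"texture"` (band-limited noise), `"blobs"` (face-like
#'   arrangement of Gaussian bumps on a textured background), or
#'   `"phantom"` (brain-like nested ellipses with distinct intensity
#'   levels plus faint texture).
#' @param shape `c(rows, cols)`, at least 32 x 32.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return numeric matrix in \[0, 1\].
#' @export
make_base_image <- function(kind = c("texture", "blobs", "phantom"),
                            shape = c(100, 100), seed = 1) {
  kind <- match.arg(kind)
  if (any(shape < 32)) stop("shape must be at least 32 x 32")
  nr <- shape[1]; nc <- shape[2]
  with_seed(seed, {
    noise <- matrix(stats::runif(nr * nc), nr, nc)
    tex <- gaussian_smooth(noise, 2)
    tex <- (tex - min(tex)) / (max(tex) - min(tex))
    g <- centered_grid(nr, nc)
    im <- switch(kind,
      texture = tex,
      blobs = {
        bump <- function(x0, y0, sx, sy, a)
          a * exp(-((g$x - x0)^2 / (2 * sx^2) + (g$y - y0)^2 / (2 * sy^2)))
        face <- bump(0, 0, 0.35 * nc, 0.45 * nr, 0.55) -
          bump(-0.15 * nc, -0.12 * nr, 0.05 * nc, 0.04 * nr, 0.45) -
          bump(0.15 * nc, -0.12 * nr, 0.05 * nc, 0.04 * nr, 0.45) +
          bump(0, 0.05 * nr, 0.03 * nc, 0.06 * nr, 0.3) -
          bump(0, 0.22 * nr, 0.12 * nc, 0.03 * nr, 0.35)
        face + 0.15 + 0.25 * tex
      },
      phantom = {
        ell <- function(x0, y0, a, b)
          ((g$x - x0) / a)^2 + ((g$y - y0) / b)^2 <= 1
        lv <- matrix(0.05, nr, nc)
        lv[ell(0, 0, 0.45 * nc, 0.45 * nr)] <- 0.9   # skull
        lv[ell(0, 0, 0.40 * nc, 0.40 * nr)] <- 0.5   # parenchyma
        lv[ell(-0.1 * nc, 0, 0.06 * nc, 0.15 * nr)] <- 0.2  # ventricles
        lv[ell(0.1 * nc, 0, 0.06 * nc, 0.15 * nr)] <- 0.2
        lv[ell(0, 0.25 * nr, 0.1 * nc, 0.08 * nr)] <- 0.7   # brainstem
        # asymmetric focal structures and gyral-scale texture break the
        # near-symmetry of the rings, so the alignment normal equations
        # stay well conditioned in every affine direction
        lv[ell(-0.22 * nc, -0.18 * nr, 0.05 * nc, 0.04 * nr)] <- 0.75
        lv[ell(0.18 * nc, 0.22 * nr, 0.04 * nc, 0.05 * nr)] <- 0.3
        inside <- ell(0, 0, 0.40 * nc, 0.40 * nr)
        lv[inside] <- lv[inside] + 0.12 * (tex[inside] - 0.5)
        lv
      })
    pmin(pmax(im, 0), 1)
  })
}

# reflect-pad a matrix by r pixels on every side
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(r)), seq_len(nr), nr + 1 - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(nc), nc + 1 - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# the three reference corners (top-left, top-right, bottom-left) of the
# image rectangle in centered coordinates
reference_corners <- function(shape) {
  cx <- (shape[2] - 1) / 2
  cy <- (shape[1] - 1) / 2
  cbind(x = c(-cx, cx, -cx), y = c(-cy, -cy, cy))
}

#' Draw a random affine warp of controlled strength
#'
#' Perturbs the three reference corners of the image rectangle by i.i.d.
#' Gaussian displacements with standard deviation `sqrt(sigma2)` pixels and
#' solves exactly for the affine parameters mapping the original corners to
#' the perturbed ones. Distortion strength is therefore monotone in
#' `sigma2`. Uses the current RNG state; seed the ensemble via
#' [make_ensemble()] or `set.seed()`.
#'
#' @param sigma2 corner displacement variance in squared pixels (>= 0).
#' @param shape image `c(rows, cols)` defining the corner positions.
#' @param max_retries resampling bound for (vanishingly rare) degenerate
#'   corner draws.
#' @return an [affine_params] vector; `sigma2 = 0` gives the identity.
#' @export
sample_affine <- function(sigma2, shape, max_retries = 10L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (sigma2 == 0) return(affine_params())
  corners <- reference_corners(shape)
  X <- cbind(corners[, 1], corners[, 2], 1)
  for (try in seq_len(max_retries)) {
    d <- matrix(stats::rnorm(6, sd = sqrt(sigma2)), 3, 2)
    target <- corners + d
    C <- tryCatch(solve(X, target), error = function(e) NULL)
    if (is.null(C)) next
    p <- c(C[1, 1] - 1, C[1, 2], C[2, 1], C[2, 2] - 1, C[3, 1], C[3, 2])
    if (abs((1 + p[1]) * (1 + p[4]) - p[2] * p[3]) > 1e-6)
      return(affine_params(p))
  }
  stop("failed to draw a non-degenerate affine warp after ", max_retries,
       " attempts")
}

# random monotone-decreasing piecewise-linear intensity remap on [0, 1]
# with 5 knots: a contrast inversion (bright tissue turns dark and vice
# versa, as between T1- and T2-weighted MRI), destroying the intensity
# correspondence raw least squares relies on while leaving edges in place
random_monotone_remap <- function() {
  y <- cumsum(c(0, stats::runif(4)))
  y <- 1 - y / y[5]
  x <- seq(0, 1, length.out = 5)
  function(v) stats::approx(x, y, xout = pmin(pmax(v, 0), 1))$y
}

shading_field <- function(kind, shape) {
  nr <- shape[1]; nc <- shape[2]
  g <- centered_grid(nr, nc)
  switch(kind,
    none = matrix(1, nr, nc),
    ramp = {
      th <- stats::runif(1, 0, 2 * pi)
      proj <- cos(th) * g$x + sin(th) * g$y
      proj <- (proj - min(proj)) / (max(proj) - min(proj))
      0.2 + 0.8 * proj
    },
    field = {
      f <- gaussian_smooth(matrix(stats::runif(nr * nc), nr, nc),
                           max(nr, nc) / 6)
      f <- (f - min(f)) / max(max(f) - min(f), 1e-12)
      0.4 + 0.8 * f
    })
}

#' Generate a synthetic ensemble with known ground-truth warps
#'
#' Each image is `modality_map(shading * warp(base, p_n))` with an opaque
#' occluding rectangle pasted last on the selected images; the drawn warp
#' parameters, shading fields and occlusion rectangles are all retained, so
#' recovery error can be measured exactly.
#'
#' The base is reflect-padded before warping so every output pixel is in
#' support: real ensembles (camera images, MRI crops) fill their frame, and
#' zero-filled borders would inject strong artificial edges that dominate
#' the quotient images.
#'
#' @param base numeric matrix in \[0, 1\] (see [make_base_image()]).
#' @param N ensemble size (>= 2).
#' @param spec a [distortion_spec].
#' @return a `synthetic_ensemble`: list with `stack` ([image_stack]),
#'   `true_params` (list of [affine_params]), `occluded` (logical vector),
#'   `occlusions` (list of rectangle coordinates or `NULL`), `modalities`
#'   (character vector) and `spec`.
#' @export
make_ensemble <- function(base, N, spec = distortion_spec()) {
  if (N < 2) stop("N must be >= 2")
  base <- as.matrix(base)
  shape <- dim(base)
  margin <- min(ceiling(3 * sqrt(spec$sigma2) + 6),
                min(shape) - 1L)
  padded <- pad_reflect(base, margin)
  with_seed(spec$seed, {
    true_params <- vector("list", N)
    images <- vector("list", N)
    occluded <- logical(N)
    occlusions <- vector("list", N)
    modalities <- character(N)
    mod_cycle <- c("identity", "gamma", "remap")
    for (n in seq_len(N)) {
      p <- sample_affine(spec$sigma2, shape)
      # warp the padded base on the same centered grid, then crop: the
      # distorted image fills its frame like a real acquisition would
      wp <- warp_image(padded, p)$values
      img <- wp[(margin + 1):(margin + shape[1]),
                (margin + 1):(margin + shape[2]), drop = FALSE]
      img <- img * shading_field(spec$shading, shape)
      mod <- if (spec$modality == "mixed")
        mod_cycle[(n - 1L) %% 3L + 1L] else spec$modality
      modalities[n] <- mod
      img <- switch(mod,
        identity = img,
        gamma = {
          gam <- sample(spec$gamma, 1)
          pmin(pmax(img, 0), 1)^gam
        },
        remap = {
          f <- random_monotone_remap()
          matrix(f(img), shape[1], shape[2])
        })
      if (spec$occlusion_frac > 0 && stats::runif(1) < spec$occlusion_prob) {
        area <- spec$occlusion_frac * prod(shape)
        asp <- stats::runif(1, 0.5, 2)
        h <- max(2L, min(shape[1], round(sqrt(area * asp))))
        w <- max(2L, min(shape[2], round(area / h)))
        r0 <- sample.int(shape[1] - h + 1L, 1)
        c0 <- sample.int(shape[2] - w + 1L, 1)
        val <- stats::runif(1)
        img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- val
        occluded[n] <- TRUE
        occlusions[[n]] <- list(row = r0, col = c0, height = h, width = w,
                                value = val)
      }
      true_params[[n]] <- p
      images[[n]] <- img
    }
    structure(list(stack = image_stack(images),
                   true_params = true_params,
                   occluded = occluded, occlusions = occlusions,
                   modalities = modalities, spec = spec),
              class = "synthetic_ensemble")
  })
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf(
    "synthetic ensemble: N = %d, sigma2 = %g, shading = %s, modality = %s\n",
    length(x$stack$images), x$spec$sigma2, x$spec$shading, x$spec$modality))
  invisible(x)
}

#' Residual corner misalignment of an ensemble
#'
#' Measures how far the ensemble is from joint alignment: each image's
#' composite warp (ground-truth distortion composed with the estimated
#' correction, if any) is applied to the three reference corners, and the
#' RMS distance of each image's corner positions from the ensemble-average
#' corner positions is returned. Comparing the value at `params = NULL`
#' (no correction) with the value at the recovered parameters quantifies
#' alignment improvement independently of any global affine ambiguity.
#'
#' @param ensemble a `synthetic_ensemble`.
#' @param params optional list of estimated [affine_params]; `NULL` means
#'   uncorrected.
#' @param subset optional integer or logical index of images to include.
#' @return RMS corner displacement in pixels.
#' @export
corner_rmse <- function(ensemble, params = NULL, subset = NULL) {
  shape <- dim(ensemble$stack$images[[1]])
  corners <- reference_corners(shape)
  idx <- seq_along(ensemble$true_params)
  if (!is.null(subset)) idx <- idx[subset]
  pos <- lapply(idx, function(n) {
    B <- affine_matrix(ensemble$true_params[[n]])
    if (!is.null(params)) B <- B %*% affine_matrix(params[[n]])
    t(B %*% rbind(t(corners), 1))[, 1:2, drop = FALSE]
  })
  avg <- Reduce(`+`, pos) / length(pos)
  sq <- vapply(pos, function(pp) mean(rowSums((pp - avg)^2)), numeric(1))
  sqrt(mean(sq))
}
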