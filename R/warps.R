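#' Affine warp parameters
#'
#' Constructs and validates a length-6 affine parameter vector `p`.
#' The induced warp, acting on centered pixel coordinates (x = column,
#' y = row, origin at the image midpoint), is
#' \deqn{w(x, y; p) = \big((1+p_1)x + p_3 y + p_5,\; p_2 x + (1+p_4) y + p_6\big)}
#' so `p = 0` is the identity and `(p5, p6)` is a translation in pixels.
#'
#' @param p numeric vector of length 6 (default all zero: identity warp).
#' @return an object of class `affine_params` (a named numeric vector).
#' @examples
#' affine_params()                      # identity
#' affine_params(c(0, 0, 0, 0, 2, -1)) # translate by (+2, -1) pixels
#' @export
affine_params <- function(p = numeric(6)) {
  p <- as.numeric(p)
  if (length(p) != 6L)
    stop("affine parameter vector must have length 6, got ", length(p))
  if (!all(is.finite(p)))
    stop("affine parameters must be finite")
  names(p) <- c("p1", "p2", "p3", "p4", "p5", "p6")
  class(p) <- "affine_params"
  p
}

#' @export
print.affine_params <- function(x, ...) {
  cat("affine warp parameters (p = 0 is identity):\n")
  print(unclass(x), ...)
  invisible(x)
}

# 3x3 homogeneous matrix of the warp (maps centered output coords to
# centered source coords under inverse-warp resampling)
affine_matrix <- function(p) {
  p <- as.numeric(p)
  matrix(c(1 + p[1], p[2], 0,
           p[3], 1 + p[4], 0,
           p[5], p[6], 1), nrow = 3L)
}

# inverse: 3x3 matrix back to a parameter vector
matrix_to_params <- function(A) {
  affine_params(c(A[1, 1] - 1, A[2, 1], A[1, 2], A[2, 2] - 1, A[1, 3], A[2, 3]))
}

# determinant of the 2x2 linear part; near-zero means degenerate warp
affine_det <- function(p) {
  p <- as.numeric(p)
  (1 + p[1]) * (1 + p[4]) - p[2] * p[3]
}

assert_nondegenerate <- function(p, tol = 1e-8) {
  d <- affine_det(p)
  if (!is.finite(d) || abs(d) < tol)
    stop("degenerate affine warp: linear part has determinant ", format(d))
  invisible(d)
}

# centered coordinate grids for an nrow x ncol image; x along columns,
# y along rows, pixel units, midpoint at zero
centered_grid <- function(nr, nc) {
  cx <- (nc - 1) / 2
  cy <- (nr - 1) / 2
  list(
    x = matrix(rep(seq_len(nc) - 1 - cx, each = nr), nr, nc),
    y = matrix(rep(seq_len(nr) - 1 - cy, times = nc), nr, nc),
    cx = cx, cy = cy
  )
}

#' Apply an affine warp to points
#'
#' Maps points given in centered pixel coordinates through the warp
#' `w(.; p)`. With `p = 0` this is the identity.
#'
#' @param p an [affine_params] vector (or plain length-6 numeric).
#' @param coords a two-column matrix (or coercible) of (x, y) points.
#' @return a two-column matrix of warped (x, y) points.
#' @examples
#' warp_points(affine_params(), cbind(3, -2))
#' @export
warp_points <- function(p, coords) {
  p <- as.numeric(p)
  coords <- matrix(as.numeric(coords), ncol = 2L)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  x <- coords[, 1]; y <- coords[, 2]
  cbind((1 + p[1]) * x + p[3] * y + p[5],
        p[2] * x + (1 + p[4]) * y + p[6])
}

#' Warp an image by an affine transform
#'
#' Inverse-warp resampling with bilinear interpolation: the output pixel at
#' centered coordinates x takes the value `image(w(x; p))`. Samples falling
#' outside the source rectangle are masked out (value 0, mask `FALSE`) so
#' that border pixels never act as outliers in the alignment cost.
#'
#' @param image numeric matrix (rows = y, columns = x), finite values.
#' @param p an [affine_params] vector.
#' @param fill handling of samples outside the source rectangle: `"mask"`
#'   (default) sets them to 0 and marks them out of support, so they are
#'   excluded from alignment costs; `"edge"` clamps the sample location to
#'   the rectangle (edge replication), producing a full-frame image — used
#'   when a frame-filling output is needed, e.g. for whole-frame quality
#'   metrics.
#' @return a `warped_image`: list with `values` (numeric matrix, 0 where
#'   masked) and `mask` (logical matrix, `TRUE` where the warped sample
#'   contributes).
#' @examples
#' im <- matrix(runif(64), 8, 8)
#' w <- warp_image(im, affine_params())
#' stopifnot(identical(w$values, im), all(w$mask))
#' @export
warp_image <- function(image, p, fill = c("mask", "edge")) {
  fill <- match.arg(fill)
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must be finite")
  p <- as.numeric(p)
  assert_nondegenerate(p)
  nr <- nrow(image); nc <- ncol(image)
  g <- centered_grid(nr, nc)
  # source sample locations in 0-based pixel units
  sx <- (1 + p[1]) * g$x + p[3] * g$y + p[5] + g$cx
  sy <- p[2] * g$x + (1 + p[4]) * g$y + p[6] + g$cy
  if (fill == "edge") {
    sx <- pmin(pmax(sx, 0), nc - 1)
    sy <- pmin(pmax(sy, 0), nr - 1)
  }
  mask <- sx >= 0 & sx <= nc - 1 & sy >= 0 & sy <= nr - 1
  # bilinear interpolation at the in-support samples
  vals <- matrix(0, nr, nc)
  if (any(mask)) {
    sxm <- sx[mask]; sym <- sy[mask]
    x0 <- floor(sxm); y0 <- floor(sym)
    # clamp so that x0+1, y0+1 stay in range on the far edge
    x0 <- pmin(x0, nc - 2); y0 <- pmin(y0, nr - 2)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    fx <- sxm - x0; fy <- sym - y0
    i00 <- y0 + 1 + x0 * nr       # column-major linear indices
    v <- (1 - fx) * (1 - fy) * image[i00] +
         (1 - fx) * fy       * image[i00 + 1] +
         fx       * (1 - fy) * image[i00 + nr] +
         fx       * fy       * image[i00 + nr + 1]
    vals[mask] <- v
  }
  structure(list(values = vals, mask = mask), class = "warped_image")
}

#' @export
print.warped_image <- function(x, ...) {
  cat(sprintf("warped image %d x %d, %.1f%% of pixels in support\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

# central-difference gradients with edge replication, unit pixel spacing;
# returns list(gx, gy) with gx along columns (x), gy along rows (y)
image_gradients <- function(im) {
  nr <- nrow(im); nc <- ncol(im)
  ip <- cbind(im[, 1], im, im[, nc])       # replicate columns
  gx <- (ip[, 3:(nc + 2)] - ip[, 1:nc]) / 2
  ip <- rbind(im[1, ], im, im[nr, ])       # replicate rows
  gy <- (ip[3:(nr + 2), ] - ip[1:nr, ]) / 2
  list(gx = gx, gy = gy)
}

#' Jacobian of the warped image with respect to the warp parameters
#'
#' Assembles the (Nx*Ny) x 6 Jacobian `G = dI_w/dp` at the current
#' parameters by the chain rule: spatial gradients of the warped image
#' (central differences, edge replication) times the warp derivative
#' `dw/dp`, evaluated on the centered coordinate grid. Rows belonging to
#' masked-out pixels are zero.
#'
#' @param image numeric matrix (the source image, before warping).
#' @param p an [affine_params] vector.
#' @return list with `G` (pixels x 6 matrix, column-major pixel order) and
#'   `mask` (logical matrix from the warp).
#' @export
compute_jacobian <- function(image, p) {
  w <- warp_image(image, p)
  gr <- image_gradients(w$values)
  # gradients at masked-out pixels (and their stencil neighbours touching
  # them) are unreliable; zero the masked rows outright
  gx <- gr$gx; gy <- gr$gy
  gx[!w$mask] <- 0
  gy[!w$mask] <- 0
  g <- centered_grid(nrow(w$values), ncol(w$values))
  G <- cbind(as.vector(gx * g$x),   # d/dp1: dw = (x, 0)
             as.vector(gy * g$x),   # d/dp2: dw = (0, x)
             as.vector(gx * g$y),   # d/dp3: dw = (y, 0)
             as.vector(gy * g$y),   # d/dp4: dw = (0, y)
             as.vector(gx),         # d/dp5: dw = (1, 0)
             as.vector(gy))         # d/dp6: dw = (0, 1)
  list(G = G, mask = w$mask, warped = w)
}

#' One Gauss-Newton (Lucas-Kanade) parameter update
#'
#' Solves the linearized least-squares subproblem for the additive
#' perturbation: `dp = (G'G)^{-1} G' (vec(mean) - vec(warped))`, restricted
#' to mask-true pixels. This is the pseudo-inverse update of the forward
#' additive scheme.
#'
#' @param mean_image numeric matrix: the current ensemble mean.
#' @param warped a `warped_image` of the image being aligned.
#' @param jac the Jacobian list from [compute_jacobian()].
#' @param cond_max reject the update when the normal-equation matrix has
#'   2-norm condition number above this (insufficient texture). Default 1e10.
#' @param damping Levenberg-Marquardt factor: solves
#'   `(G'G + damping * diag(G'G)) dp = G' r`, shrinking the step along
#'   weakly constrained parameter directions. The default 0 is the plain
#'   pseudo-inverse update.
#' @return the perturbation as an [affine_params] vector.
#' @export
gauss_newton_update <- function(mean_image, warped, jac, cond_max = 1e10,
                                damping = 0) {
  m <- as.vector(as.matrix(mean_image))
  v <- as.vector(warped$values)
  if (length(m) != length(v)) stop("mean and warped image shapes differ")
  keep <- as.vector(warped$mask)
  G <- jac$G[keep, , drop = FALSE]
  if (nrow(G) < 6L)
    stop("too few in-support pixels (", nrow(G), ") for a parameter update")
  r <- m[keep] - v[keep]
  GtG <- crossprod(G)
  kap <- tryCatch(kappa(GtG, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > cond_max)
    stop("ill-conditioned normal equations (condition number ",
         format(kap, digits = 3),
         "): insufficient texture for a stable update")
  if (damping > 0) GtG <- GtG + damping * diag(diag(GtG))
  dp <- solve(GtG, crossprod(G, r))
  affine_params(as.vector(dp))
}
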