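test_that("warp_points follows the affine parameterization", {
  # identity
  expect_equal(warp_points(affine_params(), cbind(3, -2)),
               cbind(3, -2))
  # unit translation in x
  expect_equal(warp_points(affine_params(c(0, 0, 0, 0, 1, 0)), cbind(0, 0)),
               cbind(1, 0))
  # scale term acts multiplicatively on x
  expect_equal(warp_points(affine_params(c(0.1, 0, 0, 0, 0, 0)), cbind(10, 5)),
               cbind(11, 5))
})

test_that("affine parameter validation rejects bad vectors", {
  expect_error(affine_params(1:5), "length 6")
  expect_error(affine_params(c(1, 2, 3, NA, 5, 6)), "finite")
  # degenerate linear part caught before resampling
  p_deg <- affine_params(c(-1, 0, 0, 0, 0, 0))  # (1+p1) = 0
  expect_error(warp_image(matrix(1, 8, 8), p_deg), "degenerate")
})

test_that("warp_image identity and constant-image invariants hold", {
  im <- smooth_texture(16)
  w <- warp_image(im, affine_params())
  expect_identical(w$values, im)
  expect_true(all(w$mask))

  cim <- matrix(0.7, 12, 12)
  w2 <- warp_image(cim, affine_params(c(0.02, 0.01, -0.01, 0.03, 0.4, -0.2)))
  expect_true(all(abs(w2$values[w2$mask] - 0.7) < 1e-12))
  expect_true(all(w2$values[!w2$mask] == 0))
})

test_that("unit x-translation reproduces an explicit index shift", {
  n <- 64
  ramp <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
  ramp <- ramp + smooth_texture(n, seed = 3) * 0.5
  # sampling source at x+1: output column j shows source column j+1
  w <- warp_image(ramp, affine_params(c(0, 0, 0, 0, 1, 0)))
  expect_equal(w$values[, 1:(n - 1)], ramp[, 2:n], tolerance = 1e-12)
  expect_true(all(!w$mask[, n]))
})

test_that("Jacobian matches a numerical-differentiation oracle", {
  n <- 32
  g <- seq(-1, 1, length.out = n)
  quad <- outer(g, g, function(y, x) 0.3 * x^2 + 0.2 * y^2 + 0.4 * x * y + 0.5 * x)
  quad <- quad - min(quad)
  jac <- compute_jacobian(quad, affine_params())
  # finite-difference each parameter; compare on interior pixels
  h <- 1e-5
  interior <- matrix(FALSE, n, n); interior[3:(n - 2), 3:(n - 2)] <- TRUE
  for (j in 1:6) {
    e <- numeric(6)
    e[j] <- h
    fp <- warp_image(quad, affine_params(e))$values
    fm <- warp_image(quad, affine_params(-e))$values
    fd <- (fp - fm) / (2 * h)
    Gj <- matrix(jac$G[, j], n, n)
    denom <- sqrt(sum(fd[interior]^2))
    if (denom > 0)
      expect_lt(sqrt(sum((Gj[interior] - fd[interior])^2)) / denom, 1e-3)
  }
})

test_that("translation columns of the Jacobian equal the image gradients", {
  im <- smooth_texture(24, seed = 9)
  jac <- compute_jacobian(im, affine_params())
  gr <- congealsqi:::image_gradients(im)
  expect_equal(matrix(jac$G[, 5], 24, 24), gr$gx, tolerance = 1e-14)
  expect_equal(matrix(jac$G[, 6], 24, 24), gr$gy, tolerance = 1e-14)
})

test_that("constant image gives an all-zero Jacobian", {
  jac <- compute_jacobian(matrix(2, 16, 16), affine_params())
  expect_true(all(jac$G == 0))
})

test_that("Gauss-Newton update solves the masked least-squares system", {
  im <- smooth_texture(20, seed = 5)
  jac <- compute_jacobian(im, affine_params(c(0.01, 0, 0, -0.01, 0.3, 0.1)))
  w <- jac$warped
  # zero residual => zero update
  dp0 <- gauss_newton_update(w$values, w, jac)
  expect_true(all(abs(dp0) < 1e-12))

  # oracle equivalence against a dense QR least-squares solve
  set.seed(11)
  for (rep in 1:5) {
    target <- w$values + matrix(rnorm(400, sd = 0.05), 20, 20)
    dp <- gauss_newton_update(target, w, jac)
    keep <- as.vector(w$mask)
    oracle <- qr.solve(jac$G[keep, ],
                       (as.vector(target) - as.vector(w$values))[keep])
    expect_lt(max(abs(as.numeric(dp) - oracle)), 1e-8)
  }
})

test_that("Gauss-Newton recovers a known half-pixel translation", {
  # build the pair from a larger texture so both crops are fully valid
  big <- smooth_texture(56, seed = 21)
  im <- big[5:52, 5:52]
  shifted <- warp_image(big, affine_params(c(0, 0, 0, 0, -0.5, 0)))$values[5:52, 5:52]
  # align `shifted` (content moved +0.5 px in x) to `im`: expected
  # translation estimate ~ (0.5, 0), cross-checked against an exhaustive
  # 0.01-px SSD grid search
  jac <- compute_jacobian(shifted, affine_params())
  w <- warp_image(shifted, affine_params())
  dp <- gauss_newton_update(im, w, jac)
  oracle <- grid_search_translation(im, shifted)
  expect_lt(abs(dp[5] - oracle[1]), 0.1)
  expect_lt(abs(dp[6] - oracle[2]), 0.1)
  expect_lt(abs(dp[5] - 0.5), 0.1)
  expect_true(all(abs(dp[c(1:4, 6)]) <= 0.05))
})

test_that("ill-conditioned normal equations are rejected", {
  # a pure x-ramp has no y-gradient information at all
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  jac <- compute_jacobian(ramp, affine_params())
  w <- warp_image(ramp, affine_params())
  expect_error(gauss_newton_update(ramp + 0.1, w, jac), "ill-conditioned")
})

test_that("estimating against the original recovers -p to first order", {
  im <- smooth_texture(40, seed = 13)
  set.seed(14)
  for (rep in 1:5) {
    p <- rnorm(6, sd = 0.006)
    p <- p / max(1, sqrt(sum(p^2)) / 0.02)   # ||p|| <= 0.02
    w <- warp_image(im, affine_params(p))
    # iterate the estimator to convergence; the limit is the exact affine
    # inverse, which differs from -p at second order, plus a small
    # resampling-bias floor from bilinear interpolation
    q <- affine_params()
    for (it in 1:8) {
      jac <- compute_jacobian(w$values, q)
      wq <- jac$warped
      wq$mask <- wq$mask & w$mask
      dp <- gauss_newton_update(im, wq, jac)
      q <- affine_params(as.numeric(q) + as.numeric(dp))
    }
    expect_lt(sqrt(sum((as.numeric(q) + p)^2)), 10 * sum(p^2) + 5e-3)
  }
})
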