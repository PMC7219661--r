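#' Image stack (ensemble)
#'
#' Bundles N same-sized grayscale images for groupwise alignment.
#'
#' @param images list of numeric matrices of identical dimensions.
#' @param names optional character identifiers, one per image.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(images, names = NULL) {
  if (!is.list(images) || length(images) < 2L)
    stop("an image stack needs at least 2 images")
  new_image_stack(images, names)
}

# internal constructor: skips the N >= 2 requirement (degenerate stacks are
# occasionally useful for diagnostics) but keeps shape/finiteness checks
new_image_stack <- function(images, names = NULL) {
  images <- lapply(images, as.matrix)
  dims <- vapply(images, dim, integer(2))
  if (length(images) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
    stop("images have mismatched shapes: image 1 is ",
         dims[1, 1], "x", dims[2, 1], " but image(s) ",
         paste(bad, collapse = ", "), " are ",
         paste(sprintf("%dx%d", dims[1, bad], dims[2, bad]), collapse = ", "))
  }
  if (!all(vapply(images, function(m) all(is.finite(m)), logical(1))))
    stop("all images must have finite values")
  if (is.null(names)) names <- sprintf("image%03d", seq_along(images))
  structure(list(images = images, names = as.character(names)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("image stack: %d images of %d x %d\n", length(x$images),
              d[1], d[2]))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$images)

#' Congealing configuration
#'
#' @param kmax maximum number of alternations (default 200).
#' @param emax stopping tolerance on the relative decrease of the mean
#'   misalignment cost between successive iterations (default 1e-8).
#' @param use_sqi align on hard-thresholded Self Quotient Images instead of
#'   raw intensities (default `FALSE`). The recovered warps apply equally to
#'   the original stack, which shares the geometry.
#' @param sqi an [sqi_config] used when `use_sqi` is `TRUE`.
#' @param sqi_edge working representation under `use_sqi`: `"signed"`
#'   aligns on the hard-thresholded quotient itself (the default; best for
#'   shading, occlusions and any ensemble whose contrasts share polarity),
#'   `"magnitude"` aligns on the polarity-insensitive edge map of
#'   [sqi_edge_map()] (for ensembles mixing inverted contrasts, e.g.
#'   different MRI weightings).
#' @param drift_correction re-normalize the warp set every iteration so the
#'   average affine matrix is the identity, preventing the ensemble from
#'   drifting or shrinking as a whole (default `TRUE`).
#' @param coarse_to_fine run the alternation in three stages on working
#'   images blurred with Gaussian sigma 4, then 2, then unblurred
#'   (default `TRUE`). Widens the attraction basin so that sparse edge
#'   maps and strongly distorted ensembles do not lock onto aliased
#'   correspondences; set `FALSE` for the plain single-scale alternation.
#' @param cond_max per-image guard: skip an update whose normal equations
#'   have condition number above this (default 1e10).
#' @param damping Levenberg-Marquardt factor passed to
#'   [gauss_newton_update()] during the blurred coarse-to-fine stages
#'   (default 0.01): stabilizes weakly constrained affine directions
#'   (shear/scale on sparse edge maps) while the basin is wide. The
#'   full-resolution stage always runs the plain pseudo-inverse update.
#' @param rescale map stack intensities to \[0, 1\] before processing, making
#'   `emax` and the SQI epsilon scale-free (default `TRUE`).
#' @return an object of class `congeal_config`.
#' @export
congeal_config <- function(kmax = 200, emax = 1e-8, use_sqi = FALSE,
                           sqi = sqi_config(),
                           sqi_edge = c("signed", "magnitude"),
                           drift_correction = TRUE,
                           coarse_to_fine = TRUE,
                           cond_max = 1e10, damping = 0.01,
                           rescale = TRUE) {
  if (!is.numeric(kmax) || kmax < 1) stop("kmax must be >= 1")
  if (!is.numeric(emax) || emax <= 0) stop("emax must be > 0")
  stopifnot(inherits(sqi, "sqi_config"))
  structure(list(kmax = as.integer(kmax), emax = emax,
                 use_sqi = isTRUE(use_sqi), sqi = sqi,
                 sqi_edge = match.arg(sqi_edge),
                 drift_correction = isTRUE(drift_correction),
                 coarse_to_fine = isTRUE(coarse_to_fine),
                 cond_max = cond_max, damping = damping,
                 rescale = isTRUE(rescale)),
            class = "congeal_config")
}

#' Mean image of the currently warped ensemble
#'
#' The per-pixel average of the warped images, the closed-form minimizer of
#' the mean misalignment cost for fixed warps. Only mask-true contributions
#' enter each pixel's average; pixels with no contributor are 0 with
#' `count = 0`.
#'
#' @param stack an [image_stack].
#' @param params list of [affine_params], one per image.
#' @return list with `values` (the mean image) and `count` (integer matrix
#'   of contributors per pixel).
#' @export
compute_mean_image <- function(stack, params) {
  d <- dim(stack$images[[1]])
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (n in seq_along(stack$images)) {
    w <- warp_image(stack$images[[n]], params[[n]])
    acc <- acc + w$values
    cnt <- cnt + w$mask
  }
  if (all(cnt == 0L)) stop("no pixel received any contribution: all warps degenerate")
  vals <- matrix(0, d[1], d[2])
  nz <- cnt > 0L
  vals[nz] <- acc[nz] / cnt[nz]
  list(values = vals, count = cnt)
}

#' Mean misalignment cost
#'
#' The mean over images of the squared residual between the mean image and
#' each warped image, summed over that image's in-support pixels.
#'
#' @param mean_image numeric matrix (or the list from
#'   [compute_mean_image()]).
#' @param stack an [image_stack].
#' @param params list of [affine_params].
#' @return a single nonnegative number.
#' @export
compute_c0 <- function(mean_image, stack, params) {
  if (is.list(mean_image)) mean_image <- mean_image$values
  tot <- 0
  for (n in seq_along(stack$images)) {
    w <- warp_image(stack$images[[n]], params[[n]])
    r <- (mean_image - w$values)[w$mask]
    tot <- tot + sum(r * r)
  }
  tot / length(stack$images)
}

#' Cumulative squared misalignment error (diagnostic)
#'
#' The all-pairs squared misalignment over both ordered pairs, evaluated on
#' jointly in-support pixels. Quadratic in N; kept as a diagnostic only —
#' the alignment loop never evaluates it.
#'
#' @inheritParams compute_c0
#' @return a single nonnegative number.
#' @export
compute_csme <- function(stack, params) {
  N <- length(stack$images)
  if (N < 2L) stop("CSME needs at least 2 images")
  ws <- lapply(seq_len(N), function(n) warp_image(stack$images[[n]], params[[n]]))
  tot <- 0
  for (n in seq_len(N)) {
    for (m in seq_len(N)) {
      if (m == n) next
      joint <- ws[[n]]$mask & ws[[m]]$mask
      r <- (ws[[n]]$values - ws[[m]]$values)[joint]
      tot <- tot + sum(r * r)
    }
  }
  tot
}

# compose every warp with the inverse of the ensemble-average affine matrix
# so that the average warp is exactly the identity
normalize_drift <- function(params) {
  mats <- lapply(params, affine_matrix)
  Abar <- Reduce(`+`, mats) / length(mats)
  if (abs(det(Abar[1:2, 1:2])) < 1e-8) return(params)  # pathological; skip
  Ainv <- solve(Abar)
  lapply(mats, function(A) matrix_to_params(A %*% Ainv))
}

#' One alternation of the groupwise alignment loop
#'
#' Recomputes the mean image from the current warps, then refines each
#' image's parameters by one Gauss-Newton update against that mean —
#' exactly N least-squares subproblems, never N^2. An image whose normal
#' equations are ill-conditioned keeps its previous parameters and is
#' logged; the rest proceed.
#'
#' @param state a `congeal_state` (see [congeal()]).
#' @param working_stack the [image_stack] being aligned (raw intensities or
#'   preprocessed SQIs).
#' @return the updated `congeal_state`.
#' @export
congeal_step <- function(state, working_stack) {
  N <- length(working_stack$images)
  mi <- compute_mean_image(working_stack, state$params)
  c0 <- compute_c0(mi, working_stack, state$params)
  covered <- mi$count > 0L
  new_params <- state$params
  for (n in seq_len(N)) {
    res <- tryCatch({
      jac <- compute_jacobian(working_stack$images[[n]], state$params[[n]])
      w <- jac$warped
      w$mask <- w$mask & covered
      jac$G[!as.vector(covered), ] <- 0
      dp <- gauss_newton_update(mi$values, w, jac, cond_max = state$cond_max,
                                damping = state$damping)
      affine_params(as.numeric(state$params[[n]]) + as.numeric(dp))
    }, error = function(e) e)
    state$n_solves <- state$n_solves + 1L
    if (inherits(res, "error")) {
      state$log <- c(state$log, sprintf(
        "iteration %d, %s: update skipped (%s)",
        state$iteration + 1L, working_stack$names[n], conditionMessage(res)))
    } else {
      new_params[[n]] <- res
    }
  }
  if (state$drift_correction) new_params <- normalize_drift(new_params)
  state$params <- new_params
  state$mean_image <- mi$values
  state$count <- mi$count
  state$cost_trace <- c(state$cost_trace, c0)
  state$iteration <- state$iteration + 1L
  state
}

new_congeal_state <- function(N, dims, cfg) {
  structure(list(
    params = replicate(N, affine_params(), simplify = FALSE),
    mean_image = matrix(0, dims[1], dims[2]),
    count = matrix(0L, dims[1], dims[2]),
    cost_trace = numeric(0),
    iteration = 0L,
    converged = FALSE,
    n_solves = 0L,
    log = character(0),
    drift_correction = cfg$drift_correction,
    cond_max = cfg$cond_max,
    damping = cfg$damping
  ), class = "congeal_state")
}

#' @export
print.congeal_state <- function(x, ...) {
  cat(sprintf("congeal state: %d images, iteration %d, %s\n",
              length(x$params), x$iteration,
              if (x$converged) "converged" else "not converged"))
  if (length(x$cost_trace))
    cat(sprintf("  cost: %.6g -> %.6g\n", x$cost_trace[1],
                x$cost_trace[length(x$cost_trace)]))
  if (length(x$log))
    cat("  ", length(x$log), "skipped updates logged\n")
  invisible(x)
}

#' Groupwise alignment by alternating least squares
#'
#' Jointly aligns an ensemble of images by alternating two cheap steps:
#' (1) the mean image is recomputed as the per-pixel average of the
#' currently warped ensemble — the closed-form minimizer of the mean
#' misalignment cost for fixed warps — and (2) each image's affine
#' parameters receive one Gauss-Newton update against that mean. The cost
#' per iteration is linear in the number of images.
#'
#' With `cfg$use_sqi`, alignment runs on hard-thresholded Self Quotient
#' Images, which strips smooth photometric distortions and monotone
#' intensity remaps (different MRI contrasts, shading, and much of an
#' occlusion's influence) while preserving geometry, so the recovered warps
#' apply unchanged to the original intensities.
#'
#' Iteration stops at `cfg$kmax` or when the relative decrease of the cost
#' between successive iterations falls to `cfg$emax` (relative to the
#' first iteration's cost).
#'
#' @param stack an [image_stack].
#' @param cfg a [congeal_config].
#' @return a `congeal_state` with elements `params` (final warp per image),
#'   `mean_image` (mean of the working stack — SQIs when `use_sqi`),
#'   `mean_original` (mean of the original intensities under the final
#'   warps), `cost_trace`, `iteration`, `converged`, `n_solves` and `log`.
#' @examples
#' base <- make_base_image("texture", c(48, 48), seed = 1)
#' ens <- make_ensemble(base, N = 4, distortion_spec(sigma2 = 1, seed = 2))
#' st <- congeal(ens$stack, congeal_config(kmax = 30))
#' st$converged
#' @export
congeal <- function(stack, cfg = congeal_config()) {
  if (!inherits(stack, "image_stack")) stop("stack must be an image_stack")
  if (!inherits(cfg, "congeal_config")) stop("cfg must be a congeal_config")
  work <- stack
  lo <- 0; hi <- 1
  if (cfg$rescale) {
    lo <- min(vapply(stack$images, min, numeric(1)))
    hi <- max(vapply(stack$images, max, numeric(1)))
    # preserve the zero point unless negatives force a shift: the quotient
    # image is invariant to pure scaling, but shifting the darkest pixel
    # to exactly zero would manufacture near-zero SQI denominators
    if (lo > 0) lo <- 0
    if (hi > lo)
      work$images <- lapply(stack$images, function(m) (m - lo) / (hi - lo))
    else { lo <- 0; hi <- 1 }
    stack <- work
  }
  if (cfg$use_sqi) {
    prep <- if (cfg$sqi_edge == "magnitude") sqi_edge_map else sqi_preprocess
    work$images <- lapply(work$images, prep, cfg = cfg$sqi)
  }

  state <- new_congeal_state(length(stack$images), dim(stack$images[[1]]), cfg)
  # coarse-to-fine: early stages run on blurred working images, widening
  # the attraction basin before the full-resolution refinement
  if (cfg$coarse_to_fine && cfg$kmax >= 4) {
    sigmas <- c(4, 2, 0)
    budgets <- diff(round(c(0, 0.25, 0.5, 1) * cfg$kmax))
  } else {
    sigmas <- 0
    budgets <- cfg$kmax
  }
  for (s in seq_along(sigmas)) {
    ws <- work
    if (sigmas[s] > 0)
      ws$images <- lapply(work$images, gaussian_smooth, sigma = sigmas[s])
    # damping guards the blurred stages; the full-resolution stage runs
    # the plain pseudo-inverse update
    state$damping <- if (sigmas[s] > 0) cfg$damping else 0
    stage_start <- length(state$cost_trace)
    for (k in seq_len(budgets[s])) {
      state <- congeal_step(state, ws)
      tr <- state$cost_trace
      last <- tr[length(tr)]
      # an essentially zero cost (down to averaging round-off) is converged
      if (last <= 1e-20) { state$converged <- TRUE; break }
      if (length(tr) - stage_start >= 2) {
        rel <- abs(tr[length(tr) - 1] - last) /
          max(tr[stage_start + 1], 1e-12)
        if (rel <= cfg$emax) {
          state$converged <- s == length(sigmas)
          break
        }
      }
    }
    if (state$converged && s < length(sigmas) &&
        state$cost_trace[length(state$cost_trace)] <= 1e-20) break
  }
  # final mean under the final parameters
  mi <- compute_mean_image(work, state$params)
  state$mean_image <- mi$values
  state$count <- mi$count
  state$final_cost <- compute_c0(mi, work, state$params)
  mo <- compute_mean_image(stack, state$params)
  # report the original-intensity mean in the caller's intensity units
  state$mean_original <- lo + (hi - lo) * mo$values
  state$rescale_range <- c(lo, hi)
  state$use_sqi <- cfg$use_sqi
  state
}
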