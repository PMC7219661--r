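# read one raster file as a grayscale matrix in [0, 1]
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext)),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      # Rec. 601 luminance for colour input
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  as.matrix(arr)
}

#' Load an image stack from files or a NIfTI slice series
#'
#' Reads a directory (or explicit vector) of PNG/TIFF files, or extracts
#' one 2-D slice per volume position from a NIfTI file. Colour images are
#' converted to luminance; intensities are rescaled to \[0, 1\] per stack.
#' Mismatched image shapes are an error (no silent resizing).
#'
#' @param input a directory containing PNG/TIFF files, a character vector
#'   of file paths, or a single `.nii`/`.nii.gz` path.
#' @param nifti_axis axis (1, 2 or 3) along which to slice a NIfTI volume.
#' @param nifti_slices integer vector of slice indices (1-based) to
#'   extract; for a 4-D volume, the given slice of the given axis is taken
#'   from every volume instead and `nifti_slices` must have length 1.
#' @return an [image_stack].
#' @export
load_stack <- function(input, nifti_axis = 3, nifti_slices = NULL) {
  if (length(input) == 1L && dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop("directory '", input, "' holds fewer than 2 PNG/TIFF images")
    input <- files
  }
  if (length(input) == 1L && grepl("\\.nii(\\.gz)?$", input)) {
    vol <- RNifti::readNifti(input)
    pd <- RNifti::pixdim(vol)
    if (length(pd) >= 2 && is.finite(pd[1]) && is.finite(pd[2]) &&
        abs(pd[1] - pd[2]) > 1e-6 * max(pd[1:2]))
      warning("anisotropic in-plane voxel spacing (",
              pd[1], " x ", pd[2], "); the affine model ignores spacing")
    arr <- as.array(vol)
    nd <- length(dim(arr))
    if (nd == 4L) {
      if (is.null(nifti_slices) || length(nifti_slices) != 1L)
        stop("a 4-D NIfTI needs exactly one slice index; one slice is taken per volume")
      imgs <- lapply(seq_len(dim(arr)[4]), function(t4) {
        v <- arr[, , , t4]
        slice_axis(v, nifti_axis, nifti_slices)
      })
    } else if (nd == 3L) {
      if (is.null(nifti_slices))
        stop("choose NIfTI slice indices (>= 2) to form a stack")
      imgs <- lapply(nifti_slices, function(s) slice_axis(arr, nifti_axis, s))
    } else stop("NIfTI volume must be 3-D or 4-D")
    names <- sprintf("slice%03d", seq_along(imgs))
  } else {
    missing <- input[!file.exists(input)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    imgs <- lapply(input, read_gray)
    names <- basename(input)
  }
  lo <- min(vapply(imgs, min, numeric(1)))
  hi <- max(vapply(imgs, max, numeric(1)))
  if (hi > lo) imgs <- lapply(imgs, function(m) (m - lo) / (hi - lo))
  image_stack(imgs, names)
}

slice_axis <- function(arr, axis, s) {
  d <- dim(arr)
  if (axis < 1 || axis > 3) stop("nifti_axis must be 1, 2 or 3")
  if (s < 1 || s > d[axis]) stop("slice ", s, " outside axis extent ", d[axis])
  switch(axis, arr[s, , ], arr[, s, ], arr[, , s])
}

#' Write alignment results to a directory
#'
#' Writes the aligned original-intensity images as 16-bit TIFFs (lossless
#' to about 1.5e-5), the mean image before and after alignment as PNG
#' (plus the SQI mean when SQI was used), the final parameters as JSON,
#' per-image metrics as JSON and CSV, and the per-iteration cost trace as
#' CSV.
#'
#' @param state a `congeal_state` from [congeal()].
#' @param stack the [image_stack] that was aligned.
#' @param report a `metrics_report` from [ensemble_metrics()], or `NULL`.
#' @param outdir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
save_results <- function(state, stack, report = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit_png <- function(m, name) {
    rng <- range(m)
    m01 <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
    f <- file.path(outdir, name)
    png::writePNG(m01, f, dpi = NULL)
    written <<- c(written, f)
  }
  for (n in seq_along(stack$images)) {
    w <- warp_image(stack$images[[n]], state$params[[n]])
    f <- file.path(outdir, sprintf("aligned_%03d.tif", n))
    tiff::writeTIFF(pmin(pmax(w$values, 0), 1), f, bits.per.sample = 16L)
    written <- c(written, f)
  }
  mean_before <- Reduce(`+`, stack$images) / length(stack$images)
  emit_png(mean_before, "mean_before.png")
  emit_png(if (!is.null(state$mean_original)) state$mean_original
           else state$mean_image, "mean_after.png")
  if (isTRUE(state$use_sqi)) emit_png(state$mean_image, "mean_sqi.png")

  f <- file.path(outdir, "params.json")
  jsonlite::write_json(
    lapply(state$params, function(p) as.numeric(p)), f, digits = NA)
  written <- c(written, f)

  f <- file.path(outdir, "cost_trace.csv")
  utils::write.csv(data.frame(iteration = seq_along(state$cost_trace),
                              c0 = state$cost_trace), f, row.names = FALSE)
  written <- c(written, f)

  if (!is.null(report)) {
    f <- file.path(outdir, "metrics.json")
    jsonlite::write_json(list(mpsnr = report$mpsnr, mssim = report$mssim),
                         f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
    f <- file.path(outdir, "metrics.csv")
    utils::write.csv(data.frame(image = stack$names,
                                psnr = report$psnr_per_image,
                                ssim = report$ssim_per_image),
                     f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Reload warp parameters written by [save_results()]
#'
#' @param path the `params.json` file.
#' @return list of [affine_params].
#' @export
load_params <- function(path) {
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.matrix(res)) res <- lapply(seq_len(nrow(res)), function(i) res[i, ])
  lapply(res, affine_params)
}
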