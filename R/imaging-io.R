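#' Calibrated image stack
#'
#' A 3D intensity volume with physical calibration. Voxels are stored as a
#' numeric array indexed `[slice, row, col]` with values in `[0, 1]`.
#' Conventions used throughout the package: slice indices are 0-based in all
#' coordinate arithmetic, pixel boxes are half-open `[x, x+w) x [y, y+h)`
#' with `x` along columns and `y` along rows, and micrometre positions are
#' `pixel * pixel_size_um` laterally and `slice * z_step_um` axially, with
#' +z pointing up (increasing slice index).
#'
#' @param voxels numeric 3D array `[slice, row, col]`.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um spacing between consecutive slices in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um = 1) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("voxels must be a 3D array [slice, row, col]")
  if (any(dim(voxels) < 1L)) stopf("all stack dimensions must be >= 1")
  if (!is_number(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a positive number")
  if (!is_number(z_step_um) || z_step_um <= 0)
    stopf("z_step_um must be a positive number")
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d slices x %d x %d px, %.4g um/px, %.4g um z-step\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[1]

#' Lateral pixel size from field of view
#'
#' @param fov_um numeric length-2, field of view `(fx, fy)` in micrometres.
#' @param shape_px integer length-2, image shape `(nx, ny)` in pixels.
#' @return Numeric length-2: micrometres per pixel along x and y.
#' @examples
#' um_per_pixel(c(160.08, 119.6), c(1392, 1040))  # ~0.115 in both axes
#' @export
um_per_pixel <- function(fov_um, shape_px) {
  if (length(fov_um) != 2L || length(shape_px) != 2L)
    stopf("fov_um and shape_px must have length 2")
  if (any(fov_um <= 0) || any(shape_px <= 0))
    stopf("fov_um and shape_px must be positive")
  as.numeric(fov_um) / as.numeric(shape_px)
}

#' Write an image stack as a multi-page TIFF
#'
#' Voxels are quantized to 16-bit; calibration metadata is stored in a JSON
#' sidecar file (`<path>.meta.json`) so the round trip preserves it.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- clamp(stack$voxels, 0, 1)
  pages <- lapply(seq_len(n_slices(stack)), function(i) v[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(schema_version = "1.0",
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' If the calibration sidecar is missing, defaults (0.115 um/px, 1 um z-step)
#' are applied and a warning is raised.
#'
#' @param path TIFF path written by [write_stack()] or any uniform multi-page
#'   TIFF.
#' @return An [image_stack].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    p
  })
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stopf("non-uniform slice shapes in %s", path)
  vox <- array(0, dim = c(length(pages), shp[1, 1], shp[2, 1]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    px <- meta$pixel_size_um; zs <- meta$z_step_um
  } else {
    warnf("missing calibration sidecar for %s; applying defaults (0.115 um/px, 1 um z-step)",
          path)
    px <- 0.115; zs <- 1
  }
  image_stack(vox, pixel_size_um = px, z_step_um = zs)
}

#' Background illumination correction
#'
#' Divides each slice by a heavily smoothed estimate of its background and
#' renormalizes so the slice mean intensity is preserved. The smoothing scale
#' should be much larger than any cell soma but smaller than the vignetting
#' scale.
#'
#' @param stack an [image_stack].
#' @param sigma_px Gaussian blur standard deviation for the background
#'   estimate, in pixels (default 50).
#' @param n_iter correction passes (default 2; the second pass removes most
#'   of the border bias the padded blur leaves on strong gradients).
#' @return The corrected [image_stack].
#' @export
flatfield_correct <- function(stack, sigma_px = 50, n_iter = 2) {
  stopifnot(inherits(stack, "image_stack"))
  out <- stack$voxels
  for (i in seq_len(n_slices(stack))) {
    sl <- stack$voxels[i, , ]
    if (all(sl == 0)) stopf("slice %d is constant zero; cannot flatfield", i - 1)
    corr <- sl
    for (k in seq_len(n_iter)) {
      bg <- gauss_blur2d(corr, sigma_px)
      corr <- corr / pmax(bg, .Machine$double.eps)
    }
    out[i, , ] <- corr * (mean(sl) / mean(corr))
  }
  image_stack(out, stack$pixel_size_um, stack$z_step_um)
}

#' Scored bounding boxes
#'
#' Constructs a validated data frame of per-slice detection/annotation boxes.
#' `slice` is 0-based; boxes are half-open `[x, x+w) x [y, y+h)` in pixels
#' with the origin at the image top-left.
#'
#' @param slice,x,y,w,h box coordinates (recycled to a common length).
#' @param confidence detection confidence in `[0, 1]` (default 1).
#' @param label class label (default "cell").
#' @return A `scored_boxes` data frame.
#' @export
scored_boxes <- function(slice = integer(), x = numeric(), y = numeric(),
                         w = numeric(), h = numeric(), confidence = 1,
                         label = "cell") {
  n <- length(slice)
  df <- data.frame(slice = as.integer(slice), x = as.numeric(x),
                   y = as.numeric(y), w = as.numeric(w), h = as.numeric(h),
                   confidence = rep_len(as.numeric(confidence), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$w <= 0) || any(df$h <= 0)) stopf("box w and h must be > 0")
    if (any(df$slice < 0)) stopf("slice indices must be >= 0")
    if (any(df$confidence < 0 | df$confidence > 1))
      stopf("confidence must lie in [0, 1]")
  }
  class(df) <- c("scored_boxes", "data.frame")
  df
}

#' Write bounding-box annotations/detections as JSON
#'
#' @param boxes a [scored_boxes] data frame.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path) {
  payload <- list(schema_version = "1.0",
                  boxes = lapply(seq_len(nrow(boxes)), function(i)
                    as.list(boxes[i, , drop = FALSE])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read bounding-box annotations/detections from JSON
#'
#' Malformed records are reported with their 1-based record index.
#'
#' @param path JSON path written by [write_annotations()].
#' @return A [scored_boxes] data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- payload$boxes %||% list()
  need <- c("slice", "x", "y", "w", "h")
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (!all(need %in% names(r)))
      stopf("annotation record %d is missing fields: %s", i,
            paste(setdiff(need, names(r)), collapse = ", "))
    rows[[i]] <- data.frame(slice = as.integer(r$slice), x = as.numeric(r$x),
                            y = as.numeric(r$y), w = as.numeric(r$w),
                            h = as.numeric(r$h),
                            confidence = as.numeric(r$confidence %||% 1),
                            label = as.character(r$label %||% "cell"),
                            stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(df)) return(scored_boxes())
  scored_boxes(df$slice, df$x, df$y, df$w, df$h, df$confidence, df$label)
}

#' Expand centre-slice annotations to a fixed slice depth
#'
#' Annotation practice for 3D stacks places a 2D box on the centre slice of
#' each soma and copies it to the two slices above and below, giving a
#' five-slice-deep 3D annotation. Copies falling outside the stack are
#' clipped.
#'
#' @param boxes a [scored_boxes] data frame of centre-slice boxes.
#' @param n_slices number of slices in the stack (for clipping).
#' @param depth total slice depth of the expanded annotation (odd, default 5).
#' @return A [scored_boxes] data frame with one row per (box, slice) copy.
#' @export
expand_annotation_depth <- function(boxes, n_slices, depth = 5) {
  if (depth %% 2 != 1) stopf("depth must be odd")
  half <- (depth - 1) %/% 2
  out <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, , drop = FALSE]
    slices <- (b$slice - half):(b$slice + half)
    slices <- slices[slices >= 0 & slices < n_slices]
    data.frame(slice = slices, x = b$x, y = b$y, w = b$w, h = b$h,
               confidence = b$confidence, label = b$label,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  scored_boxes(df$slice, df$x, df$y, df$w, df$h, df$confidence, df$label)
}
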