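# Per-slice cell detection (pluggable detector interface with a classical
# phantom detector) and Z-axis merging of 2D boxes into 3D detections.

#' Classical blob detector for phantom slices
#'
#' Returns a detector closure for [detect_cells_2d()]: difference-of-Gaussians
#' bandpass matched to the expected soma radius, local-maximum extraction,
#' confidence = blob response normalized to the strongest blob in the image.
#' Intended as the built-in reference detector for synthetic phantoms; a
#' trained network can be plugged in through the same interface.
#'
#' @param pixel_size_um lateral pixel size of the images it will see.
#' @param radius_um nominal soma radius (um, default 5).
#' @param min_response absolute bandpass response floor (default 0.02).
#' @return A function `image_matrix -> data.frame(x, y, w, h, confidence)`.
#' @export
phantom_cell_detector <- function(pixel_size_um, radius_um = 5,
                                  min_response = 0.02) {
  force(pixel_size_um); force(radius_um); force(min_response)
  function(img) {
    r_px <- radius_um / pixel_size_um
    s1 <- max(1, r_px / 2)
    band <- gauss_blur2d(img, s1) - gauss_blur2d(img, 2 * s1)
    rad <- max(2L, as.integer(round(r_px / 2)))
    # local maxima of the bandpass response
    loc <- band
    nr <- nrow(band); nc <- ncol(band)
    is_max <- matrix(TRUE, nr, nc)
    for (dr in -rad:rad) for (dc in -rad:rad) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(-Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[rs - dr, cs - dc] <- loc[rs, cs]
      is_max <- is_max & (loc >= shifted)
    }
    thr <- max(min_response, 3.5 * stats::mad(band))
    peaks <- which(is_max & band > thr, arr.ind = TRUE)
    if (!nrow(peaks))
      return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                        h = numeric(), confidence = numeric()))
    resp <- band[peaks]
    side <- 2 * r_px
    conf <- clamp(resp / max(resp), 0, 1)
    # refine each peak to the response-weighted centroid of its
    # neighbourhood, which re-centres boxes on the soma envelope even when
    # internal texture displaces the raw maximum
    cx <- numeric(nrow(peaks)); cy <- numeric(nrow(peaks))
    wrad <- rad
    for (k in seq_len(nrow(peaks))) {
      rr <- clamp(peaks[k, 1] + (-wrad:wrad), 1, nr)
      cc <- clamp(peaks[k, 2] + (-wrad:wrad), 1, nc)
      win <- pmax(band[unique(rr), unique(cc), drop = FALSE], 0)
      rows <- unique(rr); cols <- unique(cc)
      wsum <- sum(win)
      if (wsum > 0) {
        cy[k] <- sum(rowSums(win) * rows) / wsum - 1
        cx[k] <- sum(colSums(win) * cols) / wsum - 1
      } else {
        cy[k] <- peaks[k, 1] - 1; cx[k] <- peaks[k, 2] - 1
      }
    }
    data.frame(x = cx - side / 2, y = cy - side / 2,
               w = side, h = side, confidence = conf)
  }
}

#' Detect cells on a single image
#'
#' Applies a detector conforming to the single-image contract
#' (`image_matrix -> data.frame(x, y, w, h, confidence)`); detector errors
#' surface as an empty result plus a warning.
#'
#' @param image numeric matrix (one slice).
#' @param detector detector closure, e.g. [phantom_cell_detector()].
#' @param slice 0-based slice index recorded on the boxes.
#' @return A [scored_boxes] data frame.
#' @export
detect_cells_2d <- function(image, detector, slice = 0L) {
  res <- tryCatch(detector(image), error = function(e) {
    warnf("cell detector failed on slice %d: %s", slice, conditionMessage(e))
    NULL
  })
  if (is.null(res) || !nrow(res)) return(scored_boxes())
  scored_boxes(slice = rep(slice, nrow(res)), x = res$x, y = res$y,
               w = res$w, h = res$h, confidence = res$confidence)
}

#' Detect cells on every slice of a stack
#'
#' @param stack an [image_stack].
#' @param detector detector closure (default: [phantom_cell_detector()] at
#'   the stack's calibration).
#' @return A [scored_boxes] data frame over all slices.
#' @export
detect_cells_stack <- function(stack,
                               detector = phantom_cell_detector(stack$pixel_size_um)) {
  out <- lapply(seq_len(n_slices(stack)) - 1L, function(i)
    detect_cells_2d(stack$voxels[i + 1, , ], detector, slice = i))
  do.call(rbind, c(out, list(scored_boxes())))
}

box_rect <- function(b) c(b$x, b$y, b$x + b$w, b$y + b$h)

rect_intersect <- function(a, b) {
  r <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  if (r[3] <= r[1] || r[4] <= r[2]) NULL else r
}

rect_area <- function(r) (r[3] - r[1]) * (r[4] - r[2])

#' Merge per-slice boxes into 3D detections along Z
#'
#' Boxes are processed in ascending slice order (canonically sorted within a
#' slice, so the result is invariant to input permutation). A box joins an
#' open detection when its slice is 1--`max_gap_slices` above the
#' detection's last member slice (so up to two empty slices may intervene)
#' and its intersection with the detection's running intersection region is
#' at least `min_ratio` of the smaller of the two areas. On joining, the
#' running region is replaced by the intersection unless that would fall
#' below `min_region_px2`. Every input box ends up in exactly one
#' detection.
#'
#' @param boxes a [scored_boxes] data frame.
#' @param pixel_size_um,z_step_um calibration used to report centroids in
#'   micrometres.
#' @param min_ratio intersection / smaller-area threshold (default 0.6).
#' @param max_gap_slices largest member-slice difference that can still
#'   unite (default 3).
#' @param min_region_px2 floor on the running intersection area (default 4).
#' @return A data frame of class `detections3d` with columns `x_um, y_um,
#'   z_um` (confidence-weighted centroid), `confidence` (max member
#'   confidence), `depth_slices` (member slice span) and a list column
#'   `members` of row indices into the canonically sorted input (attached
#'   as attribute `boxes`).
#' @export
merge_boxes_3d <- function(boxes, pixel_size_um, z_step_um = 1,
                           min_ratio = 0.6, max_gap_slices = 3,
                           min_region_px2 = 4) {
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      confidence = numeric(), depth_slices = integer())
  if (!nrow(boxes)) {
    empty$members <- I(list())
    class(empty) <- c("detections3d", "data.frame")
    attr(empty, "boxes") <- boxes
    return(empty)
  }
  ord <- order(boxes$slice, boxes$y, boxes$x, boxes$w, boxes$h,
               boxes$confidence)
  bx <- boxes[ord, , drop = FALSE]
  rownames(bx) <- NULL
  groups <- list()   # each: list(region, last_slice, members)
  for (i in seq_len(nrow(bx))) {
    b <- bx[i, ]
    rb <- box_rect(b)
    best <- 0; best_ratio <- -1
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      gap <- b$slice - g$last_slice
      if (gap < 1 || gap > max_gap_slices) next
      inter <- rect_intersect(g$region, rb)
      if (is.null(inter)) next
      ratio <- rect_area(inter) / min(rect_area(g$region), rect_area(rb))
      if (ratio >= min_ratio && ratio > best_ratio) {
        best <- gi; best_ratio <- ratio
      }
    }
    if (best > 0) {
      g <- groups[[best]]
      inter <- rect_intersect(g$region, rb)
      if (rect_area(inter) >= min_region_px2) g$region <- inter
      g$last_slice <- b$slice
      g$members <- c(g$members, i)
      groups[[best]] <- g
    } else {
      groups[[length(groups) + 1]] <- list(region = rb, last_slice = b$slice,
                                           members = i)
    }
  }
  rows <- lapply(groups, function(g) {
    m <- bx[g$members, , drop = FALSE]
    wsum <- sum(m$confidence)
    wts <- if (wsum > 0) m$confidence / wsum else rep(1 / nrow(m), nrow(m))
    data.frame(x_um = sum(wts * (m$x + m$w / 2)) * pixel_size_um,
               y_um = sum(wts * (m$y + m$h / 2)) * pixel_size_um,
               z_um = sum(wts * m$slice) * z_step_um,
               confidence = max(m$confidence),
               depth_slices = max(m$slice) - min(m$slice) + 1L)
  })
  out <- do.call(rbind, rows)
  out$members <- I(lapply(groups, `[[`, "members"))
  class(out) <- c("detections3d", "data.frame")
  attr(out, "boxes") <- bx
  out
}

#' Order 3D detections for patching
#'
#' Descending confidence so that the strongest (healthiest-looking) cells
#' are offered first; exact ties break deterministically on the spatial
#' centroid `(z, y, x)`.
#'
#' @param dets a `detections3d` data frame from [merge_boxes_3d()].
#' @return The reordered data frame.
#' @export
rank_detections <- function(dets) {
  if (!nrow(dets)) return(dets)
  ord <- order(-dets$confidence, dets$z_um, dets$y_um, dets$x_um)
  out <- dets[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
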