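# 3D tracking of the target cell during the pipette approach: lateral drift
# by a pyramidal Lucas-Kanade (KLT) feature tracker, axial drift by a
# focus metric (standard deviation of difference images against the
# pre-patch template). No installed R package provides sparse optical flow,
# so the tracker core is implemented here on EBImage filtering primitives.

grad_x <- function(img) {
  nc <- ncol(img)
  (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
}

grad_y <- function(img) {
  nr <- nrow(img)
  (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
}

#' Select trackable features inside a box
#'
#' Minimum-eigenvalue (Shi-Tomasi) corner selection on the smoothed
#' structure tensor, restricted to the box, with non-maximum suppression.
#'
#' @param img numeric matrix.
#' @param box list or one-row data frame with `x, y, w, h` (pixels, 0-based
#'   top-left, half-open).
#' @param max_features at most this many features (default 30).
#' @param min_sep_px minimal feature separation (default 5).
#' @return n x 2 matrix of 0-based `(x, y)` feature positions.
#' @export
select_features <- function(img, box, max_features = 30, min_sep_px = 5) {
  ix <- grad_x(img); iy <- grad_y(img)
  sxx <- gauss_blur2d(ix * ix, 2)
  syy <- gauss_blur2d(iy * iy, 2)
  sxy <- gauss_blur2d(ix * iy, 2)
  tr <- sxx + syy
  dt <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  lmin <- (tr - dt) / 2
  r0 <- clamp(floor(box$y), 0, nrow(img) - 1)
  r1 <- clamp(ceiling(box$y + box$h) - 1, 0, nrow(img) - 1)
  c0 <- clamp(floor(box$x), 0, ncol(img) - 1)
  c1 <- clamp(ceiling(box$x + box$w) - 1, 0, ncol(img) - 1)
  sub <- lmin[(r0:r1) + 1, (c0:c1) + 1, drop = FALSE]
  ord <- order(sub, decreasing = TRUE)
  pts <- matrix(numeric(), 0, 2)
  for (k in ord) {
    if (nrow(pts) >= max_features) break
    rr <- (k - 1) %% nrow(sub); cc <- (k - 1) %/% nrow(sub)
    p <- c(c0 + cc, r0 + rr)
    if (sub[rr + 1, cc + 1] <= 0) break
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(p, nrow(pts), 2, byrow = TRUE))^2))) >=
          min_sep_px)
      pts <- rbind(pts, p)
  }
  colnames(pts) <- c("x", "y")
  pts
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1)) {
    sm <- gauss_blur2d(pyr[[l]], 1)
    pyr[[l + 1]] <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2),
                       drop = FALSE]
  }
  pyr
}

# iterative LK refinement of one feature displacement at one pyramid level
lk_refine <- function(tmpl, frame, pt, d0, half_win = 7, max_iter = 30) {
  off <- -half_win:half_win
  gx <- outer(rep(1, length(off)), off)   # window col offsets
  gy <- outer(off, rep(1, length(off)))   # window row offsets
  wr <- pt[2] + gy; wc <- pt[1] + gx
  tw <- bilinear_sample(tmpl, wr, wc)
  tx <- bilinear_sample(tmpl, wr, wc + 0.5) - bilinear_sample(tmpl, wr, wc - 0.5)
  ty <- bilinear_sample(tmpl, wr + 0.5, wc) - bilinear_sample(tmpl, wr - 0.5, wc)
  G <- matrix(c(sum(tx * tx), sum(tx * ty), sum(tx * ty), sum(ty * ty)), 2, 2)
  if (abs(det(G)) < 1e-12) return(NULL)
  d <- d0
  for (it in seq_len(max_iter)) {
    iw <- bilinear_sample(frame, wr + d[2], wc + d[1])
    e <- tw - iw
    b <- c(sum(tx * e), sum(ty * e))
    delta <- solve(G, b)
    d <- d + delta
    if (sqrt(sum(delta^2)) < 0.005) break
  }
  resid <- sqrt(mean((tw - bilinear_sample(frame, wr + d[2], wc + d[1]))^2))
  list(d = d, resid = resid, scale = stats::sd(as.numeric(tw)))
}

#' Track features between two frames with pyramidal Lucas-Kanade
#'
#' @param tmpl template frame (matrix).
#' @param frame current frame (matrix), same size.
#' @param pts n x 2 matrix of 0-based `(x, y)` positions in the template.
#' @param levels pyramid levels (default 3).
#' @param half_win half window size; window is `2*half_win+1` px (default 7,
#'   i.e. a 15 px window).
#' @return A list with `d` (n x 2 displacements, NA for lost features) and
#'   `lost` (logical vector).
#' @export
klt_track <- function(tmpl, frame, pts, levels = 3, half_win = 7) {
  pyr_t <- build_pyramid(tmpl, levels)
  pyr_f <- build_pyramid(frame, levels)
  n <- nrow(pts)
  d_out <- matrix(NA_real_, n, 2)
  lost <- rep(TRUE, n)
  for (i in seq_len(n)) {
    d <- c(0, 0)
    ok <- TRUE
    for (l in levels:1) {
      sc <- 2^(l - 1)
      res <- lk_refine(pyr_t[[l]], pyr_f[[l]], pts[i, ] / sc, d / sc,
                       half_win = half_win)
      if (is.null(res)) { ok <- FALSE; break }
      d <- res$d * sc
      if (l == 1 && (res$resid > max(0.5 * res$scale, 0.05) ||
                     sqrt(sum(d^2)) > 50))
        ok <- FALSE
    }
    if (ok) { d_out[i, ] <- d; lost[i] <- FALSE }
  }
  list(d = d_out, lost = lost)
}

#' Initialize a cell-tracking state
#'
#' Captures the template (the full reference frame plus the target box) at
#' optimal focus before the patch attempt starts, and selects KLT features
#' inside the box.
#'
#' @param frame template frame (matrix) at the cell's focal plane.
#' @param box list/one-row data frame with `x, y, w, h` in pixels.
#' @param pixel_size_um,z_step_um calibration for converting displacements
#'   to micrometres.
#' @return A `track_state` list.
#' @export
track_init <- function(frame, box, pixel_size_um, z_step_um = 1) {
  feats <- select_features(frame, box)
  if (nrow(feats) < 4)
    stopf("tracking initialization failure: fewer than 4 trackable features")
  structure(list(template = frame, box = box, features = feats,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 offset_um = c(0, 0, 0)),
            class = "track_state")
}

#' Lateral drift of the target cell
#'
#' Pyramidal KLT displacement of the template features into `frame`;
#' the reported displacement is the median over surviving (inlier)
#' features, converted to micrometres. When more than half the features
#' are lost they are refreshed from the template box.
#'
#' @param state a `track_state`.
#' @param frame current frame at the most recent focal level.
#' @return A list with `dx_um`, `dy_um`, `dx_px`, `dy_px`, `n_tracked` and
#'   the (possibly refreshed) `state`.
#' @export
track_lateral <- function(state, frame) {
  stopifnot(inherits(state, "track_state"))
  res <- klt_track(state$template, frame, state$features)
  if (all(res$lost))
    stopf("tracking lost: no feature could be followed")
  if (mean(res$lost) > 0.5) {
    feats <- select_features(state$template, state$box)
    if (nrow(feats) >= 4) {
      state$features <- feats
      res <- klt_track(state$template, frame, state$features)
      if (all(res$lost)) stopf("tracking lost: no feature could be followed")
    }
  }
  d <- res$d[!res$lost, , drop = FALSE]
  med <- apply(d, 2, median)
  # inliers: within 1 px of the median displacement
  inl <- sqrt(rowSums((d - matrix(med, nrow(d), 2, byrow = TRUE))^2)) <= 1
  if (any(inl)) med <- apply(d[inl, , drop = FALSE], 2, median)
  list(dx_um = med[1] * state$pixel_size_um,
       dy_um = med[2] * state$pixel_size_um,
       dx_px = med[1], dy_px = med[2],
       n_tracked = sum(!res$lost), state = state)
}

#' Axial drift of the target cell from a mini-stack
#'
#' For each slice of an odd-depth mini-stack centred on the most recent
#' focus position, computes the standard deviation of the difference
#' against the template over the target box; the slice with the lowest
#' value marks the cell's current focal plane. Sign convention: positive
#' means the cell moved up (toward higher slice indices / +z).
#'
#' @param state a `track_state`.
#' @param mini_stack an [image_stack] with an odd number of slices whose
#'   middle slice corresponds to the assumed focus position.
#' @return A list with `dz_um` and `profile` (per-slice focus metric).
#' @export
track_z <- function(state, mini_stack) {
  stopifnot(inherits(state, "track_state"),
            inherits(mini_stack, "image_stack"))
  nz <- n_slices(mini_stack)
  if (nz %% 2 != 1) stopf("mini-stack must have an odd number of slices")
  b <- state$box
  r0 <- clamp(floor(b$y), 0, nrow(state$template) - 1)
  r1 <- clamp(ceiling(b$y + b$h) - 1, 0, nrow(state$template) - 1)
  c0 <- clamp(floor(b$x), 0, ncol(state$template) - 1)
  c1 <- clamp(ceiling(b$x + b$w) - 1, 0, ncol(state$template) - 1)
  tpatch <- state$template[(r0:r1) + 1, (c0:c1) + 1]
  prof <- vapply(seq_len(nz), function(i)
    stats::sd(mini_stack$voxels[i, (r0:r1) + 1, (c0:c1) + 1] - tpatch),
    numeric(1))
  centre <- (nz + 1) %/% 2
  best <- which.min(prof)
  list(dz_um = (best - centre) * mini_stack$z_step_um, profile = prof)
}

#' Accumulate a tracked displacement into the target offset
#'
#' Tracking queries run only while the pipette is halted; the accumulated
#' offset corrects the planner's target position.
#'
#' @param state a `track_state`.
#' @param dxyz_um length-3 displacement (um) from [track_lateral()] /
#'   [track_z()].
#' @return The updated `track_state`.
#' @export
update_target <- function(state, dxyz_um) {
  stopifnot(inherits(state, "track_state"), length(dxyz_um) == 3)
  state$offset_um <- state$offset_um + as.numeric(dxyz_um)
  state
}

#' Corrected target position
#'
#' @param state a `track_state`.
#' @param target_um original target position (um, stage frame).
#' @return `target_um + accumulated offset`.
#' @export
tracked_target <- function(state, target_um) {
  as.numeric(target_um) + state$offset_um
}
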