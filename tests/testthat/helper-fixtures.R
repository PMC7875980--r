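# Shared fixtures: all built in code at test time.

# one-row ground-truth cell for rig scenarios
make_cell <- function(x, y, z, r = 3.5, sealable = TRUE, seal_rate = 1,
                      rupture = 250, access = 28, drift = NULL) {
  df <- data.frame(x_um = x, y_um = y, z_um = z, radius_um = r,
                   sealable = sealable, seal_rate = seal_rate,
                   rupture_threshold = rupture,
                   access_resistance_Mohm = access)
  if (!is.null(drift)) {
    df$drift_x_um_s <- drift[1]; df$drift_y_um_s <- drift[2]
    df$drift_z_um_s <- drift[3]
  }
  df
}

# smooth in-focus frame of Gaussian somata (no internal texture): the
# reference fixture for the 2D blob detector
make_soma_frame <- function(cells, n = 192, px = 0.3, contrast = 0.25,
                            noise = 0.005, seed = 1) {
  set.seed(seed)
  img <- matrix(0.5, n, n) + matrix(rnorm(n * n, sd = noise), n, n)
  xg <- matrix((seq_len(n) - 1) * px, n, n, byrow = TRUE)
  yg <- matrix((seq_len(n) - 1) * px, n, n)
  for (i in seq_len(nrow(cells))) {
    s <- cells$radius_um[i] / 2
    img <- img + contrast *
      exp(-((xg - cells$x_um[i])^2 + (yg - cells$y_um[i])^2) / (2 * s^2))
  }
  img
}

# random non-overlapping XY positions
scatter_cells <- function(n, lo = 8, hi = 50, min_sep = 12, seed = 11) {
  set.seed(seed)
  cells <- data.frame(x_um = numeric(), y_um = numeric(),
                      radius_um = numeric())
  while (nrow(cells) < n) {
    cand <- runif(2, lo, hi)
    if (!nrow(cells) ||
        min(sqrt((cells$x_um - cand[1])^2 + (cells$y_um - cand[2])^2)) > min_sep)
      cells <- rbind(cells, data.frame(x_um = cand[1], y_um = cand[2],
                                       radius_um = runif(1, 4, 6)))
  }
  cells
}

# stage position of the hunting line start for a straight approach from
# `tip` to `target` (after lateral pre-positioning), used to place
# obstacles exactly on the path
hunt_line_start <- function(tip, target, cfg = patch_config(),
                            A = default_calibration_matrix()) {
  staging <- target + c(0, 0, cfg$above_cell_offset_um)
  dp <- solve(A, staging - tip)
  tip + as.numeric(A %*% c(0, dp[2], dp[3]))
}

# exhaustive optimal-assignment oracle: maximum number of one-to-one
# (det, gt) pairs satisfying both tolerances; recursion over detections
oracle_max_matching <- function(dets, gts, lateral_tol = 5, z_tol = 3) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0L)
  ok <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    lat <- sqrt((dets$x_um[i] - gts$x_um[j])^2 + (dets$y_um[i] - gts$y_um[j])^2)
    ok[i, j] <- lat <= lateral_tol && abs(dets$z_um[i] - gts$z_um[j]) <= z_tol
  }
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    for (j in seq_len(ng)) if (ok[i, j] && !used[j]) {
      u <- used; u[j] <- TRUE
      rec(i + 1, u, count + 1L)
    }
    rec(i + 1, used, count)
  }
  rec(1L, rep(FALSE, ng), 0L)
  best
}

# first simulation times of each phase in a record, in appearance order
phase_sequence <- function(rec) {
  ph <- rec$phase_log$phase
  ph[!duplicated(ph)]
}
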