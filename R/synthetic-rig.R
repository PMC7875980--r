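# Synthetic DIC-like phantoms and a simulated electrophysiology rig.
# Everything downstream (detection, tracking, the autopatching controller)
# is exercised against these stand-ins, so generation is fully seeded and
# bit-reproducible.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic cell phantom stack
#'
#' Defaults emulate a DIC z-stack of a neocortical slice at 40x: somata of
#' 4--7 um radius, modest contrast against a textured background, 1 um slice
#' spacing. Stack extent defaults to 60 slices of 256 x 256 px at
#' 0.23 um/px (a ~59 um field) to keep generation desk-scale.
#'
#' @param stack_shape integer length-3 `(n_slices, n_rows, n_cols)`.
#' @param pixel_size_um lateral pixel size (um).
#' @param z_step_um slice spacing (um), default 1.
#' @param n_cells number of somata to place.
#' @param cell_radius_um length-2 range of soma radii (um).
#' @param cell_contrast peak soma intensity above background, in `[0, 1]`.
#' @param background_texture_scale Gaussian blur sigma (px) of the background
#'   texture.
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param sealable_fraction probability that a generated cell is sealable
#'   (forms a gigaseal under suction).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(stack_shape = c(60, 256, 256), pixel_size_um = 0.23,
                         z_step_um = 1, n_cells = 5,
                         cell_radius_um = c(4, 7), cell_contrast = 0.25,
                         background_texture_scale = 8, noise_sigma = 0.01,
                         sealable_fraction = 0.6, seed = 1) {
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 1),
            pixel_size_um > 0, z_step_um > 0, n_cells >= 0,
            length(cell_radius_um) == 2, cell_radius_um[1] > 0,
            cell_radius_um[2] >= cell_radius_um[1],
            cell_contrast >= 0, noise_sigma >= 0,
            sealable_fraction >= 0, sealable_fraction <= 1)
  structure(list(stack_shape = as.integer(stack_shape),
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 n_cells = as.integer(n_cells),
                 cell_radius_um = cell_radius_um,
                 cell_contrast = cell_contrast,
                 background_texture_scale = background_texture_scale,
                 noise_sigma = noise_sigma,
                 sealable_fraction = sealable_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Textured background common to cell and pipette phantoms: mid-grey base,
# low-frequency smoothed-noise texture that decorrelates along z like
# defocusing tissue (AR(1) between consecutive slices), optional per-voxel
# noise.
phantom_background <- function(shape, texture_scale, noise_sigma,
                               texture_amp = 0.03, z_corr = 0.85) {
  nz <- shape[1]; nr <- shape[2]; nc <- shape[3]
  # build the texture on a padded field and crop, so blur boundary effects
  # never reach the image
  m <- ceiling(3 * texture_scale)
  vox <- array(0, dim = shape)
  w <- matrix(rnorm((nr + 2 * m) * (nc + 2 * m)), nr + 2 * m, nc + 2 * m)
  for (i in seq_len(nz)) {
    if (i > 1)
      w <- z_corr * w + sqrt(1 - z_corr^2) *
        matrix(rnorm((nr + 2 * m) * (nc + 2 * m)), nr + 2 * m, nc + 2 * m)
    tex <- gauss_blur2d(w, texture_scale)[m + seq_len(nr), m + seq_len(nc)]
    tex <- texture_amp * tex / max(stats::sd(tex), .Machine$double.eps)
    sl <- 0.5 + tex
    if (noise_sigma > 0) sl <- sl + matrix(rnorm(nr * nc, sd = noise_sigma), nr, nc)
    vox[i, , ] <- sl
  }
  vox
}

#' Generate a synthetic cell phantom stack with ground truth
#'
#' Places `n_cells` non-overlapping blurred elliptical somata in a textured
#' background volume. Each soma is brightest and sharpest at its true centre
#' slice; away from it the amplitude decays as a Gaussian of z-distance
#' (sigma 3 um) and the lateral footprint widens, emulating defocus.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `stack` (an [image_stack]) and `cells`
#'   (a data frame of ground-truth cells: `x_um, y_um, z_um, radius_um,
#'   sealable, seal_rate, rupture_threshold, access_resistance_Mohm`).
#' @export
generate_cell_phantom_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$stack_shape
    px <- spec$pixel_size_um; zs <- spec$z_step_um
    vox <- phantom_background(shape, spec$background_texture_scale,
                              spec$noise_sigma)
    cells <- place_cells(spec)
    nz <- shape[1]; nr <- shape[2]; nc <- shape[3]
    if (nrow(cells)) {
      xg <- matrix((seq_len(nc) - 1) * px, nr, nc, byrow = TRUE)
      yg <- matrix((seq_len(nr) - 1) * px, nr, nc)
      for (ci in seq_len(nrow(cells))) {
        cl <- cells[ci, ]
        s0 <- cl$radius_um / 2
        ct <- cos(cl$theta); st <- sin(cl$theta)
        dxg <- xg - cl$x_um; dyg <- yg - cl$y_um
        u <- ct * dxg + st * dyg
        v <- -st * dxg + ct * dyg
        for (i in seq_len(nz)) {
          dz <- (i - 1) * zs - cl$z_um
          amp <- spec$cell_contrast * exp(-dz^2 / (2 * 3^2))
          if (amp < 1e-4) next
          sz <- s0 * sqrt(1 + (dz / 3)^2)
          blob <- amp * exp(-((u / (sz * cl$aspect))^2 + (v / sz)^2) / 2)
          vox[i, , ] <- vox[i, , ] + blob
        }
      }
    }
    vox <- clamp(vox, 0, 1)
    list(stack = image_stack(vox, px, zs),
         cells = cells[, setdiff(names(cells), c("theta", "aspect")),
                       drop = FALSE])
  })
}

# Rejection-sampling placement: pairwise centroid distance must exceed
# 2 * max radius (+1 um margin) and somata stay clear of the XY border.
place_cells <- function(spec) {
  shape <- spec$stack_shape
  fov_x <- (shape[3] - 1) * spec$pixel_size_um
  fov_y <- (shape[2] - 1) * spec$pixel_size_um
  fov_z <- (shape[1] - 1) * spec$z_step_um
  rmax <- spec$cell_radius_um[2]
  min_sep <- 2 * rmax + 1
  margin <- rmax + 1
  if (spec$n_cells > 0 && (2 * margin >= fov_x || 2 * margin >= fov_y))
    stopf("cell placement impossible at requested density (%d cells)",
          spec$n_cells)
  pos <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(pos) < spec$n_cells) {
    tries <- tries + 1
    if (tries > 2000 * max(spec$n_cells, 1))
      stopf("cell placement impossible at requested density (%d cells)",
            spec$n_cells)
    cand <- c(runif(1, margin, fov_x - margin),
              runif(1, margin, fov_y - margin),
              runif(1, min(5, fov_z / 4), fov_z - min(5, fov_z / 4)))
    if (nrow(pos) == 0 ||
        all(sqrt(rowSums((pos - matrix(cand, nrow(pos), 3, byrow = TRUE))^2)) >
            min_sep))
      pos <- rbind(pos, cand)
  }
  n <- spec$n_cells
  data.frame(
    x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
    radius_um = if (n) runif(n, spec$cell_radius_um[1], spec$cell_radius_um[2]) else numeric(),
    theta = if (n) runif(n, 0, pi) else numeric(),
    aspect = if (n) runif(n, 0.8, 1.25) else numeric(),
    sealable = if (n) runif(n) < spec$sealable_fraction else logical(),
    seal_rate = if (n) runif(n, 0.8, 1.2) else numeric(),
    rupture_threshold = if (n) rep(250, n) else numeric(),
    access_resistance_Mohm = if (n) rlnorm(n, log(30), 0.5) else numeric(),
    row.names = NULL)
}

#' Two-cylinder parametric pipette model
#'
#' The pipette silhouette is modelled as two wall cylinders sharing a common
#' reference point (the tip) and an orientation: the body direction is
#' `(cos(tilt)cos(yaw), cos(tilt)sin(yaw), sin(tilt))` and the two wall axes
#' diverge from it by `+/- half_opening` in yaw. Each wall is a Gaussian
#' tube of scale `wall_radius_um`, which also yields defocus fading with
#' z-distance from the wall.
#'
#' @param tip_um tip position (x, y, z) in stage micrometres.
#' @param yaw_rad in-plane angle of the tip-to-body direction.
#' @param tilt_rad elevation of the body direction above the XY plane
#'   (a pipette descending at 33 degrees has its body rising at +33 degrees
#'   from the tip).
#' @param half_opening_rad half-angle between the wall axes, in `(0, pi/4)`.
#' @param wall_radius_um Gaussian scale of each wall tube (um).
#' @return A `pipette_model` list.
#' @export
pipette_model <- function(tip_um, yaw_rad = 0, tilt_rad = 33 * pi / 180,
                          half_opening_rad = 0.30, wall_radius_um = 0.8) {
  stopifnot(length(tip_um) == 3, is.finite(tip_um),
            half_opening_rad > 0, half_opening_rad < pi / 4,
            wall_radius_um > 0)
  structure(list(tip_um = as.numeric(tip_um), yaw_rad = yaw_rad,
                 tilt_rad = tilt_rad, half_opening_rad = half_opening_rad,
                 wall_radius_um = wall_radius_um),
            class = "pipette_model")
}

#' @export
print.pipette_model <- function(x, ...) {
  cat(sprintf("pipette_model: tip (%.2f, %.2f, %.2f) um, yaw %.1f deg, tilt %.1f deg, opening %.1f deg, wall %.2f um\n",
              x$tip_um[1], x$tip_um[2], x$tip_um[3],
              x$yaw_rad * 180 / pi, x$tilt_rad * 180 / pi,
              x$half_opening_rad * 180 / pi, x$wall_radius_um))
  invisible(x)
}

# Unit axis directions of the two wall cylinders (tip -> body).
pipette_wall_dirs <- function(model) {
  mk <- function(yaw) c(cos(model$tilt_rad) * cos(yaw),
                        cos(model$tilt_rad) * sin(yaw),
                        sin(model$tilt_rad))
  list(mk(model$yaw_rad + model$half_opening_rad),
       mk(model$yaw_rad - model$half_opening_rad))
}

#' Render a pipette silhouette into a stack
#'
#' Composites the dark two-walled silhouette of `model` into `stack`:
#' intensity is multiplied by `1 - contrast * darkness` where darkness is
#' maximal on the wall axes and fades as a Gaussian of 3D distance (hence
#' with defocus away from the wall plane).
#'
#' @param stack an [image_stack].
#' @param model a [pipette_model] whose tip lies inside the stack bounds.
#' @param contrast maximal fractional darkening on the walls (default 0.5).
#' @return The composited [image_stack].
#' @export
render_pipette <- function(stack, model, contrast = 0.5) {
  stopifnot(inherits(stack, "image_stack"), inherits(model, "pipette_model"))
  d <- dim(stack$voxels)
  ext <- c((d[3] - 1) * stack$pixel_size_um, (d[2] - 1) * stack$pixel_size_um,
           (d[1] - 1) * stack$z_step_um)
  tip <- model$tip_um
  if (any(tip < 0) || any(tip > ext))
    stopf("pipette tip (%.1f, %.1f, %.1f) um lies outside the stack volume",
          tip[1], tip[2], tip[3])
  if (contrast == 0) return(stack)
  dirs <- pipette_wall_dirs(model)
  sw2 <- 2 * model$wall_radius_um^2
  nr <- d[2]; nc <- d[3]
  xg <- matrix((seq_len(nc) - 1) * stack$pixel_size_um, nr, nc, byrow = TRUE)
  yg <- matrix((seq_len(nr) - 1) * stack$pixel_size_um, nr, nc)
  dxg <- xg - tip[1]; dyg <- yg - tip[2]
  lat2 <- dxg^2 + dyg^2
  vox <- stack$voxels
  for (i in seq_len(d[1])) {
    dz <- (i - 1) * stack$z_step_um - tip[3]
    dark <- 0
    for (dk in dirs) {
      s <- dxg * dk[1] + dyg * dk[2] + dz * dk[3]
      s <- pmax(s, 0)  # beyond the tip there is no glass
      r2 <- pmax(lat2 + dz^2 - s^2, 0)
      dark <- pmax(dark, exp(-r2 / sw2))
    }
    vox[i, , ] <- vox[i, , ] * (1 - contrast * dark)
  }
  image_stack(vox, stack$pixel_size_um, stack$z_step_um)
}

#' Generate a synthetic pipette phantom stack
#'
#' Builds a textured background stack and composites one rendered pipette
#' with a randomized (seeded) tip position and orientation. Geometry
#' defaults to 80 slices of 288 x 288 px at 0.115 um/px with 1 um spacing.
#'
#' @param seed integer seed.
#' @param shape stack shape `(n_slices, n_rows, n_cols)`.
#' @param pixel_size_um lateral pixel size (um).
#' @param z_step_um slice spacing (um).
#' @param noise_sigma additive Gaussian noise s.d. as a fraction of the
#'   dynamic range (default 0: noiseless).
#' @param contrast wall darkening passed to [render_pipette()].
#' @return A list with `stack` (an [image_stack]) and `model` (the
#'   ground-truth [pipette_model]).
#' @export
generate_pipette_phantom <- function(seed = 1, shape = c(80, 288, 288),
                                     pixel_size_um = 0.115, z_step_um = 1,
                                     noise_sigma = 0, contrast = 0.7) {
  with_seed(seed, {
    vox <- phantom_background(shape, texture_scale = 12, noise_sigma = 0)
    stack <- image_stack(vox, pixel_size_um, z_step_um)
    ext <- c((shape[3] - 1) * pixel_size_um, (shape[2] - 1) * pixel_size_um,
             (shape[1] - 1) * z_step_um)
    tip <- c(runif(1, 0.35, 0.65) * ext[1], runif(1, 0.35, 0.65) * ext[2],
             runif(1, 0.35, 0.65) * ext[3])
    yaw <- runif(1, 0, 2 * pi)
    tilt <- (33 + runif(1, -8, 8)) * pi / 180
    model <- pipette_model(tip, yaw_rad = yaw, tilt_rad = tilt,
                           half_opening_rad = runif(1, 0.25, 0.35),
                           wall_radius_um = runif(1, 0.7, 0.9))
    stack <- render_pipette(stack, model, contrast = contrast)
    if (noise_sigma > 0) {
      rng <- diff(range(stack$voxels))
      stack$voxels <- stack$voxels +
        array(rnorm(prod(shape), sd = noise_sigma * rng), dim = shape)
    }
    list(stack = stack, model = model)
  })
}

#' Default rig calibration matrix
#'
#' Maps pipette-axis displacements to stage displacements. The pipette X
#' axis (advance) is tilted -33 degrees from the horizontal plane, so
#' advancing descends; Y and Z map to the stage axes directly.
#'
#' @param tilt_deg tilt of the advance axis below horizontal (negative =
#'   descending), default -33.
#' @param yaw_rad in-plane heading of the advance axis.
#' @return A 3x3 matrix.
#' @export
default_calibration_matrix <- function(tilt_deg = -33, yaw_rad = 0) {
  t <- tilt_deg * pi / 180
  adv <- c(cos(t) * cos(yaw_rad), cos(t) * sin(yaw_rad), sin(t))
  cbind(adv, c(0, 1, 0), c(0, 0, 1), deparse.level = 0)
}

#' Create a simulated electrophysiology rig
#'
#' The rig bundles the hidden pipette/stage calibration, pressure-controller
#' dynamics, an amplifier resistance model, and the ground-truth world
#' (cells and obstacles). The controller interacts with it only through
#' [rig_move_pipette()], [rig_set_pressure()], [rig_set_holding()],
#' [rig_step()] and [rig_read_resistance()].
#'
#' Resistance model: baseline pipette resistance drawn in 3.5--5 MOhm, plus
#' an obstacle bump while the tip is inside an obstacle radius, plus a
#' contact bump while the tip is within contact distance (cell radius +
#' 1 um) of a cell, plus the growing seal resistance. After membrane
#' rupture the measured resistance is baseline + the cell's access
#' resistance.
#'
#' @param cells data frame of ground-truth cells as produced by
#'   [generate_cell_phantom_stack()] (columns `x_um, y_um, z_um, radius_um,
#'   sealable, seal_rate, rupture_threshold, access_resistance_Mohm`;
#'   optional `drift_x_um_s, drift_y_um_s, drift_z_um_s`).
#' @param obstacles data frame with columns `x_um, y_um, z_um, radius_um,
#'   resistance_bump_Mohm` (may be empty/NULL).
#' @param tip_stage_um initial tip position in stage micrometres.
#' @param calibration hidden true 3x3 calibration matrix (default -33 degree
#'   tilt of the advance axis).
#' @param seed integer seed for the baseline resistance draw.
#' @param contact_jump_Mohm resistance jump at cell contact (default 1.0).
#' @param tau_s pressure first-order time constant (default 0.2 s).
#' @param seal_rate_per_s seal growth rate at the reference -20 mbar
#'   (default 0.05 /s, giving a gigaseal in ~14 s for a default cell).
#' @param R_max_Mohm asymptotic seal resistance (default 2000).
#' @param travel_limit_um per-axis manipulator travel limit (default 5000).
#' @return A `patch_rig` list.
#' @export
rig_create <- function(cells = NULL, obstacles = NULL,
                       tip_stage_um = c(0, 0, 0),
                       calibration = default_calibration_matrix(),
                       seed = 1, contact_jump_Mohm = 1.0, tau_s = 0.2,
                       seal_rate_per_s = 0.05, R_max_Mohm = 2000,
                       travel_limit_um = 5000) {
  if (is.null(cells))
    cells <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        radius_um = numeric(), sealable = logical(),
                        seal_rate = numeric(), rupture_threshold = numeric(),
                        access_resistance_Mohm = numeric())
  if (is.null(obstacles))
    obstacles <- data.frame(x_um = numeric(), y_um = numeric(),
                            z_um = numeric(), radius_um = numeric(),
                            resistance_bump_Mohm = numeric())
  baseline <- with_seed(seed, runif(1, 3.5, 5))
  structure(list(
    cells = cells, obstacles = obstacles,
    calibration = calibration,
    baseline_Mohm = baseline,
    contact_jump_Mohm = contact_jump_Mohm,
    tau_s = tau_s, seal_rate_per_s = seal_rate_per_s,
    R_max_Mohm = R_max_Mohm, travel_limit_um = travel_limit_um,
    state = list(tip_stage_um = as.numeric(tip_stage_um),
                 pipette_pos_um = c(0, 0, 0),
                 pressure_setpoint_mbar = 0, pressure_actual_mbar = 0,
                 holding_mV = 0, phase = "IDLE", sim_time_s = 0,
                 R_seal_Mohm = 0, suction_impulse = 0,
                 sealed_cell = NA_integer_, ruptured = FALSE)),
    class = "patch_rig")
}

#' @export
print.patch_rig <- function(x, ...) {
  s <- x$state
  cat(sprintf("patch_rig: t=%.2f s, phase %s, tip (%.1f, %.1f, %.1f) um, p=%.1f mbar, R=%.2f MOhm\n",
              s$sim_time_s, s$phase, s$tip_stage_um[1], s$tip_stage_um[2],
              s$tip_stage_um[3], s$pressure_actual_mbar,
              rig_read_resistance(x)))
  invisible(x)
}

# index of the cell in contact with the tip (within radius + 1 um), or NA;
# once a seal has started the sealed cell is anchored to the glass and
# counts as in contact regardless of later drift
rig_contact_cell <- function(rig) {
  s <- rig$state
  if (!is.na(s$sealed_cell) && (s$R_seal_Mohm > 0 || s$ruptured))
    return(s$sealed_cell)
  if (!nrow(rig$cells)) return(NA_integer_)
  tip <- rig$state$tip_stage_um
  d <- sqrt((rig$cells$x_um - tip[1])^2 + (rig$cells$y_um - tip[2])^2 +
            (rig$cells$z_um - tip[3])^2)
  hit <- which(d <= rig$cells$radius_um + 1)
  if (length(hit)) hit[which.min(d[hit])] else NA_integer_
}

#' Read the tip resistance of the simulated rig
#'
#' Emulates the 5 ms, -5 mV test-pulse resistance measurement: the returned
#' resistance obeys Ohm's law for the test pulse (a -5 mV step through
#' 5 MOhm draws 1 nA).
#'
#' @param rig a `patch_rig`.
#' @return Resistance in MOhm.
#' @export
rig_read_resistance <- function(rig) {
  stopifnot(inherits(rig, "patch_rig"))
  s <- rig$state
  if (s$ruptured && !is.na(s$sealed_cell))
    return(rig$baseline_Mohm +
             rig$cells$access_resistance_Mohm[s$sealed_cell])
  R <- rig$baseline_Mohm + s$R_seal_Mohm
  tip <- s$tip_stage_um
  if (nrow(rig$obstacles)) {
    d <- sqrt((rig$obstacles$x_um - tip[1])^2 + (rig$obstacles$y_um - tip[2])^2 +
              (rig$obstacles$z_um - tip[3])^2)
    R <- R + sum(rig$obstacles$resistance_bump_Mohm[d <= rig$obstacles$radius_um])
  }
  if (!is.na(rig_contact_cell(rig))) R <- R + rig$contact_jump_Mohm
  R
}

#' Current response to a voltage test step
#'
#' @param rig a `patch_rig`.
#' @param step_mV amplitude of the voltage step (default -5 mV).
#' @return Current in nA (`step_mV / R_Mohm`).
#' @export
rig_test_pulse_nA <- function(rig, step_mV = -5) {
  step_mV / rig_read_resistance(rig)
}

# seal growth rate at pressure p (mbar): linear in |negative pressure| up
# to -30 mbar, referenced to -20 mbar
rig_seal_k <- function(rig, p_mbar) {
  if (p_mbar >= 0) return(0)
  rig$seal_rate_per_s * min(abs(p_mbar), 30) / 20
}

#' Advance the rig simulation by one time step
#'
#' Pressure relaxes toward its setpoint with first-order time constant
#' `tau_s`. While the tip is in cell-attached contact and the pressure is
#' negative, seal resistance grows as `dR/dt = k(p) (R_max - R)` (scaled by
#' the cell's own `seal_rate`; non-sealable cells have zero growth). Once
#' gigasealed, suction at or below -100 mbar accumulates impulse
#' `|p| * dt`; crossing the cell's rupture threshold breaks the membrane
#' and drops the measured resistance to baseline + access resistance.
#'
#' @param rig a `patch_rig`.
#' @param dt_s time step in seconds (> 0).
#' @return The updated `patch_rig`.
#' @export
rig_step <- function(rig, dt_s) {
  stopifnot(inherits(rig, "patch_rig"), dt_s > 0)
  s <- rig$state
  s$sim_time_s <- s$sim_time_s + dt_s
  s$pressure_actual_mbar <- s$pressure_setpoint_mbar +
    (s$pressure_actual_mbar - s$pressure_setpoint_mbar) * exp(-dt_s / rig$tau_s)
  drift_cols <- c("drift_x_um_s", "drift_y_um_s", "drift_z_um_s")
  if (all(drift_cols %in% names(rig$cells)) && nrow(rig$cells)) {
    # a sealed cell is attached to the pipette and no longer drifts
    mv <- rep(TRUE, nrow(rig$cells))
    if (!is.na(s$sealed_cell) && (s$R_seal_Mohm > 0 || s$ruptured))
      mv[s$sealed_cell] <- FALSE
    rig$cells$x_um[mv] <- rig$cells$x_um[mv] + rig$cells$drift_x_um_s[mv] * dt_s
    rig$cells$y_um[mv] <- rig$cells$y_um[mv] + rig$cells$drift_y_um_s[mv] * dt_s
    rig$cells$z_um[mv] <- rig$cells$z_um[mv] + rig$cells$drift_z_um_s[mv] * dt_s
  }
  rig$state <- s
  ci <- rig_contact_cell(rig)
  if (!is.na(ci) && !s$ruptured) {
    s$sealed_cell <- ci
    p <- s$pressure_actual_mbar
    if (p < 0 && rig$cells$sealable[ci]) {
      k <- rig_seal_k(rig, p) * rig$cells$seal_rate[ci]
      s$R_seal_Mohm <- rig$R_max_Mohm -
        (rig$R_max_Mohm - s$R_seal_Mohm) * exp(-k * dt_s)
    }
    if (s$R_seal_Mohm + rig$baseline_Mohm >= 1000 && p <= -100) {
      s$suction_impulse <- s$suction_impulse + abs(p) * dt_s
      if (s$suction_impulse >= rig$cells$rupture_threshold[ci]) {
        s$ruptured <- TRUE
        s$R_seal_Mohm <- 0
      }
    }
  }
  rig$state <- s
  rig
}

#' Command the rig pressure setpoint
#'
#' @param rig a `patch_rig`.
#' @param mbar pressure setpoint in mbar.
#' @return The updated `patch_rig`.
#' @export
rig_set_pressure <- function(rig, mbar) {
  stopifnot(inherits(rig, "patch_rig"), is_number(mbar))
  rig$state$pressure_setpoint_mbar <- mbar
  rig
}

#' Command the holding potential
#'
#' @param rig a `patch_rig`.
#' @param mV holding potential in mV.
#' @return The updated `patch_rig`.
#' @export
rig_set_holding <- function(rig, mV) {
  stopifnot(inherits(rig, "patch_rig"), is_number(mV))
  rig$state$holding_mV <- mV
  rig
}

#' Set the rig phase annotation
#'
#' @param rig a `patch_rig`.
#' @param phase one of IDLE, HUNT, DESCEND, SEAL, BREAKIN, WHOLE_CELL,
#'   CLEAN, FAIL.
#' @return The updated `patch_rig`.
#' @export
rig_set_phase <- function(rig, phase) {
  phases <- c("IDLE", "HUNT", "DESCEND", "SEAL", "BREAKIN", "WHOLE_CELL",
              "CLEAN", "FAIL")
  stopifnot(inherits(rig, "patch_rig"), phase %in% phases)
  rig$state$phase <- phase
  rig
}

#' Move the pipette along its own axes
#'
#' The commanded pipette-frame displacement is mapped into stage space by
#' the rig's hidden true calibration matrix. Moves exceeding the per-axis
#' travel limit raise an error before any motion.
#'
#' @param rig a `patch_rig`.
#' @param delta_pipette_um length-3 displacement in pipette coordinates (um).
#' @return The updated `patch_rig`.
#' @export
rig_move_pipette <- function(rig, delta_pipette_um) {
  stopifnot(inherits(rig, "patch_rig"), length(delta_pipette_um) == 3)
  newpos <- rig$state$pipette_pos_um + as.numeric(delta_pipette_um)
  if (any(abs(newpos) > rig$travel_limit_um))
    stopf("move exceeds manipulator travel limit (%g um)", rig$travel_limit_um)
  rig$state$pipette_pos_um <- newpos
  rig$state$tip_stage_um <- rig$state$tip_stage_um +
    as.numeric(rig$calibration %*% as.numeric(delta_pipette_um))
  rig
}

# --- simulated camera -------------------------------------------------------

cell_speckle_patch <- function(cell_id, n = 48) {
  with_seed(7000 + cell_id, {
    p <- matrix(rnorm(n * n), n, n)
    p <- gauss_blur2d(p, 1.5)
    p / max(stats::sd(p), .Machine$double.eps) * 0.5
  })
}

#' Render a camera frame of ground-truth cells
#'
#' Simulates the DIC camera view at a given focal depth from the rig's
#' ground-truth cell list: each soma is a Gaussian envelope carrying a
#' fixed per-cell speckle texture (so it presents trackable features that
#' move rigidly with the cell), defocused in amplitude and width away from
#' its focal plane.
#'
#' @param cells ground-truth cell data frame (`x_um, y_um, z_um,
#'   radius_um`).
#' @param focus_z_um focal plane (stage um).
#' @param shape_px frame shape `(n_rows, n_cols)`.
#' @param pixel_size_um lateral pixel size.
#' @param origin_um stage position `(x, y)` of pixel (0, 0).
#' @param contrast peak soma contrast (default 0.25).
#' @return A numeric matrix in `[0, 1]`.
#' @export
render_cell_frame <- function(cells, focus_z_um, shape_px = c(96, 96),
                              pixel_size_um = 0.2, origin_um = c(0, 0),
                              contrast = 0.25) {
  nr <- shape_px[1]; nc <- shape_px[2]
  img <- matrix(0.5, nr, nc)
  if (!nrow(cells)) return(img)
  xg <- matrix(origin_um[1] + (seq_len(nc) - 1) * pixel_size_um, nr, nc,
               byrow = TRUE)
  yg <- matrix(origin_um[2] + (seq_len(nr) - 1) * pixel_size_um, nr, nc)
  for (ci in seq_len(nrow(cells))) {
    cl <- cells[ci, ]
    dz <- focus_z_um - cl$z_um
    amp <- contrast * exp(-dz^2 / (2 * 3^2))
    if (amp < 1e-4) next
    s0 <- cl$radius_um / 2
    sz <- s0 * sqrt(1 + (dz / 3)^2)
    u <- xg - cl$x_um; v <- yg - cl$y_um
    env <- exp(-(u^2 + v^2) / (2 * sz^2))
    sp <- cell_speckle_patch(ci)
    spk <- bilinear_sample(sp, v / 0.25 + nrow(sp) / 2, u / 0.25 + ncol(sp) / 2)
    img <- img + amp * env * (0.6 + spk)
  }
  clamp(img, 0, 1)
}

#' Render a mini-stack around an assumed focus position
#'
#' @inheritParams render_cell_frame
#' @param center_z_um assumed focus (stage um); becomes the middle slice.
#' @param half_depth slices on each side of the middle slice (default 3).
#' @param z_step_um slice spacing (default 1).
#' @return An [image_stack] with `2 * half_depth + 1` slices.
#' @export
render_cell_ministack <- function(cells, center_z_um, half_depth = 3,
                                  z_step_um = 1, shape_px = c(96, 96),
                                  pixel_size_um = 0.2, origin_um = c(0, 0),
                                  contrast = 0.25) {
  zs <- center_z_um + (-half_depth:half_depth) * z_step_um
  vox <- array(0, dim = c(length(zs), shape_px[1], shape_px[2]))
  for (i in seq_along(zs))
    vox[i, , ] <- render_cell_frame(cells, zs[i], shape_px, pixel_size_um,
                                    origin_um, contrast)
  image_stack(vox, pixel_size_um, z_step_um)
}

#' Image-based drift tracker bound to the simulated camera
#'
#' Builds the closure that [run_autopatch()] queries at pipette halts. At
#' construction it captures the template frame of the target cell at its
#' focal plane; each query renders the current camera view (lateral KLT
#' tracking) and a mini-stack around the last believed focus (axial
#' focus-difference tracking) and returns the accumulated drift estimate.
#' Only rendered images are used; ground-truth coordinates are never read
#' back directly.
#'
#' @param rig a `patch_rig` whose `cells` include the target.
#' @param target_index row index of the target cell at construction time.
#' @param shape_px camera frame shape (default 96 x 96).
#' @param pixel_size_um camera pixel size (default 0.2).
#' @param contrast soma contrast (default 0.25).
#' @return A function `function(rig) dxyz_um`.
#' @export
sim_cell_tracker <- function(rig, target_index, shape_px = c(96, 96),
                             pixel_size_um = 0.2, contrast = 0.25) {
  cl0 <- rig$cells[target_index, ]
  fov <- c(shape_px[2], shape_px[1]) * pixel_size_um
  origin <- c(cl0$x_um - fov[1] / 2, cl0$y_um - fov[2] / 2)
  z0 <- cl0$z_um
  tmpl <- render_cell_frame(rig$cells, z0, shape_px, pixel_size_um, origin,
                            contrast)
  side <- 2 * cl0$radius_um / pixel_size_um
  box <- list(x = (cl0$x_um - origin[1]) / pixel_size_um - side / 2,
              y = (cl0$y_um - origin[2]) / pixel_size_um - side / 2,
              w = side, h = side)
  st <- track_init(tmpl, box, pixel_size_um, z_step_um = 1)
  off_z <- 0
  function(rig_now) {
    frame <- render_cell_frame(rig_now$cells, z0 + off_z, shape_px,
                               pixel_size_um, origin, contrast)
    lat <- track_lateral(st, frame)
    mini <- render_cell_ministack(rig_now$cells, z0 + off_z, half_depth = 3,
                                  z_step_um = 1, shape_px = shape_px,
                                  pixel_size_um = pixel_size_um,
                                  origin_um = origin, contrast = contrast)
    dz <- track_z(st, mini)$dz_um
    off_z <<- off_z + dz
    c(lat$dx_um, lat$dy_um, off_z)
  }
}
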