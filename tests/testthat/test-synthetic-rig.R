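test_that("cell phantom generation is seeded, non-overlapping and complete", {
  spec0 <- phantom_spec(stack_shape = c(20, 96, 96), n_cells = 0, seed = 5)
  g0 <- generate_cell_phantom_stack(spec0)
  expect_equal(nrow(g0$cells), 0L)
  expect_identical(dim(g0$stack$voxels), c(20L, 96L, 96L))

  spec <- phantom_spec(stack_shape = c(40, 256, 256), pixel_size_um = 0.3,
                       n_cells = 10, seed = 1)
  g <- generate_cell_phantom_stack(spec)
  expect_equal(nrow(g$cells), 10L)
  pos <- as.matrix(g$cells[, c("x_um", "y_um", "z_um")])
  dmin <- min(stats::dist(pos))
  expect_gt(dmin, 2 * max(g$cells$radius_um))

  g2 <- generate_cell_phantom_stack(spec)
  expect_identical(g$stack$voxels, g2$stack$voxels)   # bit-identical
  g3 <- generate_cell_phantom_stack(phantom_spec(stack_shape = c(40, 256, 256),
                                                 pixel_size_um = 0.3,
                                                 n_cells = 10, seed = 2))
  expect_false(identical(g$stack$voxels, g3$stack$voxels))

  dense <- phantom_spec(stack_shape = c(10, 48, 48), pixel_size_um = 0.2,
                        n_cells = 50, seed = 1)
  expect_error(generate_cell_phantom_stack(dense), "placement impossible")
})

test_that("cells are sharpest at their own slice and fade with defocus", {
  spec <- phantom_spec(stack_shape = c(40, 128, 128), pixel_size_um = 0.4,
                       n_cells = 2, noise_sigma = 0, seed = 3)
  g <- generate_cell_phantom_stack(spec)
  for (i in seq_len(nrow(g$cells))) {
    cl <- g$cells[i, ]
    r <- round(cl$y_um / 0.4) + 1; c <- round(cl$x_um / 0.4) + 1
    prof <- g$stack$voxels[, r, c]
    zi <- round(cl$z_um) + 1
    expect_lt(abs(which.max(prof) - zi), 2)
    expect_gt(prof[zi], prof[min(zi + 6, 40)])
  }
})

test_that("rendered pipette darkens walls and is deterministic", {
  vox <- array(0.5, c(30, 128, 128))
  st <- image_stack(vox, 0.2, 1)
  m <- pipette_model(c(12, 12, 15), yaw_rad = 0.6, tilt_rad = 0.58)
  r1 <- render_pipette(st, m)
  r2 <- render_pipette(st, m)
  expect_identical(r1$voxels, r2$voxels)

  # mean intensity along the wall axes vs background
  dirs <- autopatchr:::pipette_wall_dirs(m)
  wall_vals <- unlist(lapply(dirs, function(dk) {
    s <- seq(1, 10, by = 0.5)
    autopatchr:::trilinear_sample(r1$voxels,
                                  slice = (m$tip_um[3] + s * dk[3]) / 1,
                                  row = (m$tip_um[2] + s * dk[2]) / 0.2,
                                  col = (m$tip_um[1] + s * dk[1]) / 0.2)
  }))
  expect_lt(mean(wall_vals), 0.7 * 0.5)

  expect_identical(render_pipette(st, m, contrast = 0)$voxels, st$voxels)
  out <- pipette_model(c(200, 12, 15))
  expect_error(render_pipette(st, out), "outside")
})

test_that("rig resistance follows baseline, contact jump and Ohm's law", {
  for (s in 1:5) {
    r <- rig_create(seed = s)
    expect_gte(rig_read_resistance(r), 3.5)
    expect_lte(rig_read_resistance(r), 5)
  }
  cell <- make_cell(0, 0, 0, r = 5)
  rig <- rig_create(cells = cell, tip_stage_um = c(0, 0, 5.9), seed = 1)
  expect_gte(rig_read_resistance(rig), rig$baseline_Mohm + 1)
  far <- rig_create(cells = cell, tip_stage_um = c(0, 0, 50), seed = 1)
  expect_equal(rig_read_resistance(far), far$baseline_Mohm)

  # -5 mV across 5 MOhm draws 1 nA
  rig5 <- rig_create(seed = 1)
  rig5$baseline_Mohm <- 5
  expect_equal(rig_test_pulse_nA(rig5, -5), -1)
})

test_that("pressure relaxes first-order toward the setpoint, monotonically", {
  rig <- rig_create(seed = 2)
  rig <- rig_set_pressure(rig, 60)
  rig <- rig_step(rig, rig$tau_s)
  expect_equal(rig$state$pressure_actual_mbar, 60 * (1 - exp(-1)),
               tolerance = 1e-9)
  gaps <- numeric()
  for (i in 1:40) {
    rig <- rig_step(rig, 0.05)
    gaps <- c(gaps, abs(60 - rig$state$pressure_actual_mbar))
  }
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("seal grows only in contact with suction and reaches GOhm in time", {
  cell <- make_cell(0, 0, 0)
  rig <- rig_create(cells = cell, tip_stage_um = c(0, 0, 4), seed = 3)
  rig <- rig_set_pressure(rig, -20)
  t <- 0
  r_prev <- rig_read_resistance(rig)
  while (rig_read_resistance(rig) < 1000 && t < 40) {
    rig <- rig_step(rig, 0.05)
    t <- t + 0.05
    expect_gte(rig_read_resistance(rig), r_prev - 1e-9)  # non-decreasing
    r_prev <- rig_read_resistance(rig)
  }
  expect_gt(t, 10); expect_lt(t, 25)

  # no contact: seal resistance stays zero
  rig2 <- rig_create(cells = cell, tip_stage_um = c(0, 0, 50), seed = 3)
  rig2 <- rig_set_pressure(rig2, -20)
  for (i in 1:100) rig2 <- rig_step(rig2, 0.05)
  expect_equal(rig2$state$R_seal_Mohm, 0)

  # non-sealable cell: no growth despite contact + suction
  rig3 <- rig_create(cells = make_cell(0, 0, 0, sealable = FALSE),
                     tip_stage_um = c(0, 0, 4), seed = 3)
  rig3 <- rig_set_pressure(rig3, -20)
  for (i in 1:200) rig3 <- rig_step(rig3, 0.05)
  expect_equal(rig3$state$R_seal_Mohm, 0)
})

test_that("rupture needs a gigaseal plus enough suction impulse", {
  cell <- make_cell(0, 0, 0, rupture = 250, access = 30)
  rig <- rig_create(cells = cell, tip_stage_um = c(0, 0, 4), seed = 4)
  # suction pulses before any seal: never ruptures
  rig_a <- rig_set_pressure(rig, -120)
  for (i in 1:100) rig_a <- rig_step(rig_a, 0.05)
  expect_false(rig_a$state$ruptured)

  # gigaseal first, then pulse until impulse crosses the threshold
  rig <- rig_set_pressure(rig, -25)
  while (rig$state$R_seal_Mohm + rig$baseline_Mohm < 1000)
    rig <- rig_step(rig, 0.05)
  rig <- rig_set_pressure(rig, -120)
  for (i in 1:100) { rig <- rig_step(rig, 0.05); if (rig$state$ruptured) break }
  expect_true(rig$state$ruptured)
  expect_equal(rig_read_resistance(rig),
               rig$baseline_Mohm + cell$access_resistance_Mohm)
})

test_that("pipette moves respect the hidden calibration and travel limits", {
  rig <- rig_create(seed = 1)
  r0 <- rig_move_pipette(rig, c(0, 0, 0))
  expect_equal(r0$state$tip_stage_um, rig$state$tip_stage_um)

  r1 <- rig_move_pipette(rig, c(10, 0, 0))
  d <- r1$state$tip_stage_um - rig$state$tip_stage_um
  expect_lt(d[3], 0)                       # the advance axis descends
  expect_equal(sqrt(sum(d^2)), 10, tolerance = 1e-9)

  r2 <- rig_move_pipette(rig_move_pipette(rig, c(3, -2, 1)), c(-1, 5, 2))
  r3 <- rig_move_pipette(rig, c(2, 3, 3))
  expect_equal(r2$state$tip_stage_um, r3$state$tip_stage_um, tolerance = 1e-9)

  expect_error(rig_move_pipette(rig, c(1e5, 0, 0)), "travel limit")
})
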