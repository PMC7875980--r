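# Small phantoms (60 x 192 x 192 at 0.15 um/px) keep these unit tests fast;
# the full-geometry accuracy suite runs in the acceptance tests.

small_phantom <- function(seed, noise = 0) {
  generate_pipette_phantom(seed = seed, shape = c(60, 192, 192),
                           pixel_size_um = 0.15, noise_sigma = noise)
}

test_that("darkness map is offset-invariant, normalized and zero on uniform input", {
  u <- image_stack(array(0.4, c(5, 48, 48)), 0.2, 1)
  expect_true(all(darkness_map(u)$voxels == 0))

  ph <- small_phantom(21)
  m1 <- darkness_map(ph$stack)
  shifted <- ph$stack
  shifted$voxels <- shifted$voxels + 0.07
  m2 <- darkness_map(shifted)
  expect_equal(m1$voxels, m2$voxels, tolerance = 1e-9)
  expect_gte(min(m1$voxels), 0); expect_lte(max(m1$voxels), 1)

  # wall voxels much darker than background in the map
  dirs <- autopatchr:::pipette_wall_dirs(ph$model)
  wall <- unlist(lapply(dirs, function(dk) {
    s <- seq(1, 8, by = 0.5)
    autopatchr:::trilinear_sample(m1$voxels,
                                  slice = ph$model$tip_um[3] + s * dk[3],
                                  row = (ph$model$tip_um[2] + s * dk[2]) / 0.15,
                                  col = (ph$model$tip_um[1] + s * dk[1]) / 0.15)
  }))
  expect_gt(mean(wall), 3 * mean(m1$voxels))
})

test_that("initialization lands inside the refinement capture range", {
  for (s in c(21, 22, 23)) {
    ph <- small_phantom(s)
    init <- initialize_pipette_model(ph$stack)
    expect_lt(sqrt(sum((init$tip_um - ph$model$tip_um)^2)), 10)
    dyaw <- abs((init$yaw_rad - ph$model$yaw_rad + pi) %% (2 * pi) - pi)
    expect_lt(dyaw * 180 / pi, 15)
    expect_lt(abs(init$tilt_rad - ph$model$tilt_rad) * 180 / pi, 15)
  }
  blank <- image_stack(array(0.5, c(20, 96, 96)), 0.15, 1)
  expect_error(initialize_pipette_model(blank), "detection failure")
})

test_that("fitting energy prefers the true pose and ignores intensity offsets", {
  ph <- small_phantom(24)
  map <- darkness_map(ph$stack)
  e_true <- pipette_energy(map, ph$model)
  shifted_model <- ph$model
  shifted_model$tip_um <- ph$model$tip_um + c(5, 0, 0)
  expect_lt(e_true, pipette_energy(map, shifted_model))

  # local minimum against lateral/axial/angular perturbations
  for (dp in list(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(-3, 0, 0))) {
    m <- ph$model; m$tip_um <- m$tip_um + dp
    expect_lt(e_true, pipette_energy(map, m))
  }
  for (da in c(-5, 5) * pi / 180) {
    m <- ph$model; m$yaw_rad <- m$yaw_rad + da
    expect_lt(e_true, pipette_energy(map, m))
  }

  u <- darkness_map(image_stack(array(0.4, c(5, 48, 48)), 0.2, 1))
  expect_equal(pipette_energy(u, pipette_model(c(4, 4, 2))), 0)

  off <- ph$stack; off$voxels <- off$voxels + 0.05
  expect_equal(pipette_energy(darkness_map(off), ph$model), e_true,
               tolerance = 1e-9)
})

test_that("gradient-descent refinement converges from a perturbed start", {
  ph <- small_phantom(25)
  map <- darkness_map(ph$stack)
  init <- ph$model
  init$tip_um <- init$tip_um + c(2, -2, 1)   # 3 um off
  ref <- refine_pipette_model(map, init)
  # sub-pixel-scale accuracy at this reduced unit-test geometry; the
  # full-geometry 0.3 um bound is asserted in the acceptance suite
  expect_lt(sqrt(sum((ref$model$tip_um - ph$model$tip_um)^2)), 0.6)
  expect_true(all(diff(ref$energy_trace) <= 1e-12))

  # starting at the truth never worsens the tip estimate beyond its start
  ref2 <- refine_pipette_model(map, ph$model)
  e0 <- sqrt(sum((ph$model$tip_um - ph$model$tip_um)^2))
  expect_lte(sqrt(sum((ref2$model$tip_um - ph$model$tip_um)^2)),
             max(e0, 0.3))
})

test_that("full tip detector is sub-micrometre on phantoms and fails cleanly", {
  ph <- small_phantom(26)
  res <- detect_tip(ph$stack)
  expect_lt(sqrt(sum((res$tip_um - ph$model$tip_um)^2)), 0.5)
  expect_true(all(diff(res$energy_trace) <= 1e-12))
  blank <- image_stack(array(0.5, c(20, 96, 96)), 0.15, 1)
  expect_error(detect_tip(blank), "detection failure")
})

test_that("calibration estimation recovers any invertible map", {
  # identity moves
  D <- diag(3) * 20
  cal_id <- estimate_calibration(D, D)
  expect_equal(cal_id$matrix, diag(3), tolerance = 1e-9)

  # tilted true matrix from 3 noiseless axis moves
  A <- default_calibration_matrix()
  obs <- t(A %*% t(D))
  cal <- estimate_calibration(D, obs)
  expect_equal(cal$matrix, A, tolerance = 1e-9)

  # arbitrary invertible map, 6 moves
  set.seed(7)
  A2 <- matrix(rnorm(9), 3, 3) + diag(3)
  D6 <- rbind(D, matrix(runif(9, -30, 30), 3, 3))
  cal2 <- estimate_calibration(D6, t(A2 %*% t(D6)))
  expect_equal(cal2$matrix, A2, tolerance = 1e-9)

  # noisy observations: per-entry error within 2 percent
  set.seed(8)
  D50 <- rbind(diag(3) * 50, diag(3) * -50)
  obs_n <- t(A %*% t(D50)) + matrix(rnorm(18, sd = 0.5), 6, 3)
  cal3 <- estimate_calibration(D50, obs_n)
  expect_lt(max(abs(cal3$matrix - A)), 0.02 * max(abs(A)))

  expect_error(estimate_calibration(D[1:2, ], obs[1:2, ]), "degenerate")
  expect_error(estimate_calibration(rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                                    matrix(1, 3, 3)), "degenerate")
})

test_that("pipette/stage mappings round trip and close the loop with the rig", {
  cal <- calibration_transform(default_calibration_matrix())
  expect_equal(pipette_to_stage(calibration_transform(diag(3)), c(1, 2, 3)),
               c(1, 2, 3))
  v <- c(4.2, -1.7, 9)
  expect_equal(stage_to_pipette(cal, pipette_to_stage(cal, v)), v,
               tolerance = 1e-12)

  # closed loop: command a stage target through the inverse map
  rig <- rig_create(seed = 5)
  target <- c(25, -10, -15)
  rig2 <- rig_move_pipette(rig, stage_to_pipette(cal, target))
  expect_equal(rig2$state$tip_stage_um, target, tolerance = 1e-9)
})
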