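target <- c(50, 0, -30)
cal <- calibration_transform(default_calibration_matrix())

test_that("trajectory planning spaces 2 um waypoints toward the staging point", {
  cfg <- patch_config()
  # place the tip so the staging point lies 20 um straight down the axis
  adv <- default_calibration_matrix()[, 1]
  staging <- target + c(0, 0, cfg$above_cell_offset_um)
  tip <- staging - 20 * adv
  plan <- plan_trajectory(cal, tip, target, cfg)
  expect_null(plan$lateral)
  expect_length(plan$hunt, 10)
  expect_true(all(vapply(plan$hunt, function(w) w[1], numeric(1)) == 2))

  # already at the staging point: descent only
  plan2 <- plan_trajectory(cal, staging, target, cfg)
  expect_length(plan2$hunt, 0)
  expect_equal(pipette_to_stage(cal, plan2$descent_step_pipette),
               c(0, 0, -cfg$step_um), tolerance = 1e-9)

  # waypoints map through the calibration and back exactly
  for (w in plan$hunt)
    expect_equal(stage_to_pipette(cal, pipette_to_stage(cal, w)), w,
                 tolerance = 1e-9)

  expect_error(plan_trajectory(cal, c(0, 0, 0), c(1e5, 0, 0), cfg),
               "planning error")
})

test_that("hunting holds its pressure band and classifies obstacle hits", {
  cfg <- patch_config()
  start <- hunt_line_start(c(0, 0, 0), target, cfg)
  adv <- default_calibration_matrix()[, 1]
  obst_pos <- start + adv * 25
  obst <- data.frame(x_um = obst_pos[1], y_um = obst_pos[2], z_um = obst_pos[3],
                     radius_um = 4, resistance_bump_Mohm = 1.5)
  rig <- rig_create(cells = make_cell(50, 0, -30), obstacles = obst, seed = 7)
  rec <- run_autopatch(rig, target, cfg)
  expect_equal(rec$outcome, "WHOLE_CELL")

  hunt <- subset(rec$phase_log, phase == "HUNT" & event == "hunt_step")
  expect_true(all(hunt$pressure_mbar >= 50 & hunt$pressure_mbar <= 70))
  expect_true(any(rec$phase_log$event == "obstacle_hit"))

  # avoidance sub-steps appear in their numbered order
  av <- subset(rec$phase_log, event == "avoid_substep")
  sub <- as.integer(vapply(strsplit(av$detail, ";"), `[[`, character(1), 1))
  firsts <- vapply(1:6, function(k) which(sub == k)[1], numeric(1))
  expect_true(all(diff(firsts) > 0))
})

test_that("an unobstructed run never triggers avoidance and ends whole-cell", {
  rig <- rig_create(cells = make_cell(50, 0, -30), seed = 42)
  rec <- run_autopatch(rig, target, patch_config())
  expect_equal(rec$outcome, "WHOLE_CELL")
  expect_false(any(rec$phase_log$event == "avoid_substep"))
  expect_lt(rec$Rs_Mohm, 100)
})

test_that("an impassable obstacle wall exhausts the spiral and fails", {
  cfg <- patch_config()
  start <- hunt_line_start(c(0, 0, 0), target, cfg)
  adv <- default_calibration_matrix()[, 1]
  hit <- start + adv * 25
  grid <- expand.grid(dy = seq(-18, 18, by = 3), dz = seq(-18, 18, by = 3))
  wall <- data.frame(x_um = hit[1], y_um = hit[2] + grid$dy,
                     z_um = hit[3] + grid$dz, radius_um = 3,
                     resistance_bump_Mohm = 1.5)
  rig <- rig_create(cells = make_cell(50, 0, -30), obstacles = wall, seed = 7)
  rec <- run_autopatch(rig, target, cfg)
  expect_equal(rec$outcome, "OBSTACLE_FAIL")
})

test_that("descent detects contact at the configured threshold semantics", {
  cfg <- patch_config()
  dsc_pressure <- function(rec)
    subset(rec$phase_log, event %in% c("descend_step", "contact"))$pressure_mbar
  rig <- rig_create(cells = make_cell(50, 0, -30), seed = 42)
  rec <- run_autopatch(rig, target, cfg)
  p <- dsc_pressure(rec)
  expect_true(all(p >= 10 & p <= 30))

  # jump just below the threshold: no contact, missed-cell error
  rig_lo <- rig_create(cells = make_cell(50, 0, -30), seed = 42,
                       contact_jump_Mohm = 0.99 * cfg$contact_threshold_Mohm)
  rec_lo <- run_autopatch(rig_lo, target, cfg)
  expect_equal(rec_lo$outcome, "ERROR")
  expect_true(any(grepl("missed cell", rec_lo$phase_log$detail)))

  # just above: contact and a full attempt
  rig_hi <- rig_create(cells = make_cell(50, 0, -30), seed = 42,
                       contact_jump_Mohm = 1.01 * cfg$contact_threshold_Mohm)
  expect_equal(run_autopatch(rig_hi, target, cfg)$outcome, "WHOLE_CELL")
})

test_that("a default sealable cell gigaseals within the deadline, no escalation", {
  rig <- rig_create(cells = make_cell(50, 0, -30), seed = 42)
  rec <- run_autopatch(rig, target, patch_config())
  lg <- rec$phase_log
  expect_false(any(lg$event == "seal_escalation"))
  t_seal <- lg$time_s[lg$event == "seal_start"]
  t_giga <- lg$time_s[lg$event == "gigaseal"]
  expect_lt(t_giga - t_seal, 30)
})

test_that("seal escalation runs its stages strictly in protocol order", {
  rig <- rig_create(cells = make_cell(50, 0, -30, sealable = FALSE), seed = 8)
  rec <- run_autopatch(rig, target, patch_config())
  expect_equal(rec$outcome, "SEAL_FAIL")
  esc <- subset(rec$phase_log, event == "seal_escalation")$detail
  expect_equal(esc, c("vacuum_x1.5", "vacuum_x2", "wiggle_axis1",
                      "wiggle_axis2", "wiggle_axis3", "release", "reapply"))
  sealp <- subset(rec$phase_log, phase == "SEAL")$pressure_mbar
  expect_true(all(sealp >= -60 & sealp <= 0))

  # a slow sealer recovers during escalation instead of failing
  slow <- make_cell(50, 0, -30, seal_rate = 0.35)
  rec2 <- run_autopatch(rig_create(cells = slow, seed = 9), target,
                        patch_config())
  expect_equal(rec2$outcome, "WHOLE_CELL")
  expect_gte(sum(rec2$phase_log$event == "seal_escalation"), 1)
})

test_that("break-in pulse durations follow 0.5 + 0.2k within the time cap", {
  rig <- rig_create(cells = make_cell(50, 0, -30), seed = 42)
  rec <- run_autopatch(rig, target, patch_config())
  pulses <- subset(rec$phase_log, event == "breakin_pulse")
  durs <- as.numeric(vapply(strsplit(pulses$detail, ";"), `[[`,
                            character(1), 2))
  k <- seq_along(durs)
  expect_equal(durs, 0.5 + 0.2 * k)
  expect_true(all(pulses$pressure_mbar >= -140 & pulses$pressure_mbar <= -100))
  expect_true(rec$Rs_Mohm > 0)

  # unreachable rupture threshold: BREAKIN_FAIL within 180 s of phase time
  tough <- make_cell(50, 0, -30, rupture = 1e9)
  rec2 <- run_autopatch(rig_create(cells = tough, seed = 42), target,
                        patch_config())
  expect_equal(rec2$outcome, "BREAKIN_FAIL")
  lg <- rec2$phase_log
  t0 <- lg$time_s[lg$event == "breakin_start"]
  t1 <- max(lg$time_s[lg$phase == "BREAKIN"])
  expect_lte(t1 - t0, 180 + 1e-6)
})

test_that("phase order follows the protocol DAG and pressures stay in band", {
  scenarios <- list(
    run_autopatch(rig_create(cells = make_cell(50, 0, -30), seed = 42),
                  target, patch_config()),
    run_autopatch(rig_create(cells = make_cell(50, 0, -30, sealable = FALSE),
                             seed = 8), target, patch_config()),
    run_autopatch(rig_create(cells = make_cell(50, 0, -30, rupture = 1e9),
                             seed = 42), target, patch_config()))
  order_ref <- c("IDLE", "HUNT", "DESCEND", "SEAL", "BREAKIN", "WHOLE_CELL",
                 "FAIL")
  for (rec in scenarios) {
    seqp <- phase_sequence(rec)
    expect_equal(seqp, intersect(order_ref, seqp))   # monotone in the DAG
    lg <- rec$phase_log
    expect_true(all(subset(lg, phase == "HUNT" &
                                event == "hunt_step")$pressure_mbar %in% 50:70))
    expect_true(all(subset(lg, phase == "DESCEND")$pressure_mbar >= 10 &
                    subset(lg, phase == "DESCEND")$pressure_mbar <= 30))
    sp <- subset(lg, phase == "SEAL")$pressure_mbar
    if (length(sp)) expect_true(all(sp >= -60 & sp <= 0))
    bp <- subset(lg, event == "breakin_pulse")$pressure_mbar
    if (length(bp)) expect_true(all(bp >= -140 & bp <= -100))
    expect_true(all(diff(lg$time_s) >= 0))
  }
})

test_that("identical configuration and seeds give identical attempt records", {
  r1 <- run_autopatch(rig_create(cells = make_cell(50, 0, -30), seed = 42),
                      target, patch_config())
  r2 <- run_autopatch(rig_create(cells = make_cell(50, 0, -30), seed = 42),
                      target, patch_config())
  expect_identical(r1$phase_log, r2$phase_log)
  expect_identical(r1$Rs_Mohm, r2$Rs_Mohm)
})

test_that("a target outside manipulator travel errors before any motion", {
  rig <- rig_create(cells = make_cell(50, 0, -30), seed = 1)
  rec <- run_autopatch(rig, c(2e4, 0, 0), patch_config())
  expect_equal(rec$outcome, "ERROR")
  expect_false(any(rec$phase_log$event %in%
                     c("hunt_step", "descend_step", "contact")))
})

test_that("pipette cleaning uses only the protocol pressures and durations", {
  cfg <- patch_config(alconox_bath_um = c(-200, 300, 100),
                      acsf_bath_um = c(-200, 350, 100))
  ctx <- autopatch_context(rig_create(seed = 3), cfg, target)
  ctx <- clean_pipette(ctx)
  ev <- ctx$log
  press <- Filter(function(e) e$event == "clean_pressure", ev)
  setp <- vapply(press, function(e) e$mbar, numeric(1))
  expect_true(all(setp %in% c(-300, 1000)))
  durs <- vapply(press, function(e) e$duration_s, numeric(1))
  baths <- vapply(Filter(function(e) e$event == "clean_bath", ev),
                  function(e) e$bath, character(1))
  expect_equal(baths, c("alconox", "acsf"))
  # alconox phase: 4 s vacuum + 5 alternation pairs + 10 s expulsion
  expect_equal(durs[1], 4)
  expect_equal(durs[2:11], rep(1, 10))
  expect_equal(durs[12], 10)
  expect_equal(durs[13], 10)               # aCSF rinse
  expect_equal(sum(durs[1:12]), 4 + 10 + 10)

  bad <- autopatch_context(rig_create(seed = 3), patch_config(), target)
  expect_error(clean_pipette(bad), "configuration error")
})

test_that("cytoplasm harvesting runs its pressure sequence only in whole-cell", {
  cfg <- patch_config()
  ctx <- autopatch_context(rig_create(seed = 4), cfg, target)
  expect_error(harvest_cytoplasm(ctx), "state error")

  ctx$rig <- rig_set_phase(ctx$rig, "WHOLE_CELL")
  t0 <- ctx$rig$state$sim_time_s
  ctx <- harvest_cytoplasm(ctx)
  st <- Filter(function(e) e$event == "harvest_stage", ctx$log)
  expect_equal(vapply(st, function(e) e$mbar, numeric(1)), c(-40, -60, -40))
  expect_equal(vapply(st, function(e) e$duration_s, numeric(1)),
               c(60, 150, 60))
  expect_equal(ctx$rig$state$sim_time_s - t0, 270, tolerance = 0.2)
})

test_that("diary appends, survives corruption and aggregates into a report", {
  td <- withr::local_tempdir()
  dpath <- file.path(td, "diary.jsonl")
  recs <- list(
    run_autopatch(rig_create(cells = make_cell(50, 0, -30), seed = 42),
                  target, patch_config()),
    run_autopatch(rig_create(cells = make_cell(50, 0, -30, sealable = FALSE),
                             seed = 8), target, patch_config()),
    run_autopatch(rig_create(cells = make_cell(50, 0, -30), seed = 43),
                  target, patch_config()))
  for (r in recs) diary_append(r, dpath)
  back <- read_diary(dpath)
  expect_length(back, 3)
  expect_equal(back[[1]]$outcome, recs[[1]]$outcome)
  expect_equal(back[[1]]$phase_log$time_s, recs[[1]]$phase_log$time_s)
  expect_equal(back[[1]]$phase_log$event, recs[[1]]$phase_log$event)
  expect_equal(back[[2]]$Rs_Mohm, recs[[2]]$Rs_Mohm)

  cat("not json at all\n", file = dpath, append = TRUE)
  expect_warning(back2 <- read_diary(dpath), "corrupt")
  expect_length(back2, 3)
  expect_equal(attr(back2, "n_corrupt"), 1L)

  rep <- suppressWarnings(generate_report(dpath, file.path(td, "rep")))
  expect_equal(rep$n_attempts, 3)
  expect_equal(sum(rep$outcomes$n), 3)
  expect_setequal(rep$outcomes$outcome, unique(vapply(recs, `[[`,
                                                      character(1), "outcome")))
  expect_true(file.exists(file.path(td, "rep.json")))
  expect_true(file.exists(file.path(td, "rep.csv")))
})

test_that("run configuration survives an XML round trip and checks its ranges", {
  td <- withr::local_tempdir()
  cfg <- patch_config(hunt_pressure_mbar = 55, seal_pressure_mbar = -15,
                      alconox_bath_um = c(1, 2, 3))
  p <- file.path(td, "cfg.xml")
  write_patch_config(cfg, p)
  cfg2 <- read_patch_config(p)
  keep <- function(x) x[!vapply(x, is.null, logical(1))]
  expect_equal(keep(unclass(cfg2)), keep(unclass(cfg)))

  expect_error(patch_config(hunt_pressure_mbar = 80), "outside allowed range")
  expect_error(patch_config(breakin_pressure_mbar = -90), "outside allowed range")
  expect_error(patch_config(contact_threshold_Mohm = 0.5), "outside allowed range")
})
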