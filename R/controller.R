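# The autopatching finite-state machine: trajectory planning, hunting with
# obstacle avoidance, descent/contact detection, gigaseal formation with
# escalation, break-in, cleaning and harvesting, with a structured event
# log per attempt. Phase order is HUNT -> DESCEND -> SEAL -> BREAKIN ->
# WHOLE_CELL with FAIL edges only; HUNT is re-entered only after obstacle
# avoidance.

#' Autopatching configuration
#'
#' Defaults sit at the protocol's published working points; each pressure
#' and threshold is validated against its allowed range.
#'
#' @param hunt_pressure_mbar positive pressure while hunting, in `[50, 70]`
#'   (default 60).
#' @param position_pressure_mbar low positive pressure during descent, in
#'   `[10, 30]` (default 20).
#' @param seal_pressure_mbar suction during sealing, in `[-30, -10]`
#'   (default -20).
#' @param breakin_pressure_mbar suction pulses for break-in, in
#'   `[-140, -100]` (default -120).
#' @param contact_threshold_Mohm resistance jump marking cell contact, in
#'   `[0.7, 1.2]` (default 1.0).
#' @param obstacle_threshold_Mohm resistance jump marking an obstacle
#'   (defaults to the contact threshold).
#' @param step_um hunting/descent step (default 2).
#' @param above_cell_offset_um staging height above the target (default 5).
#' @param holding_target_mV final holding potential (default -60).
#' @param holding_step_mV holding ramp step (default -10, one step per
#'   second).
#' @param gigaseal_Mohm seal success resistance (default 1000).
#' @param seal_deadline_s time allowed before escalation (default 30).
#' @param breakin_timeout_s break-in phase cap (default 180).
#' @param fail_Rs_Mohm series-resistance cutoff for a successful whole-cell
#'   outcome (default 100).
#' @param cell_diameter_um expected soma diameter, bounds the descent search
#'   (default 10).
#' @param pullback_um pull-back distance on an obstacle hit (default 6).
#' @param spiral_pitch_um radial pitch of the avoidance spiral (default 1).
#' @param spiral_points_per_turn probe points per spiral turn (default 8).
#' @param spiral_max_radius_um abort radius of the spiral (default 15).
#' @param obstacle_pass_um forward clearance added past an obstacle
#'   (default 8).
#' @param interpulse_pause_s pause between break-in pulses (default 2).
#' @param dt_s discrete-event simulation step (default 0.05).
#' @param harvest_mid_s duration of the middle harvesting stage
#'   (default 150, within the protocol's 2--3 min).
#' @param alconox_bath_um,acsf_bath_um stage positions of the cleaning
#'   baths (NULL until calibrated).
#' @return A `patch_config` list.
#' @export
patch_config <- function(hunt_pressure_mbar = 60, position_pressure_mbar = 20,
                         seal_pressure_mbar = -20, breakin_pressure_mbar = -120,
                         contact_threshold_Mohm = 1.0,
                         obstacle_threshold_Mohm = contact_threshold_Mohm,
                         step_um = 2, above_cell_offset_um = 5,
                         holding_target_mV = -60, holding_step_mV = -10,
                         gigaseal_Mohm = 1000, seal_deadline_s = 30,
                         breakin_timeout_s = 180, fail_Rs_Mohm = 100,
                         cell_diameter_um = 10, pullback_um = 6,
                         spiral_pitch_um = 1, spiral_points_per_turn = 8,
                         spiral_max_radius_um = 15, obstacle_pass_um = 8,
                         interpulse_pause_s = 2, dt_s = 0.05,
                         harvest_mid_s = 150, alconox_bath_um = NULL,
                         acsf_bath_um = NULL) {
  in_range <- function(x, lo, hi, name) {
    if (x < lo || x > hi)
      stopf("%s = %g outside allowed range [%g, %g]", name, x, lo, hi)
    x
  }
  cfg <- list(
    hunt_pressure_mbar = in_range(hunt_pressure_mbar, 50, 70, "hunt_pressure_mbar"),
    position_pressure_mbar = in_range(position_pressure_mbar, 10, 30, "position_pressure_mbar"),
    seal_pressure_mbar = in_range(seal_pressure_mbar, -30, -10, "seal_pressure_mbar"),
    breakin_pressure_mbar = in_range(breakin_pressure_mbar, -140, -100, "breakin_pressure_mbar"),
    contact_threshold_Mohm = in_range(contact_threshold_Mohm, 0.7, 1.2, "contact_threshold_Mohm"),
    obstacle_threshold_Mohm = obstacle_threshold_Mohm,
    step_um = step_um, above_cell_offset_um = above_cell_offset_um,
    holding_target_mV = holding_target_mV, holding_step_mV = holding_step_mV,
    gigaseal_Mohm = gigaseal_Mohm, seal_deadline_s = seal_deadline_s,
    breakin_timeout_s = breakin_timeout_s, fail_Rs_Mohm = fail_Rs_Mohm,
    cell_diameter_um = cell_diameter_um, pullback_um = pullback_um,
    spiral_pitch_um = spiral_pitch_um,
    spiral_points_per_turn = spiral_points_per_turn,
    spiral_max_radius_um = spiral_max_radius_um,
    obstacle_pass_um = obstacle_pass_um,
    interpulse_pause_s = interpulse_pause_s, dt_s = dt_s,
    harvest_mid_s = harvest_mid_s,
    alconox_bath_um = alconox_bath_um, acsf_bath_um = acsf_bath_um)
  if (cfg$step_um <= 0) stopf("step_um must be > 0")
  structure(cfg, class = "patch_config")
}

#' Write / read the run configuration as XML
#'
#' @param cfg a [patch_config].
#' @param path XML file path.
#' @return `path` invisibly / the parsed [patch_config].
#' @export
write_patch_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "patch_config"))
  doc <- xml2::xml_new_root("patch_config")
  for (nm in names(cfg)) {
    val <- cfg[[nm]]
    if (is.null(val)) next
    xml2::xml_add_child(doc, nm, paste(format(val, digits = 15), collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_patch_config
#' @export
read_patch_config <- function(path) {
  doc <- xml2::read_xml(path)
  kids <- xml2::xml_children(doc)
  vals <- lapply(kids, function(k) {
    v <- as.numeric(strsplit(xml2::xml_text(k), " +")[[1]])
    v
  })
  names(vals) <- xml2::xml_name(kids)
  do.call(patch_config, vals)
}

#' Plan the pipette trajectory to a target
#'
#' The hunting segment runs along the manipulator's X axis (the pipette's
#' longitudinal axis) in `step_um` steps toward a staging point
#' `above_cell_offset_um` above the target, after a single lateral
#' pre-positioning move; it is followed by a pure stage-Z descent segment.
#'
#' @param cal a [calibration_transform].
#' @param tip_um current tip position (stage um).
#' @param target_um target centroid (stage um).
#' @param cfg a [patch_config].
#' @param max_travel_um per-axis pipette-frame travel bound checked before
#'   any motion (default 5000).
#' @return A list with `lateral` (one pipette-frame pre-positioning move or
#'   NULL), `hunt` (list of pipette-frame step vectors), `staging_um`, and
#'   `descent_step_pipette` (pipette-frame move producing a `step_um` stage
#'   descent).
#' @export
plan_trajectory <- function(cal, tip_um, target_um, cfg,
                            max_travel_um = 5000) {
  staging <- as.numeric(target_um) + c(0, 0, cfg$above_cell_offset_um)
  delta_pip <- stage_to_pipette(cal, staging - as.numeric(tip_um))
  if (any(abs(delta_pip) > max_travel_um))
    stopf("planning error: target outside manipulator travel")
  dx <- delta_pip[1]
  if (dx < -1e-9)
    stopf("planning error: target lies behind the pipette axis")
  lateral <- NULL
  if (sqrt(sum(delta_pip[2:3]^2)) > 1e-9)
    lateral <- c(0, delta_pip[2], delta_pip[3])
  hunt <- list()
  if (dx > 1e-9) {
    nfull <- floor(dx / cfg$step_um + 1e-9)
    steps <- rep(cfg$step_um, nfull)
    rem <- dx - nfull * cfg$step_um
    if (rem > 1e-9) steps <- c(steps, rem)
    hunt <- lapply(steps, function(s) c(s, 0, 0))
  }
  list(lateral = lateral, hunt = hunt, staging_um = staging,
       descent_step_pipette = stage_to_pipette(cal, c(0, 0, -cfg$step_um)))
}

#' Create an autopatching context
#'
#' Bundles the rig, configuration, calibration, target and event log that
#' the phase operations ([hunt_step()], [avoid_obstacle()],
#' [descend_to_cell()], [form_seal()], [break_in()]) thread through.
#'
#' @param rig a `patch_rig`.
#' @param cfg a [patch_config].
#' @param cal a [calibration_transform] (defaults to the rig's true matrix,
#'   as after a perfect calibration run).
#' @param target_um target centroid (stage um).
#' @param tracker optional closure `function(rig) dxyz_um` returning the
#'   accumulated target drift estimate (see [sim_cell_tracker()]).
#' @return An `autopatch_context` list.
#' @export
autopatch_context <- function(rig, cfg, target_um,
                              cal = calibration_transform(rig$calibration),
                              tracker = NULL) {
  stopifnot(inherits(rig, "patch_rig"), inherits(cfg, "patch_config"))
  ctx <- list(rig = rig, cfg = cfg, cal = cal,
              target0_um = as.numeric(target_um),
              target_um = as.numeric(target_um),
              tracker = tracker, plan = NULL, hunt_index = 0L,
              reads = numeric(), log = list(), outcome = NA_character_,
              Rs_Mohm = NA_real_)
  ctx_log(ctx, "attempt_start")
}

ctx_log <- function(ctx, event, ...) {
  s <- ctx$rig$state
  entry <- c(list(time_s = s$sim_time_s, phase = s$phase,
                  pressure_mbar = s$pressure_setpoint_mbar,
                  pressure_actual_mbar = s$pressure_actual_mbar,
                  resistance_Mohm = rig_read_resistance(ctx$rig),
                  event = event), list(...))
  ctx$log[[length(ctx$log) + 1]] <- entry
  ctx
}

ctx_elapse <- function(ctx, seconds) {
  n <- max(1L, round(seconds / ctx$cfg$dt_s))
  for (i in seq_len(n)) ctx$rig <- rig_step(ctx$rig, ctx$cfg$dt_s)
  ctx
}

ctx_track <- function(ctx, where) {
  if (is.null(ctx$tracker)) return(ctx)
  off <- ctx$tracker(ctx$rig)
  ctx$target_um <- ctx$target0_um + off
  ctx_log(ctx, "track_update", at = where, offset_x_um = off[1],
          offset_y_um = off[2], offset_z_um = off[3])
}

ctx_replan <- function(ctx) {
  ctx$plan <- plan_trajectory(ctx$cal, ctx$rig$state$tip_stage_um,
                              ctx$target_um, ctx$cfg)
  ctx$hunt_index <- 0L
  if (!is.null(ctx$plan$lateral)) {
    ctx$rig <- rig_move_pipette(ctx$rig, ctx$plan$lateral)
    ctx <- ctx_log(ctx, "lateral_preposition")
  }
  ctx
}

ctx_baseline <- function(ctx) {
  if (!length(ctx$reads)) return(rig_read_resistance(ctx$rig))
  mean(utils::tail(ctx$reads, 5))
}

#' Advance one hunting waypoint
#'
#' Moves one `step_um` along the pipette axis under hunting pressure, reads
#' the tip resistance and classifies the step as `clear`, `obstacle`,
#' `contact` (resistance jump with the target closer than 10 um laterally)
#' or `arrived`.
#'
#' @param ctx an `autopatch_context` with an active plan (from
#'   [plan_trajectory()]).
#' @return The updated context; `ctx$event` holds the classification.
#' @export
hunt_step <- function(ctx) {
  if (ctx$hunt_index >= length(ctx$plan$hunt)) {
    ctx$event <- "arrived"
    return(ctx_log(ctx, "arrived"))
  }
  ctx$hunt_index <- ctx$hunt_index + 1L
  ctx$rig <- rig_move_pipette(ctx$rig, ctx$plan$hunt[[ctx$hunt_index]])
  ctx <- ctx_elapse(ctx, ctx$cfg$dt_s)
  R <- rig_read_resistance(ctx$rig)
  base <- ctx_baseline(ctx)
  dR <- R - base
  tip <- ctx$rig$state$tip_stage_um
  lat <- sqrt(sum((tip[1:2] - ctx$target_um[1:2])^2))
  if (dR >= ctx$cfg$obstacle_threshold_Mohm && lat > 10) {
    ctx$event <- "obstacle"
    return(ctx_log(ctx, "obstacle_hit", delta_R_Mohm = dR))
  }
  if (dR >= ctx$cfg$contact_threshold_Mohm && lat <= 10) {
    ctx$event <- "contact"
    return(ctx_log(ctx, "early_contact", delta_R_Mohm = dR))
  }
  ctx$reads <- c(ctx$reads, R)
  ctx$event <- "clear"
  ctx_log(ctx, "hunt_step")
}

#' Bypass an obstacle on the trajectory
#'
#' Executes the numbered avoidance manoeuvre: (1) the obstacle was hit on
#' the trajectory, (2) pull back, (3) probe lateral offsets on a growing
#' Archimedean spiral until the resistance returns to baseline, (4) advance
#' past the obstacle depth at that offset, (5) return to the trajectory,
#' (6) resume approaching. Exhausting the spiral radius yields
#' `OBSTACLE_FAIL`.
#'
#' @param ctx context whose last event was `obstacle`.
#' @return The updated context; `ctx$event` is `passed` or `failed`.
#' @export
avoid_obstacle <- function(ctx) {
  cfg <- ctx$cfg
  base <- ctx_baseline(ctx)
  ctx <- ctx_log(ctx, "avoid_substep", substep = 1)   # obstacle on trajectory
  ctx$rig <- rig_move_pipette(ctx$rig, c(-cfg$pullback_um, 0, 0))
  ctx <- ctx_elapse(ctx, cfg$dt_s)
  ctx <- ctx_log(ctx, "avoid_substep", substep = 2)   # pulled back
  k <- 0
  offset <- NULL
  repeat {
    k <- k + 1
    r <- cfg$spiral_pitch_um * k / cfg$spiral_points_per_turn
    if (r > cfg$spiral_max_radius_um) {
      ctx$event <- "failed"
      ctx$outcome <- "OBSTACLE_FAIL"
      return(ctx_log(ctx, "avoid_failed", max_radius_um = r))
    }
    th <- 2 * pi * k / cfg$spiral_points_per_turn
    cand <- c(0, r * cos(th), r * sin(th))
    ctx$rig <- rig_move_pipette(ctx$rig, cand - (offset %||% c(0, 0, 0)))
    offset <- cand
    ctx <- ctx_elapse(ctx, cfg$dt_s)
    if (abs(rig_read_resistance(ctx$rig) - base) > 0.2) next
    # probe forward at this offset
    ctx <- ctx_log(ctx, "avoid_substep", substep = 3, radius_um = r)
    adv <- 0
    blocked <- FALSE
    while (adv < cfg$pullback_um + cfg$obstacle_pass_um) {
      step <- min(cfg$step_um, cfg$pullback_um + cfg$obstacle_pass_um - adv)
      ctx$rig <- rig_move_pipette(ctx$rig, c(step, 0, 0))
      adv <- adv + step
      ctx <- ctx_elapse(ctx, cfg$dt_s)
      if (rig_read_resistance(ctx$rig) - base >= cfg$obstacle_threshold_Mohm) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) {
      ctx <- ctx_log(ctx, "avoid_substep", substep = 4)   # obstacle passed
      break
    }
    ctx$rig <- rig_move_pipette(ctx$rig, c(-adv, 0, 0))   # retreat, widen
    ctx <- ctx_elapse(ctx, cfg$dt_s)
  }
  ctx$rig <- rig_move_pipette(ctx$rig, -offset)           # back to trajectory
  ctx <- ctx_elapse(ctx, cfg$dt_s)
  ctx <- ctx_log(ctx, "avoid_substep", substep = 5)
  ctx <- ctx_track(ctx, "after_avoidance")
  ctx <- ctx_replan(ctx)
  ctx <- ctx_log(ctx, "avoid_substep", substep = 6)       # approach resumes
  ctx$event <- "passed"
  ctx
}

#' Descend onto the cell and detect contact
#'
#' Lowers the pressure to the positioning value, then steps the tip down in
#' stage Z monitoring the test-pulse resistance; contact is a resistance
#' rise of at least the contact threshold over the baseline (mean of the
#' last 5 hunting reads). Travelling more than twice the staging offset
#' plus one cell diameter without contact is a missed-cell error.
#'
#' @param ctx context at the staging point.
#' @return The updated context; `ctx$event` is `contact`.
#' @export
descend_to_cell <- function(ctx) {
  cfg <- ctx$cfg
  ctx$rig <- rig_set_phase(ctx$rig, "DESCEND")
  ctx$rig <- rig_set_pressure(ctx$rig, cfg$position_pressure_mbar)
  ctx <- ctx_elapse(ctx, 5 * ctx$rig$tau_s)      # let the pressure settle
  base <- ctx_baseline(ctx)
  ctx <- ctx_log(ctx, "descend_start", baseline_Mohm = base)
  travelled <- 0
  limit <- 2 * cfg$above_cell_offset_um + cfg$cell_diameter_um
  while (travelled < limit) {
    ctx$rig <- rig_move_pipette(ctx$rig, ctx$plan$descent_step_pipette)
    travelled <- travelled + cfg$step_um
    ctx <- ctx_elapse(ctx, cfg$dt_s)
    R <- rig_read_resistance(ctx$rig)
    ctx <- ctx_log(ctx, "descend_step", delta_R_Mohm = R - base)
    if (R - base >= cfg$contact_threshold_Mohm) {
      ctx$event <- "contact"
      return(ctx_log(ctx, "contact", delta_R_Mohm = R - base))
    }
  }
  ctx$event <- "error"
  ctx$outcome <- "ERROR"
  ctx_log(ctx, "error",
          message = sprintf("missed cell: descended %g um without contact",
                            travelled))
}

seal_wait <- function(ctx, seconds, label) {
  cfg <- ctx$cfg
  t_end <- ctx$rig$state$sim_time_s + seconds
  while (ctx$rig$state$sim_time_s < t_end - 1e-9) {
    ctx$rig <- rig_step(ctx$rig, cfg$dt_s)
    # holding potential ramp: one step per second toward the target
    h <- ctx$rig$state$holding_mV
    if (h > cfg$holding_target_mV &&
        abs(ctx$rig$state$sim_time_s - round(ctx$rig$state$sim_time_s)) < cfg$dt_s / 2)
      ctx$rig <- rig_set_holding(ctx$rig,
                                 max(h + cfg$holding_step_mV,
                                     cfg$holding_target_mV))
    if (rig_read_resistance(ctx$rig) >= cfg$gigaseal_Mohm) {
      ctx$sealed <- TRUE
      return(ctx_log(ctx, "gigaseal", during = label))
    }
  }
  ctx
}

#' Form a gigaseal on the contacted cell
#'
#' Pressure is ceased immediately at contact, then the seal suction is
#' applied while the holding potential ramps stepwise to its target. If
#' 1 GOhm is not reached within the deadline, escalation stages run in
#' fixed order: suction x1.5 for 20 s, x2 for 20 s, +/-2 um wiggle on each
#' axis (2 s per axis), pressure release for 10 s, reapplication for 20 s.
#'
#' @param ctx context whose last event was `contact`.
#' @return The updated context; `ctx$event` is `gigaseal` or `seal_fail`.
#' @export
form_seal <- function(ctx) {
  cfg <- ctx$cfg
  ctx$rig <- rig_set_phase(ctx$rig, "SEAL")
  ctx$rig <- rig_set_pressure(ctx$rig, 0)       # immediate cease of pressure
  ctx$sealed <- FALSE
  ctx <- ctx_log(ctx, "seal_start")
  ctx <- seal_wait(ctx, 1, "cease")
  if (!ctx$sealed) {
    ctx$rig <- rig_set_pressure(ctx$rig, cfg$seal_pressure_mbar)
    ctx <- ctx_log(ctx, "seal_suction")
    ctx <- seal_wait(ctx, cfg$seal_deadline_s, "base")
  }
  if (!ctx$sealed) {
    for (mult in c(1.5, 2)) {
      ctx$rig <- rig_set_pressure(ctx$rig, mult * cfg$seal_pressure_mbar)
      ctx <- ctx_log(ctx, "seal_escalation", stage = sprintf("vacuum_x%g", mult))
      ctx <- seal_wait(ctx, 20, sprintf("vacuum_x%g", mult))
      if (ctx$sealed) break
    }
  }
  if (!ctx$sealed) {
    for (axis in 1:3) {
      wig <- c(0, 0, 0); wig[axis] <- 2
      ctx$rig <- rig_move_pipette(ctx$rig, wig)
      ctx <- ctx_log(ctx, "seal_escalation", stage = sprintf("wiggle_axis%d", axis))
      ctx <- seal_wait(ctx, 1, "wiggle")
      ctx$rig <- rig_move_pipette(ctx$rig, -wig)
      ctx <- seal_wait(ctx, 1, "wiggle")
      if (ctx$sealed) break
    }
  }
  if (!ctx$sealed) {
    ctx$rig <- rig_set_pressure(ctx$rig, 0)
    ctx <- ctx_log(ctx, "seal_escalation", stage = "release")
    ctx <- seal_wait(ctx, 10, "release")
  }
  if (!ctx$sealed) {
    ctx$rig <- rig_set_pressure(ctx$rig, cfg$seal_pressure_mbar)
    ctx <- ctx_log(ctx, "seal_escalation", stage = "reapply")
    ctx <- seal_wait(ctx, 20, "reapply")
  }
  if (ctx$sealed) {
    ctx$event <- "gigaseal"
  } else {
    ctx$event <- "seal_fail"
    ctx$outcome <- "SEAL_FAIL"
    ctx$rig <- rig_set_phase(ctx$rig, "FAIL")
    ctx <- ctx_log(ctx, "seal_fail")
  }
  ctx
}

#' Break into the cell with suction pulses
#'
#' Pulse `k` lasts `0.5 + 0.2 k` seconds at the break-in pressure with a
#' pause between pulses, for at most the configured timeout. Success is
#' membrane rupture; the series resistance is then recorded.
#'
#' @param ctx context after a gigaseal.
#' @return The updated context; `ctx$event` is `whole_cell` or
#'   `breakin_fail`.
#' @export
break_in <- function(ctx) {
  cfg <- ctx$cfg
  ctx$rig <- rig_set_phase(ctx$rig, "BREAKIN")
  t_start <- ctx$rig$state$sim_time_s
  ctx <- ctx_log(ctx, "breakin_start")
  attempt <- 0
  repeat {
    attempt <- attempt + 1
    dur <- 0.5 + 0.2 * attempt
    elapsed <- ctx$rig$state$sim_time_s - t_start
    if (elapsed + dur > cfg$breakin_timeout_s) {
      ctx$event <- "breakin_fail"
      ctx$outcome <- "BREAKIN_FAIL"
      ctx$rig <- rig_set_phase(ctx$rig, "FAIL")
      return(ctx_log(ctx, "breakin_fail", attempts = attempt - 1))
    }
    ctx$rig <- rig_set_pressure(ctx$rig, cfg$breakin_pressure_mbar)
    ctx <- ctx_log(ctx, "breakin_pulse", attempt = attempt,
                   duration_s = dur)
    t_end <- ctx$rig$state$sim_time_s + dur
    while (ctx$rig$state$sim_time_s < t_end - 1e-9) {
      ctx$rig <- rig_step(ctx$rig, cfg$dt_s)
      if (ctx$rig$state$ruptured) break
    }
    ctx$rig <- rig_set_pressure(ctx$rig, 0)
    ctx <- ctx_log(ctx, "breakin_pause", attempt = attempt)
    if (!ctx$rig$state$ruptured) ctx <- ctx_elapse(ctx, cfg$interpulse_pause_s)
    if (ctx$rig$state$ruptured) {
      ctx$Rs_Mohm <- rig_read_resistance(ctx$rig)
      ctx$rig <- rig_set_phase(ctx$rig, "WHOLE_CELL")
      ctx$event <- "whole_cell"
      return(ctx_log(ctx, "whole_cell", Rs_Mohm = ctx$Rs_Mohm))
    }
  }
}

#' Clean the pipette in detergent and aCSF baths
#'
#' Alconox bath: -300 mbar suction for 4 s, five alternations of
#' +1000 / -300 mbar (1 s each), then +1000 mbar expulsion for 10 s.
#' aCSF bath: +1000 mbar for 10 s. The pipette then returns to its start
#' position. Pressure setpoints never leave {-300, 0, +1000} mbar.
#'
#' @param ctx an `autopatch_context` whose config carries calibrated
#'   `alconox_bath_um` and `acsf_bath_um` stage positions.
#' @return The updated context.
#' @export
clean_pipette <- function(ctx) {
  cfg <- ctx$cfg
  if (is.null(cfg$alconox_bath_um) || is.null(cfg$acsf_bath_um))
    stopf("configuration error: cleaning bath positions are not calibrated")
  ctx$rig <- rig_set_phase(ctx$rig, "CLEAN")
  start_um <- ctx$rig$state$tip_stage_um
  goto <- function(ctx, stage_pos) {
    delta <- stage_to_pipette(ctx$cal, as.numeric(stage_pos) -
                                ctx$rig$state$tip_stage_um)
    ctx$rig <- rig_move_pipette(ctx$rig, delta)
    ctx_elapse(ctx, 1)
  }
  press <- function(ctx, mbar, secs) {
    ctx$rig <- rig_set_pressure(ctx$rig, mbar)
    ctx <- ctx_log(ctx, "clean_pressure", mbar = mbar, duration_s = secs)
    ctx_elapse(ctx, secs)
  }
  ctx <- goto(ctx, cfg$alconox_bath_um)
  ctx <- ctx_log(ctx, "clean_bath", bath = "alconox")
  ctx <- press(ctx, -300, 4)
  for (i in 1:5) {
    ctx <- press(ctx, 1000, 1)
    ctx <- press(ctx, -300, 1)
  }
  ctx <- press(ctx, 1000, 10)
  ctx <- goto(ctx, cfg$acsf_bath_um)
  ctx <- ctx_log(ctx, "clean_bath", bath = "acsf")
  ctx <- press(ctx, 1000, 10)
  ctx$rig <- rig_set_pressure(ctx$rig, 0)
  ctx <- goto(ctx, start_um)
  ctx <- ctx_log(ctx, "clean_done")
  ctx
}

#' Harvest the cytoplasm after whole-cell access
#'
#' Gentle suction sequence: -40 mbar for 60 s, -60 mbar for the configured
#' middle duration (default 150 s), then -40 mbar for 60 s.
#'
#' @param ctx an `autopatch_context` in the WHOLE_CELL phase.
#' @return The updated context.
#' @export
harvest_cytoplasm <- function(ctx) {
  if (ctx$rig$state$phase != "WHOLE_CELL")
    stopf("state error: harvesting requires the WHOLE_CELL phase (now %s)",
          ctx$rig$state$phase)
  stages <- list(c(-40, 60), c(-60, ctx$cfg$harvest_mid_s), c(-40, 60))
  for (st in stages) {
    ctx$rig <- rig_set_pressure(ctx$rig, st[1])
    ctx <- ctx_log(ctx, "harvest_stage", mbar = st[1], duration_s = st[2])
    ctx <- ctx_elapse(ctx, st[2])
  }
  ctx$rig <- rig_set_pressure(ctx$rig, 0)
  ctx_log(ctx, "harvest_done")
}

ctx_record <- function(ctx) {
  log_df <- do.call(rbind, lapply(ctx$log, function(e)
    data.frame(time_s = e$time_s, phase = e$phase,
               pressure_mbar = e$pressure_mbar,
               pressure_actual_mbar = e$pressure_actual_mbar,
               resistance_Mohm = e$resistance_Mohm, event = e$event,
               detail = paste(vapply(e[setdiff(names(e),
                 c("time_s", "phase", "pressure_mbar", "pressure_actual_mbar",
                   "resistance_Mohm", "event"))],
                 function(v) paste(format(v), collapse = ","), character(1)),
                 collapse = ";"),
               stringsAsFactors = FALSE)))
  structure(list(target_um = ctx$target0_um, outcome = ctx$outcome,
                 Rs_Mohm = ctx$Rs_Mohm, phase_log = log_df),
            class = "patch_attempt_record")
}

#' @export
print.patch_attempt_record <- function(x, ...) {
  cat(sprintf("patch attempt -> %s%s | %d events, %.1f s simulated\n",
              x$outcome,
              if (is.finite(x$Rs_Mohm %||% NA_real_))
                sprintf(" (Rs %.1f MOhm)", x$Rs_Mohm) else "",
              nrow(x$phase_log), max(x$phase_log$time_s)))
  invisible(x)
}

#' Run one complete automated patch attempt
#'
#' Orchestrates plan -> hunt (with tracking compensation at halts and
#' obstacle avoidance) -> descend -> seal -> break-in on the simulated rig
#' and returns the full attempt record. A successful `WHOLE_CELL` outcome
#' additionally requires the recorded series resistance to stay at or
#' below `fail_Rs_Mohm`.
#'
#' @param rig a `patch_rig`.
#' @param target_um target centroid (stage um), e.g. one row of
#'   [rank_detections()] output.
#' @param cfg a [patch_config].
#' @param cal calibration (defaults to the rig's true matrix).
#' @param tracker optional drift tracker, see [sim_cell_tracker()].
#' @return A `patch_attempt_record`.
#' @export
run_autopatch <- function(rig, target_um, cfg = patch_config(),
                          cal = calibration_transform(rig$calibration),
                          tracker = NULL) {
  ctx <- autopatch_context(rig, cfg, target_um, cal, tracker)
  res <- tryCatch(run_attempt(ctx), error = function(e) {
    c2 <- ctx_log(ctx, "error", message = conditionMessage(e))
    c2$outcome <- "ERROR"
    c2
  })
  if (is.na(res$outcome)) res$outcome <- "ERROR"
  ctx_record(res)
}

run_attempt <- function(ctx) {
  cfg <- ctx$cfg
  ctx$rig <- rig_set_phase(ctx$rig, "HUNT")
  ctx$rig <- rig_set_pressure(ctx$rig, cfg$hunt_pressure_mbar)
  ctx <- ctx_elapse(ctx, 5 * ctx$rig$tau_s)
  ctx <- ctx_track(ctx, "start")
  ctx <- ctx_replan(ctx)
  guard <- 0
  staged <- FALSE
  repeat {
    guard <- guard + 1
    if (guard > 10000) stopf("controller did not terminate")
    ctx <- hunt_step(ctx)
    if (ctx$event == "clear") next
    if (ctx$event == "obstacle") {
      ctx <- avoid_obstacle(ctx)
      if (ctx$event == "failed") return(ctx)
      next
    }
    if (ctx$event == "arrived" && !staged) {
      # halt at the staging point: one tracking update, then re-plan the
      # (short) residual approach toward the possibly drifted target
      staged <- TRUE
      ctx <- ctx_track(ctx, "staging")
      ctx <- ctx_replan(ctx)
      next
    }
    break   # final arrival or early contact
  }
  if (ctx$event == "arrived") ctx <- descend_to_cell(ctx)
  if (ctx$event == "error") return(ctx)
  ctx <- form_seal(ctx)
  if (ctx$event != "gigaseal") return(ctx)
  ctx <- break_in(ctx)
  if (ctx$event != "whole_cell") return(ctx)
  if (ctx$Rs_Mohm <= cfg$fail_Rs_Mohm) {
    ctx$outcome <- "WHOLE_CELL"
  } else {
    ctx$outcome <- "BREAKIN_FAIL"   # access too poor to count as success
    ctx <- ctx_log(ctx, "rs_reject", Rs_Mohm = ctx$Rs_Mohm)
  }
  ctx
}
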