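# Planar lifting-trial generator.
#
# One trial = quiet standing, minimum-jerk trunk flexion down to a shelf-
# height-dependent peak angle, a grasp dwell (the box attaches mid-dwell),
# minimum-jerk ascent carrying the box, and a final standing hold. The
# ground-truth lumbar extension moment, ground reaction forces and centre of
# pressure are generated mutually consistently from the same kinematics, so
# top-down and bottom-up moment computations agree by construction.

min_jerk <- function(tau) {
  # position, velocity, acceleration of the unit minimum-jerk profile
  list(
    s = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
    v = 30 * tau^2 - 60 * tau^3 + 30 * tau^4,
    a = 60 * tau - 180 * tau^2 + 120 * tau^3
  )
}

# piecewise trunk-flexion trajectory in degrees; returns angle and its two
# analytic time derivatives on the sample grid
flexion_trajectory <- function(time, theta_peak, t1, t_desc, t_dwell, t_asc) {
  t2 <- t1 + t_desc
  t3 <- t2 + t_dwell
  t4 <- t3 + t_asc
  th <- numeric(length(time))
  thd <- numeric(length(time))
  thdd <- numeric(length(time))
  desc <- time >= t1 & time < t2
  dwell <- time >= t2 & time < t3
  asc <- time >= t3 & time < t4
  tau <- (time[desc] - t1) / t_desc
  mj <- min_jerk(tau)
  th[desc] <- theta_peak * mj$s
  thd[desc] <- theta_peak * mj$v / t_desc
  thdd[desc] <- theta_peak * mj$a / t_desc^2
  th[dwell] <- theta_peak
  tau <- (time[asc] - t3) / t_asc
  mj <- min_jerk(tau)
  th[asc] <- theta_peak * (1 - mj$s)
  thd[asc] <- -theta_peak * mj$v / t_asc
  thdd[asc] <- -theta_peak * mj$a / t_asc^2
  list(theta = th, theta_dot = thd, theta_ddot = thdd,
       t_bounds = c(t1, t2, t3, t4))
}

#' Simulate a single lifting trial
#'
#' Generates one symmetric lift of `task$box_mass` kg from a shelf at
#' `task$origin_height` cm by the given participant. The sagittal trunk
#' trajectory is minimum-jerk; the peak flexion angle decreases linearly with
#' shelf height between `sim$flexion_at_low` and `sim$flexion_at_high`
#' degrees. The box attaches to the hands mid-dwell and is carried through
#' the ascent and final hold; in default mode it is co-located with the HAT
#' centre of mass, in the sensitivity mode (`sim$box_at_hands = TRUE`) it
#' sits `sim$hand_offset` m anterior of it.
#'
#' The ground-truth lumbar extension moment about a fixed L5/S1 pivot is
#' `I_pivot * alpha + m_hat * (g * x - xddot * z)` plus the analogous box
#' terms while the box is held, where `(x, z)` is the HAT-COM position
#' relative to the pivot and `alpha` the flexion-positive trunk angular
#' acceleration. With this convention the inertial terms vanish during the
#' grasp dwell and dip below the static value during the accelerating
#' transients, so the trial peak is the quasi-static deep-flexion hold (see
#' the methods vignette for why this form is preferred here).
#'
#' Total vertical ground force carries the supported weight plus the vertical
#' inertia of the HAT (+box); it is split between the feet by a seeded
#' asymmetry factor. The centre of pressure is placed by the moment balance
#' about the pivot (quasi-statically, the whole-body COM projection) plus
#' seeded noise. Trunk channels are exact analytic derivatives of the
#' generated kinematics, gravity-free, evaluated at a trunk-mounted point
#' `profile$imu_distance` m from the pivot. Per-lift style variability
#' (flexion jitter, tempo jitter, a multiplicative "reach" factor on the
#' HAT-COM horizontal arm) and all noise are drawn from `seed`; box mass
#' never enters the kinematics, so trials differing only in box mass share
#' identical trunk channels for the same seed.
#'
#' @param profile an [anthro_profile()].
#' @param task one row of [build_task_grid()] (or a list with `task_id`,
#'   `box_mass`, `origin_height`).
#' @param config a [default_config()] list.
#' @param seed integer seed for this trial's style and noise draws.
#' @param repetition repetition index recorded in the trial metadata.
#' @return A `lift_trial` data frame (one row per sample at `sim$fs` Hz) with
#'   idealized wearable channels (`trunk_angle_*`, `trunk_acc_*`,
#'   `trunk_angvel_*`, `foot_force_*`, `cop_ap_*`, `cop_ml_*`), laboratory
#'   channels (`grf_*`, `cop_global_*`, `arm_truth`), the ground truth
#'   `lumbar_moment_truth` (Nm) and `hold_mask`; trial metadata is attached
#'   as attributes (`box_mass`, `theta_peak_deg`, `arm_peak`, `m_hat`, ...).
#' @export
#' @examples
#' p <- anthro_profile(1, 80, 1.75)
#' task <- build_task_grid(n_masses = 1, n_heights = 1)[1, ]
#' tr <- simulate_lift(p, task, default_config(), seed = 1)
#' max(tr$lumbar_moment_truth) > 0
simulate_lift <- function(profile, task, config = default_config(), seed = 1L,
                          repetition = 1L) {
  stopifnot(inherits(profile, "anthro_profile"))
  sim <- config$sim
  g <- GRAVITY
  if (task$box_mass < 0) stop_config("box_mass must be >= 0")
  dt <- 1 / sim$fs
  for (ph in c("pad_start", "descent", "dwell", "ascent", "pad_end")) {
    if (sim[[ph]] < 2 * dt) {
      stop_config("phase '%s' (%.3f s) too short for sampling rate %g Hz",
                  ph, sim[[ph]], sim$fs)
    }
  }

  # --- seeded per-trial style and noise draws (order fixed; independent of
  #     box mass so kinematics match across box masses for the same seed)
  set.seed(derive_seed(seed, 17L))
  rep_flex <- rnorm_trunc(1, 0, sim$rep_flexion_sd, trunc = 2)
  rep_speed <- rnorm_trunc(1, 1, sim$rep_speed_sd, trunc = 2)
  reach <- runif(1, 1 - sim$reach_halfwidth, 1 + sim$reach_halfwidth)
  split <- rnorm_trunc(1, 0.5, sim$split_sd, trunc = 2)
  offax <- replicate(2, list(
    amp = runif(2, 0, sim$offaxis_angle_sd),
    freq = runif(2, 0.3, 1.2),
    phase = runif(2, 0, 2 * pi)
  ), simplify = FALSE)

  # --- peak flexion from shelf height
  hr <- config$tasks$height_range
  frac <- if (diff(hr) == 0) 0.5 else (task$origin_height - hr[1]) / diff(hr)
  theta_peak <- sim$flexion_at_low + frac * (sim$flexion_at_high - sim$flexion_at_low) +
    profile$style_flexion_offset + rep_flex
  if (theta_peak < 0 || theta_peak > 135) {
    stop_config("peak flexion mapping gave %.1f deg, outside [0, 135]", theta_peak)
  }

  speed <- profile$style_speed_factor * rep_speed
  t_desc <- sim$descent / speed
  t_dwell <- sim$dwell
  t_asc <- sim$ascent / speed
  t_total <- sim$pad_start + t_desc + t_dwell + t_asc + sim$pad_end
  time <- seq(0, t_total, by = dt)
  n <- length(time)

  traj <- flexion_trajectory(time, theta_peak, sim$pad_start,
                             t_desc, t_dwell, t_asc)
  t_grasp <- sim$pad_start + t_desc + t_dwell / 2
  hold <- time >= t_grasp

  # radians for dynamics
  th <- traj$theta * pi / 180
  thd <- traj$theta_dot * pi / 180
  thdd <- traj$theta_ddot * pi / 180

  d_eff <- reach * profile$hat_com_distance
  x_h <- d_eff * sin(th)
  z_h <- d_eff * cos(th)
  xdd_h <- d_eff * (thdd * cos(th) - thd^2 * sin(th))
  zdd_h <- -d_eff * (thdd * sin(th) + thd^2 * cos(th))

  if (isTRUE(sim$box_at_hands)) {
    x_b <- x_h + sim$hand_offset
    z_b <- z_h
  } else {
    x_b <- x_h
    z_b <- z_h
  }
  xdd_b <- xdd_h
  zdd_b <- zdd_h

  m_hat <- profile$hat_mass
  m_box <- task$box_mass
  moment <- profile$hat_inertia_pivot * thdd +
    m_hat * (g * x_h - xdd_h * z_h) +
    ifelse(hold, m_box * (g * x_b - xdd_b * z_b), 0)

  fz <- profile$body_mass * g + ifelse(hold, m_box, 0) * g +
    m_hat * zdd_h + ifelse(hold, m_box, 0) * zdd_b
  fx <- m_hat * xdd_h + ifelse(hold, m_box, 0) * xdd_b
  x_cop <- (moment + fx * profile$pivot_height) / fz

  # wearable trunk point (fixed on the trunk, unaffected by reach)
  r_imu <- profile$imu_distance
  acc_ap <- r_imu * (thdd * cos(th) - thd^2 * sin(th))
  acc_vert <- -r_imu * (thdd * sin(th) + thd^2 * cos(th))

  sinusoid <- function(par) {
    ang <- par$amp[1] * sin(2 * pi * par$freq[1] * time + par$phase[1]) +
      par$amp[2] * sin(2 * pi * par$freq[2] * time + par$phase[2])
    vel <- par$amp[1] * 2 * pi * par$freq[1] * cos(2 * pi * par$freq[1] * time + par$phase[1]) +
      par$amp[2] * 2 * pi * par$freq[2] * cos(2 * pi * par$freq[2] * time + par$phase[2])
    list(ang = ang, vel = vel)
  }
  lat <- sinusoid(offax[[1]])
  twi <- sinusoid(offax[[2]])

  # per-foot laboratory signals; feet flat, long axes along global +x
  fz_l <- split * fz
  fz_r <- (1 - split) * fz
  fx_l <- split * fx
  fx_r <- (1 - split) * fx
  cop_noise <- matrix(rnorm(4L * n, 0, sim$cop_sd), ncol = 4L)

  pose_l <- foot_pose(origin = c(0, sim$foot_ml_offset, 0))
  pose_r <- foot_pose(origin = c(0, -sim$foot_ml_offset, 0))
  grf_l <- cbind(fx_l, 0, fz_l)
  grf_r <- cbind(fx_r, 0, fz_r)
  cop_l <- transform_cop_to_foot_frame(
    cbind(x_cop, sim$foot_ml_offset, 0), pose_l)
  cop_r <- transform_cop_to_foot_frame(
    cbind(x_cop, -sim$foot_ml_offset, 0), pose_r)

  trial <- data.frame(
    time = time,
    trunk_angle_flexion = traj$theta,
    trunk_angle_lateral = lat$ang,
    trunk_angle_twist = twi$ang,
    trunk_acc_ap = acc_ap,
    trunk_acc_ml = 0,
    trunk_acc_vert = acc_vert,
    trunk_angvel_flexion = traj$theta_dot,
    trunk_angvel_lateral = lat$vel,
    trunk_angvel_twist = twi$vel,
    foot_force_left = project_grf_to_foot_normal(grf_l, pose_l),
    foot_force_right = project_grf_to_foot_normal(grf_r, pose_r),
    cop_ap_left = cop_l[, 1] + cop_noise[, 1],
    cop_ml_left = cop_l[, 2] + cop_noise[, 2],
    cop_ap_right = cop_r[, 1] + cop_noise[, 3],
    cop_ml_right = cop_r[, 2] + cop_noise[, 4],
    grf_left_x = fx_l, grf_left_y = 0, grf_left_z = fz_l,
    grf_right_x = fx_r, grf_right_y = 0, grf_right_z = fz_r,
    cop_global_x = x_cop, cop_global_y = 0,
    arm_truth = x_h,
    lumbar_moment_truth = moment,
    hold_mask = hold
  )
  structure(trial,
    class = c("lift_trial", "data.frame"),
    participant_id = profile$participant_id,
    task_id = as.integer(task$task_id),
    repetition = as.integer(repetition),
    box_mass = m_box,
    origin_height = task$origin_height,
    trial_seed = as.integer(seed),
    fs = sim$fs,
    box_at_hands = isTRUE(sim$box_at_hands),
    reach_factor = reach,
    theta_peak_deg = theta_peak,
    arm_peak = d_eff * sin(theta_peak * pi / 180),
    grasp_time = t_grasp,
    m_hat = m_hat,
    hat_com_distance = profile$hat_com_distance,
    hat_inertia_pivot = profile$hat_inertia_pivot,
    body_mass = profile$body_mass,
    pivot_height = profile$pivot_height
  )
}

trial_id <- function(trial) {
  sprintf("P%02d_T%03d_R%02d", attr(trial, "participant_id"),
          attr(trial, "task_id"), attr(trial, "repetition"))
}

#' Generate a full trial collection with manifest
#'
#' One trial per (participant, task, repetition), each with its own RNG
#' substream derived from `seed`, so the collection is reproducible and
#' insensitive to generation order. When `out_dir` is given, every trial is
#' written as a CSV (one header-named column per channel) together with
#' `manifest.csv` and `profiles.csv`.
#'
#' @param profiles list of [anthro_profile()] (e.g. [sample_participants()]).
#' @param tasks data.frame from [build_task_grid()].
#' @param config a [default_config()] list.
#' @param seed master integer seed.
#' @param out_dir optional output directory.
#' @return List with `trials` (named list of `lift_trial`), `manifest`
#'   (data.frame), `profiles`, and `config`.
#' @export
generate_dataset <- function(profiles, tasks, config = default_config(),
                             seed = 1L, out_dir = NULL) {
  trials <- list()
  rows <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop_config("cannot create output directory: %s", out_dir)
    }
  }
  for (p in profiles) {
    for (ti in seq_len(nrow(tasks))) {
      task <- tasks[ti, ]
      for (r in seq_len(task$repetitions)) {
        tseed <- derive_seed(seed, p$participant_id, task$task_id, r)
        tr <- simulate_lift(p, task, config, seed = tseed, repetition = r)
        id <- trial_id(tr)
        trials[[id]] <- tr
        path <- NA_character_
        if (!is.null(out_dir)) {
          path <- file.path(out_dir, paste0(id, ".csv"))
          utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
        }
        rows[[id]] <- data.frame(
          trial_id = id,
          participant_id = p$participant_id,
          task_id = task$task_id,
          repetition = r,
          box_mass_kg = task$box_mass,
          origin_height_cm = task$origin_height,
          trial_seed = tseed,
          n_samples = nrow(tr),
          theta_peak_deg = attr(tr, "theta_peak_deg"),
          arm_peak_m = attr(tr, "arm_peak"),
          reach_factor = attr(tr, "reach_factor"),
          peak_lumbar_truth = max(tr$lumbar_moment_truth),
          file = path
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(profiles_table(profiles),
                     file.path(out_dir, "profiles.csv"), row.names = FALSE)
  }
  list(trials = trials, manifest = manifest, profiles = profiles,
       config = config)
}

#' Bottom-up lumbar moment from ground forces
#'
#' Recomputes the lumbar extension moment from the generated ground reaction
#' forces and foot geometry: the moment of the ground reaction about the
#' L5/S1 pivot (force-weighted centre of pressure times vertical force, minus
#' the shear force times pivot height). With noise-free signals this agrees
#' with the top-down `lumbar_moment_truth` to machine precision; with default
#' COP noise the discrepancy is of order force x noise.
#'
#' @param trial a `lift_trial`.
#' @return numeric vector, Nm, same length as the trial.
#' @export
bottom_up_lumbar_moment <- function(trial) {
  fz <- trial$grf_left_z + trial$grf_right_z
  fx <- trial$grf_left_x + trial$grf_right_x
  x_cop <- (trial$grf_left_z * trial$cop_ap_left +
              trial$grf_right_z * trial$cop_ap_right) / fz
  fz * x_cop - fx * attr(trial, "pivot_height")
}
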