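#' Default run configuration
#'
#' Returns the nested list of parameters controlling every stage of the
#' pipeline. Any subset can be overridden via `...` (named top-level sections
#' replaced element-wise), or by editing a YAML file written with
#' [write_config()].
#'
#' Sections and notable defaults:
#'
#' * `participants`: `n = 10` simulated workers; body mass drawn uniformly
#'   from `body_mass` (kg), stature from `stature` (m). The head-arms-trunk
#'   (HAT) segment carries `hat_mass_fraction = 0.678` of body mass, its
#'   centre of mass sits `hat_com_frac = 0.17` of stature anterior/superior of
#'   the L5/S1 pivot, and its inertia is that of a rectangular prism of height
#'   `prism_height_frac * stature` and depth `prism_depth` m.
#' * `tasks`: `n_masses x n_heights` grid spanning `mass_range` kg and
#'   `height_range` cm (defaults give the 50-task grid), `repetitions` lifts
#'   of each task per participant.
#' * `sim`: sampling rate `fs` (Hz), phase durations (s) for quiet standing,
#'   minimum-jerk descent, grasp dwell, ascent and final hold; the linear
#'   peak-flexion mapping from shelf height (`flexion_at_low` degrees at the
#'   low end of `height_range`, `flexion_at_high` at the high end); noise
#'   terms (off-axis angle sinusoids, left/right force split, COP noise,
#'   per-lift reach variability of the HAT-COM horizontal arm); and the
#'   box-at-hands sensitivity mode.
#' * `estimator`: gradient-boosted tree hyperparameters (`nrounds = 100`,
#'   `eta = 0.1`, `max_depth = 3`) and the training-sample threshold
#'   `threshold = 100` Nm on the target lumbar moment.
#' * `workday`: `n_days = 1000` simulated workdays per participant, lift
#'   count uniform on `lift_range = c(800, 2000)`, lift-counter nominal load
#'   moment `nominal_moment = 75` Nm, `moment_type` either `"load"` (default)
#'   or `"lumbar"`, and the damage-equation grouping `eq4_grouping`
#'   (`"exponent_inclusive"` or `"additive_constant"`).
#' * `evaluation`: agreement band in absolute risk percentage points
#'   (`band = 10`).
#'
#' @param ... named overrides, e.g. `workday = list(n_days = 50)`.
#' @return A list of class `liftrisk_config`.
#' @export
#' @examples
#' cfg <- default_config(participants = list(n_participants = 3),
#'                       workday = list(n_days = 50))
#' cfg$participants$n_participants
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    participants = list(
      n_participants = 10L,
      body_mass = c(75, 85),          # kg
      stature = c(1.70, 1.85),        # m
      hat_mass_fraction = 0.678,
      hat_com_frac = 0.17,            # of stature, pivot -> HAT COM
      prism_height_frac = 0.6 / 1.75, # of stature
      prism_depth = 0.20,             # m
      pivot_height_frac = 0.60,       # of stature, ground -> L5/S1
      imu_frac = 0.60,                # of trunk length, pivot -> IMU
      speed_factor = c(0.9, 1.1),     # per-participant lifting tempo
      flexion_offset_sd = 2           # deg, per-participant style offset
    ),
    tasks = list(
      mass_range = c(5, 23),          # kg
      height_range = c(40, 160),      # cm
      n_masses = 5L,
      n_heights = 10L,
      repetitions = 2L
    ),
    sim = list(
      fs = 100,                       # Hz
      pad_start = 0.4,                # s quiet standing
      descent = 1.6,                  # s (divided by speed factor)
      dwell = 0.8,                    # s grasp dwell at peak flexion
      ascent = 1.8,                   # s
      pad_end = 0.6,                  # s standing hold with box
      flexion_at_low = 80,            # deg at height_range[1]
      flexion_at_high = 25,           # deg at height_range[2]
      rep_flexion_sd = 1.5,           # deg, per-lift jitter (truncated 2 sd)
      rep_speed_sd = 0.05,            # per-lift tempo jitter
      reach_halfwidth = 0.45,         # per-lift uniform HAT-arm (load position) factor
      offaxis_angle_sd = 1.0,         # deg, lateral-bend / twist sinusoids
      split_sd = 0.05,                # left/right force share about 0.5
      cop_sd = 0.005,                 # m, additive COP noise
      foot_ml_offset = 0.15,          # m, foot centres from midline
      box_at_hands = FALSE,
      hand_offset = 0.25              # m anterior of HAT COM (sensitivity mode)
    ),
    estimator = list(
      nrounds = 100L,
      eta = 0.1,
      max_depth = 3L,
      min_child_weight = 50,          # per-leaf Hessian floor (regularization)
      smooth_window = 0.3,            # s, moving average on predicted series
      threshold = 100                 # Nm, strict > filter on training target
    ),
    workday = list(
      n_days = 1000L,
      lift_range = c(800L, 2000L),
      nominal_moment = 75,            # Nm, lift-counter baseline
      moment_type = "load",           # or "lumbar"
      eq4_grouping = "exponent_inclusive"
    ),
    evaluation = list(
      band = 10                       # absolute risk percentage points
    )
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "liftrisk_config"
  validate_config(cfg)
  cfg
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg$sim, {
    for (d in c(pad_start, descent, dwell, ascent, pad_end)) {
      check_number(d, "phase duration", lower = 1e-6)
    }
    check_number(fs, "fs", lower = 1e-6)
  })
  if (diff(cfg$tasks$mass_range) < 0 || diff(cfg$tasks$height_range) < 0) {
    stop_config("task mass/height ranges must be non-decreasing")
  }
  if (!cfg$workday$moment_type %in% c("load", "lumbar")) {
    stop_config("moment_type must be 'load' or 'lumbar'")
  }
  if (!cfg$workday$eq4_grouping %in% c("exponent_inclusive", "additive_constant")) {
    stop_config("eq4_grouping must be 'exponent_inclusive' or 'additive_constant'")
  }
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a `liftrisk_config` list.
#' @return `read_config()` returns a `liftrisk_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Short deterministic hash of a configuration
#'
#' FNV-1a over the canonical JSON serialization; recorded in every output
#' file so downstream artifacts can be traced to the exact configuration.
#'
#' @param cfg a `liftrisk_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
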