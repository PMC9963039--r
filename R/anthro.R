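#' Anthropometric profile of a simulated participant
#'
#' Builds the head-arms-trunk (HAT) rigid-segment parameters used by the
#' planar lifting model. The HAT is treated as a rectangular prism of mass
#' `hat_mass_fraction * body_mass`; its moment of inertia about its own centre
#' of mass is `m_hat * (h^2 + d^2) / 12` and about the L5/S1 pivot
#' `I_com + m_hat * hat_com_distance^2` (parallel-axis).
#'
#' @param participant_id integer id.
#' @param body_mass body mass, kg (> 0).
#' @param stature standing height, m (> 0).
#' @param hat_mass_fraction fraction of body mass in the HAT segment, in (0,1).
#' @param hat_com_distance pivot-to-HAT-COM distance, m (> 0).
#' @param hat_prism_height,hat_prism_depth prism dimensions, m.
#' @param pivot_height height of the L5/S1 pivot above the ground, m.
#' @param imu_distance pivot-to-IMU distance along the trunk axis, m.
#' @param style_speed_factor dimensionless lifting-tempo multiplier.
#' @param style_flexion_offset degrees added to the task peak-flexion target.
#' @return A list of class `anthro_profile` with the fields above plus
#'   `hat_mass`, `hat_inertia_com` and `hat_inertia_pivot` (kg m^2).
#' @export
#' @examples
#' p <- anthro_profile(1, body_mass = 80, stature = 1.75)
#' p$hat_inertia_pivot > p$hat_inertia_com
anthro_profile <- function(participant_id, body_mass, stature,
                           hat_mass_fraction = 0.678,
                           hat_com_distance = 0.17 * stature,
                           hat_prism_height = 0.6 * stature / 1.75,
                           hat_prism_depth = 0.20,
                           pivot_height = 0.60 * stature,
                           imu_distance = 0.6 * 2 * hat_com_distance,
                           style_speed_factor = 1,
                           style_flexion_offset = 0) {
  check_number(body_mass, "body_mass", lower = 1e-6)
  check_number(stature, "stature", lower = 1e-6)
  check_number(hat_com_distance, "hat_com_distance", lower = 1e-6)
  if (hat_mass_fraction <= 0 || hat_mass_fraction >= 1) {
    stop_config("hat_mass_fraction must lie strictly inside (0, 1)")
  }
  m_hat <- hat_mass_fraction * body_mass
  i_com <- m_hat * (hat_prism_height^2 + hat_prism_depth^2) / 12
  i_pivot <- i_com + m_hat * hat_com_distance^2
  stopifnot(i_com > 0, i_pivot > 0)
  structure(list(
    participant_id = as.integer(participant_id),
    body_mass = body_mass,
    stature = stature,
    hat_mass_fraction = hat_mass_fraction,
    hat_mass = m_hat,
    hat_com_distance = hat_com_distance,
    hat_prism_height = hat_prism_height,
    hat_prism_depth = hat_prism_depth,
    hat_inertia_com = i_com,
    hat_inertia_pivot = i_pivot,
    pivot_height = pivot_height,
    imu_distance = imu_distance,
    style_speed_factor = style_speed_factor,
    style_flexion_offset = style_flexion_offset
  ), class = "anthro_profile")
}

#' @export
print.anthro_profile <- function(x, ...) {
  cat(sprintf(
    "participant %d: %.1f kg, %.2f m (HAT %.1f kg, arm %.3f m, I_pivot %.2f kg m^2)\n",
    x$participant_id, x$body_mass, x$stature, x$hat_mass,
    x$hat_com_distance, x$hat_inertia_pivot))
  invisible(x)
}

#' Sample a cohort of participants
#'
#' Body mass and stature are drawn uniformly from the configured ranges;
#' all HAT parameters scale with stature as in [anthro_profile()]. Per-
#' participant lifting style (tempo multiplier, flexion offset) is also
#' sampled here so that the same seed always reproduces the same cohort.
#'
#' @param n number of participants; must be at least 2 because downstream
#'   model training is leave-one-participant-out.
#' @param config a [default_config()] list (the `participants` section is
#'   used).
#' @param seed integer seed.
#' @return List of [anthro_profile()] objects.
#' @export
#' @examples
#' cohort <- sample_participants(3, default_config(), seed = 1)
#' length(cohort)
sample_participants <- function(n, config = default_config(), seed = 1L) {
  if (!is.numeric(n) || n < 2) {
    stop_config(paste("need at least 2 participants:",
                      "leave-one-participant-out cross-validation requires",
                      "one participant to hold out and at least one to train on"))
  }
  n <- as.integer(n)
  pc <- config$participants
  set.seed(derive_seed(seed, 101L))
  body_mass <- runif(n, pc$body_mass[1], pc$body_mass[2])
  stature <- runif(n, pc$stature[1], pc$stature[2])
  speed <- runif(n, pc$speed_factor[1], pc$speed_factor[2])
  flex_off <- rnorm_trunc(n, 0, pc$flexion_offset_sd, trunc = 2)
  lapply(seq_len(n), function(i) {
    anthro_profile(
      participant_id = i,
      body_mass = body_mass[i],
      stature = stature[i],
      hat_mass_fraction = pc$hat_mass_fraction,
      hat_com_distance = pc$hat_com_frac * stature[i],
      hat_prism_height = pc$prism_height_frac * stature[i],
      hat_prism_depth = pc$prism_depth,
      pivot_height = pc$pivot_height_frac * stature[i],
      imu_distance = pc$imu_frac * 2 * pc$hat_com_frac * stature[i],
      style_speed_factor = speed[i],
      style_flexion_offset = flex_off[i]
    )
  })
}

#' Tabulate a cohort as a data frame
#' @param profiles list of [anthro_profile()] objects.
#' @return data.frame with one row per participant.
#' @export
profiles_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(p[setdiff(names(p), character(0))], stringsAsFactors = FALSE)
  }))
}
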