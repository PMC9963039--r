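# Reading a generated (or user-supplied) trial directory back into memory:
# the inverse of generate_dataset(out_dir = ...), restoring the per-trial
# metadata attributes from manifest.csv and profiles.csv so every downstream
# stage can run from persisted intermediates.

#' Read a trial directory
#'
#' Loads `manifest.csv`, `profiles.csv` and the per-trial CSVs written by
#' [generate_dataset()] (or conforming user data) and reconstructs the
#' `lift_trial` objects with their metadata attributes.
#'
#' @param dir directory containing `manifest.csv`, `profiles.csv` and trial
#'   CSV files.
#' @param config a [default_config()]; supplies the sampling rate and
#'   box-at-hands flag if the manifest lacks them.
#' @return list with `trials`, `manifest`, `profiles` (as in
#'   [generate_dataset()]).
#' @export
read_trial_dir <- function(dir, config = default_config()) {
  man_path <- file.path(dir, "manifest.csv")
  prof_path <- file.path(dir, "profiles.csv")
  for (p in c(man_path, prof_path)) {
    if (!file.exists(p)) stop_config("missing %s", p)
  }
  manifest <- utils::read.csv(man_path)
  prof_tab <- utils::read.csv(prof_path)
  profiles <- lapply(seq_len(nrow(prof_tab)), function(i) {
    r <- prof_tab[i, ]
    anthro_profile(r$participant_id, r$body_mass, r$stature,
                   hat_mass_fraction = r$hat_mass_fraction,
                   hat_com_distance = r$hat_com_distance,
                   hat_prism_height = r$hat_prism_height,
                   hat_prism_depth = r$hat_prism_depth,
                   pivot_height = r$pivot_height,
                   imu_distance = r$imu_distance,
                   style_speed_factor = r$style_speed_factor,
                   style_flexion_offset = r$style_flexion_offset)
  })
  names(profiles) <- prof_tab$participant_id
  trials <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- row$file
    if (is.na(path) || !file.exists(path)) {
      path <- file.path(dir, paste0(row$trial_id, ".csv"))
    }
    if (!file.exists(path)) stop_config("trial file not found: %s", path)
    df <- utils::read.csv(path)
    df$hold_mask <- as.logical(df$hold_mask)
    prof <- profiles[[as.character(row$participant_id)]]
    fs <- if (nrow(df) > 1) 1 / mean(diff(df$time)) else config$sim$fs
    trials[[row$trial_id]] <- structure(
      df, class = c("lift_trial", "data.frame"),
      participant_id = prof$participant_id,
      task_id = as.integer(row$task_id),
      repetition = as.integer(row$repetition),
      box_mass = row$box_mass_kg,
      origin_height = row$origin_height_cm,
      trial_seed = row$trial_seed,
      fs = fs,
      box_at_hands = isTRUE(config$sim$box_at_hands),
      reach_factor = row$reach_factor,
      theta_peak_deg = row$theta_peak_deg,
      arm_peak = row$arm_peak_m,
      m_hat = prof$hat_mass,
      hat_com_distance = prof$hat_com_distance,
      hat_inertia_pivot = prof$hat_inertia_pivot,
      body_mass = prof$body_mass,
      pivot_height = prof$pivot_height)
  }
  list(trials = trials, manifest = manifest, profiles = unname(profiles))
}
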