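# shared fixtures, built in code

# small-but-complete configuration for fast pipeline tests
smoke_config <- function(...) {
  default_config(
    participants = list(n_participants = 3),
    tasks = list(n_masses = 2, n_heights = 3, repetitions = 1),
    workday = list(n_days = 50),
    ...
  )
}

# disable every stochastic generator term (style jitter, reach, asymmetry,
# off-axis sinusoids, COP noise) so trials are deterministic functions of
# profile and task
noise_free <- function(cfg) {
  cfg$sim$rep_flexion_sd <- 0
  cfg$sim$rep_speed_sd <- 0
  cfg$sim$reach_halfwidth <- 0
  cfg$sim$split_sd <- 0
  cfg$sim$offaxis_angle_sd <- 0
  cfg$sim$cop_sd <- 0
  cfg$participants$flexion_offset_sd <- 0
  cfg$participants$speed_factor <- c(1, 1)
  cfg
}

reference_profile <- function(id = 1L, body_mass = 80, stature = 1.75) {
  anthro_profile(id, body_mass = body_mass, stature = stature)
}

# a cached tiny trial set spanning 3 participants for estimator tests
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- smoke_config()
      profiles <- sample_participants(3, cfg, seed = 11)
      tasks <- with(cfg$tasks, build_task_grid(mass_range, height_range,
                                               n_masses, n_heights, repetitions))
      cache <<- c(generate_dataset(profiles, tasks, cfg, seed = 11),
                  list(cfg = cfg))
    }
    cache
  }
})
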