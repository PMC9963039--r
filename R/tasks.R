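#' Build the lifting-task grid
#'
#' Evenly spaced grid of symmetric lifting tasks crossing box mass and
#' lift-origin (shelf) height, inclusive of both range endpoints. The default
#' configuration (5 masses over 5-23 kg by 10 heights over 40-160 cm) yields
#' 50 distinct tasks. A count of 1 on either axis places the task at the
#' range midpoint.
#'
#' @param mass_range length-2 numeric, kg.
#' @param height_range length-2 numeric, cm above the ground.
#' @param n_masses,n_heights grid sizes (>= 1).
#' @param repetitions lifts of each task per participant (>= 1).
#' @return data.frame with columns `task_id`, `box_mass` (kg),
#'   `origin_height` (cm), `repetitions`.
#' @export
#' @examples
#' grid <- build_task_grid()
#' nrow(grid)   # 50
build_task_grid <- function(mass_range = c(5, 23), height_range = c(40, 160),
                            n_masses = 5L, n_heights = 10L, repetitions = 1L) {
  if (length(mass_range) != 2L || length(height_range) != 2L ||
      any(!is.finite(c(mass_range, height_range)))) {
    stop_config("mass_range and height_range must be finite length-2 vectors")
  }
  if (diff(mass_range) < 0 || diff(height_range) < 0) {
    stop_config("task ranges must be non-decreasing")
  }
  if (n_masses < 1 || n_heights < 1 || repetitions < 1) {
    stop_config("n_masses, n_heights and repetitions must be >= 1")
  }
  if ((n_masses > 1 && diff(mass_range) == 0) ||
      (n_heights > 1 && diff(height_range) == 0)) {
    stop_config("degenerate range with more than one grid point requested")
  }
  axis_points <- function(rng, n) {
    if (n == 1L) mean(rng) else seq(rng[1], rng[2], length.out = n)
  }
  masses <- axis_points(mass_range, as.integer(n_masses))
  heights <- axis_points(height_range, as.integer(n_heights))
  grid <- expand.grid(box_mass = masses, origin_height = heights,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    task_id = seq_len(nrow(grid)),
    box_mass = grid$box_mass,
    origin_height = grid$origin_height,
    repetitions = as.integer(repetitions)
  )
}
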