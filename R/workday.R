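# Monte-Carlo workday simulation: resample lifts from a participant's
# peak-load-moment lookup table, accumulate fatigue damage per sensor
# condition, and convert to LBD risk. The same sampled lift sequence feeds
# all conditions, so differences between conditions isolate estimator error
# from sampling noise.

lookup_moment_cols <- function(moment_type) {
  base <- if (moment_type == "lumbar") "peak_lumbar_" else "peak_load_"
  c(lab = paste0(base, "lab"), trunk = paste0(base, "trunk"),
    trunkforce = paste0(base, "trunkforce"))
}

#' Simulate one material-handling workday
#'
#' Draws the lift count uniformly from `workday$lift_range` (inclusive),
#' samples that many lift ids uniformly with replacement from the
#' participant's lookup table, and computes cumulative damage and LBD risk
#' separately from the lab-based, Trunk and Trunk+Force peak moments of the
#' *same* sampled lifts. Negative estimated load moments are clamped to zero
#' before damage computation (a negative "load" is physically meaningless to
#' the fatigue model); the number of clamped lifts is reported.
#'
#' @param lookup rows of a [peak_moment_lookup()] for one participant.
#' @param config a [default_config()].
#' @param seed integer seed for this day's draws.
#' @param day_index index recorded in the result.
#' @return one-row data.frame (class `workday_result`) with `participant_id`,
#'   `day_index`, `day_seed`, `n_lifts`, `D_*` and `R_*` for the three
#'   conditions, the lift-counter baseline `R_liftcounter`,
#'   `mean_bend_angle`, and `n_clamped_*` counts; the sampled lift ids are
#'   attached as attribute `lift_ids`.
#' @export
simulate_workday <- function(lookup, config = default_config(), seed = 1L,
                             day_index = 1L) {
  if (!nrow(lookup)) stop_config("empty lookup table")
  wd <- config$workday
  cols <- lookup_moment_cols(wd$moment_type)
  missing <- setdiff(unname(cols), names(lookup))
  if (length(missing)) {
    stop_config("lookup is missing column(s): %s", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  n_lifts <- sample(wd$lift_range[1]:wd$lift_range[2], 1L)
  ids <- sample.int(nrow(lookup), n_lifts, replace = TRUE)
  counts <- tabulate(ids, nbins = nrow(lookup))
  out <- data.frame(
    participant_id = lookup$participant_id[1],
    day_index = as.integer(day_index),
    day_seed = as.integer(seed),
    n_lifts = n_lifts
  )
  for (cond in names(cols)) {
    m <- lookup[[cols[[cond]]]]
    clamped <- sum(counts[m < 0])
    m <- pmax(m, 0)
    D <- sum(counts * per_lift_damage(m, wd$eq4_grouping))
    if (wd$eq4_grouping == "additive_constant") D <- D + 0.32
    out[[paste0("D_", cond)]] <- D
    out[[paste0("R_", cond)]] <- lbd_risk(D)$R
    out[[paste0("n_clamped_", cond)]] <- clamped
  }
  out$R_liftcounter <- lift_counter_baseline(n_lifts, wd$nominal_moment,
                                             wd$eq4_grouping)
  out$mean_bend_angle <- sum(counts * lookup$peak_bend_angle) / n_lifts
  structure(out, lift_ids = ids, class = c("workday_result", "data.frame"))
}

#' Run the full workday simulation
#'
#' `workday$n_days` simulated workdays per participant, each with an RNG
#' substream derived from `(seed, participant, day)` so results do not
#' depend on execution order.
#'
#' @param lookup a [peak_moment_lookup()] covering >= 1 participant.
#' @param config a [default_config()].
#' @param seed master integer seed.
#' @return data.frame with `n_days x participants` rows of
#'   [simulate_workday()] results.
#' @export
run_simulation <- function(lookup, config = default_config(), seed = 1L) {
  pids <- sort(unique(lookup$participant_id))
  if (!length(pids)) stop_config("empty lookup table")
  n_days <- config$workday$n_days
  rows <- vector("list", length(pids) * n_days)
  k <- 0L
  for (p in pids) {
    lk <- lookup[lookup$participant_id == p, , drop = FALSE]
    for (d in seq_len(n_days)) {
      k <- k + 1L
      rows[[k]] <- simulate_workday(lk, config,
                                    seed = derive_seed(seed, 31L, p, d),
                                    day_index = d)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
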