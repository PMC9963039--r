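# Accuracy metrics comparing Trunk, Trunk+Force and lift-counter LBD risk
# estimates against lab-based risk, with the accompanying statistics. All
# risks are handled on the 0-100 percent scale throughout reporting.

#' Root-mean-square error
#'
#' @param estimates,truths equal-length numeric vectors (risk, percent).
#' @return `sqrt(mean((estimates - truths)^2))`, percentage points.
#' @export
#' @examples
#' rmse(c(60, 50), c(50, 50))   # 7.071
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(estimates) < 1L) {
    stop_config("estimates and truths must have equal length >= 1")
  }
  sqrt(mean((estimates - truths)^2))
}

#' Fraction of days within an absolute agreement band
#'
#' A day counts as accurate when the estimate lies within `band` absolute
#' percentage points of the truth, boundary inclusive: a 65% true risk with
#' a 75% estimate is within the default +/-10-point band, 75.01% is not.
#'
#' @inheritParams rmse
#' @param band absolute half-width, percentage points (>= 0).
#' @return fraction in `[0, 1]`.
#' @export
within_band_fraction <- function(estimates, truths, band = 10) {
  if (band < 0) stop_config("band must be >= 0")
  if (length(estimates) != length(truths)) {
    stop_config("estimates and truths must have equal length")
  }
  mean(abs(estimates - truths) <= band)
}

#' Per-participant Pearson correlations
#'
#' @param results data.frame with a `participant_id` column.
#' @param est_col,truth_col column names to correlate.
#' @return named numeric vector of r per participant; participants with zero
#'   variance in either column get `NA` with a warning (excluded from
#'   pooling).
#' @export
pearson_by_participant <- function(results, est_col, truth_col) {
  vapply(split(results, results$participant_id), function(df) {
    x <- df[[est_col]]
    y <- df[[truth_col]]
    if (length(x) < 3L) stop_config("need >= 3 days per participant for r")
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero variance; correlation undefined for participant ",
              df$participant_id[1], call. = FALSE)
      return(NA_real_)
    }
    cor(x, y)
  }, numeric(1))
}

#' Fisher-z averaged correlation
#'
#' Transforms each r to `atanh(r)`, averages on the z scale, and transforms
#' back: `tanh(mean(atanh(r)))`. `NA` values (undefined correlations) are
#' dropped.
#'
#' @param r_values numeric vector with all `|r| < 1`.
#' @return pooled correlation coefficient.
#' @export
#' @examples
#' fisher_average(c(0, 0.8))   # 0.5
fisher_average <- function(r_values) {
  r_values <- r_values[!is.na(r_values)]
  if (!length(r_values)) stop_config("no finite correlations to average")
  if (any(abs(r_values) >= 1)) {
    stop_config("|r| = 1 gives an infinite Fisher z; cannot average")
  }
  tanh(mean(atanh(r_values)))
}

#' Compare per-participant RMSE between two conditions
#'
#' Kolmogorov-Smirnov normality check of each condition's RMSE vector
#' (one-sample test against a normal with the sample mean and SD — no
#' Lilliefors correction, flagged as such in the output), a paired t-test,
#' and Cohen's d using the pooled SD of the two conditions,
#' `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`. When the paired
#' differences have zero SD, t is undefined and reported as 0 with a warning.
#'
#' @param rmse_a,rmse_b paired per-participant RMSE vectors (n >= 3).
#' @return list with `ks_p_a`, `ks_p_b`, `t`, `df`, `p`, `d`, and
#'   `definitions` metadata.
#' @export
#' @examples
#' compare_conditions(c(2, 3, 4), c(1, 1, 1))$t   # 3.464
compare_conditions <- function(rmse_a, rmse_b) {
  if (length(rmse_a) != length(rmse_b) || length(rmse_a) < 3L) {
    stop_config("need paired vectors of length >= 3")
  }
  ks_p <- function(x) {
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  diffs <- rmse_a - rmse_b
  if (sd(diffs) == 0) {
    warning("zero-variance paired differences; t undefined, reported as 0",
            call. = FALSE)
    t_stat <- 0
    p_val <- 1
  } else {
    tt <- t.test(rmse_a, rmse_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  pooled_sd <- sqrt((sd(rmse_a)^2 + sd(rmse_b)^2) / 2)
  d <- if (pooled_sd == 0) 0 else (mean(rmse_a) - mean(rmse_b)) / pooled_sd
  list(
    ks_p_a = ks_p(rmse_a), ks_p_b = ks_p(rmse_b),
    t = t_stat, df = length(rmse_a) - 1L, p = p_val, d = d,
    definitions = list(
      ks = "one-sample KS vs N(sample mean, sample sd); lilliefors_uncorrected",
      d = "pooled-SD Cohen's d: (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)"
    )
  )
}

#' What drives the trunk-only risk estimate?
#'
#' Pooled Pearson correlations of the Trunk condition's risk with the number
#' of lifts in the day and with the day's mean peak bend angle — the two
#' quantities a trunk IMU can plausibly track.
#'
#' @param results a [run_simulation()] table.
#' @return list with `r_vs_lift_count` and `r_vs_bend_angle`.
#' @export
trunk_risk_drivers <- function(results) {
  safe_cor <- function(x, y) if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  list(
    r_vs_lift_count = safe_cor(results$R_trunk, results$n_lifts),
    r_vs_bend_angle = safe_cor(results$R_trunk, results$mean_bend_angle)
  )
}

#' Evaluate a workday simulation
#'
#' Computes the full accuracy summary: per participant, the RMSE of the
#' Trunk, Trunk+Force and lift-counter risk estimates against lab-based risk
#' (percentage points), the fraction of days within the +/-`band`-point
#' agreement band, and the Pearson correlation per condition; pooled, the
#' between-participant mean and SD of RMSE, Fisher-z-averaged correlations,
#' the paired comparison of the two wearable conditions, and the trunk-risk
#' driver correlations.
#'
#' @param results a [run_simulation()] table.
#' @param config a [default_config()].
#' @return list of class `lbd_evaluation` with elements `per_participant`
#'   (data.frame), `pooled`, `tests`, `drivers`, `band`.
#' @export
evaluate_workdays <- function(results, config = default_config()) {
  band <- config$evaluation$band
  per <- lapply(split(results, results$participant_id), function(df) {
    lab <- 100 * df$R_lab
    trunk <- 100 * df$R_trunk
    tf <- 100 * df$R_trunkforce
    lc <- 100 * df$R_liftcounter
    data.frame(
      participant_id = df$participant_id[1],
      n_days = nrow(df),
      rmse_trunk = rmse(trunk, lab),
      rmse_trunkforce = rmse(tf, lab),
      rmse_liftcounter = rmse(lc, lab),
      within_trunk = within_band_fraction(trunk, lab, band),
      within_trunkforce = within_band_fraction(tf, lab, band),
      r_trunk = if (sd(trunk) > 0 && sd(lab) > 0) cor(trunk, lab) else NA_real_,
      r_trunkforce = if (sd(tf) > 0 && sd(lab) > 0) cor(tf, lab) else NA_real_
    )
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  pooled <- list(
    rmse_trunk_mean = mean(per$rmse_trunk),
    rmse_trunk_sd = sd(per$rmse_trunk),
    rmse_trunkforce_mean = mean(per$rmse_trunkforce),
    rmse_trunkforce_sd = sd(per$rmse_trunkforce),
    rmse_liftcounter_mean = mean(per$rmse_liftcounter),
    within_trunk_mean = mean(per$within_trunk),
    within_trunkforce_mean = mean(per$within_trunkforce),
    r_trunk = fisher_average(per$r_trunk),
    r_trunkforce = fisher_average(per$r_trunkforce),
    n_clamped = c(trunk = sum(results$n_clamped_trunk),
                  trunkforce = sum(results$n_clamped_trunkforce),
                  lab = sum(results$n_clamped_lab))
  )
  tests <- compare_conditions(per$rmse_trunk, per$rmse_trunkforce)
  structure(list(per_participant = per, pooled = pooled, tests = tests,
                 drivers = trunk_risk_drivers(results), band = band),
            class = "lbd_evaluation")
}

#' @export
print.lbd_evaluation <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("LBD risk estimation accuracy over %d participants x %d workdays\n",
              nrow(x$per_participant), x$per_participant$n_days[1]))
  cat(sprintf("  RMSE  trunk: %.1f +/- %.1f %%   trunk+force: %.1f +/- %.1f %%   lift-counter: %.1f %%\n",
              p$rmse_trunk_mean, p$rmse_trunk_sd,
              p$rmse_trunkforce_mean, p$rmse_trunkforce_sd,
              p$rmse_liftcounter_mean))
  cat(sprintf("  within +/-%g pts  trunk: %.1f %%   trunk+force: %.1f %%\n",
              x$band, 100 * p$within_trunk_mean, 100 * p$within_trunkforce_mean))
  cat(sprintf("  pooled r  trunk: %.2f   trunk+force: %.2f\n",
              p$r_trunk, p$r_trunkforce))
  cat(sprintf("  paired t(%d) = %.2f, p = %.2g, d = %.2f\n",
              x$tests$df, x$tests$t, x$tests$p, x$tests$d))
  cat(sprintf("  trunk risk vs lift count r = %.2f, vs bend angle r = %.2f\n",
              x$drivers$r_vs_lift_count, x$drivers$r_vs_bend_angle))
  invisible(x)
}

# flatten an evaluation into plain lists for JSON serialization
evaluation_to_list <- function(ev) {
  list(
    per_participant = ev$per_participant,
    pooled = ev$pooled[setdiff(names(ev$pooled), "n_clamped")],
    n_clamped = as.list(ev$pooled$n_clamped),
    tests = ev$tests,
    drivers = ev$drivers,
    band = ev$band
  )
}
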