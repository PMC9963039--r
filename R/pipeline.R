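# End-to-end pipeline: generate -> idealize -> train (trunk, then
# trunk+force) -> convert -> simulate -> evaluate, with stable file
# contracts: every tabular output is CSV, every summary JSON, and every file
# carries the configuration hash and master seed.

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[liftrisk] %s (%.1f s elapsed)",
                               sprintf(fmt, ...),
                               proc.time()[["elapsed"]] - .liftrisk_t0$t))
  invisible(NULL)
}

.liftrisk_t0 <- new.env()

#' Run the complete simulation pipeline
#'
#' Executes all stages for one configuration: sample the cohort, build the
#' task grid, generate the seeded trials, cross-validate the Trunk and
#' Trunk+Force lumbar-moment estimators leave-one-participant-out, build the
#' peak-moment lookup tables (including the load-moment conversion), run the
#' Monte-Carlo workday simulation, and evaluate accuracy. Idempotent for a
#' fixed configuration and seed.
#'
#' @param config a [default_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @param out_dir optional run directory. When given, writes `config.yaml`,
#'   `manifest.csv`, `profiles.csv`, `lookup.csv`, `workdays.csv` and
#'   `summary.json` (plus per-trial CSVs when `write_trials = TRUE`).
#' @param write_trials also write one CSV per trial (large).
#' @param verbose log per-stage progress messages.
#' @return list with `profiles`, `tasks`, `trials`, `manifest`,
#'   `pred_trunk`, `pred_trunkforce`, `lookup`, `workdays`, `evaluation`,
#'   `config`, `seed`, `config_hash`.
#' @export
run_all <- function(config = default_config(), seed = config$seed,
                    out_dir = NULL, write_trials = FALSE, verbose = FALSE) {
  .liftrisk_t0$t <- proc.time()[["elapsed"]]
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_config("stage '%s' failed: %s", name, conditionMessage(e))
    })
    stage_msg(verbose, "stage %s done", name)
    res
  }

  profiles <- run_stage("sample_participants",
    sample_participants(config$participants$n_participants, config, seed))
  tasks <- run_stage("build_task_grid", with(config$tasks,
    build_task_grid(mass_range, height_range, n_masses, n_heights, repetitions)))
  ds <- run_stage("generate", generate_dataset(
    profiles, tasks, config, seed,
    out_dir = if (isTRUE(write_trials)) file.path(out_dir, "trials") else NULL))
  pred_trunk <- run_stage("train_trunk",
    lopo_cross_validate(ds$trials, "trunk", config, seed))
  pred_tf <- run_stage("train_trunk_force",
    lopo_cross_validate(ds$trials, "trunk_force", config, seed))
  lookup <- run_stage("convert",
    peak_moment_lookup(ds$trials, pred_trunk, pred_tf, profiles, config))
  workdays <- run_stage("simulate", run_simulation(lookup, config, seed))
  evaluation <- run_stage("evaluate", evaluate_workdays(workdays, config))

  if (!is.null(out_dir)) {
    stamp <- function(df) {
      df$config_hash <- hash
      df$seed <- seed
      df
    }
    utils::write.csv(stamp(ds$manifest), file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(profiles_table(profiles)),
                     file.path(out_dir, "profiles.csv"), row.names = FALSE)
    utils::write.csv(stamp(as.data.frame(lookup)),
                     file.path(out_dir, "lookup.csv"), row.names = FALSE)
    utils::write.csv(stamp(as.data.frame(workdays)),
                     file.path(out_dir, "workdays.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(list(config_hash = hash, seed = seed), evaluation_to_list(evaluation)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns")
  }
  stage_msg(verbose, "run complete")
  list(profiles = profiles, tasks = tasks, trials = ds$trials,
       manifest = ds$manifest, pred_trunk = pred_trunk,
       pred_trunkforce = pred_tf, lookup = lookup, workdays = workdays,
       evaluation = evaluation, config = config, seed = seed,
       config_hash = hash)
}

trial_required_cols <- function() {
  c("time", trunk_channel_names(), force_channel_names(),
    "lumbar_moment_truth", "hold_mask")
}

lookup_required_cols <- function() {
  c("participant_id", "trial_id", "box_mass", "peak_bend_angle",
    "peak_lumbar_lab", "peak_lumbar_trunk", "peak_lumbar_trunkforce",
    "peak_load_lab", "peak_load_trunk", "peak_load_trunkforce")
}

#' Validate user-supplied trial or lookup CSV files
#'
#' Checks a trial CSV (per-sample channels), a lookup CSV, or a directory of
#' them against the package's schemas and reports every violation with its
#' file, row and column. A file is classified as a lookup if it has a
#' `peak_load_lab` column, as a trial if it has a `time` column.
#'
#' @param path a CSV file or a directory containing CSV files.
#' @return data.frame with columns `file`, `row`, `column`, `message`
#'   (zero rows when everything conforms), of class `validation_report`.
#' @export
validate_inputs <- function(path) {
  if (!file.exists(path)) stop_config("path does not exist: %s", path)
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else {
    path
  }
  violations <- list()
  note <- function(file, row, column, message) {
    violations[[length(violations) + 1L]] <<-
      data.frame(file = file, row = row, column = column, message = message)
  }
  for (f in files) {
    df <- tryCatch(utils::read.csv(f), error = function(e) {
      note(f, NA, NA, paste("unreadable:", conditionMessage(e)))
      NULL
    })
    if (is.null(df)) next
    if ("peak_load_lab" %in% names(df) || "peak_lumbar_lab" %in% names(df)) {
      for (col in setdiff(lookup_required_cols(), names(df))) {
        note(f, NA, col, "required lookup column missing")
      }
      for (col in intersect(lookup_required_cols(), names(df))) {
        bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))) &
                       col != "trial_id")
        for (r in bad) note(f, r, col, "non-finite value")
      }
    } else if ("time" %in% names(df)) {
      for (col in setdiff(trial_required_cols(), names(df))) {
        note(f, NA, col, "required trial channel missing")
      }
      dt <- diff(df$time)
      if (length(dt) && (any(dt <= 0) ||
                         max(dt) - min(dt) > 1e-6 * max(abs(dt)))) {
        note(f, which.max(abs(dt - stats::median(dt))) + 1L, "time",
             "time base not strictly increasing and uniform")
      }
      for (col in intersect(trial_required_cols(), names(df))) {
        bad <- which(is.na(df[[col]]))
        for (r in bad) note(f, r, col, "missing value")
      }
    } else if (basename(f) %in% c("manifest.csv", "profiles.csv",
                                  "config.yaml")) {
      next
    } else {
      note(f, NA, NA, "unrecognized schema: no 'time' or peak-moment columns")
    }
  }
  out <- if (length(violations)) do.call(rbind, violations) else {
    data.frame(file = character(), row = integer(), column = character(),
               message = character())
  }
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Risk scatter plot against lab-based risk
#'
#' Scatter of per-workday Trunk and Trunk+Force risk estimates against the
#' lab-based risk with a unity line, coloured by participant. Requires
#' ggplot2.
#'
#' @param results a [run_simulation()] table.
#' @return a ggplot object.
#' @export
plot_risk_scatter <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("plot_risk_scatter requires the ggplot2 package")
  }
  long <- rbind(
    data.frame(lab = 100 * results$R_lab, est = 100 * results$R_trunk,
               participant = factor(results$participant_id),
               condition = "Trunk"),
    data.frame(lab = 100 * results$R_lab, est = 100 * results$R_trunkforce,
               participant = factor(results$participant_id),
               condition = "Trunk+Force")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = lab, y = est, colour = participant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Lab-based LBD risk (%)", y = "Estimated LBD risk (%)") +
    ggplot2::theme_minimal()
}
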