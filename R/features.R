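# Per-sample feature tables for the lumbar-moment estimators. Features are
# the instantaneous channel values (no windows or lags): 9 trunk channels for
# the Trunk condition, 15 for Trunk+Force.

#' Build a per-sample feature table
#'
#' Pools all time samples of all trials into one table whose feature columns
#' are the condition's wearable channels, with the ground-truth lumbar moment
#' as target and (participant, trial, sample) keys for traceability.
#'
#' @param trials named list of `lift_trial` data frames (see
#'   [generate_dataset()]).
#' @param condition `"trunk"` (9 channels) or `"trunk_force"` (15 channels).
#' @return data.frame of class `feature_table` with attribute `channels`;
#'   columns: keys `participant_id`, `trial_id`, `sample_index`; the channel
#'   columns; and `target` (Nm).
#' @export
build_features <- function(trials, condition = c("trunk", "trunk_force")) {
  condition <- match.arg(condition)
  channels <- switch(condition,
    trunk = trunk_channel_names(),
    trunk_force = c(trunk_channel_names(), force_channel_names())
  )
  blocks <- lapply(names(trials), function(id) {
    tr <- trials[[id]]
    missing <- setdiff(channels, names(tr))
    if (length(missing)) {
      stop_config("trial %s is missing channel(s): %s", id,
                  paste(missing, collapse = ", "))
    }
    cbind(
      data.frame(participant_id = attr(tr, "participant_id"),
                 trial_id = id,
                 sample_index = seq_len(nrow(tr))),
      as.data.frame(tr)[, channels, drop = FALSE],
      data.frame(target = tr$lumbar_moment_truth)
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (anyNA(out)) stop_config("feature table contains missing values")
  structure(out, channels = channels, condition = condition,
            class = c("feature_table", "data.frame"))
}

#' Filter training samples by target magnitude
#'
#' Keeps only rows whose target lumbar moment strictly exceeds `threshold`
#' (default 100 Nm). Applied to training data only, so the estimators
#' prioritize the high-moment samples that drive fatigue damage rather than
#' overfitting quiet standing; held-out predictions are always made on the
#' full, unfiltered series.
#'
#' @param table a [build_features()] table.
#' @param threshold Nm; rows with `target > threshold` survive (strict).
#' @return filtered `feature_table`.
#' @export
filter_training_samples <- function(table, threshold = 100) {
  if (!"target" %in% names(table)) stop_config("table has no 'target' column")
  keep <- table$target > threshold
  if (!any(keep)) {
    stop_config(paste("no training samples exceed the %g Nm threshold;",
                      "check that the threshold matches the generator",
                      "configuration"), threshold)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, channels = attr(table, "channels"),
            condition = attr(table, "condition"),
            class = class(table))
}
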