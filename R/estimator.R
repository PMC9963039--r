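# Gradient-boosted decision-tree regressors for time-series lumbar moment,
# with leave-one-participant-out cross-validation.

#' Train a gradient-boosted lumbar-moment estimator
#'
#' Fits a gradient-boosted decision-tree regressor (squared-error loss,
#' single-threaded and therefore bit-reproducible for fixed data) mapping the
#' instantaneous wearable channels to lumbar moment. Defaults: 100 boosting
#' stages, learning rate 0.1, depth-3 trees.
#'
#' @param table a (typically [filter_training_samples()]-filtered)
#'   [build_features()] table.
#' @param nrounds number of boosting stages.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param min_child_weight minimum summed Hessian per leaf; the package
#'   default (50, set in [default_config()]) damps per-sample noise chasing
#'   on large near-duplicate sample sets.
#' @param seed integer seed for the booster's RNG.
#' @return object of class `moment_estimator`; supports [predict()] on a
#'   `feature_table` (returns Nm per row).
#' @export
train_estimator <- function(table, nrounds = 100L, eta = 0.1, max_depth = 3L,
                            min_child_weight = 1, seed = 1L) {
  channels <- attr(table, "channels")
  if (is.null(channels)) stop_config("not a feature table: no channel attribute")
  if (nrow(table) < 2L) {
    stop_config("degenerate training table: need at least 2 samples")
  }
  x <- as.matrix(table[, channels, drop = FALSE])
  y <- table$target
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = eta,
                  max_depth = max_depth, min_child_weight = min_child_weight,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, channels = channels,
                 condition = attr(table, "condition"),
                 hyperparams = list(nrounds = nrounds, eta = eta,
                                    max_depth = max_depth,
                                    min_child_weight = min_child_weight,
                                    seed = seed)),
            class = "moment_estimator")
}

#' @export
predict.moment_estimator <- function(object, newdata, ...) {
  missing <- setdiff(object$channels, names(newdata))
  if (length(missing)) {
    stop_config("newdata is missing channel(s): %s",
                paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(newdata)[, object$channels, drop = FALSE])
  stats::predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' @export
print.moment_estimator <- function(x, ...) {
  cat(sprintf("moment estimator (%s, %d channels, %d rounds, eta %.2f, depth %d)\n",
              x$condition %||% "?", length(x$channels),
              x$hyperparams$nrounds, x$hyperparams$eta, x$hyperparams$max_depth))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-participant-out cross-validated predictions
#'
#' For each participant, trains an estimator on all *other* participants'
#' samples (after the training-target threshold filter) and predicts the
#' held-out participant's full trials without any filtering, so every trial
#' receives exactly one held-out prediction and no information from the
#' held-out participant's targets can leak into their predictions.
#'
#' @param trials named list of `lift_trial`s spanning >= 2 participants.
#' @param condition `"trunk"` or `"trunk_force"`.
#' @param config a [default_config()] (the `estimator` section is used).
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `trial_id`, `sample_index`,
#'   `pred` (Nm) covering every sample of every trial; the per-fold models
#'   are attached as attribute `models`.
#' @export
lopo_cross_validate <- function(trials, condition = c("trunk", "trunk_force"),
                                config = default_config(), seed = 1L) {
  condition <- match.arg(condition)
  est <- config$estimator
  features <- build_features(trials, condition)
  pids <- sort(unique(features$participant_id))
  if (length(pids) < 2L) {
    stop_config("leave-one-participant-out needs >= 2 participants")
  }
  per_p <- table(factor(features$participant_id, levels = pids))
  if (any(per_p == 0)) stop_config("participant with zero trials")
  preds <- vector("list", length(pids))
  models <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    p <- pids[i]
    train_tab <- features[features$participant_id != p, , drop = FALSE]
    attr(train_tab, "channels") <- attr(features, "channels")
    attr(train_tab, "condition") <- condition
    class(train_tab) <- class(features)
    train_tab <- filter_training_samples(train_tab, est$threshold)
    model <- train_estimator(train_tab, nrounds = est$nrounds, eta = est$eta,
                             max_depth = est$max_depth,
                             min_child_weight = est$min_child_weight %||% 1,
                             seed = derive_seed(seed, 23L, p))
    test_tab <- features[features$participant_id == p, , drop = FALSE]
    preds[[i]] <- data.frame(
      participant_id = test_tab$participant_id,
      trial_id = test_tab$trial_id,
      sample_index = test_tab$sample_index,
      pred = predict(model, test_tab)
    )
    models[[i]] <- model
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  structure(out, models = stats::setNames(models, paste0("P", pids)),
            condition = condition)
}
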