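# Per-lift peak extraction and the peak-moment lookup tables that drive the
# workday simulation: for every recorded lift, the peak lumbar moment under
# each condition (lab truth, Trunk, Trunk+Force) and its conversion to a peak
# load moment.

#' Extract per-trial peak lumbar moments
#'
#' Peak = maximum over the trial (trials are single lifts, so the lift
#' window is the whole series). When held-out prediction tables are
#' supplied, their per-trial peaks are extracted the same way.
#'
#' Predicted series are smoothed with a centred moving average of
#' `smooth_window` seconds before the maximum is taken: the per-sample
#' estimator noise is serially uncorrelated, so the maximum of the raw
#' series over several hundred samples is biased upward by a few Nm for
#' every condition, and a short moving average removes that artifact without
#' touching the (piecewise-constant around the peak) ground-truth series,
#' which is never smoothed.
#'
#' @param trials named list of `lift_trial`s.
#' @param pred_trunk,pred_trunkforce optional prediction tables from
#'   [lopo_cross_validate()].
#' @param smooth_window moving-average width in seconds applied to predicted
#'   series before peak extraction (0 disables).
#' @return data.frame, one row per trial: keys, `box_mass`,
#'   `peak_bend_angle` (deg) and `peak_lumbar_lab` (plus
#'   `peak_lumbar_trunk` / `peak_lumbar_trunkforce` and the corresponding
#'   peak sample indices when predictions are given).
#' @export
extract_peaks <- function(trials, pred_trunk = NULL, pred_trunkforce = NULL,
                          smooth_window = 0.3) {
  if (!length(trials)) stop_config("no trials supplied")
  peak_of <- function(v, id) {
    if (!length(v) || all(is.na(v))) stop_config("empty series for trial %s", id)
    which.max(v)
  }
  split_pred <- function(pred) {
    if (is.null(pred)) return(NULL)
    split(pred, pred$trial_id)
  }
  pt <- split_pred(pred_trunk)
  pf <- split_pred(pred_trunkforce)
  rows <- lapply(names(trials), function(id) {
    tr <- trials[[id]]
    i_lab <- peak_of(tr$lumbar_moment_truth, id)
    row <- data.frame(
      trial_id = id,
      participant_id = attr(tr, "participant_id"),
      task_id = attr(tr, "task_id"),
      repetition = attr(tr, "repetition"),
      box_mass = attr(tr, "box_mass"),
      peak_bend_angle = max(tr$trunk_angle_flexion),
      peak_lumbar_lab = tr$lumbar_moment_truth[i_lab],
      idx_lab = i_lab
    )
    for (cond in c("trunk", "trunkforce")) {
      p <- if (cond == "trunk") pt[[id]] else pf[[id]]
      if (!is.null(p)) {
        v <- p$pred[order(p$sample_index)]
        if (length(v) != nrow(tr)) {
          stop_config("prediction length mismatch for trial %s", id)
        }
        v <- smooth_series(v, attr(tr, "fs"), smooth_window)
        i <- peak_of(v, id)
        row[[paste0("peak_lumbar_", cond)]] <- v[i]
        row[[paste0("idx_", cond)]] <- i
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# conversion inputs at a trial's peak sample; L is the horizontal HAT-COM
# arm implied by the participant's nominal (table-based) anthropometry and
# the trunk flexion angle at that sample — every condition, including the
# lab-based one, converts with the same table-based arm
conversion_at <- function(trial, idx) {
  dt <- 1 / attr(trial, "fs")
  alpha <- central_diff(trial$trunk_angvel_flexion, dt)[idx] * pi / 180
  a <- trial$trunk_acc_ap[idx]
  L <- attr(trial, "hat_com_distance") *
    sin(trial$trunk_angle_flexion[idx] * pi / 180)
  list(a = a, alpha = alpha, L = max(L, 0))
}

#' Build the peak-moment lookup table
#'
#' Runs [extract_peaks()] and converts each condition's peak lumbar moment to
#' a peak load moment with [lumbar_to_load_moment()], evaluating `a`, `alpha`
#' and `L` at that condition's peak sample. Every condition — including the
#' lab-based one — converts with the horizontal arm implied by the
#' participant's table-based anthropometry and the trunk flexion angle at
#' the peak, which is how L is estimated in practice (the true per-lift load
#' position is not observable outside the simulation). The lifted mass and
#' the participant's HAT parameters are task/participant metadata in every
#' condition.
#'
#' @inheritParams extract_peaks
#' @param profiles list of [anthro_profile()]s covering the trials.
#' @param config a [default_config()].
#' @return data.frame of class `peak_lookup`, one row per lift, with columns
#'   `participant_id`, `trial_id`, `box_mass`, `peak_bend_angle`,
#'   `peak_lumbar_lab`, `peak_lumbar_trunk`, `peak_lumbar_trunkforce`,
#'   `peak_load_lab`, `peak_load_trunk`, `peak_load_trunkforce`.
#' @export
peak_moment_lookup <- function(trials, pred_trunk, pred_trunkforce, profiles,
                               config = default_config()) {
  peaks <- extract_peaks(trials, pred_trunk, pred_trunkforce,
                         smooth_window = config$estimator$smooth_window %||% 0.3)
  conds <- c(lab = "lab", trunk = "trunk", trunkforce = "trunkforce")
  for (cond in conds) {
    lum_col <- paste0("peak_lumbar_", cond)
    idx_col <- paste0("idx_", cond)
    if (!lum_col %in% names(peaks)) next
    load <- numeric(nrow(peaks))
    for (r in seq_len(nrow(peaks))) {
      tr <- trials[[peaks$trial_id[r]]]
      cv <- conversion_at(tr, peaks[[idx_col]][r])
      load[r] <- lumbar_to_load_moment(
        m_lumbar = peaks[[lum_col]][r],
        m_hat = attr(tr, "m_hat"),
        L = cv$L, a = cv$a, alpha = cv$alpha,
        m_box = attr(tr, "box_mass"),
        I = attr(tr, "hat_inertia_pivot")
      )
    }
    peaks[[paste0("peak_load_", cond)]] <- load
  }
  peaks <- peaks[, !grepl("^idx_", names(peaks))]
  class(peaks) <- c("peak_lookup", "data.frame")
  peaks
}
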