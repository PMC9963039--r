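# LiFFT: fatigue-failure cumulative damage and low-back disorder risk, plus
# the lumbar-to-load-moment conversion that turns the machine-learning target
# (total lumbar extension moment) into the tool's per-lift input (the moment
# created by the lifted object alone).

#' Convert a peak lumbar moment into a load moment
#'
#' Subtracts the upper-body contributions from the total lumbar extension
#' moment: `M_load = M_lumbar - [m_hat * (a + g) * L + m_box * a * L] -
#' I * alpha`, where `a` is the sagittal (anteroposterior) trunk linear
#' acceleration at the peak sample, `alpha` the sagittal trunk angular
#' acceleration (rad/s^2, flexion-positive), `L` the horizontal distance from
#' the L5/S1 pivot to the HAT centre of mass at that sample, and `I` the HAT
#' moment of inertia about the pivot. The result can be negative when the
#' lumbar moment is an estimate with error; callers decide whether to clamp
#' (the workday simulation clamps at zero before damage computation).
#'
#' All arguments are vectorized.
#'
#' @param m_lumbar peak lumbar extension moment, Nm.
#' @param m_hat HAT mass, kg.
#' @param L horizontal pivot-to-HAT-COM distance at the peak sample, m.
#' @param a sagittal trunk linear acceleration at the peak sample, m/s^2.
#' @param alpha sagittal trunk angular acceleration at the peak, rad/s^2.
#' @param m_box lifted-object mass, kg.
#' @param I HAT moment of inertia about the pivot, kg m^2.
#' @param g gravitational acceleration, m/s^2.
#' @return load moment, Nm.
#' @export
#' @examples
#' # static case: M_load = M_lumbar - m_hat * g * L
#' lumbar_to_load_moment(200, m_hat = 47.46, L = 0.2)   # 106.88 Nm
lumbar_to_load_moment <- function(m_lumbar, m_hat, L, a = 0, alpha = 0,
                                  m_box = 0, I = 0, g = GRAVITY) {
  if (any(L < 0)) stop_config("L must be >= 0")
  if (any(m_hat <= 0)) stop_config("m_hat must be > 0")
  if (any(m_box < 0)) stop_config("m_box must be >= 0")
  m_lumbar - (m_hat * (a + g) * L + m_box * a * L) - I * alpha
}

#' Per-lift damage fraction
#'
#' The fatigue-failure damage inflicted by one lift with peak load moment
#' `m_load`: `exp(0.038 * m_load + 0.32) / 902416` under the default
#' grouping. The alternative grouping (`"additive_constant"`) treats the
#' 0.32 as a single constant added once per workday after the sum, so its
#' per-lift term is `exp(0.038 * m_load) / 902416`; see
#' [cumulative_damage()].
#'
#' @param m_load peak load moment(s), Nm (finite; may be negative, though
#'   physically meaningful inputs are non-negative).
#' @param grouping `"exponent_inclusive"` (default) or `"additive_constant"`.
#' @return dimensionless damage fraction(s), strictly positive, strictly
#'   increasing and convex in `m_load`.
#' @export
#' @examples
#' per_lift_damage(75)    # 2.638e-5
per_lift_damage <- function(m_load, grouping = c("exponent_inclusive",
                                                 "additive_constant")) {
  grouping <- match.arg(grouping)
  if (any(!is.finite(m_load))) stop_config("m_load must be finite")
  if (grouping == "exponent_inclusive") {
    exp(0.038 * m_load + 0.32) / 902416
  } else {
    exp(0.038 * m_load) / 902416
  }
}

#' Cumulative damage over a sequence of lifts
#'
#' Sums per-lift damage fractions; fatigue-failure accumulation is additive.
#' An empty lift list gives `D = 0`. Under the `"additive_constant"`
#' grouping the 0.32 constant is added once after the sum (and omitted for an
#' empty workday).
#'
#' @param m_loads numeric vector of peak load moments, Nm (may be empty).
#' @inheritParams per_lift_damage
#' @return A list of class `damage_accumulator` with `per_lift_damage`,
#'   cumulative `D` and lift count `n`.
#' @export
#' @examples
#' cumulative_damage(rep(75, 2000))$D    # 5.277e-2
cumulative_damage <- function(m_loads, grouping = c("exponent_inclusive",
                                                    "additive_constant")) {
  grouping <- match.arg(grouping)
  if (length(m_loads) == 0) {
    d <- numeric(0)
    D <- 0
  } else {
    d <- per_lift_damage(m_loads, grouping)
    D <- sum(d)
    if (grouping == "additive_constant") D <- D + 0.32
  }
  structure(list(per_lift_damage = d, D = D, n = length(m_loads)),
            class = "damage_accumulator")
}

#' Low-back disorder risk from cumulative damage
#'
#' Logistic risk of being in a high-risk job: `Y = 1.72 + log10(D)`,
#' `R = exp(Y) / (1 + exp(Y))`. `D = 0` returns the exact limit `R = 0`
#' (an empty workday is a legitimate boundary, not an error).
#'
#' @param D cumulative damage (dimensionless, >= 0; vectorized).
#' @return A list of class `risk_result` with `D`, logit `Y` and probability
#'   `R` (for vector input, vectors of the same length).
#' @export
#' @examples
#' lbd_risk(1)$R          # 0.848
lbd_risk <- function(D) {
  if (any(!is.finite(D)) || any(D < 0)) stop_config("D must be finite and >= 0")
  Y <- ifelse(D > 0, 1.72 + log10(D), -Inf)
  R <- ifelse(D > 0, stats::plogis(Y), 0)
  structure(list(D = D, Y = Y, R = R), class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("D = %.4g, Y = %.4f, LBD risk R = %.1f%%\n",
              x$D[1], x$Y[1], 100 * x$R[1]))
  invisible(x)
}

#' Lift-counter baseline risk
#'
#' Risk of a workday of `n_lifts` lifts when every lift is assumed to inflict
#' the damage of a nominal `nominal_moment` Nm peak load moment; depends only
#' on the lift count.
#'
#' @param n_lifts number of lifts (>= 0; vectorized).
#' @param nominal_moment nominal peak load moment, Nm (default 75).
#' @inheritParams per_lift_damage
#' @return risk probability in `[0, 1)` (vectorized).
#' @export
#' @examples
#' lift_counter_baseline(2000)    # 0.609
lift_counter_baseline <- function(n_lifts, nominal_moment = 75,
                                  grouping = c("exponent_inclusive",
                                               "additive_constant")) {
  grouping <- match.arg(grouping)
  if (any(n_lifts < 0)) stop_config("n_lifts must be >= 0")
  d <- per_lift_damage(nominal_moment, grouping)
  D <- n_lifts * d
  if (grouping == "additive_constant") D <- ifelse(n_lifts > 0, D + 0.32, 0)
  lbd_risk(D)$R
}
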