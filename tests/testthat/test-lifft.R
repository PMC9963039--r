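# The fatigue-failure model and the lumbar-to-load-moment conversion.
# Expected values are computed by independent closed-form/loop oracles,
# frozen where stated.

oracle_damage <- function(m) exp(0.038 * m + 0.32) / 902416

test_that("per-lift damage matches the closed-form oracle at worked values", {
  expect_equal(per_lift_damage(0), exp(0.32) / 902416, tolerance = 1e-12)
  expect_equal(per_lift_damage(0), 1.526e-6, tolerance = 1e-3)
  expect_equal(per_lift_damage(75), exp(0.038 * 75 + 0.32) / 902416,
               tolerance = 1e-12)
  expect_equal(per_lift_damage(75), 2.638e-5, tolerance = 1e-3)
  expect_error(per_lift_damage(NaN), "finite")
})

test_that("vectorized damage/risk match an element-by-element loop on 10k inputs", {
  set.seed(42)
  m <- runif(10000, -50, 300)
  vec <- per_lift_damage(m)
  loop <- vapply(m, oracle_damage, numeric(1))
  expect_equal(vec, loop, tolerance = 1e-12)

  D <- cumsum(abs(vec))[seq(1, 10000, by = 97)]
  vecR <- lbd_risk(D)$R
  loopR <- vapply(D, function(d) {
    y <- 1.72 + log10(d)
    exp(y) / (1 + exp(y))
  }, numeric(1))
  expect_equal(vecR, loopR, tolerance = 1e-12)
})

test_that("cumulative damage is an additive, order-free sum", {
  set.seed(7)
  a <- runif(500, 0, 200)
  b <- runif(300, 0, 200)
  Dab <- cumulative_damage(c(a, b))$D
  expect_equal(Dab, cumulative_damage(a)$D + cumulative_damage(b)$D,
               tolerance = 1e-12)
  expect_equal(cumulative_damage(numeric(0))$D, 0)
  n_same <- cumulative_damage(rep(80, 137))
  expect_equal(n_same$D, 137 * per_lift_damage(80), tolerance = 1e-12)
  expect_identical(n_same$n, 137L)
  expect_true(all(n_same$per_lift_damage > 0))
})

test_that("damage is strictly increasing and convex in load moment", {
  m <- seq(-20, 250, by = 1)
  d <- per_lift_damage(m)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(d, differences = 2) > 0))
  expect_true(per_lift_damage(100) > per_lift_damage(75))
  expect_true(per_lift_damage(75) > per_lift_damage(0))
})

test_that("risk is a logistic in log10 damage with correct limits and bounds", {
  expect_equal(lbd_risk(1)$Y, 1.72)
  expect_equal(lbd_risk(1)$R, exp(1.72) / (1 + exp(1.72)), tolerance = 1e-12)
  expect_equal(lbd_risk(1)$R, 0.848, tolerance = 1e-3)
  expect_identical(lbd_risk(0)$R, 0)       # empty-workday limit, not an error
  expect_error(lbd_risk(-1), ">= 0")
  D <- 10^seq(-8, 4, by = 0.25)
  R <- lbd_risk(D)$R
  expect_true(all(diff(R) > 0))
  expect_true(all(R > 0 & R < 1))
  # R ~ e^1.72 * D^(1/ln 10) near 0, so the approach to the limits is slow
  expect_lt(lbd_risk(1e-12)$R, 1e-4)
  expect_gt(lbd_risk(1e9)$R, 1 - 1e-4)
  # internal consistency R = e^Y/(1+e^Y)
  rr <- lbd_risk(D)
  expect_equal(rr$R, exp(rr$Y) / (1 + exp(rr$Y)), tolerance = 1e-12)
})

test_that("the chained workday oracle reproduces D and R for 2000 nominal lifts", {
  # independent chain: 2000 identical 75 Nm lifts summed by a loop
  D <- 0
  for (i in 1:2000) D <- D + oracle_damage(75)
  expect_equal(D, 5.277e-2, tolerance = 1e-3)
  expect_equal(cumulative_damage(rep(75, 2000))$D, D, tolerance = 1e-12)
  R <- lbd_risk(D)$R
  expect_equal(R, 0.609, tolerance = 1e-3)
  expect_equal(lift_counter_baseline(2000), R, tolerance = 1e-12)
})

test_that("the alternative damage grouping adds the constant once after the sum", {
  m <- c(40, 75, 120)
  expect_equal(cumulative_damage(m, "additive_constant")$D,
               sum(exp(0.038 * m)) / 902416 + 0.32, tolerance = 1e-12)
  expect_equal(cumulative_damage(numeric(0), "additive_constant")$D, 0)
  expect_equal(lift_counter_baseline(0, grouping = "additive_constant"), 0)
})

test_that("lumbar-to-load conversion matches hand arithmetic and is vectorized", {
  # static case: M_load = M_lumbar - m_hat * g * L exactly
  expect_equal(lumbar_to_load_moment(200, m_hat = 47.46, L = 0.2),
               200 - 47.46 * 9.81 * 0.2, tolerance = 1e-12)
  expect_equal(lumbar_to_load_moment(200, m_hat = 47.46, L = 0.2),
               106.8835, tolerance = 1e-4)
  # static case independent of box mass
  expect_equal(lumbar_to_load_moment(200, 47.46, 0.2, m_box = 15),
               lumbar_to_load_moment(200, 47.46, 0.2, m_box = 0))
  # full formula against a hand-written scalar oracle on random inputs
  set.seed(3)
  n <- 200
  ml <- runif(n, 50, 400); mh <- runif(n, 40, 60); L <- runif(n, 0, 0.4)
  a <- runif(n, -3, 3); al <- runif(n, -5, 5); mb <- runif(n, 0, 25)
  I <- runif(n, 3, 9)
  got <- lumbar_to_load_moment(ml, mh, L, a, al, mb, I)
  want <- vapply(seq_len(n), function(i) {
    ml[i] - (mh[i] * (a[i] + 9.81) * L[i] + mb[i] * a[i] * L[i]) - I[i] * al[i]
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(lumbar_to_load_moment(200, m_hat = -1, L = 0.2), "m_hat")
  expect_error(lumbar_to_load_moment(200, m_hat = 47, L = -0.1), "L must")
})

test_that("zero-box trials convert to load moments centred on zero", {
  cfg <- default_config()
  profiles <- sample_participants(5, cfg, seed = 1)
  tasks <- build_task_grid(mass_range = c(0, 0), height_range = c(40, 160),
                           n_masses = 1, n_heights = 10, repetitions = 2)
  ds <- generate_dataset(profiles, tasks, cfg, seed = 1)
  # module-level conversion with the true horizontal arm: exact up to the
  # (tiny) dynamic residual at the quasi-static peak
  resid <- vapply(ds$trials, function(tr) {
    i <- which.max(tr$lumbar_moment_truth)
    lumbar_to_load_moment(tr$lumbar_moment_truth[i], attr(tr, "m_hat"),
                          L = tr$arm_truth[i])
  }, numeric(1))
  expect_lt(max(abs(resid)), 1)
  # pipeline conversion with the table-based arm: unbiased across lifts
  lk <- peak_moment_lookup(ds$trials, NULL, NULL, profiles, cfg)
  expect_lt(abs(mean(lk$peak_load_lab)), 5)
})
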