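# Accuracy metrics and the statistical comparisons.

test_that("rmse matches hand arithmetic and a loop oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(60, 50), c(50, 50)), sqrt(100 / 2))
  expect_equal(rmse(c(60, 50), c(50, 50)), 7.071, tolerance = 1e-4)
  x <- c(10, 20, 30); expect_equal(rmse(x + 5, x), 5)
  set.seed(6)
  a <- rnorm(500); b <- rnorm(500)
  loop <- sqrt(sum(vapply(seq_along(a), function(i) (a[i] - b[i])^2,
                          numeric(1))) / 500)
  expect_equal(rmse(a, b), loop, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("the agreement band is inclusive at exactly +/-10 points", {
  expect_equal(within_band_fraction(75, 65), 1)       # the worked example
  expect_equal(within_band_fraction(75.01, 65), 0)    # boundary + epsilon
  expect_equal(within_band_fraction(55, 65), 1)
  x <- runif(50, 0, 100)
  expect_equal(within_band_fraction(x, x), 1)
  # monotone in the band width
  set.seed(8)
  est <- runif(200, 0, 100); tru <- runif(200, 0, 100)
  f <- vapply(c(0, 5, 10, 20, 50), function(b)
    within_band_fraction(est, tru, b), numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_error(within_band_fraction(1, 1, band = -1), ">= 0")
})

test_that("per-participant Pearson r handles exact and attenuated cases", {
  df <- data.frame(participant_id = rep(1:2, each = 10),
                   truth = rep(1:10, 2))
  df$est <- df$truth
  r <- pearson_by_participant(df, "est", "truth")
  expect_equal(unname(r), c(1, 1))
  df$est <- -df$truth + 7
  expect_equal(unname(pearson_by_participant(df, "est", "truth")),
               c(-1, -1))
  # noise with sd equal to the signal's sd attenuates r to ~1/sqrt(2)
  set.seed(10)
  tru <- rnorm(1000, 50, 10)
  est <- tru + rnorm(1000, 0, sd(tru))
  one <- data.frame(participant_id = 1, truth = tru, est = est)
  expect_equal(unname(pearson_by_participant(one, "est", "truth")),
               1 / sqrt(2), tolerance = 0.05)
  flat <- data.frame(participant_id = 1, truth = rep(1, 5), est = 1:5)
  expect_warning(r0 <- pearson_by_participant(flat, "est", "truth"),
                 "zero variance")
  expect_true(is.na(r0))
})

test_that("Fisher-z averaging matches hand arithmetic and stays bounded", {
  expect_equal(fisher_average(c(0.5, 0.5)), 0.5)
  expect_equal(fisher_average(c(0, 0.8)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_average(0.73), 0.73)
  expect_equal(fisher_average(c(0.2, NA, 0.2)), 0.2)
  set.seed(11)
  r <- runif(8, -0.9, 0.9)
  fa <- fisher_average(r)
  expect_gte(fa, min(r)); expect_lte(fa, max(r))
  expect_error(fisher_average(c(0.5, 1)), "infinite")
})

test_that("paired comparison reproduces hand-computed t and pooled-SD d", {
  res <- compare_conditions(c(2, 3, 4), c(1, 1, 1))   # diffs 1, 2, 3
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2L)
  # vectors with means 15.8 / 4.7 and SDs 2.3 / 1.1
  a <- c(15.8 - 2.3, 15.8, 15.8 + 2.3)
  b <- c(4.7 - 1.1, 4.7, 4.7 + 1.1)
  expect_equal(sd(a), 2.3); expect_equal(sd(b), 1.1)
  res2 <- compare_conditions(a, b)
  expect_equal(res2$d, 11.1 / sqrt((2.3^2 + 1.1^2) / 2), tolerance = 1e-9)
  expect_equal(res2$d, 6.157, tolerance = 1e-3)
  expect_warning(null <- compare_conditions(c(1, 2, 3), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(null$t, 0)
  expect_equal(null$d, 0)
  expect_error(compare_conditions(1:2, 1:2), ">= 3")
})

test_that("trunk-risk drivers: deterministic lookup vs shuffled independence", {
  n <- sample(800:2000, 5000, replace = TRUE)
  res <- data.frame(R_trunk = lift_counter_baseline(n), n_lifts = n,
                    mean_bend_angle = runif(5000, 30, 80))
  dr <- trunk_risk_drivers(res)
  expect_gt(dr$r_vs_lift_count, 0.99)   # risk is a monotone curve in n
  expect_equal(cor(rank(res$R_trunk), rank(res$n_lifts)), 1)  # Spearman 1
  shuffled <- res
  shuffled$n_lifts <- sample(shuffled$n_lifts)
  expect_lt(abs(trunk_risk_drivers(shuffled)$r_vs_lift_count), 0.05)
  expect_lt(abs(dr$r_vs_bend_angle), 0.05)  # angle was independent noise
})

test_that("evaluation summary has coherent per-participant and pooled fields", {
  set.seed(12)
  n_days <- 60
  mk <- function(p, bias) {
    lab <- runif(n_days, 0.3, 0.7)
    data.frame(participant_id = p, n_lifts = sample(800:2000, n_days, TRUE),
               R_lab = lab,
               R_trunk = pmin(pmax(lab + bias + rnorm(n_days, 0, 0.03), 0), 0.99),
               R_trunkforce = pmin(pmax(lab + rnorm(n_days, 0, 0.01), 0), 0.99),
               R_liftcounter = pmin(pmax(lab + 0.2, 0), 0.99),
               n_clamped_lab = 0L, n_clamped_trunk = 0L, n_clamped_trunkforce = 0L,
               mean_bend_angle = runif(n_days, 40, 70))
  }
  res <- rbind(mk(1, 0.15), mk(2, -0.12), mk(3, 0.18))
  ev <- evaluate_workdays(res, default_config())
  per <- ev$per_participant
  expect_equal(nrow(per), 3L)
  expect_true(all(per$within_trunk >= 0 & per$within_trunk <= 1))
  expect_true(all(per$rmse_trunk > per$rmse_trunkforce))
  expect_true(all(abs(per$r_trunk) <= 1, abs(per$r_trunkforce) <= 1))
  expect_equal(ev$pooled$rmse_trunk_mean, mean(per$rmse_trunk))
  # pooled r equals per-participant r when all are equal
  expect_equal(fisher_average(rep(0.8, 3)), 0.8)
  expect_gt(ev$tests$t, 0)
  expect_output(print(ev), "RMSE")
})
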