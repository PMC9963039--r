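# Synthetic lifting generator: cohort sampling, task grid, single-trial
# physics and dataset assembly.

test_that("participant sampling is seeded, range-respecting and needs n >= 2", {
  cfg <- default_config()
  a <- sample_participants(10, cfg, seed = 1)
  b <- sample_participants(10, cfg, seed = 1)
  expect_identical(a, b)
  c2 <- sample_participants(10, cfg, seed = 2)
  expect_false(identical(a, c2))
  expect_error(sample_participants(1, cfg), "cross-validation")
  masses <- vapply(a, `[[`, numeric(1), "body_mass")
  expect_true(all(masses >= cfg$participants$body_mass[1] &
                    masses <= cfg$participants$body_mass[2]))
})

test_that("body mass draws are uniform over the configured range (KS, 10k draws)", {
  cfg <- default_config(participants = list(body_mass = c(60, 100)))
  big <- sample_participants(10000, cfg, seed = 5)
  masses <- vapply(big, `[[`, numeric(1), "body_mass")
  ks <- suppressWarnings(ks.test(masses, "punif", 60, 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("anthro profile enforces its invariants", {
  p <- reference_profile()
  expect_equal(p$hat_mass, 0.678 * 80)
  expect_equal(p$hat_inertia_com,
               p$hat_mass * (p$hat_prism_height^2 + p$hat_prism_depth^2) / 12)
  expect_equal(p$hat_inertia_pivot,
               p$hat_inertia_com + p$hat_mass * p$hat_com_distance^2)
  expect_gt(p$hat_inertia_pivot, p$hat_inertia_com)
  expect_error(anthro_profile(1, 80, 1.75, hat_mass_fraction = 1.2), "hat_mass_fraction")
  expect_error(anthro_profile(1, -5, 1.75), "body_mass")
})

test_that("task grid covers both ranges inclusively with unique pairs", {
  g <- build_task_grid()
  expect_equal(nrow(g), 50L)
  expect_equal(range(g$box_mass), c(5, 23))
  expect_equal(range(g$origin_height), c(40, 160))
  expect_equal(nrow(unique(g[, c("box_mass", "origin_height")])), 50L)

  g1 <- build_task_grid(n_masses = 1, n_heights = 1)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$box_mass, 14)          # midpoint of 5-23
  expect_equal(g1$origin_height, 100)    # midpoint of 40-160

  g12 <- build_task_grid(n_masses = 3, n_heights = 4)
  expect_equal(nrow(g12), 12L)
  expect_equal(nrow(unique(g12[, c("box_mass", "origin_height")])), 12L)
  expect_error(build_task_grid(mass_range = c(10, 5)), "non-decreasing")
  expect_error(build_task_grid(mass_range = c(5, 5), n_masses = 3), "degenerate")
})

test_that("quiet standing and held-box quasi-static force balance hold", {
  cfg <- default_config()
  p <- reference_profile()
  task <- list(task_id = 1L, box_mass = 10, origin_height = 60)
  tr <- simulate_lift(p, task, cfg, seed = 4)
  g <- 9.81
  # initial sample: no box, no motion
  f0 <- tr$foot_force_left[1] + tr$foot_force_right[1]
  expect_lt(abs(f0 - p$body_mass * g) / (p$body_mass * g), 0.005)
  expect_lt(abs(tr$lumbar_moment_truth[1]), 1e-9)
  # every quasi-static held sample supports body + box weight within 1%
  acc <- sqrt(tr$trunk_acc_ap^2 + tr$trunk_acc_vert^2)
  alpha <- abs(c(0, diff(tr$trunk_angvel_flexion)) * attr(tr, "fs")) * pi / 180
  qs <- tr$hold_mask & acc < 0.05 & alpha < 0.05
  expect_gt(sum(qs), 10)
  ftot <- tr$foot_force_left[qs] + tr$foot_force_right[qs]
  want <- (p$body_mass + task$box_mass) * g
  expect_true(all(abs(ftot - want) / want < 0.01))
})

test_that("box mass changes forces but not kinematics for the same seed", {
  cfg <- default_config()
  p <- reference_profile()
  t5 <- simulate_lift(p, list(task_id = 1, box_mass = 5, origin_height = 80),
                      cfg, seed = 9)
  t15 <- simulate_lift(p, list(task_id = 1, box_mass = 15, origin_height = 80),
                       cfg, seed = 9)
  kin <- c("trunk_angle_flexion", "trunk_angle_lateral", "trunk_angle_twist",
           "trunk_angvel_flexion", "trunk_acc_ap", "trunk_acc_vert")
  for (ch in kin) expect_identical(t5[[ch]], t15[[ch]])
  # held-phase quasi-static total force differs by exactly 10 kg * g
  i <- which(t5$hold_mask & t5$trunk_angle_flexion == max(t5$trunk_angle_flexion))[1]
  d <- (t15$foot_force_left[i] + t15$foot_force_right[i]) -
    (t5$foot_force_left[i] + t5$foot_force_right[i])
  expect_equal(d, 10 * 9.81, tolerance = 1e-9)
})

test_that("noise-free peak moment matches the quasi-static closed form", {
  cfg <- noise_free(default_config())
  p <- reference_profile()
  tr <- simulate_lift(p, list(task_id = 1, box_mass = 0, origin_height = 40),
                      cfg, seed = 1)
  theta <- attr(tr, "theta_peak_deg") * pi / 180
  oracle <- p$hat_mass * 9.81 * p$hat_com_distance * sin(theta)
  expect_lt(abs(max(tr$lumbar_moment_truth) - oracle) / oracle, 0.05)
})

test_that("peak moment is monotone in box mass and anti-monotone in shelf height", {
  cfg <- noise_free(default_config())
  p <- reference_profile()
  grid <- build_task_grid()
  peaks <- matrix(NA_real_, 5, 10)
  for (i in seq_len(nrow(grid))) {
    tr <- simulate_lift(p, grid[i, ], cfg, seed = 1)
    peaks[(i - 1) %% 5 + 1, (i - 1) %/% 5 + 1] <- max(tr$lumbar_moment_truth)
  }
  for (h in 1:10) expect_true(all(diff(peaks[, h]) >= 0))   # heavier box
  for (m in 1:5) expect_true(all(diff(peaks[m, ]) <= 0))    # higher shelf
})

test_that("bottom-up moment recomputation agrees with the truth", {
  cfg <- noise_free(default_config())
  p <- reference_profile()
  tr <- simulate_lift(p, list(task_id = 1, box_mass = 18, origin_height = 50),
                      cfg, seed = 2)
  bu <- bottom_up_lumbar_moment(tr)
  expect_lt(sqrt(mean((bu - tr$lumbar_moment_truth)^2)), 5)
})

test_that("degenerate inputs are rejected with explicit errors", {
  p <- reference_profile()
  task <- list(task_id = 1, box_mass = 10, origin_height = 60)
  bad <- default_config()
  bad$sim$dwell <- 0.005
  expect_error(simulate_lift(p, task, bad, 1), "too short")
  expect_error(simulate_lift(p, list(task_id = 1, box_mass = -2,
                                     origin_height = 60),
                             default_config(), 1), "box_mass")
  steep <- default_config(sim = list(flexion_at_low = 140))
  expect_error(simulate_lift(p, list(task_id = 1, box_mass = 5,
                                     origin_height = 40), steep, 1),
               "outside \\[0, 135\\]")
})

test_that("dataset generation is reproducible with a complete manifest", {
  ds <- tiny_dataset()
  expect_equal(length(ds$trials), 3 * 6)
  expect_equal(nrow(ds$manifest), 3 * 6)
  # byte-identical manifests for the same seed
  cfg <- ds$cfg
  tasks <- with(cfg$tasks, build_task_grid(mass_range, height_range,
                                           n_masses, n_heights, repetitions))
  ds2 <- generate_dataset(ds$profiles, tasks, cfg, seed = 11)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(ds$manifest, f1, row.names = FALSE)
  write.csv(ds2$manifest, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # dropping one participant removes exactly tasks x reps rows
  ds3 <- generate_dataset(ds$profiles[-1], tasks, cfg, seed = 11)
  expect_equal(nrow(ds$manifest) - nrow(ds3$manifest), 6L)
  # trial CSVs are written when requested
  out <- tempfile("trials")
  ds4 <- generate_dataset(ds$profiles[1], tasks[1:2, ], cfg, seed = 11,
                          out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_equal(sum(grepl("^P01", list.files(out))), 2L)
})
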