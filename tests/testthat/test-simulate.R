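test_that("simulated trajectories have the requested length and degenerate correctly", {
  cfg <- sim_config(fps = 60, duration_s = 10, seed = 1)
  tr <- simulate_trajectory(cfg)
  expect_equal(nrow(tr), 600L)
  expect_equal(tr$t_s, (0:599) / 60)

  still <- simulate_trajectory(sim_config(mean_speed_cms = 0, seed = 2))
  expect_true(all(still$x_cm == still$x_cm[1]))
  expect_true(all(still$y_cm == still$y_cm[1]))
  expect_true(all(still$z_cm == still$z_cm[1]))
  kin <- compute_kinematics(still)
  expect_true(all(kin$steps$speed_cms == 0))

  expect_error(sim_config(fps = Inf), "finite")
  expect_error(sim_config(outlier_rate = 1), "outlier_rate")
})

test_that("grand-mean realized speed matches the configured mean speed", {
  # Monte-Carlo oracle: the stationary 3D speed is Maxwell with mean equal
  # to mean_speed_cms by construction of the per-axis sd
  speeds <- vapply(1:200, function(s) {
    tr <- simulate_trajectory(sim_config(duration_s = 2, mean_speed_cms = 25,
                                         seed = s))
    mean(compute_kinematics(tr)$steps$speed_cms)
  }, numeric(1))
  expect_lt(abs(mean(speeds) - 25) / 25, 0.10)
})

test_that("identical seeds give byte-identical serialized output", {
  cfg <- sim_config(seed = 42)
  t1 <- corrupt_trajectory(simulate_trajectory(cfg), cfg)
  t2 <- corrupt_trajectory(simulate_trajectory(cfg), cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table_csv(t1, f1, "trajectory")
  write_table_csv(t2, f2, "trajectory")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("corruption is the identity at zero noise and matches its nominal rates", {
  cfg0 <- sim_config(noise_sd_cm = 0, outlier_rate = 0, seed = 5)
  tr <- simulate_trajectory(cfg0)
  ob <- corrupt_trajectory(tr, cfg0)
  expect_equal(ob$x_cm, tr$x_cm)
  expect_equal(ob$y_cm, tr$y_cm)
  expect_equal(ob$z_cm, tr$z_cm)
  expect_false(any(ob$truth_outlier))

  # binomial expectation: 600 frames at rate 0.01 -> ~6 outliers per track
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(outlier_rate = 0.01, seed = s)
    sum(corrupt_trajectory(simulate_trajectory(cfg), cfg)$truth_outlier)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 6), 0.75)

  # law of large numbers: per-axis RMS deviation approaches noise_sd
  cfgN <- sim_config(duration_s = 100, noise_sd_cm = 0.5, outlier_rate = 0,
                     seed = 7)
  trN <- simulate_trajectory(cfgN)
  obN <- corrupt_trajectory(trN, cfgN)
  for (cl in c("x_cm", "y_cm", "z_cm"))
    expect_lt(abs(sqrt(mean((obN[[cl]] - trN[[cl]])^2)) - 0.5), 0.02)
})

test_that("stereo projection of a simulated path round-trips and is epipolar-aligned", {
  cfg <- sim_config(seed = 11, duration_s = 2)
  tr <- simulate_trajectory(cfg)
  rig <- demo_rig()
  st <- project_to_stereo(tr, rig, pixel_noise_sd_px = 0)
  expect_equal(st$n_dropped, 0L)
  pts <- triangulate_tracks(rig, st$left, st$right)
  expect_lt(max(abs(pts - cbind(tr$x_cm, tr$y_cm, tr$z_cm))), 1e-6)

  rt <- rectify_tracks(rig, st$left, st$right)
  expect_lt(max(abs(rt$left[, "v_px"] - rt$right[, "v_px"])), 1e-6)
})

test_that("mean reprojection error under pixel noise matches the Rayleigh-mean oracle", {
  # with per-axis N(0, s) pixel noise the displacement norm is Rayleigh(s):
  # E||e|| = s * sqrt(pi/2); frozen for s = 0.5: 0.6266570686577501
  tr <- simulate_trajectory(sim_config(seed = 21, duration_s = 5))
  rig <- demo_rig()
  clean <- project_to_stereo(tr, rig, pixel_noise_sd_px = 0)
  noisy <- project_to_stereo(tr, rig, pixel_noise_sd_px = 0.5, seed = 9)
  err <- mean(sqrt(rowSums((as.matrix(noisy$left[, c("u_px", "v_px")]) -
                            as.matrix(clean$left[, c("u_px", "v_px")]))^2)))
  expect_lt(abs(err - 0.6266570686577501), 0.05)
})

test_that("synthetic respirometry recovers its generating power law", {
  rsp <- simulate_respirometry(K_true = 3.9994, E_true = 0.7789, n = 40,
                               lognormal_sd = 0, seed = 3)
  fit <- fit_allometry(rsp$mass_g, rsp$smr_mgO2_d)
  expect_equal(unname(coef(fit)["K"]), 3.9994, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["E"]), 0.7789, tolerance = 1e-12)

  # simulation oracle: median exponent error at n = 50, lognormal sd 0.1
  err <- vapply(1:100, function(s) {
    r <- simulate_respirometry(4, 0.78, n = 50, lognormal_sd = 0.1, seed = s)
    abs(fit_allometry(r$mass_g, r$smr_mgO2_d)$E - 0.78)
  }, numeric(1))
  expect_lt(median(err), 0.02)
})

test_that("simulated feeding observations express the configured selectivity", {
  prof <- substrate_profile(c(rock = 0.5, sand = 0.5))
  even <- simulate_feeding_observations(prof, c(rock = 1, sand = 1),
                                        n_fish = 150, seed = 1)
  sel <- manly_ratios(table_to_counts(table(even$substrate)), prof)
  expect_lt(max(abs(sel$preference_pct - 50)), 5)

  # multinomial expectation: weights (3, 1) on equal availability -> 75/25
  skew <- simulate_feeding_observations(prof, c(rock = 3, sand = 1),
                                        n_fish = 300, seed = 2)
  truth <- attr(skew, "truth_selectivity")
  expect_equal(unname(truth["rock"]), 0.75, tolerance = 1e-12)
  sel2 <- manly_ratios(table_to_counts(table(skew$substrate)), prof)
  expect_lt(abs(sel2$preference_pct[["rock"]] - 75), 3)

  empty <- simulate_feeding_observations(prof, c(rock = 1, sand = 1),
                                         n_fish = 0, seed = 3)
  expect_equal(nrow(empty), 0L)
  expect_error(simulate_feeding_observations(prof, c(rock = 0, sand = 0),
                                             n_fish = 2),
               "not all zero")
})
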