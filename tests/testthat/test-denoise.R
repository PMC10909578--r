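test_that("IQR outlier removal places Tukey fences by interpolated quartiles", {
  # x {1..9, 100}: Q1 = 3.25, Q3 = 7.75 (type-7 interpolation), upper fence
  # 7.75 + 1.5 * 4.5 = 14.5 -> only the 100 is removed
  tr <- coord_track(c(1:9, 100))
  res <- remove_outliers_iqr(tr)
  expect_equal(which(res$outlier_mask), 10L)
  expect_equal(nrow(res$trajectory), 9L)

  # tight band, no spikes -> nothing removed
  calm <- coord_track(sin(seq(0, 2 * pi, length.out = 50)))
  expect_equal(sum(remove_outliers_iqr(calm)$outlier_mask), 0L)

  # k -> infinity is the identity
  expect_equal(sum(remove_outliers_iqr(tr, k = 1e9)$outlier_mask), 0L)

  # a spike on any single axis removes the whole frame
  tr_y <- coord_track(rep(1, 10), y = c(rep(0, 5), 50, rep(0, 4)))
  expect_equal(which(remove_outliers_iqr(tr_y)$outlier_mask), 6L)

  short <- coord_track(c(1, 2, 3))
  expect_warning(res3 <- remove_outliers_iqr(short), "shorter than 4")
  expect_equal(nrow(res3$trajectory), 3L)
})

test_that("running median smooths spikes and leaves structure alone", {
  five <- coord_track(c(1, 9, 2, 8, 3))
  sm <- running_median(five, window = 5)
  expect_equal(sm$x_cm[3], 3)           # median of the five values
  expect_equal(nrow(sm), 5L)            # length preserved at the edges

  const <- coord_track(rep(4, 20))
  expect_equal(running_median(const)$x_cm, rep(4, 20))

  # single spike in a linear series is fully removed at the spike frame
  x <- as.numeric(1:21); x[11] <- 100
  sm2 <- running_median(coord_track(x), window = 5)
  expect_lte(abs(sm2$x_cm[11] - 11), 1)  # spike replaced by a neighbour value

  expect_error(running_median(const, window = 4), "odd")
})

test_that("Kalman smoother is exact on model-consistent input and shrinks toward data as meas_sd -> 0", {
  lin <- linear_track(n = 120, v = c(30, -10, 5))
  sm <- kalman_smooth(lin, meas_sd = 0.5, process_sd = 50)
  expect_lt(max(abs(sm$x_cm - lin$x_cm)), 1e-6)
  expect_lt(max(abs(sm$y_cm - lin$y_cm)), 1e-6)
  expect_lt(max(abs(sm$z_cm - lin$z_cm)), 1e-6)

  set.seed(8)
  wig <- coord_track(cumsum(rnorm(80)))
  sm0 <- kalman_smooth(wig, meas_sd = 1e-6, process_sd = 50)
  expect_lt(max(abs(sm0$x_cm - wig$x_cm)), 1e-3)

  expect_error(kalman_smooth(wig, meas_sd = -1), "positive")
})

test_that("Kalman smoother agrees with a batch MAP oracle on a tiny series", {
  # independent oracle: the RTS smoother mean equals the MAP of the joint
  # linear-Gaussian model, solved here as one dense least-squares problem in
  # the stacked states (p_i, v_i)
  set.seed(12)
  y <- cumsum(rnorm(8)); t <- (0:7) / 60
  meas_sd <- 0.5; process_sd <- 50
  n <- length(y); dt <- diff(t)
  v0 <- (y[2] - y[1]) / dt[1]
  P0 <- diag(c(meas_sd^2, max(4 * meas_sd^2 / dt[1]^2, 1)))
  rows <- list(); rhs <- c()
  add <- function(A, b, W) {
    L <- chol(solve(W))   # whiten: L A z = L b
    rows[[length(rows) + 1]] <<- L %*% A; rhs <<- c(rhs, as.numeric(L %*% b))
  }
  Z <- function(i) {  # selector of state i in the stacked vector
    M <- matrix(0, 2, 2 * n); M[1, 2 * i - 1] <- 1; M[2, 2 * i] <- 1; M
  }
  add(Z(1), c(y[1], v0), P0)                          # prior on first state
  for (i in 1:(n - 1)) {
    F_ <- matrix(c(1, 0, dt[i], 1), 2, 2)
    Q <- process_sd^2 * matrix(c(dt[i]^3 / 3, dt[i]^2 / 2,
                                 dt[i]^2 / 2, dt[i]), 2, 2)
    add(Z(i + 1) - F_ %*% Z(i), c(0, 0), Q)           # transition
  }
  for (i in 1:n) add(Z(i)[1, , drop = FALSE], y[i], matrix(meas_sd^2)) # obs
  A <- do.call(rbind, rows)
  zhat <- qr.solve(A, rhs)
  oracle <- zhat[seq(1, 2 * n, by = 2)]

  sm <- kalman_smooth(coord_track(y, fps = 60), meas_sd, process_sd)
  expect_equal(sm$x_cm, oracle, tolerance = 1e-8)
})

test_that("the full chain improves corrupted tracks and respects gaps", {
  wins <- vapply(1:25, function(s) {
    cfg <- sim_config(noise_sd_cm = 0.5, outlier_rate = 0.01, seed = s)
    tru <- simulate_trajectory(cfg)
    obs <- corrupt_trajectory(tru, cfg)
    dn <- denoise_trajectory(obs)
    rmse_vs_truth(dn$trajectory, tru) < rmse_vs_truth(obs, tru)
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # chain applied to an already-clean model-consistent track barely moves it
  lin <- linear_track(n = 200, v = c(20, 5, -8))
  dn <- denoise_trajectory(lin)
  expect_lt(max(abs(dn$trajectory$x_cm - lin$x_cm)), 0.5 / 10)
  expect_equal(dn$n_outliers_removed, 0L)
})

test_that("axis relabeling commutes with every denoising stage", {
  cfg <- sim_config(seed = 17)
  obs <- corrupt_trajectory(simulate_trajectory(cfg), cfg)
  for (f in list(function(tr) remove_outliers_iqr(tr)$trajectory,
                 running_median,
                 kalman_smooth)) {
    a <- swap_axes(f(obs), "x_cm", "y_cm")
    b <- f(swap_axes(obs, "x_cm", "y_cm"))
    expect_equal(a$x_cm, b$x_cm)
    expect_equal(a$y_cm, b$y_cm)
    expect_equal(a$z_cm, b$z_cm)
  }
})

test_that("kinematics are exact finite differences and never span gaps", {
  # x {0, 1, 3} cm at 60 fps -> vx {60, 120} cm/s, ax {3600} cm/s^2
  tr <- coord_track(c(0, 1, 3))
  kin <- compute_kinematics(tr)
  expect_equal(kin$steps$vx_cms, c(60, 120))
  expect_equal(kin$accel$ax_cms2, 3600)

  # consecutive points 1 cm apart -> speed 60 cm/s; linear motion -> a = 0
  lin <- linear_track(n = 10, v = c(60, 0, 0))
  kl <- compute_kinematics(lin)
  expect_equal(kl$steps$speed_cms, rep(60, 9))
  expect_true(all(abs(kl$accel$ax_cms2) < 1e-9))

  # a gap splits the series: no velocity across it, accelerations only
  # where three consecutive frames exist
  df <- data.frame(frame = c(0:3, 6:9), x_cm = 1:8, y_cm = 0, z_cm = 150)
  kg <- compute_kinematics(trajectory3d(df, fps = 60))
  expect_equal(kg$steps$frame, c(0, 1, 2, 6, 7, 8))
  expect_equal(kg$accel$frame, c(0, 1, 6, 7))
})
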