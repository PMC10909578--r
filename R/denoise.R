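#' Interquartile-range outlier removal
#'
#' Per-axis Tukey fences over the whole track: quartiles Q1, Q3 computed by
#' linear interpolation between order statistics ([stats::quantile()] type 7),
#' fences at `Q1 - k*IQR` and `Q3 + k*IQR`. A frame is removed when ANY of
#' its three coordinates falls outside the fences of its axis, leaving a gap
#' in the frame index; downstream stages are gap-aware and never difference
#' across a gap.
#'
#' @param traj a [trajectory3d()].
#' @param k fence multiplier, default 1.5.
#' @return list with `trajectory` (frames retained) and `outlier_mask`
#'   (logical, TRUE where a frame was removed).
#' @export
remove_outliers_iqr <- function(traj, k = 1.5) {
  if (nrow(traj) < 4L) {
    warning("track shorter than 4 frames: outlier screen skipped")
    return(list(trajectory = traj, outlier_mask = rep(FALSE, nrow(traj))))
  }
  out <- rep(FALSE, nrow(traj))
  for (cl in c("x_cm", "y_cm", "z_cm"))
    out <- out | iqr_outlier_mask(traj[[cl]], k)
  keep <- traj[!out, , drop = FALSE]
  attr(keep, "fps") <- traj_fps(traj)
  class(keep) <- class(traj)
  list(trajectory = keep, outlier_mask = out)
}

# shared IQR fence rule (also used for trait screening)
iqr_outlier_mask <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Running-median smoothing
#'
#' Centered running median applied per axis, default window 5 (at a 60 Hz
#' acquisition rate a 5-point window preserves features down to ~10 Hz while
#' suppressing isolated spikes). At the track ends the window shrinks
#' symmetrically (width 3 at the penultimate samples, 1 at the ends), so
#' output length equals input length.
#'
#' @param traj a [trajectory3d()].
#' @param window odd window width >= 3, default 5.
#' @return the smoothed [trajectory3d()].
#' @export
running_median <- function(traj, window = 5L) {
  if (window %% 2L == 0L || window < 3L)
    stop("'window' must be an odd integer >= 3")
  sm <- traj
  if (nrow(traj) > 1L) {
    k <- min(window, if (nrow(traj) %% 2L == 0L) nrow(traj) - 1L else nrow(traj))
    if (k >= 3L)
      for (cl in c("x_cm", "y_cm", "z_cm"))
        sm[[cl]] <- as.numeric(stats::runmed(traj[[cl]], k, endrule = "median"))
  }
  attr(sm, "fps") <- traj_fps(traj)
  class(sm) <- class(traj)
  sm
}

# Per-axis forward Kalman filter + Rauch-Tung-Striebel smoother for a
# constant-velocity state [position, velocity], position-only observation.
# Time-aware transition bridges gaps left by outlier removal. Process noise
# is continuous white acceleration with intensity process_sd^2:
#   Q(dt) = process_sd^2 * [[dt^3/3, dt^2/2], [dt^2/2, dt]].
# The state is initialized from the first two observations so that data
# exactly consistent with the model (noise-free uniform motion) pass through
# unchanged.
rts_smooth_axis <- function(y, t, meas_sd, process_sd) {
  n <- length(y)
  r <- meas_sd^2; q <- process_sd^2
  xf <- matrix(0, n, 2); xp <- matrix(0, n, 2)
  Pf <- array(0, c(2, 2, n)); Pp <- array(0, c(2, 2, n))
  v0 <- if (n >= 2) (y[2] - y[1]) / (t[2] - t[1]) else 0
  x <- c(y[1], v0)
  P <- matrix(c(r, 0, 0, max(4 * r / (t[min(2, n)] - t[1])^2, 1)), 2, 2)
  xp[1, ] <- x; Pp[, , 1] <- P
  for (i in seq_len(n)) {
    if (i > 1L) {
      dt <- t[i] - t[i - 1]
      F_ <- matrix(c(1, 0, dt, 1), 2, 2)
      Q <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
      x <- as.numeric(F_ %*% x)
      P <- F_ %*% P %*% t(F_) + Q
      xp[i, ] <- x; Pp[, , i] <- P
    }
    S <- P[1, 1] + r
    K <- P[, 1] / S
    x <- x + K * (y[i] - x[1])
    P <- P - outer(K, P[1, ])
    xf[i, ] <- x; Pf[, , i] <- P
  }
  xs <- xf
  if (n > 1L) for (i in (n - 1L):1L) {
    dt <- t[i + 1] - t[i]
    F_ <- matrix(c(1, 0, dt, 1), 2, 2)
    G <- Pf[, , i] %*% t(F_) %*% solve(Pp[, , i + 1])
    xs[i, ] <- xf[i, ] + as.numeric(G %*% (xs[i + 1, ] - xp[i + 1, ]))
  }
  xs[, 1]
}

#' Kalman smoothing of a 3D trajectory
#'
#' Per-axis linear-Gaussian state-space model with position+velocity state,
#' constant-velocity transition at the frame interval, position-only
#' observation; a forward filter followed by a Rauch-Tung-Striebel backward
#' smoother (tracks are processed offline, so the two-sided smoother is used
#' rather than the causal filter). Gaps in the frame index are bridged by
#' time-aware prediction.
#'
#' @param traj a [trajectory3d()].
#' @param meas_sd measurement noise standard deviation, cm (default 0.5).
#' @param process_sd process noise intensity (white acceleration), cm/s^2
#'   (default 50).
#' @return the smoothed [trajectory3d()].
#' @export
kalman_smooth <- function(traj, meas_sd = 0.5, process_sd = 50) {
  if (nrow(traj) < 2L) stop("need at least 2 frames")
  if (!is.finite(meas_sd) || meas_sd <= 0 || !is.finite(process_sd) ||
      process_sd <= 0)
    stop("'meas_sd' and 'process_sd' must be positive")
  sm <- traj
  for (cl in c("x_cm", "y_cm", "z_cm"))
    sm[[cl]] <- rts_smooth_axis(traj[[cl]], traj$t_s, meas_sd, process_sd)
  attr(sm, "fps") <- traj_fps(traj)
  class(sm) <- class(traj)
  sm
}

#' Three-step trajectory denoising chain
#'
#' Applies, in fixed order: (1) IQR outlier removal ([remove_outliers_iqr()]),
#' needed because the Kalman stage assumes Gaussian measurement noise and is
#' sensitive to gross outliers; (2) 5-point running-median smoothing
#' ([running_median()]); (3) constant-velocity Kalman smoothing
#' ([kalman_smooth()]).
#'
#' @param traj a [trajectory3d()].
#' @param iqr_k IQR fence multiplier.
#' @param median_window running-median window.
#' @param meas_sd,process_sd Kalman noise parameters, cm and cm/s^2.
#' @return list with `trajectory` (denoised), `n_outliers_removed`, and
#'   `outlier_mask` relative to the input frames.
#' @export
denoise_trajectory <- function(traj, iqr_k = 1.5, median_window = 5L,
                               meas_sd = 0.5, process_sd = 50) {
  st1 <- remove_outliers_iqr(traj, k = iqr_k)
  st2 <- running_median(st1$trajectory, window = median_window)
  st3 <- kalman_smooth(st2, meas_sd = meas_sd, process_sd = process_sd)
  list(trajectory = st3,
       n_outliers_removed = sum(st1$outlier_mask),
       outlier_mask = st1$outlier_mask)
}
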