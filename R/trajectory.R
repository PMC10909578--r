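#' 3D trajectory container
#'
#' A `trajectory3d` is a data frame with one row per retained video frame and
#' columns `track_id`, `species`, `frame` (integer frame index, strictly
#' increasing), `t_s` (time in seconds), and `x_cm`, `y_cm`, `z_cm`
#' (coordinates in centimetres, left-camera frame). The acquisition rate is
#' stored in the `fps` attribute and must be constant within a track. Extra
#' columns (e.g. `truth_*` ground-truth columns written by the simulator) are
#' preserved but never consumed by the analysis stages.
#'
#' @param df data frame with at least `frame`, `x_cm`, `y_cm`, `z_cm`.
#'   `t_s` is derived from `frame`/`fps` when absent; `track_id` and
#'   `species` default to `"track1"` / `"unknown"`.
#' @param fps acquisition rate, frames per second (> 0).
#' @return a `trajectory3d` object (data frame subclass).
#' @export
trajectory3d <- function(df, fps = 60) {
  stopifnot(is.data.frame(df))
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number")
  need <- c("frame", "x_cm", "y_cm", "z_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "))
  if (!("t_s" %in% names(df))) df$t_s <- df$frame / fps
  if (!("track_id" %in% names(df))) df$track_id <- "track1"
  if (!("species" %in% names(df))) df$species <- "unknown"
  for (cl in c("frame", "t_s", "x_cm", "y_cm", "z_cm")) {
    if (!is.numeric(df[[cl]])) stop("column '", cl, "' must be numeric")
    if (anyNA(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("column '", cl, "' contains non-finite values")
  }
  if (nrow(df) > 1L && any(diff(df$frame) <= 0))
    stop("'frame' must be strictly increasing within a track")
  df <- df[, c("track_id", "species", "frame", "t_s", "x_cm", "y_cm", "z_cm",
               setdiff(names(df), c("track_id", "species", "frame", "t_s",
                                    "x_cm", "y_cm", "z_cm")))]
  attr(df, "fps") <- fps
  class(df) <- c("trajectory3d", "data.frame")
  df
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frames @ %g fps, track '%s' (%s)\n",
              nrow(x), attr(x, "fps"), x$track_id[1], x$species[1]))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("... (", nrow(x) - 4L, " more frames)\n", sep = "")
  invisible(x)
}

#' @export
plot.trajectory3d <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (cl in c("x_cm", "y_cm", "z_cm"))
    graphics::plot(x$t_s, x[[cl]], type = "l", xlab = "t [s]", ylab = cl, ...)
  invisible(x)
}

traj_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) stop("trajectory has no 'fps' attribute")
  fps
}

traj_matrix <- function(traj) {
  cbind(x = traj$x_cm, y = traj$y_cm, z = traj$z_cm)
}

#' Per-frame kinematics of a 3D trajectory
#'
#' Speed is the Euclidean displacement between consecutive frames times the
#' frame rate (cm/s, one value per frame pair); per-axis velocities are the
#' corresponding coordinate differences times the frame rate; per-axis
#' accelerations are velocity differences times the frame rate (cm/s^2, one
#' value per frame triple). When outlier removal has left gaps in the frame
#' index, differences that would span a gap are never computed: the series is
#' split at gaps and only within-segment differences are returned.
#'
#' @param traj a [trajectory3d()].
#' @return a `kinematics` object: list with elements `steps` (data frame
#'   `frame`, `speed_cms`, `vx_cms`, `vy_cms`, `vz_cms`; `frame` labels the
#'   leading frame of each consecutive pair) and `accel` (data frame `frame`,
#'   `ax_cms2`, `ay_cms2`, `az_cms2`, computed where three consecutive frames
#'   exist), plus `fps`.
#' @export
compute_kinematics <- function(traj) {
  if (nrow(traj) < 3L) stop("need at least 3 frames to compute kinematics")
  fps <- traj_fps(traj)
  p <- traj_matrix(traj)
  fr <- traj$frame
  dfr <- diff(fr)
  consec <- dfr == 1L             # frame pairs with no gap
  dv <- apply(p, 2, diff, simplify = FALSE)
  vx <- dv$x * fps; vy <- dv$y * fps; vz <- dv$z * fps
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  steps <- data.frame(frame = fr[-length(fr)],
                      speed_cms = speed, vx_cms = vx, vy_cms = vy,
                      vz_cms = vz)[consec, , drop = FALSE]
  # acceleration needs two adjacent gap-free steps
  ok <- consec[-length(consec)] & consec[-1L]
  ax <- diff(vx) * fps; ay <- diff(vy) * fps; az <- diff(vz) * fps
  accel <- data.frame(frame = fr[seq_len(length(fr) - 2L)],
                      ax_cms2 = ax, ay_cms2 = ay,
                      az_cms2 = az)[ok, , drop = FALSE]
  rownames(steps) <- rownames(accel) <- NULL
  structure(list(steps = steps, accel = accel, fps = fps),
            class = "kinematics")
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics> %d speed steps, %d acceleration frames @ %g fps\n",
              nrow(x$steps), nrow(x$accel), x$fps))
  cat(sprintf("  mean speed %.2f cm/s\n", mean(x$steps$speed_cms)))
  invisible(x)
}
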