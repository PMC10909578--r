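# shared fixtures: built in code, no data files

# uniform linear motion track (model-consistent for every denoising stage)
linear_track <- function(n = 60, v = c(30, 0, 0), fps = 60, origin = c(0, 0, 150)) {
  t <- (seq_len(n) - 1) / fps
  trajectory3d(data.frame(frame = seq_len(n) - 1L,
                          x_cm = origin[1] + v[1] * t,
                          y_cm = origin[2] + v[2] * t,
                          z_cm = origin[3] + v[3] * t),
               fps = fps)
}

# trajectory from explicit coordinate vectors
coord_track <- function(x, y = NULL, z = NULL, fps = 60) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  if (is.null(z)) z <- rep(150, n)
  trajectory3d(data.frame(frame = seq_len(n) - 1L, x_cm = x, y_cm = y,
                          z_cm = z), fps = fps)
}

# random 3D points comfortably inside the demo rig's shared field of view
random_scene_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n, -30, 30), runif(n, -20, 20), runif(n, 80, 300))
}

# swap two coordinate axes of a trajectory (for commutation properties)
swap_axes <- function(traj, a = "x_cm", b = "y_cm") {
  df <- as.data.frame(traj)
  tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp
  trajectory3d(df, fps = attr(traj, "fps"))
}

table_to_counts <- function(tb) stats::setNames(as.numeric(tb), names(tb))

rmse_vs_truth <- function(traj, truth) {
  # align on frame index (outlier removal may have dropped frames)
  m <- match(traj$frame, truth$frame)
  d <- cbind(traj$x_cm - truth$x_cm[m], traj$y_cm - truth$y_cm[m],
             traj$z_cm - truth$z_cm[m])
  sqrt(mean(rowSums(d^2)))
}
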