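#' Two-camera pinhole rig
#'
#' Describes a calibrated stereo pair: per-camera pinhole intrinsics with
#' radial (`k1`, `k2`) and tangential (`p1`, `p2`) distortion, and the pose of
#' the right camera relative to the left. The world frame is the left camera
#' frame; units are centimetres; pixel origin top-left, +x right, +y down.
#' A point `X` in the left frame maps to `R %*% X + t` in the right frame.
#'
#' Calibration parameter estimation (checkerboard solving) is out of scope:
#' parameters arrive from an external calibration, via [read_rig()] or this
#' constructor.
#'
#' @param left,right camera parameter lists with fields `fx`, `fy`, `cx`,
#'   `cy` (pixels) and optionally `k1`, `k2`, `p1`, `p2` (default 0).
#' @param rotation 3x3 orthonormal rotation of the right camera relative to
#'   the left.
#' @param translation length-3 baseline vector (cm), `|translation| > 0`.
#' @param image_size `c(width, height)` in pixels.
#' @return a `camera_rig` object.
#' @export
camera_rig <- function(left, right, rotation, translation,
                       image_size = c(1920L, 1080L)) {
  cam <- function(p, side) {
    defaults <- list(k1 = 0, k2 = 0, p1 = 0, p2 = 0)
    p <- utils::modifyList(defaults, as.list(p))
    need <- c("fx", "fy", "cx", "cy")
    if (!all(need %in% names(p)))
      stop(side, " camera needs fields fx, fy, cx, cy")
    if (p$fx <= 0 || p$fy <= 0) stop(side, " camera focal lengths must be > 0")
    p[c("fx", "fy", "cx", "cy", "k1", "k2", "p1", "p2")]
  }
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("'rotation' must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("'rotation' must be orthonormal (R'R = I to 1e-10)")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || sqrt(sum(translation^2)) <= 0)
    stop("'translation' must be a length-3 vector with positive norm")
  structure(list(left = cam(left, "left"), right = cam(right, "right"),
                 rotation = rotation, translation = translation,
                 image_size = as.numeric(image_size)),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  b <- sqrt(sum(x$translation^2))
  cat(sprintf("<camera_rig> baseline %.2f cm, image %dx%d px\n",
              b, x$image_size[1], x$image_size[2]))
  cat(sprintf("  left : fx=%.1f fy=%.1f c=(%.1f,%.1f) k1=%.3g k2=%.3g\n",
              x$left$fx, x$left$fy, x$left$cx, x$left$cy, x$left$k1, x$left$k2))
  cat(sprintf("  right: fx=%.1f fy=%.1f c=(%.1f,%.1f) k1=%.3g k2=%.3g\n",
              x$right$fx, x$right$fy, x$right$cx, x$right$cy,
              x$right$k1, x$right$k2))
  invisible(x)
}

rot_about_y <- function(theta) {
  matrix(c(cos(theta), 0, -sin(theta),
           0, 1, 0,
           sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
}

#' Demonstration stereo rig
#'
#' A synthetic action-camera-like converging rig: 1080p images, ~1400 px
#' focal length, 40 cm baseline along x with a slight (2 degree) convergence,
#' and mild radial/tangential distortion. Geometry plausible for a
#' diver-deployed two-camera frame filming a 1 m quadrat at 0.5-3 m range.
#'
#' @param distortion logical; set `FALSE` for an ideal distortion-free rig.
#' @return a [camera_rig()].
#' @export
demo_rig <- function(distortion = TRUE) {
  d <- if (distortion) list(k1 = -0.12, k2 = 0.02, p1 = 5e-4, p2 = -3e-4)
       else list(k1 = 0, k2 = 0, p1 = 0, p2 = 0)
  left <- c(list(fx = 1400, fy = 1405, cx = 962, cy = 538), d)
  right <- c(list(fx = 1395, fy = 1398, cx = 958, cy = 542), d)
  conv <- 2 * pi / 180
  camera_rig(left, right,
             rotation = rot_about_y(conv),
             translation = c(-40, 0, 0),   # right camera 40 cm to the left cam's +x
             image_size = c(1920, 1080))
}

apply_distortion <- function(cam, xn, yn) {
  r2 <- xn^2 + yn^2
  radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  xd <- xn * radial + 2 * cam$p1 * xn * yn + cam$p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + cam$p1 * (r2 + 2 * yn^2) + 2 * cam$p2 * xn * yn
  cbind(xd, yd)
}

# invert the distortion map by fixed-point iteration
undistort_normalized <- function(cam, xd, yd, max_iter = 20L, tol = 1e-12) {
  xn <- xd; yn <- yd
  for (i in seq_len(max_iter)) {
    d <- apply_distortion(cam, xn, yn)
    ex <- d[, 1] - xd; ey <- d[, 2] - yd
    xn <- xn - ex; yn <- yn - ey
    if (max(abs(ex), abs(ey)) < tol) break
  }
  cbind(xn, yn)
}

cam_params <- function(rig, side) {
  side <- match.arg(side, c("left", "right"))
  rig[[side]]
}

to_camera_frame <- function(rig, side, pts) {
  if (side == "right") pts <- pts %*% t(rig$rotation) +
      matrix(rig$translation, nrow(pts), 3, byrow = TRUE)
  pts
}

#' Project 3D points through one camera of a rig
#'
#' Standard pinhole projection: transform into the camera frame, perspective
#' division, radial/tangential distortion of the normalized coordinates, then
#' pixel mapping through the intrinsics.
#'
#' @param rig a [camera_rig()].
#' @param side `"left"` or `"right"`.
#' @param points3d numeric matrix (n x 3) or length-3 vector, cm, in the
#'   left-camera (world) frame.
#' @return n x 2 matrix of pixel coordinates `(u_px, v_px)`.
#' @export
project_point <- function(rig, side, points3d) {
  side <- match.arg(side, c("left", "right"))
  pts <- if (is.null(dim(points3d))) matrix(points3d, 1, 3) else as.matrix(points3d)
  pc <- to_camera_frame(rig, side, pts)
  if (any(pc[, 3] <= 0))
    stop("point(s) at or behind the ", side, " camera (depth <= 0)")
  cam <- cam_params(rig, side)
  d <- apply_distortion(cam, pc[, 1] / pc[, 3], pc[, 2] / pc[, 3])
  cbind(u_px = cam$fx * d[, 1] + cam$cx, v_px = cam$fy * d[, 2] + cam$cy)
}

# Fusiello-style rectifying rotation: new x axis along the baseline, new z
# close to the left optical axis. Returns the rotation taking left-frame
# coordinates into the rectified frame.
rectifying_rotation <- function(rig) {
  c2 <- -crossprod(rig$rotation, rig$translation)[, 1]  # right centre, left frame
  e1 <- c2 / sqrt(sum(c2^2))
  if (e1[1] < 0) e1 <- -e1                       # keep +x to the right
  e2 <- c(-e1[2], e1[1], 0)
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-12) e2 <- c(0, 1, 0) else e2 <- e2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rbind(e1, e2, e3)
}

rectified_intrinsics <- function(rig) {
  list(f = rig$left$fx, cx = rig$left$cx, cy = rig$left$cy,
       baseline = sqrt(sum(rig$translation^2)))
}

#' Rectify matched pixel tracks
#'
#' Undistorts both tracks, rotates the viewing rays into a common rectified
#' frame whose x axis lies along the baseline, and re-projects with shared
#' intrinsics (the left camera's `fx` as common focal length). After
#' rectification corresponding points share a row (`v_px`) coordinate up to
#' noise, and triangulation reduces to the 1D disparity formula.
#'
#' @param rig a [camera_rig()].
#' @param left_track,right_track data frames or matrices with pixel columns
#'   `u_px`, `v_px`, frame-synchronized row by row.
#' @return list with `left`, `right` (rectified pixel matrices),
#'   `rotations` (list of the two rectifying rotations, left-frame and
#'   right-frame), and `intrinsics` (common `f`, `cx`, `cy`, `baseline`).
#' @export
rectify_tracks <- function(rig, left_track, right_track) {
  lp <- as.matrix(as.data.frame(left_track)[, c("u_px", "v_px")])
  rp <- as.matrix(as.data.frame(right_track)[, c("u_px", "v_px")])
  if (nrow(lp) != nrow(rp))
    stop("left/right tracks differ in length (", nrow(lp), " vs ", nrow(rp),
         "): tracks must be frame-synchronized")
  Rrect <- rectifying_rotation(rig)
  Rl <- Rrect
  Rr <- Rrect %*% t(rig$rotation)
  ki <- rectified_intrinsics(rig)
  rect_one <- function(cam, px, Rside) {
    n <- undistort_normalized(cam, (px[, 1] - cam$cx) / cam$fx,
                              (px[, 2] - cam$cy) / cam$fy)
    rays <- cbind(n[, 1], n[, 2], 1) %*% t(Rside)
    cbind(u_px = ki$f * rays[, 1] / rays[, 3] + ki$cx,
          v_px = ki$f * rays[, 2] / rays[, 3] + ki$cy)
  }
  list(left = rect_one(rig$left, lp, Rl),
       right = rect_one(rig$right, rp, Rr),
       rotations = list(left = Rl, right = Rr),
       intrinsics = ki)
}

#' Triangulate rectified correspondences
#'
#' For a rectified pair the depth along the rectified optical axis is
#' `f * baseline / disparity` with `disparity = u_left - u_right`; lateral
#' coordinates are back-projected and the result is rotated back into the
#' left-camera frame. Exact inverse of projection on noise-free input.
#'
#' @param rig a [camera_rig()].
#' @param left_px,right_px rectified pixel matrices (`u_px`, `v_px`), as
#'   produced by [rectify_tracks()].
#' @param rotations the rectifying rotations returned by [rectify_tracks()];
#'   recomputed from the rig when omitted.
#' @return n x 3 matrix of points (cm) in the left-camera frame.
#' @export
triangulate <- function(rig, left_px, right_px, rotations = NULL) {
  lp <- as.matrix(left_px); rp <- as.matrix(right_px)
  if (is.null(rotations)) rotations <- list(left = rectifying_rotation(rig))
  ki <- rectified_intrinsics(rig)
  disp <- lp[, 1] - rp[, 1]
  if (any(!is.finite(disp)))
    stop("non-finite disparity: pixel coordinates could not be undistorted")
  if (any(disp <= 0))
    stop("non-positive disparity: degenerate stereo geometry for ",
         sum(disp <= 0), " point(s)")
  z <- ki$f * ki$baseline / disp
  x <- (lp[, 1] - ki$cx) * z / ki$f
  y <- (lp[, 2] - ki$cy) * z / ki$f
  pts_rect <- cbind(x, y, z)
  pts <- pts_rect %*% rotations$left   # R' applied row-wise
  colnames(pts) <- c("x_cm", "y_cm", "z_cm")
  pts
}

#' Triangulate raw (distorted) pixel tracks
#'
#' Convenience wrapper: [rectify_tracks()] then [triangulate()].
#'
#' @inheritParams rectify_tracks
#' @return n x 3 matrix of points (cm) in the left-camera frame.
#' @export
triangulate_tracks <- function(rig, left_track, right_track) {
  rt <- rectify_tracks(rig, left_track, right_track)
  triangulate(rig, rt$left, rt$right, rt$rotations)
}

#' Calibration accuracy from repeated measurements of a known spacing
#'
#' Summarizes measured distances between reference marks of known separation
#' (e.g. dots 199 mm apart on a calibration frame) as mean absolute error and
#' mean absolute percentage error.
#'
#' @param measured_mm numeric vector of measured distances, mm.
#' @param known_spacing_mm true mark separation, mm (default 199).
#' @return a `calibration_check` list: `known_spacing_mm`, `measured_mm`,
#'   `mae_mm`, `mae_sd_mm`, `mape_pct`.
#' @export
calibration_accuracy <- function(measured_mm, known_spacing_mm = 199) {
  measured_mm <- as.numeric(measured_mm)
  if (length(measured_mm) == 0L || anyNA(measured_mm))
    stop("need at least one finite measured distance")
  err <- abs(measured_mm - known_spacing_mm)
  structure(list(known_spacing_mm = known_spacing_mm,
                 measured_mm = measured_mm,
                 mae_mm = mean(err),
                 mae_sd_mm = if (length(err) > 1L) stats::sd(err) else NA_real_,
                 mape_pct = mean(err / known_spacing_mm) * 100),
            class = "calibration_check")
}

#' @export
print.calibration_check <- function(x, ...) {
  cat(sprintf("<calibration_check> n=%d vs %g mm: MAE %.2f mm, MAPE %.2f%%\n",
              length(x$measured_mm), x$known_spacing_mm, x$mae_mm, x$mape_pct))
  invisible(x)
}

#' Pixel-space reprojection error
#'
#' Mean Euclidean distance, in pixels, between observed pixel positions and
#' the projections of given 3D points. Distinct from the millimetre-scale 3D
#' reconstruction error reported by [reconstruction_error()].
#'
#' @param rig a [camera_rig()].
#' @param side `"left"` or `"right"`.
#' @param points3d n x 3 matrix, cm, left-camera frame.
#' @param pixels n x 2 observed pixel matrix.
#' @return mean reprojection error in pixels.
#' @export
reprojection_error_px <- function(rig, side, points3d, pixels) {
  pr <- project_point(rig, side, points3d)
  px <- as.matrix(pixels)
  mean(sqrt(rowSums((pr - px[, 1:2])^2)))
}

#' 3D reconstruction error
#'
#' Mean Euclidean distance between triangulated and reference 3D points,
#' reported in millimetres (10 x cm).
#'
#' @param estimated,truth n x 3 matrices, cm.
#' @return mean 3D error in mm.
#' @export
reconstruction_error <- function(estimated, truth) {
  e <- as.matrix(estimated); t3 <- as.matrix(truth)
  mean(sqrt(rowSums((e - t3)^2))) * 10
}
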