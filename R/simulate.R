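#' Trajectory simulation settings
#'
#' Parameters of the synthetic swim-path generator and its corruption model.
#' The movement model is a mean-reverting (Ornstein-Uhlenbeck) velocity
#' process per axis, discretized at the acquisition rate: it has stationary,
#' bounded speeds, matching the station-keeping foraging movement of reef
#' grazers. Defaults emulate 60 fps stereo-video tracks with mean speeds in
#' the mid-20s cm/s.
#'
#' @param fps frames per second (> 0), default 60.
#' @param duration_s track duration, s, default 10.
#' @param mean_speed_cms target mean 3D speed, cm/s, default 26.
#' @param speed_relaxation mean-reversion rate of the velocity process,
#'   1/s, default 1.
#' @param noise_sd_cm isotropic Gaussian measurement noise per axis, cm,
#'   default 0.5.
#' @param outlier_rate per-frame probability of a gross outlier, default 0.01.
#' @param outlier_scale_cm magnitude of outlier displacement spikes, cm,
#'   default 10.
#' @param seed integer random seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fps = 60, duration_s = 10, mean_speed_cms = 26,
                       speed_relaxation = 1, noise_sd_cm = 0.5,
                       outlier_rate = 0.01, outlier_scale_cm = 10,
                       seed = 1L) {
  cfg <- list(fps = fps, duration_s = duration_s,
              mean_speed_cms = mean_speed_cms,
              speed_relaxation = speed_relaxation,
              noise_sd_cm = noise_sd_cm, outlier_rate = outlier_rate,
              outlier_scale_cm = outlier_scale_cm, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num))) stop("all simulation settings must be finite")
  if (fps <= 0) stop("'fps' must be > 0")
  if (duration_s <= 0) stop("'duration_s' must be > 0")
  if (mean_speed_cms < 0) stop("'mean_speed_cms' must be >= 0")
  if (speed_relaxation <= 0) stop("'speed_relaxation' must be > 0")
  if (noise_sd_cm < 0) stop("'noise_sd_cm' must be >= 0")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("'outlier_rate' must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a noise-free ground-truth swim path
#'
#' Each velocity axis follows a zero-mean Ornstein-Uhlenbeck process with
#' relaxation rate `speed_relaxation`, discretized exactly at the frame
#' interval and started from its stationary distribution; positions are the
#' discrete integral of the velocity. The stationary per-axis velocity sd is
#' chosen as `mean_speed_cms / (2*sqrt(2/pi))` so the mean of the resulting
#' 3D (Maxwell-distributed) speed equals `mean_speed_cms`. The exact
#' per-frame velocity/acceleration series used to drive the positions are
#' returned in `truth_*` columns; downstream analysis stages never read
#' them.
#'
#' @param config a [sim_config()].
#' @param track_id,species labels stored on the track.
#' @return a [trajectory3d()] with extra columns `truth_vx_cms`,
#'   `truth_vy_cms`, `truth_vz_cms`.
#' @export
simulate_trajectory <- function(config, track_id = "sim1",
                                species = "Acanthurus nigrofuscus") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- round(config$fps * config$duration_s)
  dt <- 1 / config$fps
  sigma_st <- config$mean_speed_cms / (2 * sqrt(2 / pi))  # Maxwell mean speed
  a <- exp(-config$speed_relaxation * dt)
  b <- sigma_st * sqrt(1 - a^2)
  v <- matrix(0, n, 3)
  if (sigma_st > 0) {
    v[1, ] <- stats::rnorm(3, 0, sigma_st)
    for (i in seq_len(n)[-1]) v[i, ] <- a * v[i - 1, ] + b * stats::rnorm(3)
  }
  p <- apply(v * dt, 2, function(col) cumsum(c(0, col[-n])))
  p <- p + matrix(c(0, 0, 150), n, 3, byrow = TRUE)  # ~1.5 m in front of rig
  df <- data.frame(track_id = track_id, species = species,
                   frame = seq_len(n) - 1L, t_s = (seq_len(n) - 1L) * dt,
                   x_cm = p[, 1], y_cm = p[, 2], z_cm = p[, 3],
                   truth_vx_cms = v[, 1], truth_vy_cms = v[, 2],
                   truth_vz_cms = v[, 3])
  trajectory3d(df, fps = config$fps)
}

#' Corrupt a ground-truth trajectory with measurement noise and outliers
#'
#' Adds i.i.d. Gaussian noise per axis (`noise_sd_cm`) and replaces a
#' Bernoulli(`outlier_rate`) subset of frames with displacement spikes of
#' magnitude `outlier_scale_cm` in a uniformly random direction (additive
#' spikes, not dropouts). The noise-free coordinates are kept in `truth_x_cm`
#' etc. and the spike positions in `truth_outlier`; the denoising stages
#' never read these columns.
#'
#' @param traj a noise-free [trajectory3d()] from [simulate_trajectory()].
#' @param config a [sim_config()]; its `seed` offset by 1 drives the noise so
#'   path and corruption are independently reproducible.
#' @return the corrupted [trajectory3d()] with `truth_x_cm`, `truth_y_cm`,
#'   `truth_z_cm` and logical `truth_outlier` columns.
#' @export
corrupt_trajectory <- function(traj, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(traj)
  out <- as.data.frame(traj)
  out$truth_x_cm <- out$x_cm; out$truth_y_cm <- out$y_cm
  out$truth_z_cm <- out$z_cm
  noise <- matrix(stats::rnorm(3 * n, 0, config$noise_sd_cm), n, 3)
  mask <- stats::runif(n) < config$outlier_rate
  out$x_cm <- out$x_cm + noise[, 1]
  out$y_cm <- out$y_cm + noise[, 2]
  out$z_cm <- out$z_cm + noise[, 3]
  if (any(mask)) {
    dir <- matrix(stats::rnorm(3 * sum(mask)), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2)) * config$outlier_scale_cm
    out$x_cm[mask] <- out$x_cm[mask] + dir[, 1]
    out$y_cm[mask] <- out$y_cm[mask] + dir[, 2]
    out$z_cm[mask] <- out$z_cm[mask] + dir[, 3]
  }
  out$truth_outlier <- mask
  trajectory3d(out, fps = traj_fps(traj))
}

#' Project a 3D trajectory to stereo pixel tracks
#'
#' Applies the pinhole projection of each camera ([project_point()]) and adds
#' optional Gaussian pixel noise. Points behind either camera, or projecting
#' outside either image, are flagged and dropped with the count reported (a
#' real rig simply never records them). On a rectified rig with zero noise
#' the left/right row coordinates agree exactly.
#'
#' @param traj a [trajectory3d()] (coordinates in the left-camera frame).
#' @param rig a [camera_rig()].
#' @param pixel_noise_sd_px per-axis Gaussian pixel noise sd, default 0.
#' @param seed seed for the pixel noise.
#' @return list with data frames `left` and `right` (`frame`, `u_px`,
#'   `v_px`), `n_dropped`, and `kept` (logical index into the input frames).
#' @export
project_to_stereo <- function(traj, rig, pixel_noise_sd_px = 0, seed = 1L) {
  stopifnot(inherits(rig, "camera_rig"))
  pts <- traj_matrix(traj)
  depth_l <- pts[, 3]
  pr <- to_camera_frame(rig, "right", pts)
  kept <- depth_l > 0 & pr[, 3] > 0
  lp <- matrix(NA_real_, nrow(pts), 2); rp <- lp
  if (any(kept)) {
    lp[kept, ] <- project_point(rig, "left", pts[kept, , drop = FALSE])
    rp[kept, ] <- project_point(rig, "right", pts[kept, , drop = FALSE])
  }
  in_frame <- function(px) !is.na(px[, 1]) &
    px[, 1] >= 0 & px[, 1] <= rig$image_size[1] &
    px[, 2] >= 0 & px[, 2] <= rig$image_size[2]
  kept <- kept & in_frame(lp) & in_frame(rp)
  n_dropped <- sum(!kept)
  if (n_dropped > 0)
    message(n_dropped,
            " point(s) behind a camera or outside the frame were dropped")
  lp <- lp[kept, , drop = FALSE]
  rp <- rp[kept, , drop = FALSE]
  if (pixel_noise_sd_px > 0) {
    set.seed(seed)
    lp <- lp + matrix(stats::rnorm(length(lp), 0, pixel_noise_sd_px), ncol = 2)
    rp <- rp + matrix(stats::rnorm(length(rp), 0, pixel_noise_sd_px), ncol = 2)
  }
  fr <- traj$frame[kept]
  list(left = data.frame(frame = fr, u_px = lp[, 1], v_px = lp[, 2]),
       right = data.frame(frame = fr, u_px = rp[, 1], v_px = rp[, 2]),
       n_dropped = n_dropped, kept = kept)
}

#' Simulate a respirometry (SMR vs mass) table
#'
#' `SMR_i = K_true * mass_i^E_true * exp(eps_i)` with
#' `eps_i ~ Normal(0, lognormal_sd^2)`; masses are log-uniform over
#' `mass_range_g` (spanning at least one decade) so the log-log design is
#' well conditioned.
#'
#' @param K_true,E_true true allometric parameters.
#' @param n number of fish (>= 3).
#' @param lognormal_sd sd of the multiplicative lognormal noise (log scale).
#' @param seed integer seed.
#' @param mass_range_g mass range, g, default `c(5, 200)`.
#' @return data frame `mass_g`, `smr_mgO2_d`, with the truth in attributes
#'   `truth_K`, `truth_E`.
#' @export
simulate_respirometry <- function(K_true, E_true, n = 50L, lognormal_sd = 0.1,
                                  seed = 1L, mass_range_g = c(5, 200)) {
  if (!is.finite(K_true) || K_true <= 0) stop("'K_true' must be > 0")
  if (n < 3L) stop("'n' must be >= 3")
  if (mass_range_g[2] / mass_range_g[1] < 10)
    stop("'mass_range_g' must span at least one decade")
  set.seed(seed)
  mass <- exp(stats::runif(n, log(mass_range_g[1]), log(mass_range_g[2])))
  smr <- K_true * mass^E_true * exp(stats::rnorm(n, 0, lognormal_sd))
  structure(data.frame(mass_g = mass, smr_mgO2_d = smr),
            truth_K = K_true, truth_E = E_true)
}

#' Simulate substrate-labelled feeding observations
#'
#' Draws per-fish quadrat visits with bite times, 3D bite positions and
#' substrate labels. Bite substrate is drawn with probability proportional to
#' availability x selectivity weight, so Manly's selection ratios estimated
#' from the output should converge to the normalized weights.
#'
#' @param profile a [substrate_profile()] (availability fractions).
#' @param selectivity_weights named non-negative weights, one per category in
#'   `profile` (not all zero).
#' @param n_fish number of fish visits to draw (0 gives an empty table).
#' @param bite_rate_mean mean bite rate, bites/min, default 42 (between the
#'   two focal-species field means).
#' @param seed integer seed.
#' @param species,quadrat labels for the generated rows.
#' @return data frame with one row per bite (`fish_id`, `species`, `quadrat`,
#'   `TL_mm`, `entry_s`, `exit_s`, `t_s`, `substrate`, `x_cm`, `y_cm`,
#'   `z_cm`) and the normalized ground-truth selectivity in attribute
#'   `truth_selectivity`.
#' @export
simulate_feeding_observations <- function(profile, selectivity_weights,
                                          n_fish, bite_rate_mean = 42,
                                          seed = 1L,
                                          species = "Acanthurus nigrofuscus",
                                          quadrat = "Q1") {
  stopifnot(inherits(profile, "substrate_profile"))
  cats <- names(profile$cover)
  if (length(cats) == 0L) stop("empty substrate profile")
  w <- selectivity_weights[cats]
  if (anyNA(w) || any(w < 0) || sum(w) == 0)
    stop("'selectivity_weights' must cover every profile category, be >= 0 ",
         "and not all zero")
  p_use <- profile$cover * w
  p_use <- p_use / sum(p_use)
  set.seed(seed)
  rows <- vector("list", n_fish)
  for (i in seq_len(n_fish)) {
    tl <- stats::rlnorm(1, log(110), 0.2)                 # ~11 cm grazers
    entry <- stats::runif(1, 0, 2400)
    dur <- stats::runif(1, 10, 60)
    nb <- max(1L, stats::rpois(1, bite_rate_mean * dur / 60))
    bt <- sort(stats::runif(nb, entry, entry + dur))
    pos <- matrix(stats::runif(nb * 2, 0, 100), ncol = 2)  # 1 m2 quadrat
    rows[[i]] <- data.frame(
      fish_id = sprintf("fish%03d", i), species = species, quadrat = quadrat,
      TL_mm = tl, entry_s = entry, exit_s = entry + dur, t_s = bt,
      substrate = sample(cats, nb, replace = TRUE, prob = p_use),
      x_cm = pos[, 1], y_cm = pos[, 2], z_cm = 0)
  }
  out <- if (n_fish > 0) do.call(rbind, rows) else
    data.frame(fish_id = character(), species = character(),
               quadrat = character(), TL_mm = numeric(), entry_s = numeric(),
               exit_s = numeric(), t_s = numeric(), substrate = character(),
               x_cm = numeric(), y_cm = numeric(), z_cm = numeric())
  structure(out, truth_selectivity = p_use / profile$cover /
              sum(p_use / profile$cover))
}

#' Simulate a trait table for model-structure comparison
#'
#' Generates log-normal trait observations (e.g. bite rates) with a species
#' fixed effect and optional fish- and quadrat-level random intercepts, for
#' exercising [trait_model_selection()]: with `fish_sd = quadrat_sd = 0` the
#' data have no grouping structure and a fixed-effects-only model should win
#' on AIC.
#'
#' @param n_fish fish per species; each fish is observed `obs_per_fish` times.
#' @param obs_per_fish repeated observations per fish.
#' @param species_effect log-scale offset of the second species.
#' @param fish_sd,quadrat_sd random-intercept sds (log scale).
#' @param resid_sd residual sd (log scale).
#' @param baseline_log log-scale intercept, default log(40) (bites/min).
#' @param n_quadrats number of quadrats fish are spread over.
#' @param seed integer seed.
#' @return data frame `fish_id`, `species`, `quadrat`, `mass_g`, `trait`.
#' @export
simulate_trait_observations <- function(n_fish = 15L, obs_per_fish = 4L,
                                        species_effect = 0.4, fish_sd = 0,
                                        quadrat_sd = 0, resid_sd = 0.3,
                                        baseline_log = log(40),
                                        n_quadrats = 5L, seed = 1L) {
  set.seed(seed)
  sp <- rep(c("A", "B"), each = n_fish)
  fid <- sprintf("fish%03d", seq_along(sp))
  f_eff <- stats::rnorm(length(sp), 0, fish_sd)
  q_eff <- stats::rnorm(n_quadrats, 0, quadrat_sd)
  rows <- lapply(seq_along(sp), function(i) {
    qd <- sample.int(n_quadrats, obs_per_fish, replace = TRUE)
    lt <- baseline_log + (sp[i] == "B") * species_effect + f_eff[i] +
      q_eff[qd] + stats::rnorm(obs_per_fish, 0, resid_sd)
    data.frame(fish_id = fid[i], species = sp[i],
               quadrat = sprintf("Q%d", qd),
               mass_g = stats::rlnorm(obs_per_fish, log(30), 0.3),
               trait = exp(lt))
  })
  do.call(rbind, rows)
}
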