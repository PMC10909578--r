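#' Pipeline configuration
#'
#' Assembles all stage parameters of the end-to-end run. With no input paths
#' the pipeline generates its own synthetic inputs (trajectories, stereo
#' projections, cover counts, bite tables) with known ground truth; with
#' paths given, the corresponding stage reads the files instead.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory (created if missing).
#' @param n_tracks synthetic tracks per species.
#' @param sim named list of [sim_config()] overrides for the simulator.
#' @param denoise named list: `iqr_k`, `median_window`, `meas_sd`,
#'   `process_sd`.
#' @param use_stereo route synthetic tracks through stereo projection and
#'   triangulation before denoising (exercises the geometry stage).
#' @param pixel_noise_sd_px pixel noise added to the synthetic projections.
#' @param feeding named list: `n_fish`, `bite_rate_mean`, `window_min`,
#'   `area_m2`, `selectivity_weights`.
#' @param trajectory_csv,feeding_csv,cover_csv optional input paths replacing
#'   the synthetic inputs.
#' @param presets energetics presets, default [species_presets()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("reefodba_run_"),
                            n_tracks = 3L, sim = list(), denoise = list(),
                            use_stereo = TRUE, pixel_noise_sd_px = 0,
                            feeding = list(), trajectory_csv = NULL,
                            feeding_csv = NULL, cover_csv = NULL,
                            presets = NULL) {
  for (p in c(trajectory_csv, feeding_csv, cover_csv))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  den <- utils::modifyList(list(iqr_k = 1.5, median_window = 5L,
                                meas_sd = 0.5, process_sd = 50), denoise)
  fed <- utils::modifyList(
    list(n_fish = 12L, bite_rate_mean = 42, window_min = 45, area_m2 = 1,
         selectivity_weights = c(rock = 3, rubble = 2, sand = 0.5,
                                 live_coral = 0.2, dead_coral = 1)),
    feeding)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_tracks = as.integer(n_tracks), sim = sim, denoise = den,
                 use_stereo = isTRUE(use_stereo),
                 pixel_noise_sd_px = pixel_noise_sd_px, feeding = fed,
                 trajectory_csv = trajectory_csv, feeding_csv = feeding_csv,
                 cover_csv = cover_csv, presets = presets),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the two branches of the analysis on synthetic (or supplied)
#' inputs: movement branch -- simulate ground-truth swim paths, corrupt them,
#' optionally project/triangulate through the stereo rig, denoise
#' (IQR -> running median -> Kalman), compute kinematics, ODBA and energy
#' expenditure per track; feeding branch -- benthic cover to availability,
#' bite tables to bite rates, bite distances, biomass, feeding rate, feeding
#' pressure and Manly selectivity. Writes per-stage CSVs, a JSON run
#' manifest (seed, parameters, version, per-stage counters) and a
#' human-readable summary; reruns with the same configuration are
#' byte-identical (the manifest's timestamp aside).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the per-track energetics table, feeding
#'   summary, selectivity result, per-track denoising counters, and output
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- if (is.null(config$presets)) species_presets() else config$presets
  rig <- demo_rig()
  species <- names(presets)

  ## ---- movement branch ----
  stage <- "simulate"
  res <- tryCatch({
    tracks <- list()
    if (is.null(config$trajectory_csv)) {
      idx <- 0L
      for (sp in species) for (j in seq_len(config$n_tracks)) {
        idx <- idx + 1L
        scfg <- do.call(sim_config,
                        utils::modifyList(config$sim,
                                          list(seed = config$seed + 100L * idx)))
        tru <- simulate_trajectory(scfg, track_id = sprintf("trk%02d", idx),
                                   species = sp)
        obs <- corrupt_trajectory(tru, scfg)
        tracks[[length(tracks) + 1L]] <- list(truth = tru, obs = obs)
      }
    } else {
      tr <- read_table_csv(config$trajectory_csv, "trajectory")
      for (id in unique(tr$track_id)) {
        sub <- tr[tr$track_id == id, , drop = FALSE]
        tracks[[length(tracks) + 1L]] <-
          list(truth = NULL, obs = trajectory3d(as.data.frame(sub),
                                                fps = attr(tr, "fps")))
      }
    }
    say(length(tracks), " track(s) entering the movement branch")

    stage <- "triangulate"
    if (config$use_stereo) {
      for (i in seq_along(tracks)) {
        obs <- tracks[[i]]$obs
        st <- project_to_stereo(obs, rig,
                                pixel_noise_sd_px = config$pixel_noise_sd_px,
                                seed = config$seed + i)
        pts <- triangulate_tracks(rig, st$left, st$right)
        kept <- as.data.frame(obs)[st$kept, , drop = FALSE]
        kept$x_cm <- pts[, 1]; kept$y_cm <- pts[, 2]; kept$z_cm <- pts[, 3]
        tracks[[i]]$obs <- trajectory3d(kept, fps = traj_fps(obs))
      }
    }

    stage <- "denoise"
    counters <- data.frame(track_id = character(), frames_in = integer(),
                           outliers_removed = integer(),
                           frames_out = integer())
    for (i in seq_along(tracks)) {
      obs <- tracks[[i]]$obs
      dn <- denoise_trajectory(obs, iqr_k = config$denoise$iqr_k,
                               median_window = config$denoise$median_window,
                               meas_sd = config$denoise$meas_sd,
                               process_sd = config$denoise$process_sd)
      tracks[[i]]$clean <- dn$trajectory
      counters <- rbind(counters, data.frame(
        track_id = obs$track_id[1], frames_in = nrow(obs),
        outliers_removed = dn$n_outliers_removed,
        frames_out = nrow(dn$trajectory)))
      say(sprintf("  %s: %d frames in, %d outliers removed, %d out",
                  obs$track_id[1], nrow(obs), dn$n_outliers_removed,
                  nrow(dn$trajectory)))
    }

    stage <- "energetics"
    set.seed(config$seed + 7L)
    energetics <- do.call(rbind, lapply(tracks, function(tk) {
      sp <- tk$clean$species[1]
      cfgE <- if (sp %in% names(presets)) presets[[sp]] else presets[[1]]
      tl <- stats::rlnorm(1, log(110), 0.15)
      mass <- mass_from_length(a = 0.0206, b = 3.01, TL_mm = tl)
      s <- summarize_trajectory(tk$clean, mass, cfgE)
      if (!is.null(tk$truth)) {
        st <- summarize_trajectory(tk$truth, mass, cfgE)
        s$truth_mean_EE_W <- st$mean_EE_W
        s$truth_mean_velocity_cms <- st$mean_velocity_cms
      }
      s
    }))

    ## ---- feeding branch ----
    stage <- "benthic cover"
    if (is.null(config$cover_csv)) {
      # cell counts emulating a rubble/dead-coral dominated quadrat
      counts <- c(rock = 150, rubble = 430, sand = 160, live_coral = 100,
                  dead_coral = 160)
    } else {
      cov <- read_table_csv(config$cover_csv, "cover")
      counts <- tapply(cov$cells, cov$category, sum)
    }
    profile <- benthic_cover(counts, quadrat = "Q1")

    stage <- "feeding"
    if (is.null(config$feeding_csv)) {
      bites <- simulate_feeding_observations(
        profile, config$feeding$selectivity_weights,
        n_fish = config$feeding$n_fish,
        bite_rate_mean = config$feeding$bite_rate_mean,
        seed = config$seed + 13L)
    } else {
      bites <- read_table_csv(config$feeding_csv, "feeding")
    }
    bites$mass_g <- mass_from_length(0.0206, 3.01, bites$TL_mm)
    events <- split_events(bites)
    event_summary <- do.call(rbind, lapply(events, function(ev) data.frame(
      fish_id = ev$fish_id[1], species = ev$species[1],
      quadrat = ev$quadrat[1],
      bite_rate_min = bite_rate(ev),
      mean_bite_distance_mm = mean_bite_distance(ev),
      n_bites = nrow(ev))))
    rownames(event_summary) <- NULL
    feeding_summary <- data.frame(
      species = names(feeding_rate(bites, config$feeding$window_min,
                                   config$feeding$area_m2)),
      feeding_rate_bites_m2_h = as.numeric(
        feeding_rate(bites, config$feeding$window_min, config$feeding$area_m2)),
      feeding_pressure_kgbites_m2_h = as.numeric(
        feeding_pressure(bites, config$feeding$window_min,
                         config$feeding$area_m2)),
      biomass_g_m2 = biomass_per_quadrat(bites, config$feeding$area_m2))

    stage <- "selectivity"
    use <- table(bites$substrate)
    sel <- manly_ratios(stats::setNames(as.numeric(use), names(use)), profile)

    stage <- "write outputs"
    paths <- list(
      energetics = file.path(config$out_dir, "energetics.csv"),
      events = file.path(config$out_dir, "feeding_events.csv"),
      feeding = file.path(config$out_dir, "feeding_summary.csv"),
      selectivity = file.path(config$out_dir, "selectivity.csv"),
      counters = file.path(config$out_dir, "denoise_counters.csv"),
      manifest = file.path(config$out_dir, "manifest.json"),
      summary = file.path(config$out_dir, "summary.txt"))
    utils::write.csv(energetics, paths$energetics, row.names = FALSE)
    utils::write.csv(event_summary, paths$events, row.names = FALSE)
    utils::write.csv(feeding_summary, paths$feeding, row.names = FALSE)
    utils::write.csv(data.frame(category = names(sel$w), w = sel$w,
                                preference_pct = sel$preference_pct,
                                row.names = NULL),
                     paths$selectivity, row.names = FALSE)
    utils::write.csv(counters, paths$counters, row.names = FALSE)
    cfg_flat <- unclass(config)
    cfg_flat$presets <- NULL
    write_manifest(cfg_flat, paths$manifest,
                   extra = list(counters = counters))
    writeLines(c(
      "reefodba pipeline summary",
      sprintf("seed %d | %d tracks | %d bites | %d feeding events",
              config$seed, length(tracks), nrow(bites), length(events)),
      sprintf("mean EE %.3f W | mean velocity %.1f cm/s",
              mean(energetics$mean_EE_W), mean(energetics$mean_velocity_cms)),
      sprintf("top substrate preference: %s (%.1f%%)",
              names(which.max(sel$preference_pct)), max(sel$preference_pct))),
      paths$summary)

    list(energetics = energetics, event_summary = event_summary,
         feeding_summary = feeding_summary, selectivity = sel,
         counters = counters, profile = profile, paths = paths)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  say("pipeline complete: outputs in ", config$out_dir)
  invisible(res)
}
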