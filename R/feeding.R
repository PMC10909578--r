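#' Substrate availability profile of a quadrat
#'
#' Relative cover fractions of the benthic categories (live coral, standing
#' dead coral, rock, rubble, sand) within a survey quadrat.
#'
#' @param cover named numeric vector of non-negative fractions summing to 1
#'   (to 1e-9).
#' @param quadrat quadrat identifier.
#' @return a `substrate_profile` object.
#' @export
substrate_profile <- function(cover, quadrat = "Q1") {
  cover <- unlist(cover)
  if (length(cover) == 0L || is.null(names(cover)) || any(names(cover) == ""))
    stop("'cover' must be a non-empty named vector")
  if (any(cover < 0)) stop("cover fractions must be >= 0")
  if (abs(sum(cover) - 1) > 1e-9)
    stop("cover fractions must sum to 1 (got ", format(sum(cover)), ")")
  structure(list(quadrat = quadrat, cover = cover),
            class = "substrate_profile")
}

#' @export
print.substrate_profile <- function(x, ...) {
  cat(sprintf("<substrate_profile> quadrat '%s'\n", x$quadrat))
  print(round(100 * x$cover, 1))
  invisible(x)
}

#' Benthic cover from annotated cell counts
#'
#' Converts per-category counts of annotated image cells (~1000 cells of
#' ~5 cm^2 each per 1 m^2 quadrat) into relative cover fractions.
#'
#' @param counts named non-negative integer vector of cell counts per
#'   category.
#' @param quadrat quadrat identifier.
#' @return a [substrate_profile()].
#' @export
benthic_cover <- function(counts, quadrat = "Q1") {
  counts <- unlist(counts)
  if (any(counts < 0)) stop("cell counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stop("total cell count must be > 0")
  substrate_profile(counts / total, quadrat = quadrat)
}

# split a bite table into per-event (fish visit) groups
split_events <- function(bites) {
  need <- c("fish_id", "entry_s", "exit_s", "t_s")
  miss <- setdiff(need, names(bites))
  if (length(miss))
    stop("bite table missing column(s): ", paste(miss, collapse = ", "))
  split(bites, interaction(bites$fish_id, bites$entry_s, drop = TRUE))
}

#' Bite rate of one feeding event
#'
#' Bites counted over the visit, standardized by the visit duration:
#' `n_bites / duration_minutes`.
#'
#' @param event data frame of one fish's visit (one row per bite) with
#'   `entry_s`, `exit_s`.
#' @return bites per minute.
#' @export
bite_rate <- function(event) {
  dur_s <- event$exit_s[1] - event$entry_s[1]
  if (!is.finite(dur_s) || dur_s <= 0)
    stop("feeding event has non-positive duration")
  nrow(event) / (dur_s / 60)
}

#' Mean distance between consecutive bites
#'
#' Mean Euclidean distance between consecutive bite positions in bite-time
#' order, in millimetres. With fewer than two positioned bites the metric is
#' undefined and `NA` is returned (never zero, never imputed).
#'
#' @param event data frame of one fish's visit with `t_s` and bite positions
#'   `x_cm`, `y_cm`, `z_cm` (rows with any missing coordinate are excluded).
#' @return mean bite distance, mm, or `NA_real_`.
#' @export
mean_bite_distance <- function(event) {
  pos_ok <- stats::complete.cases(event[, c("x_cm", "y_cm", "z_cm")])
  ev <- event[pos_ok, , drop = FALSE]
  if (nrow(ev) < 2L) return(NA_real_)
  ev <- ev[order(ev$t_s), , drop = FALSE]
  d <- sqrt(diff(ev$x_cm)^2 + diff(ev$y_cm)^2 + diff(ev$z_cm)^2)
  mean(d) * 10
}

event_masses <- function(bites) {
  if (!("mass_g" %in% names(bites)))
    stop("bite table needs a 'mass_g' column (see mass_from_length())")
  bites
}

#' Fish biomass per quadrat
#'
#' Sum of the body masses of the individual fish that bit within the
#' observation window, standardized by quadrat area. Each individual is
#' counted once even if it re-entered the quadrat several times.
#'
#' @param bites bite table (one row per bite) with `fish_id` and `mass_g`.
#' @param area_m2 quadrat area, m^2, default 1.
#' @return biomass, g/m^2.
#' @export
biomass_per_quadrat <- function(bites, area_m2 = 1) {
  if (nrow(bites) == 0L) return(0)
  bites <- event_masses(bites)
  first <- !duplicated(bites$fish_id)
  sum(bites$mass_g[first]) / area_m2
}

#' Per-species feeding rate
#'
#' Total bites standardized by area and observation time:
#' bites / m^2 / h, grouped by species.
#'
#' @param bites bite table with `species`.
#' @param window_min observation window, minutes, default 45.
#' @param area_m2 quadrat area, m^2, default 1.
#' @return named vector, bites m^-2 h^-1 per species.
#' @export
feeding_rate <- function(bites, window_min = 45, area_m2 = 1) {
  if (window_min <= 0) stop("'window_min' must be > 0")
  if (nrow(bites) == 0L) return(stats::setNames(numeric(0), character(0)))
  r <- tapply(rep(1, nrow(bites)), bites$species, sum) / area_m2 /
    (window_min / 60)
  stats::setNames(as.numeric(r), names(r))
}

#' Per-species feeding pressure
#'
#' Biomass-standardized bite impact: for each bite the mass (kg) of the
#' biting fish is accumulated, and the mass-weighted bite sum is standardized
#' by area and observation time, giving kg bites m^-2 h^-1. Two identical
#' fish therefore exert the same pressure as one such fish biting twice as
#' often.
#'
#' @inheritParams feeding_rate
#' @return named vector, kg bites m^-2 h^-1 per species.
#' @export
feeding_pressure <- function(bites, window_min = 45, area_m2 = 1) {
  if (nrow(bites) == 0L) return(stats::setNames(numeric(0), character(0)))
  bites <- event_masses(bites)
  r <- tapply(bites$mass_g / 1000, bites$species, sum) / area_m2 /
    (window_min / 60)
  stats::setNames(as.numeric(r), names(r))
}

#' Manly's selection ratios and feeding preference
#'
#' Design-I selection ratios: `w_c = (u_c / sum(u)) / (a_c / sum(a))`, the
#' proportional use of category `c` relative to its proportional
#' availability; standardized ratios `w_c / sum(w) * 100` give feeding
#' preference percentages (Manly's standardized alpha), which always sum to
#' 100. Use counts may be pooled across individuals (default) or computed
#' per individual and summed per category before standardization.
#'
#' @param use either a named vector of bite counts per category (pooled
#'   mode), or, with `mode = "per_fish"`, a bite table with `fish_id` and
#'   `substrate` columns.
#' @param profile a [substrate_profile()]; every used category must have
#'   positive availability.
#' @param mode `"pooled"` (default) or `"per_fish"`.
#' @return a `selectivity_result` list: `w` (selection ratios),
#'   `preference_pct`, `use`, `availability`, `mode`.
#' @export
manly_ratios <- function(use, profile, mode = c("pooled", "per_fish")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "substrate_profile"))
  avail <- profile$cover
  if (mode == "per_fish") {
    bites <- use
    if (!all(c("fish_id", "substrate") %in% names(bites)))
      stop("per-fish mode needs a bite table with 'fish_id' and 'substrate'")
    per <- lapply(split(bites, bites$fish_id), function(b) {
      u <- table(factor(b$substrate, levels = names(avail)))
      manly_w(as.numeric(u), stats::setNames(names(avail), names(avail)), avail)
    })
    w <- Reduce(`+`, per)              # summed ratios per grazed substrate
  } else {
    u <- unlist(use)
    if (is.null(names(u))) stop("'use' must be a named count vector")
    full <- stats::setNames(numeric(length(avail)), names(avail))
    unknown <- setdiff(names(u), names(avail))
    if (length(unknown))
      stop("bites on categories absent from the profile: ",
           paste(unknown, collapse = ", "))
    full[names(u)] <- u
    w <- manly_w(full, names(avail), avail)
  }
  pref <- w / sum(w) * 100
  structure(list(w = w, preference_pct = pref,
                 use = if (mode == "pooled") full else table(use$substrate),
                 availability = avail, mode = mode),
            class = "selectivity_result")
}

manly_w <- function(u, cats, avail) {
  if (sum(u) <= 0) stop("total use must be > 0")
  used_zero_avail <- u > 0 & avail[cats] <= 0
  if (any(used_zero_avail))
    stop("bites recorded on categories with zero availability: ",
         paste(names(avail)[used_zero_avail], collapse = ", "))
  w <- (u / sum(u)) / (avail / sum(avail))
  w[avail <= 0] <- 0
  stats::setNames(as.numeric(w), names(avail))
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> (%s mode)\n", x$mode))
  print(data.frame(w = round(x$w, 3),
                   preference_pct = round(x$preference_pct, 2)))
  invisible(x)
}

#' Compare trait-model structures by AIC
#'
#' Thin orchestration over [stats::lm()] and [lme4::lmer()]: fits the
#' candidate set of models for a positive trait (log-transformed, optionally
#' IQR-screened first) and ranks them by AIC. Candidates: an LMM with fish
#' and quadrat random intercepts, an LMM with fish only, and a linear model
#' without random effects, each with species alone and (optionally) species
#' plus log mass as fixed effects. Mixed models are fitted by maximum
#' likelihood (`REML = FALSE`) so AIC values are comparable across fixed
#' effects; singular random-effect fits are reported in the `singular`
#' column, not dropped. Exact AIC ties are broken deterministically in
#' favour of fewer estimated parameters.
#'
#' @param data data frame with `trait` (> 0), `species`, `fish_id`,
#'   `quadrat`, and `mass_g` when `include_mass = TRUE`.
#' @param include_mass also fit the `species + log(mass)` variants.
#' @param iqr_screen drop rows whose log trait falls outside Tukey fences
#'   (same convention as the trajectory outlier screen).
#' @param iqr_k fence multiplier for the screen.
#' @return a `trait_model_ranking` data frame: `model`, `AIC`, `df`,
#'   `singular`, sorted by AIC (ties: fewer df first), with the fitted
#'   objects in attribute `fits`.
#' @export
trait_model_selection <- function(data, include_mass = TRUE,
                                  iqr_screen = TRUE, iqr_k = 1.5) {
  if (any(data$trait <= 0)) stop("trait values must be positive")
  data$log_trait <- log(data$trait)
  if (iqr_screen) data <- data[!iqr_outlier_mask(data$log_trait, iqr_k), ]
  fixed <- c("species")
  if (include_mass) fixed <- c(fixed, "species + log(mass_g)")
  fits <- list()
  for (fx in fixed) {
    lab <- if (grepl("mass", fx)) "species+mass" else "species"
    fits[[paste0("lmm_fish_quadrat: ", lab)]] <- suppressMessages(
      lme4::lmer(stats::as.formula(paste("log_trait ~", fx,
                                         "+ (1 | fish_id) + (1 | quadrat)")),
                 data = data, REML = FALSE))
    fits[[paste0("lmm_fish: ", lab)]] <- suppressMessages(
      lme4::lmer(stats::as.formula(paste("log_trait ~", fx, "+ (1 | fish_id)")),
                 data = data, REML = FALSE))
    fits[[paste0("lm: ", lab)]] <-
      stats::lm(stats::as.formula(paste("log_trait ~", fx)), data = data)
  }
  tab <- data.frame(
    model = names(fits),
    AIC = vapply(fits, stats::AIC, numeric(1)),
    df = vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1)),
    singular = vapply(fits, function(f)
      if (inherits(f, "merMod")) lme4::isSingular(f) else FALSE, logical(1)),
    row.names = NULL)
  tab <- tab[order(tab$AIC, tab$df), ]
  rownames(tab) <- NULL
  structure(tab, fits = fits, class = c("trait_model_ranking", "data.frame"))
}

#' @export
print.trait_model_ranking <- function(x, ...) {
  cat("<trait_model_ranking> (best first)\n")
  print(as.data.frame(x))
  invisible(x)
}
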