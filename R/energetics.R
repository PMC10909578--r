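#' Energetics configuration
#'
#' Bundles the constants that convert ODBA into energy expenditure: the
#' allometric intercept `K` (mg O2 g^-E d^-1) and exponent `E` of the
#' SMR-mass power law, the Q10 temperature coefficient with reference and
#' study temperatures, and the oxy-calorific coefficient (J per mg O2,
#' 14.1 for ammoniotelic animals).
#'
#' @param K allometric intercept, mg O2 g^-E d^-1 (> 0).
#' @param E allometric exponent, dimensionless (0 < E < 2).
#' @param Q10 metabolic temperature coefficient (> 0), default 1.92.
#' @param T_ref_C respirometry reference temperature, degrees C, default 28.
#' @param T_study_C field temperature, degrees C, default 21.
#' @param oxycal_J_mgO2 oxy-calorific coefficient, default 14.1.
#' @return an `energetics_config` list.
#' @export
energetics_config <- function(K, E, Q10 = 1.92, T_ref_C = 28, T_study_C = 21,
                              oxycal_J_mgO2 = 14.1) {
  if (!is.finite(K) || K <= 0) stop("'K' must be > 0")
  if (!is.finite(E) || E <= 0 || E >= 2) stop("'E' must lie in (0, 2)")
  if (!is.finite(Q10) || Q10 <= 0) stop("'Q10' must be > 0")
  if (!is.finite(oxycal_J_mgO2) || oxycal_J_mgO2 <= 0)
    stop("'oxycal_J_mgO2' must be > 0")
  structure(list(K = K, E = E, Q10 = Q10, T_ref_C = T_ref_C,
                 T_study_C = T_study_C, oxycal_J_mgO2 = oxycal_J_mgO2,
                 seconds_per_day = 86400),
            class = "energetics_config")
}

#' @export
print.energetics_config <- function(x, ...) {
  cat(sprintf(paste0("<energetics_config> SMR = %.4f * mass^%.4f mg O2/d; ",
                     "Q10 %.2f (%g -> %g degC); oxycal %.1f J/mg O2\n"),
              x$K, x$E, x$Q10, x$T_ref_C, x$T_study_C, x$oxycal_J_mgO2))
  invisible(x)
}

#' Surrogate-species energetics presets
#'
#' SMR-mass relations of respirometry surrogate species, used in place of
#' unmeasured focal species: *Ctenochaetus striatus* (SMR = 3.9994 *
#' mass^0.7789) stands in for *Acanthurus nigrofuscus* and *Zebrasoma
#' scopas* (SMR = 3.9109 * mass^0.6958) for *Zebrasoma xanthurum*. Both use
#' Q10 = 1.92, a 28 degC reference and a 21 degC study temperature.
#'
#' @return named list of [energetics_config()] objects, keyed by focal
#'   species name, each carrying the surrogate species in attribute
#'   `surrogate`.
#' @export
species_presets <- function() {
  list(
    "Acanthurus nigrofuscus" =
      structure(energetics_config(K = 3.9994, E = 0.7789),
                surrogate = "Ctenochaetus striatus"),
    "Zebrasoma xanthurum" =
      structure(energetics_config(K = 3.9109, E = 0.6958),
                surrogate = "Zebrasoma scopas")
  )
}

#' Fit the allometric SMR-mass power law
#'
#' Ordinary least squares of log SMR on log body mass. The intercept of the
#' log-log regression gives `K = exp(intercept)` (natural logs; the result is
#' base-invariant) and the slope gives the exponent `E`, so that
#' `SMR = K * mass^E`.
#'
#' @param mass_g body masses, g (> 0, n >= 3).
#' @param smr_mgO2_d standard metabolic rates, mg O2 per day (> 0).
#' @return an `allometry_fit` object with components `K`, `E`, `lm` (the
#'   underlying [stats::lm()] fit on the log-log scale), `n`, `r_squared`,
#'   `sigma_log`.
#' @export
fit_allometry <- function(mass_g, smr_mgO2_d) {
  mass_g <- as.numeric(mass_g); smr_mgO2_d <- as.numeric(smr_mgO2_d)
  if (length(mass_g) != length(smr_mgO2_d))
    stop("'mass_g' and 'smr_mgO2_d' must have equal length")
  if (length(mass_g) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(mass_g)) || any(!is.finite(smr_mgO2_d)) ||
      any(mass_g <= 0) || any(smr_mgO2_d <= 0))
    stop("masses and SMR values must be positive and finite")
  fit <- stats::lm(log(smr_mgO2_d) ~ log(mass_g))
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # noiseless data fit perfectly
  structure(list(K = exp(unname(cf[1])), E = unname(cf[2]), lm = fit,
                 n = length(mass_g),
                 r_squared = sm$r.squared,
                 sigma_log = sm$sigma),
            class = "allometry_fit")
}

#' @export
coef.allometry_fit <- function(object, ...) c(K = object$K, E = object$E)

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("<allometry_fit> SMR = %.4f * mass^%.4f (n=%d, R2=%.3f)\n",
              x$K, x$E, x$n, x$r_squared))
  invisible(x)
}

#' @export
predict.allometry_fit <- function(object, mass_g, ...) {
  object$K * mass_g^object$E
}

#' Overall dynamic body acceleration
#'
#' `ODBA_i = |ax_i| + |ay_i| + |az_i|`: the per-frame sum of absolute
#' accelerations over the three orthogonal axes. Accelerations derived from
#' positional tracking carry no gravity/static component, so no static
#' subtraction is applied; magnitudes (cm/s^2) are treated as unitless in the
#' energy-expenditure conversion.
#'
#' @param ax,ay,az equal-length per-axis acceleration series, cm/s^2.
#' @return numeric ODBA series.
#' @export
odba <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("acceleration series must have equal length")
  abs(ax) + abs(ay) + abs(az)
}

#' Q10 temperature adjustment factor
#'
#' `Q10 ^ ((T_ref - T_study) / 10)`: rescales metabolic rates measured at a
#' reference temperature to the (usually colder) study temperature. With the
#' defaults Q10 = 1.92, 28 degC reference and 21 degC study the factor is
#' about 1.579.
#'
#' @param Q10 temperature coefficient (> 0).
#' @param T_ref_C,T_study_C reference and study temperatures, degrees C.
#' @return the scalar adjustment factor.
#' @export
temperature_adjustment <- function(Q10 = 1.92, T_ref_C = 28, T_study_C = 21) {
  if (!is.finite(Q10) || Q10 <= 0) stop("'Q10' must be > 0")
  Q10^((T_ref_C - T_study_C) / 10)
}

#' Per-frame energy expenditure from ODBA
#'
#' `EE_i = K * mass^E * ODBA_i * TAF * oxycal / 86400`, in watts: the
#' allometric SMR prediction (mg O2/d) is modulated by per-frame ODBA,
#' corrected to study temperature, converted to joules via the oxy-calorific
#' coefficient and divided by the seconds in a day.
#'
#' @param mass_g body mass, g (> 0).
#' @param odba_series per-frame ODBA values (unitless).
#' @param config an [energetics_config()].
#' @return numeric series of per-frame EE, W.
#' @export
ee_per_frame <- function(mass_g, odba_series, config) {
  stopifnot(inherits(config, "energetics_config"))
  if (!is.finite(mass_g) || mass_g <= 0) stop("'mass_g' must be > 0")
  taf <- temperature_adjustment(config$Q10, config$T_ref_C, config$T_study_C)
  config$K * mass_g^config$E * odba_series * taf * config$oxycal_J_mgO2 /
    config$seconds_per_day
}

#' Summarize a trajectory's movement energetics
#'
#' Chains [compute_kinematics()], [odba()] and [ee_per_frame()] and averages
#' over the frames where each quantity is defined: mean speed over the n-1
#' valid frame pairs, mean EE over the n-2 valid frame triples (arithmetic
#' means; gap-spanning frames are excluded, not interpolated).
#'
#' @param traj a denoised [trajectory3d()] with at least 3 frames.
#' @param mass_g body mass, g.
#' @param config an [energetics_config()].
#' @return a one-row data frame: `track_id`, `species`, `mass_g`,
#'   `mean_velocity_cms`, `mean_EE_W`, `n_frames`, `n_speed`, `n_accel`.
#' @export
summarize_trajectory <- function(traj, mass_g, config) {
  if (nrow(traj) < 3L)
    stop("track '", traj$track_id[1], "': need >= 3 frames, got ", nrow(traj))
  kin <- compute_kinematics(traj)
  ob <- odba(kin$accel$ax_cms2, kin$accel$ay_cms2, kin$accel$az_cms2)
  ee <- ee_per_frame(mass_g, ob, config)
  data.frame(track_id = traj$track_id[1], species = traj$species[1],
             mass_g = mass_g,
             mean_velocity_cms = mean(kin$steps$speed_cms),
             mean_EE_W = if (length(ee)) mean(ee) else NA_real_,
             n_frames = nrow(traj),
             n_speed = nrow(kin$steps), n_accel = nrow(kin$accel))
}

#' Body mass from total length
#'
#' Species-specific length-weight relationship `mass = a * TL^b`. Published
#' length-weight coefficients (e.g. FishBase) conventionally expect length in
#' centimetres while field measurements here are in millimetres, and a unit
#' mix-up changes mass by ~10^b, so the length unit of the supplied
#' coefficients must be stated explicitly.
#'
#' @param a,b length-weight coefficients (a > 0).
#' @param TL_mm total length, mm (> 0).
#' @param coef_length_unit unit of length the coefficients expect: `"cm"`
#'   (FishBase convention, default) or `"mm"`.
#' @return mass, g.
#' @export
mass_from_length <- function(a, b, TL_mm, coef_length_unit = c("cm", "mm")) {
  coef_length_unit <- match.arg(coef_length_unit)
  if (!is.finite(a) || a <= 0) stop("'a' must be > 0")
  if (any(!is.finite(TL_mm)) || any(TL_mm <= 0)) stop("'TL_mm' must be > 0")
  L <- if (coef_length_unit == "cm") TL_mm / 10 else TL_mm
  a * L^b
}

#' Total length from body mass (inverse length-weight relation)
#'
#' @inheritParams mass_from_length
#' @param mass_g mass, g (> 0).
#' @return total length, mm.
#' @export
length_from_mass <- function(a, b, mass_g, coef_length_unit = c("cm", "mm")) {
  coef_length_unit <- match.arg(coef_length_unit)
  if (!is.finite(a) || a <= 0) stop("'a' must be > 0")
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) stop("'mass_g' must be > 0")
  L <- (mass_g / a)^(1 / b)
  if (coef_length_unit == "cm") L * 10 else L
}
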