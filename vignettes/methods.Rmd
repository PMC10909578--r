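---
title: "From stereo-video fish tracks to foraging energetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stereo-video fish tracks to foraging energetics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefodba)
```

## The problem

Estimating how much energy a wild fish spends while foraging is hard:
respirometry chambers capture resting metabolism, not field activity.
A practical proxy chain is: film foraging fish with a calibrated
two-camera (stereo) rig, reconstruct 3D swim paths, differentiate them
into accelerations, summarize movement intensity as overall dynamic body
acceleration (ODBA), and scale ODBA into watts through a species'
standard-metabolic-rate (SMR) allometry with a temperature correction.
Alongside the movement branch, quadrat observations of bites on labelled
substrates yield community feeding metrics: bite rates, bite distances,
biomass, feeding rate, feeding pressure and Manly selectivity.

`reefodba` implements this full chain, and — because real deployments of
the chain depend on video infrastructure that no R package can carry — a
synthetic-data module that generates every input with known ground truth.
All guarantees quoted below are computed by the package's own test suite
on that synthetic data.

## Stereo geometry

Both cameras follow the standard pinhole model with radial (`k1`, `k2`)
and tangential (`p1`, `p2`) distortion applied to the normalized image
coordinates after perspective division. The world frame is the left
camera frame, units are centimetres, pixels have their origin at the
top-left with +y downward; every 3D coordinate in the package therefore
reads "cm relative to the left camera".

Triangulation proceeds by rectification: viewing rays are undistorted
(fixed-point inversion of the distortion map, at most 20 iterations,
tolerance 1e-12 px — well below any physical pixel scale), rotated into
a common frame whose x-axis lies along the baseline, and re-projected
with a shared focal length. In that frame corresponding points share a
row coordinate and depth is `f * B / d` for disparity `d`. On noise-free
synthetic projections the round trip `triangulate(project(P)) = P` holds
to better than 1e-6 cm, and rectified row residuals vanish to the same
tolerance; both are asserted in the tests over 1000 random points.

Calibration parameter *estimation* is deliberately out of scope:
checkerboard solvers are mature external tools, and the analysis only
needs the forward/inverse geometry, so rig parameters arrive via
`camera_rig()` or a YAML/JSON file. Two accuracy metrics are exposed and
named distinctly, because they are often conflated: `calibration_accuracy()`
summarizes measured distances of a known reference spacing (MAE in mm and
MAPE in %), while `reprojection_error_px()` is the pixel-space residual
and `reconstruction_error()` the millimetre-scale 3D residual.

## The synthetic movement model

Each velocity axis follows a zero-mean Ornstein-Uhlenbeck process with
relaxation rate `speed_relaxation` (default 1 s^-1, i.e. a ~1 s velocity
decorrelation time, plausible for station-keeping grazers), discretized
exactly at the frame interval and started from its stationary
distribution; positions integrate the velocity. The stationary per-axis
sd is set to `mean_speed / (2 * sqrt(2/pi))` so that the mean of the
Maxwell-distributed 3D speed equals `mean_speed` (default 26 cm/s, in
the range reported for foraging surgeonfishes). Corruption adds
isotropic Gaussian noise (default 0.5 cm per axis) and replaces a
Bernoulli(0.01) subset of frames with 10 cm displacement spikes —
additive point outliers, not dropouts, because the downstream cleaning
step removes points rather than filling gaps.

What this generator emulates: stationary foraging kinematics at 60 fps,
realistic measurement noise, sporadic gross tracking failures, and exact
stereo observability of the same path. What it does not emulate:
burst-and-glide gaits, behavioural state switching, occlusion-induced
dropout runs, identity swaps between fish, or depth-dependent noise.
Passing tests therefore demonstrate correctness of the computational
chain under a plausible stationary regime, not behavioural realism.

Ground truth (noise-free coordinates, exact per-frame velocities, the
outlier mask) travels in `truth_`-prefixed columns that no analysis
function reads; tests enforce the separation by construction.

## Denoising

The cleaning chain is fixed in order: IQR outlier removal, then a
5-point running median, then Kalman smoothing. The IQR step screens each
coordinate axis against Tukey fences `Q1 - 1.5*IQR` / `Q3 + 1.5*IQR`
with quartiles by linear interpolation between order statistics (the
`type = 7` convention; fence placement depends on the convention, so it
is pinned in code and tests). A frame is *removed* when any axis is
outside its fences, leaving a gap — every later stage is gap-aware and
never differences across one. Screening coordinates (rather than
displacements or velocities) is a genuine design choice: over a
wandering track the coordinate fences are wide, so this step mainly
catches extreme excursions, and single-frame spikes are instead
absorbed by the median stage, which replaces an isolated spike with a
neighbouring value. At the track ends the median window shrinks
symmetrically (3 at the penultimate sample, 1 at the end), so output
length equals input length.

The Kalman stage is a per-axis linear-Gaussian constant-velocity model —
state (position, velocity), transition over the actual time step (which
bridges gaps), continuous white-acceleration process noise of intensity
`process_sd^2`, position-only observation — run as a forward filter plus
Rauch-Tung-Striebel backward smoother, since trajectories are processed
offline and the two-sided smoother strictly dominates the causal filter
there. Defaults `meas_sd = 0.5` cm and `process_sd = 50` cm/s^2 are
fixed configuration, not maximum-likelihood estimates. The state is
initialized from the first two observations, which makes the smoother
exactly reproduce model-consistent input (uniform linear motion passes
through unchanged to < 1e-6 cm). A test cross-checks the smoother
against an independent batch MAP solution of the same joint Gaussian
model, solved as one dense least-squares problem.

On the generator's study conditions (0.5 cm noise, 1% outliers, 600
frames) the chain reduces positional RMSE against ground truth in 100%
of 200 seeded tracks.

## Kinematics, ODBA and energy expenditure

Speed is the norm of the displacement between consecutive frames times
the frame rate (n-1 values); per-axis acceleration is the second
difference times the squared rate (n-2 values). ODBA is the per-frame
sum of absolute accelerations across axes. Because these accelerations
come from positional differentiation, there is no gravity/static
component to subtract — unlike tag accelerometry — and the magnitudes
are treated as unitless in the energy conversion.

Per-frame energy expenditure in watts is

```
EE_i = K * mass^E * ODBA_i * Q10^((T_ref - T_study)/10) * 14.1 / 86400
```

with `K` (mg O2 g^-E d^-1) and `E` from the log-log OLS regression of
SMR on body mass (`fit_allometry()`; `K = exp(intercept)`, base-invariant),
the Q10 factor rescaling the reference-temperature SMR (defaults 1.92,
28 °C → 21 °C, factor ≈ 1.5787), 14.1 J per mg O2 as the oxy-calorific
coefficient for ammoniotelic animals, and 86400 converting per-day rates
to per-second. Surrogate-species presets ship for the two focal
surgeonfishes: *Ctenochaetus striatus* (3.9994, 0.7789) standing in for
*Acanthurus nigrofuscus* and *Zebrasoma scopas* (3.9109, 0.6958) for
*Zebrasoma xanthurum*. Per-trajectory summaries are arithmetic means
over the frames where each quantity is defined (not time-weighted over
gaps); both the per-track table and any cross-individual averaging are
left to the caller, since frame-weighted and track-weighted community
means differ and both are legitimate.

Length-weight conversion `mass = a * TL^b` takes an explicit
`coef_length_unit` argument because published coefficients conventionally
expect centimetres while field lengths are measured in millimetres; a
silent unit mismatch would change masses by roughly `10^b`.

### A limit worth knowing about

The end-to-end check compares EE computed from denoised noisy tracks
with EE from the noise-free ground-truth kinematics. Under the OU
velocity model the true per-frame acceleration is white up to the
Nyquist frequency (its per-axis sd is `sigma_v * sqrt(2*theta*fps)`,
about 180 cm/s^2 at the defaults), while 0.5 cm measurement noise at
60 fps swamps the acceleration spectrum above roughly 4 Hz. No smoother
can recover the unobservable high-frequency band, so the denoised mean
ODBA captures about half of the ground-truth value (median relative
error ≈ 0.52 over 100 seeds, computed by the acceptance suite). This is
an information-theoretic property of differentiating noisy position
data, not an implementation defect; the corresponding strict-recovery
test is left failing by design rather than loosened, and the acceptance
script reports the measured value. For real deployments the practical
implications are (a) ODBA from video tracking is a *relative* activity
index unless the smoothing bandwidth is calibrated against respirometry,
and (b) comparisons between species filmed with the same rig and
settings remain valid because the attenuation is common to both.

## Feeding metrics

Benthic availability comes from annotated cell counts
(`benthic_cover()`), bite rates standardize counts by visit duration,
and bite distances average consecutive 3D bite separations in time order
(undefined — reported as `NA`, never zero or imputed — with fewer than
two positioned bites). Biomass sums each individual once per 45-min
window; feeding rate is bites per m^2 per hour; feeding pressure is the
mass-weighted bite sum (kg bites m^-2 h^-1), a biomass-standardized
bite-impact formulation chosen because it reproduces the conventional
units exactly and reduces to rate × mass when all fish share one mass.
It is isolated in one function so an alternative weighting can be
substituted.

Selectivity uses Manly's design-I selection ratio
`w_c = (u_c/Σu)/(a_c/Σa)` with availability taken from cover fractions,
standardized to preference percentages `w_c/Σw * 100` (which sum to 100
by construction). Pooling bites across individuals is the default;
a per-individual mode (ratios per fish, summed per category, then
standardized) is provided because field protocols differ on this point,
and the two agree for identical fish. Bites on a category with zero
recorded availability raise an error naming the category — that is a
data problem, not a zero preference.

Trait-model comparison (`trait_model_selection()`) is thin orchestration
over `lm()` and `lme4::lmer()`: log-transformed traits, optional IQR
screening with the same fence convention as the trajectory stage,
maximum-likelihood fits so AIC is comparable across fixed effects,
singular random-effect fits reported rather than dropped, and exact AIC
ties broken deterministically toward fewer parameters. On data simulated
with a pure species effect and no grouping structure the
fixed-effects-only model attains the lowest AIC in ≈96% of 100 seeds —
boundary (zero-variance) mixed fits carry the same likelihood with extra
parameters, so this is the expected outcome, and the converse holds
when strong fish-level intercepts are simulated.

## Problem sizes and tolerances

The shipped checks use 600-frame tracks (10 s at 60 fps), 200 seeds for
denoising efficacy, 500 seeds of n = 50 respirometry fits (median
exponent error ≈ 0.010, well under the 0.02 acceptance band), ~10,000
synthetic bites for selectivity recovery (maximum preference error
≈ 0.4 percentage points against a 2-point band), and 100 seeds for the
model-selection and end-to-end checks — sizes at which every Monte-Carlo
margin above is stable across seeds while the whole suite stays
interactive. Numerical tolerances: geometric round trips at 1e-6 cm,
undistortion at 1e-12 px, worked-value identities at 1e-9 relative,
preference sums at 1e-9.

## Known limitations

- No air-water refraction or rolling-shutter correction; rig parameters
  are taken as given, so miscalibration propagates undetected into all
  3D quantities.
- The OU movement model has no behavioural states; energy estimates on
  real fish additionally face the spectral attenuation discussed above.
- Temperature is one scalar per analysis; no depth-temperature profile.
- Multi-fish identity association is out of scope: one track is one
  fish.
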