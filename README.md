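# reefodba

Foraging energetics and community feeding metrics of coral-reef fishes
from stereo-video 3D tracks.

Herbivorous reef fishes — grazers such as surgeonfishes — mediate the
balance between algae and coral, and their effect on a reef is set by
where they bite, how often, and how much energy their foraging costs.
`reefodba` is for movement ecologists and reef scientists who film
foraging fish with calibrated two-camera rigs and want to go from pixel
tracks to watts and selectivity estimates in one audited chain:

1. **Stereo geometry** — pinhole projection with radial/tangential
   distortion, rectification, disparity triangulation
   (`depth = f·B/disparity`), and calibration accuracy metrics.
2. **Trajectory denoising** — interquartile-range outlier removal
   (Tukey fences `Q1 − 1.5·IQR`, `Q3 + 1.5·IQR` per axis), a 5-point
   running median, and a constant-velocity Kalman smoother
   (forward filter + RTS backward pass, gap-aware).
3. **Energetics** — per-frame overall dynamic body acceleration
   `ODBA = |a_x| + |a_y| + |a_z|` converted to energy expenditure

   ```
   EE = K · mass^E · ODBA · Q10^((T_ref − T_study)/10) · 14.1 / 86400   [W]
   ```

   with `(K, E)` from the log-log regression of standard metabolic rate
   on body mass (surrogate-species presets included) and 14.1 J per mg O2
   as the oxy-calorific coefficient.
4. **Feeding metrics** — benthic cover, bite rates, inter-bite
   distances, biomass, feeding rate (bites m⁻² h⁻¹), feeding pressure
   (kg bites m⁻² h⁻¹), Manly's design-I selection ratios
   `w_c = (u_c/Σu)/(a_c/Σa)` with preference percentages, and
   AIC-based comparison of trait-model structures (via `lme4`).
5. **Synthetic data** — every input the chain consumes can be generated
   with known ground truth (Ornstein-Uhlenbeck swim paths, exact stereo
   projections, power-law respirometry tables, selectivity-weighted bite
   tables), so the whole pipeline is testable without field data.

## Worked example

```r
library(reefodba)

# a 10 s, 60 fps synthetic foraging track with 0.5 cm noise, 1% outliers
cfg   <- sim_config(seed = 7)
truth <- simulate_trajectory(cfg)
obs   <- corrupt_trajectory(truth, cfg)

dn <- denoise_trajectory(obs)
dn$n_outliers_removed
#> [1] 109        # IQR screen clips spikes plus the path's extreme excursions

preset <- species_presets()[["Acanthurus nigrofuscus"]]
preset
#> <energetics_config> SMR = 3.9994 * mass^0.7789 mg O2/d; Q10 1.92 (28 -> 21 degC); oxycal 14.1 J/mg O2

mass <- mass_from_length(a = 0.0206, b = 3.01, TL_mm = 113)  # 30.45 g
summarize_trajectory(dn$trajectory, mass, preset)
#>   track_id                species   mass_g mean_velocity_cms mean_EE_W n_frames n_speed n_accel
#> 1     sim1 Acanthurus nigrofuscus 30.45323          27.61591  3.003327      491     489     487
```

The fish swam at a mean 27.6 cm/s and spent about 3.0 W while foraging
(its allometric SMR modulated by movement intensity and corrected from
the 28 °C respirometry reference to the 21 °C study temperature,
factor `temperature_adjustment() = 1.578741`).

Feeding selectivity against substrate availability:

```r
prof  <- benthic_cover(c(rock = 150, rubble = 430, sand = 160,
                         live_coral = 100, dead_coral = 160))
bites <- simulate_feeding_observations(
  prof, c(rock = 3, rubble = 2, sand = 0.5, live_coral = 0.2, dead_coral = 1),
  n_fish = 40, seed = 7)
manly_ratios(setNames(as.numeric(table(bites$substrate)),
                      names(table(bites$substrate))), prof)
#> <selectivity_result> (pooled mode)
#>                w preference_pct
#> rock       1.957          45.33
#> rubble     1.253          29.03
#> sand       0.328           7.59
#> live_coral 0.157           3.64
#> dead_coral 0.622          14.42
```

`w > 1` means a substrate is bitten more than its availability predicts:
this simulated fish targets rock (45% preference) and avoids live coral,
close to the generating weights `(3, 2, 0.5, 0.2, 1)` normalized.

An end-to-end run (simulate → project → triangulate → denoise →
energetics, plus cover → bites → selectivity) with per-stage CSVs and a
JSON manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
```

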