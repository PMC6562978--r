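# mobspace

Grouping and spacing analysis of eastern grey kangaroo (*Macropus
giganteus*) mobs across landscapes shared with humans.

Kangaroo populations can experience sharply different human behaviour
within one contiguous landscape: benign attention at a campground,
indifference on wildlife-friendly farmland, occasional or frequent
hunting elsewhere. `mobspace` is for behavioural ecologists who survey
such populations and want the standard analysis chain for grouping and
spacing behaviour under a disturbance regime of frequency (high/low) ×
intent (benign/harm), labelled HB, LB, LH, HH:

* **chain-rule group assignment** — individuals within a threshold
  distance (15/30/50 m) of any group member belong to the group
  (connected components of the threshold graph, i.e. a single-linkage
  cut), with the pouch-young counting rule (in-pouch joeys ride with
  their mother and are excluded from group size but included in
  composition);
* **group metrics** — size, geometric centre, clusteredness (mean
  nearest-neighbour distance), demographic composition over six classes
  (LA, MA, SA, SUB, YAF, PY);
* **landscape metrics** — distance from group centre to forested cover,
  front/behind positioning of vulnerable individuals (mothers,
  young-at-foot, pouch young) via `delta = GDC − IDC`, grazing density
  per km² of cleared habitat, and relative green channel brightness
  ("greenness") of forage patches;
* **inference** — D'Agostino skewness and Anscombe–Glynn kurtosis tests
  of group-size distributions; one-way ANOVA with Tukey HSD on log
  density; linear mixed models (session random intercept) for group
  size, clusteredness, demography and greenness with least-squares-means
  Tukey contrasts and likelihood-ratio tests; binomial GAMs for
  positioning; and the headline model

  ```
  size_ij ~ NB(mu_ij, theta),  log mu_ij = alpha_z + beta_z * log d_ij + b_j,
  b_j ~ N(0, sigma^2)          (session j, zone z, Laplace approximation)
  ```

  — negative binomial group size against log distance-to-cover nested
  within disturbance type, 95% Wald CIs, a slope "detected" when its CI
  excludes zero. Under benign disturbance groups grow with distance from
  cover (the many-eyes antipredator pattern); under harmful disturbance
  the slope collapses to zero.
* **a synthetic survey generator** with planted landscape, densities,
  slopes, demography, positioning bias and greenness, so the whole
  pipeline runs and is validated with no field data.

## Worked example

```r
library(mobspace)
cfg <- simulation_config(seed = 1)          # four default zones, 6 sessions
sv  <- generate_survey(cfg)
sv
#> Synthetic survey: 6 sessions, 2219 individuals, 243 planted groups, seed 1

dens <- grazing_density(sv$observations, sv$landscape)
round(tapply(dens$density_km2, dens$zone, mean), 1)
#>    HB    HH    LB    LH
#> 149.1  29.0  77.6  75.0

parts <- survey_partitions(sv$observations, sv$landscape, chains = c(15, 30, 50))
nb <- groupsize_cover_glmm(parts[parts$chain_m == 15, ])
nb
#> negative binomial GLMM fit: size ~ zone + zone:logd + (1 | session) (n = 243)
#>   session sigma = 5.12e-05
#>   fixed effects:
#>          term estimate  lower   upper detected
#> 1 (Intercept)    1.050 -2.034 4.13302    FALSE
#> 2      zoneLB   -0.533 -3.743 2.67738    FALSE
#> 3      zoneLH    2.286 -1.073 5.64490    FALSE
#> 4      zoneHH    2.525 -1.292 6.34251    FALSE
#> 5 zoneHB:logd    0.234 -0.496 0.96437    FALSE
#> 6 zoneLB:logd    0.301  0.133 0.46989     TRUE
#> 7 zoneLH:logd   -0.273 -0.553 0.00567    FALSE
#> 8 zoneHH:logd   -0.308 -0.750 0.13307    FALSE
```

Mean densities keep the planted ordering HB > LB ≈ LH > HH (HB, a 17.1 ha
campground, is noisy in a single six-session survey). At the 15 m chain
the benign LB slope of log group size on log distance-to-cover is
positive and detected (CI excludes zero) while the harm-zone slope CIs
reach zero; HB's slope is positive but its small area leaves
single-survey power low — the replicate experiments below quantify that.
The session random-effect SD is effectively zero, as expected for
independent sessions.

The full survey-to-figures workflow lives in `analysis/01_simulate.R`
through `analysis/05_report.R` (run them in order from the repository
root; outputs land under `results/`). `run_pipeline(cfg, out_dir)` runs
the same chain programmatically and writes a manifest with checksums.

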