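# mangroveBiomass

Stand structure and organ-weight estimation for *Avicennia germinans*
(black mangrove) forests surveyed with the point-centered quarter method
(PCQM), for ecologists comparing biomass allocation across natural,
degraded and restored coastal ecosystems.

The package covers the full field-to-figures chain:

* **Synthetic stands** — spatially explicit single-species stands per
  ecosystem condition (homogeneous Poisson locations; DBH and height marks
  calibrated to published per-class ranges), so the whole pipeline is
  testable without field data.
* **PCQM survey** — transects of 25 points at 10 m spacing; nearest tree
  per compass quadrant within a 10 m search radius (vacant quarters kept);
  Cottam–Curtis density (trees/ha = 10⁴ / d̄², d̄ the mean point-to-tree
  distance in m), basal area, and upper-inclusive diameter classes
  (5,10], (10,20], (20,30], (30,40], (40,∞) cm.
* **Allometry** — per-tree organ weights from the published power laws

  W_T = 0.0696 ρ (D²H)^0.931  W_AG = 0.251 ρ D^2.46  W_R = 0.199 ρ^0.899 D^2.22

  (D in cm, H in m, ρ = 0.64 g/cm³, weights in kg), and per-hectare scaling
  kg/ha = total / (π r² n_points) × 10⁴ over the combined sampling-circle
  area.
* **Inference** — Shapiro–Wilk screening on log10 weights, Kruskal–Wallis
  with Dunn's post-hoc pairwise tests per organ, Spearman organ–organ rank
  correlation matrices per ecosystem, and a Gaussian identity-link GLM of
  total per-tree weight on ecosystem type (reference level: degraded).

External per-tree tables (e.g. a deposited replication file) are ingested
through a declarative column mapping with row-by-row invariant validation
(`read_survey_table()`).

## Worked example

```r
library(mangroveBiomass)
cfg <- pipeline_config(seed = 20230701L, n_sites = 3L)  # 3 sites x 25 points x 4 quarters per ecosystem
bundle <- run_pipeline(cfg)
print(bundle)
```

```
Trees sampled: 899

Per-hectare organ totals (kg/ha, pooled points):
  degraded  trunk           3617.47
  degraded  aboveground     7484.57
  degraded  root            3437.63
  natural   trunk          13986.25
  natural   aboveground    39798.55
  natural   root           15540.45
  restored  trunk           3848.59
  restored  aboveground     6476.12
  restored  root            3034.68

trunk weight: Kruskal-Wallis chi-squared = 550.63, df = 2, p = 2.71e-120
  Dunn degraded vs natural: z = -21.18, p = 1.44e-99 (none)
  Dunn degraded vs restored: z = -1.87, p = 0.062 (none)
  Dunn natural vs restored: z = 19.33, p = 2.97e-83 (none)
...
GLM total weight ~ ecosystem (reference degraded), n = 899, AIC = 11867.02:
  (Intercept)                  est     114.58  se    10.26  t   11.17  p 3.32e-27
  ecosystemnatural             est     429.90  se    14.50  t   29.66  p 3.34e-135
  ecosystemrestored            est      -9.65  se    14.50  t   -0.67  p 0.506
```

Reading: natural stands carry far more weight per hectare in every organ
(their thicker diameter classes dominate the power laws); Dunn separates
the natural ecosystem from both others while degraded vs restored does not
differ; the GLM intercept is the degraded mean total weight per tree (kg)
and the coefficients are mean differences against it — natural strongly
positive, restored indistinguishable from degraded.

The staged equivalent lives in `analysis/01_simulate.R` …
`analysis/05_report.R`: each script narrates one stage and writes its
tables under `results/`.

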