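---
title: "From plotless transects to organ weights: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plotless transects to organ weights: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveBiomass)
```

## The problem

Black mangrove (*Avicennia germinans*) forests along disturbed coastlines
occur in three recognisable conditions — natural (mature, low-disturbance),
degraded (heavily disturbed), and restored (juvenile, replanted) — and the
standing biomass of their trees differs across those conditions. Quantifying
that difference from field surveys involves three linked steps, each of which
this package implements as tested code:

1. **Plotless stand sampling.** The point-centered quarter method (PCQM)
   walks a 250 m line transect with 25 points at 10 m intervals; at each
   point a 10 m-radius circle is split into four compass quadrants and the
   nearest tree per quadrant is measured (distance, DBH, height). Point-to-
   tree distances give a density estimate without plot boundaries.
2. **Allometric organ weights.** Per-tree dry weights of trunk, aboveground
   material and roots follow published power laws in DBH \(D\) (cm), height
   \(H\) (m) and wood specific gravity \(\rho\) (g/cm³):
   \[
     W_T = 0.0696\,\rho\,(D^2 H)^{0.931},\qquad
     W_{AG} = 0.251\,\rho\,D^{2.46},\qquad
     W_R = 0.199\,\rho^{0.899}\,D^{2.22},
   \]
   with \(\rho = 0.64\) for *A. germinans*. Transect totals scale to kg/ha
   by the combined area of the sampling circles:
   \(\mathrm{kg/ha} = \mathrm{total} / (\pi r^2 n_{points}) \times 10^4\).
3. **Inference.** Log10-transformed weights are screened with Shapiro–Wilk;
   organ weights are compared across ecosystem types with Kruskal–Wallis and
   Dunn's post-hoc pairwise tests; organ–organ association is measured with
   Spearman rank correlations; and total per-tree weight is regressed on
   ecosystem type with a Gaussian identity-link GLM.

Because the field data live in an external repository, the package ships a
synthetic stand generator calibrated to the published dendrometric summary,
so every downstream stage is testable offline, plus a declarative
column-mapping reader (`read_survey_table()`) for ingesting the real
per-tree table when it is available.

## The synthetic stand generator

`study_profiles()` encodes one profile per ecosystem condition. Each profile
is a marked point process:

* **Locations** follow a homogeneous Poisson process. The survey reports no
  spatial structure, so homogeneity is the parsimonious choice; a Thomas
  cluster variant (`process = "thomas"`) exists purely for
  estimator-robustness experiments and is never a default.
* **Stem intensity** is the sum of the published per-class densities
  (natural 2513.89, degraded 2647.61, restored 7976.06 trees/ha), and the
  class mixing proportions are those densities renormalised. The published
  per-class densities may not be the decomposition the original authors'
  software used — their per-class formula is unstated — so these intensities
  are a calibration choice of this package, not a reproduction claim.
* **DBH within a class** is uniform on the *observed* per-class range (for
  example the natural > 30–40 cm class draws from [32.44, 32.72] cm), which
  is strictly inside the class bounds. Only ranges are published, so
  calibration is to ranges, not moments; a truncated lognormal alternative
  is available.
* **Height** is linear in log(DBH) — monotone, as tree allometry requires —
  with intercept and slope fitted through the class midpoints per ecosystem,
  Gaussian noise (default sd 1 m, a realistic rangefinder-plus-stand spread
  given the published 3–5 m within-class ranges), and an exact
  truncated-normal draw inside the class's observed height range (floored at
  0.1 m). Truncation is what lets restored 10–20 cm trees sit in
  [11.07, 12.56] m — taller than any natural class — reproducing the
  "taller but thinner" restored stands.

**What the generator does not emulate:** spatial clustering or inhibition,
measurement error in distances, within-class DBH–height correlation beyond
the monotone mean map, multi-species quarters, and any temporal dynamics.
Tests passing on these stands therefore validate the *estimators and
pipeline plumbing*, not ecological realism of any particular forest.

**Seed policy.** One master integer seed; each site draws from a stream
derived by a fixed offset (`site_seed()`), so adding a tenth site would not
reshuffle the first nine. All generation restores the caller's RNG state.

## PCQM choices

* **Density estimator.** The original survey delegates to an external R
  package without printing a formula. We implement the classical
  Cottam–Curtis mean-distance estimator, density/ha \(= 10^4/\bar d^2\),
  because it is the canonical PCQM estimator and is directly testable: on
  simulated Poisson stands of 2500 trees/ha the mean of 100 transect
  estimates lands within 10% of truth, and the median relative error
  shrinks as the transect grows (25 vs 200–400 points).
* **Truncated search.** The 10 m radius makes this a truncated PCQM.
  Quarters with no tree inside the radius are kept as *vacancies* and
  reported; they are never re-sampled. The vacancy-corrected density
  variant (multiply by the occupied fraction) is switchable and off by
  default.
* **Quadrant geometry.** N/S/E/W quarters are the four 90° sectors centred
  on the compass axes (boundaries on the 45° diagonals, assigned to the N/S
  sectors; a tree exactly at the point goes to N). Any fixed partition is
  equivalent for the estimator; ties in distance break by
  (distance, x, y, tree index) so sampling is deterministic.
* **Overlap.** Adjacent 10 m circles at 10 m spacing overlap; a tree may be
  nearest to two different points and is then recorded at both (never twice
  at one point). No deduplication is applied, matching the field protocol's
  geometry.
* **Diameter classes** are upper-inclusive half-open intervals (5,10],
  (10,20], (20,30], (30,40], (40,∞) cm — a DBH of exactly 10 falls in the
  lower class, matching the "> 5–10" labelling. DBH ≤ 5 cm is *below the
  classification* and raises an explicit signal rather than being dropped.
* **Per-class density** is reported as overall density × class share of
  records — a documented decomposition, since no per-class plotless formula
  is published.

## Allometric choices

* **Trunk exponent grouping.** The trunk equation is evaluated as
  \(0.0696\,\rho\,(D^2H)^{0.931}\), not \(0.0696\,\rho\,D^2H^{0.931}\). At
  the thick end of the natural stands (D ≈ 32.6 cm, H ≈ 9.3 m, ρ = 0.64)
  the grouped form gives ≈ 233 kg against a published 30–40 cm class mean
  of 250.60 ± 8.25 kg, while the ungrouped form gives ≈ 377 kg; the grouped
  form is also the canonical common mangrove trunk equation. The ungrouped
  parse stays available behind `grouping = "ungrouped"` and the choice is
  echoed in every report header.
* **Units** enter the formulas exactly as published (D cm, H m, ρ g/cm³,
  weights kg); no internal conversion.
* **Numerics.** The power term is evaluated in log space and the
  coefficients multiply outside it, so unit inputs recover the coefficients
  *exactly* and log-space agrees with the direct product form to 1e-10
  over D ∈ [5, 50], H ∈ [1, 30].
* **Per-hectare pooling.** The scaling formula says "total number of
  sampling points" without qualification. Ecosystem-level figures pool all
  points across the ecosystem's sites (3 × 25 = 75); per-site figures
  (n = 25) are emitted alongside. The overlap of sampling circles is
  ignored in the area term, exactly as the formula prescribes, and the
  report header notes the resulting double-counting.

## Statistical choices

* **Where the log10 transform applies.** The transform is used for the
  Shapiro–Wilk screen only. Kruskal–Wallis, Dunn and Spearman are rank
  based and invariant under monotone maps, so they run on raw weights; the
  GLM runs on raw totals because its intercept is a kg-scale group mean.
* **Dunn's test** is implemented from the tie-corrected rank-sum formula
  (no suitable implementation ships with base R) and cross-checked in the
  tests against an independent recomputation; p-values default to
  unadjusted two-sided (the cited implementation's default), with
  Bonferroni and Holm options. Degenerate all-identical input returns
  z = 0, p = 1.
* **GLM reference level** is `degraded`, fixed explicitly: it is the
  alphabetical first level and makes the natural contrast positive and the
  restored contrast negative.
* **Calibration checks.** Kruskal–Wallis type-I error is verified to sit in
  [0.03, 0.07] at nominal 0.05 over 2,000 null simulations (three equal
  lognormal groups, n = 50). GLM group-mean recovery is scored per group
  mean across 100 replicates (300 checks), expecting ≥ 93% of them within
  2 standard errors; nominal coverage of a single 2-SE interval is ≈ 95%,
  so a joint all-three-at-once criterion would sit near 87% by construction
  and would not be a meaningful calibration bar.
* Significance is two-sided at 0.05 throughout.

## Degenerate inputs and tie-breaks

Vanishing intensity gives an empty scene; an all-vacant survey makes
density an explicit error; constant vectors make Shapiro–Wilk an error and
Spearman an NA with a warning; all-identical groups give H = 0, p = 1;
single-tree summary cells report an undefined (NA) standard error; class
cells with no trees are omitted. External rows violating any record
invariant (distance beyond the radius, non-positive sizes, bad quadrant,
duplicate quarter) are rejected row by row with reasons.

## Problem sizes

The default configuration mirrors the field campaign: 3 sites × 25 points ×
4 quarters per ecosystem, giving up to 300 trees per ecosystem and ~900
overall — the same order as the published 625. Test simulations use 270 ×
50–60 m scenes (one transect each), 500 small scenes for the brute-force
equivalence sweep, 100 transects for density recovery, and 2,000
replicates for the null calibration; these sizes give stable Monte Carlo
behaviour at interactive runtimes.

## Known limitations

* The Cottam–Curtis estimator is biased under clustered or inhibited
  spatial patterns; the Thomas variant exists to explore exactly that.
* Per-class densities and basal areas depend on the decomposition choice
  above and are not comparable to figures produced by other per-class
  formulas.
* The truncated search radius biases density slightly downward in sparse
  stands (vacancies discard long distances); the vacancy-corrected option
  addresses occupancy, not the distance truncation itself.
* Allometric coefficients are taken as given; no refitting, no
  leaf/branch subdivision, no carbon-fraction conversion.
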