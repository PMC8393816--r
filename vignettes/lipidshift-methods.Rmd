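---
title: "Methods: differential composition analysis for targeted shotgun lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential composition analysis for targeted shotgun lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidshift)
```

## The measurement model

A targeted shotgun (SRM) lipidomics run yields one counts-per-second
intensity per transition, i.e. per analyte, for every injection. The
design `lipidshift` assumes is: compartments (default `homogenate`,
`mitochondria`) × groups (a reference, default `mock`, and one or more
treated groups, default `APPswe`) × biological replicates (default
n = 7) × technical replicates (default 3). Because only precursor and
fragment masses are observed, a glycerophospholipid species is a *sum
composition*: `PCaa C38:4` is every diacyl phosphatidylcholine whose
two chains total 38 carbons and 4 double bonds. The nomenclature module
parses this dialect (including lyso and explicit two-chain `PG
18:2/16:0` forms) and exposes class, linkage, carbons, double bonds and
carnitine chain parity, which all aggregations key on. Assigning
individual fatty acids to sn-positions is out of scope by construction
of the measurement.

## Normalization

Deuterated or short-chain internal standards are spiked per lipid class
before extraction; dividing each analyte by its (class, linkage)
standard cancels extraction and ionization yield. The order of
operations matters and is fixed: the lipid/standard **ratio is formed
per technical replicate**, then the ratios are averaged per sample
(`normalize_to_standard()` then `collapse_technical()`). Averaging raw
intensities first and dividing afterwards is *not* equivalent (a ratio
of means is not a mean of ratios) and is not what this assay's
processing convention prescribes.

Degenerate inputs: a zero or missing standard invalidates its whole
class for that sample (dropped with a warning and reported in an
attribute), while a zero *analyte* intensity is kept as ratio 0 — zero
SRM signal is informative, missing standard signal is not. An optional
per-sample `scale` column accommodates upstream protein-amount
adjustment; it cancels in the ratios.

The matrix-effect QC reports, per standard and non-reference group, the
percent change of the mean standard intensity against the reference
group (`(group − reference)/reference × 100`), with per-compartment
maximum and mean absolute change and a pooled mean. Because the metric
is an absolute value of a noisy difference, it is biased upward by
sampling error (a folded-normal effect): with the default technical CV
of 5% and 21 measurements per group mean, a true 1.2% shift reads as
roughly 1.4–1.9% on average. The unit tests therefore verify the metric
exactly at zero technical noise and within Monte-Carlo tolerance at
near-zero noise; QC numbers on noisy data should be read as upper
bounds on the true matrix effect.

## Per-species statistics and the trend criterion

For one compartment and contrast, each species' replicate ratios are
scaled by the control mean, so the control sits at 1. Then:

* fold change *FC* = mean of scaled treated values;
* SEM = SD(scaled treated)/√n — the error bar on the fold-change scale;
* *p* from a two-tailed **pooled-variance** Student *t* on the unscaled
  ratios. The classical pooled test is used rather than Welch because
  the target workflow names Student's *t* and the design is balanced
  (n = 7 vs 7), where the two are near-identical. Testing is on raw
  ratios, not logs, matching the fold-change scale of the reported
  effect sizes.

Classification is two-tiered: `significant_up/down` when *p* ≤ α
(default 0.05, no multiple-testing correction — a Benjamini–Hochberg
column is emitted as supplementary output only, to match the target
workflow's convention), otherwise `trend_up/down` when
|*FC* − 1| exceeds the **average SEM of the analysis set**, otherwise
`unchanged`. The average SEM is computed over whatever set is passed
in: the whole panel for panel-wide volcano output, one (class, linkage)
set for per-class figures — each analysis draws its own guide lines.
Degenerate cases are explicit: both groups constant and equal gives
p = 1 (`degenerate`); a zero control mean makes the species
not-evaluable rather than infinite.

### A calibration property of the trend criterion

The trend tier is intentionally liberal, and users should know *how*
liberal. For a null species, the fold-change estimate has standard
deviation ≈ σ√(2/n) (σ = per-replicate CV), while the threshold —
the average SEM — is ≈ σ/√n. The ratio of the two is 1/√2 regardless of
σ and n, so under *homogeneous* noise about
2·(1 − Φ(1/√2)) ≈ 48% of null species exceed the trend threshold. The
package's Monte-Carlo suite reproduces this (≈ 45–50% of nulls labeled
under the default CVs), while the *significant* tier stays calibrated
at α (measured 0.048 over 10,180 null contrasts). In real panels,
per-species variances are strongly heterogeneous; the average SEM is
then pulled up by the noisiest species and the trend tier flags far
fewer nulls. The synthetic generator deliberately uses a single CV pair
and therefore represents the worst case for trend specificity —
passing recovery tests here says nothing about trend false-positive
rates on real data, which depend on the variance distribution.

## Compositional views

**Mol%** divides each species by the summed signal of its (class,
linkage) set per sample (×100), removing any whole-class abundance
effect; sums are 100 by construction whenever the class sum is
positive, and a zero class sum flags all its species not-evaluable in
that sample. The same statistics/classification machinery runs
unchanged on mol% tables.

**Double-bond ratios** sum the ratios of species with the numerator
double-bond count and divide by the denominator set's sum, *per
replicate*, then express the treated mean as % of the control mean with
SEM in percentage points and a Student-t p across replicates. Ratios
are formed per replicate and then averaged — not as a ratio of group
means — because the reported uncertainty (± SEM) is defined over
replicate-level ratio values. `linkage = "ax"` pools diacyl and ether
species. A replicate with a zero denominator sum is excluded with a
warning; if all are excluded the ratio is not-evaluable.

**Carnitine panel.** C0 is free carnitine, C2 acetyl- (the
β-oxidation end product), C3 propionyl-carnitine. The derived sums are
defined as: Ceven = even chains ≥ 4, Codd = odd chains ≥ 5, CX = all
acyl-carnitines (chain ≥ 2, excluding free carnitine). C2 is kept out
of Ceven and C3 out of Codd because each serves as the denominator of
its own ratio (Ceven/C2, Codd/C3) — including them would make the
ratios partially self-referential. This is an explicit interpretation
(the convention is not uniquely fixed by the workflow this implements)
and is localized in `carnitine_panel()` should a user need the
inclusive variant. Ratios with a zero denominator in a replicate drop
that replicate; missing input species (no C2, no C3) flag the dependent
ratios not-evaluable.

**Chain-length bins** default to ≤ 33 (short), 34–39 (mid), ≥ 40
(long) total carbons — i.e. roughly two C16–C20 chains for the mid bin
— and are configurable.

## Compartment comparison

"Changed" means any trend or significant label. The shift test builds
the 2×2 table (compartments × increased/decreased) and applies the
package's own two-sided Fisher exact test: the sum of hypergeometric
point probabilities ≤ that of the observed table (minimum-likelihood
convention, as in standard statistical software), with a relative
tolerance of 1e-12 guarding floating-point ties. The implementation is
verified against an exhaustive `choose()`-based enumeration oracle on
every 2×2 table with total ≤ 40 and spot-checked against
`stats::fisher.test`. The Venn partition assigns every changed species
to exactly one of six cells (exclusive up/down per compartment, shared
same direction, shared opposite direction).

## The synthetic generator

`simulate_dataset()` draws, in a fixed documented order (analyte
baselines → matrix-effect signs → biological factors → technical
factors) under one integer seed:

* per-analyte baseline expectations, log-uniform over 10³–10⁵ cps;
* *unit-mean* log-normal biological noise (default CV 0.15), one draw
  per sample × analyte, shared across that sample's technical
  replicates;
* unit-mean log-normal technical noise (default CV 0.05) per injection;
* planted fold changes multiply the expected intensity of selected
  species in non-reference groups — because all noise has unit mean,
  the planted value propagates *exactly* in expectation, and exactly
  full stop when CVs are zero;
* standards receive technical noise only, plus a ±1.2% (default)
  multiplicative matrix-effect shift per (standard, group, compartment)
  in non-reference groups, so the QC metric has signal to find.

Default CVs were chosen as representative of replicate-level spread in
targeted lipidomics of cultured cells: ~15% biological, ~5% technical,
~1.2% matrix-effect amplitude. The generator reproduces the *moments*
the analysis depends on; it does not emulate ionization physics,
isotope patterns, drift, batch structure, heteroscedastic per-species
variances or missingness — so tests passing on synthetic data validate
the pipeline's arithmetic and calibration, not robustness to those
real-data features.

The default panel is a 226-analyte reconstruction (207
glycerophospholipids + 19 carnitines; exact counts per group in
`inst/extdata/panel_manifest.txt`): regular carbon × double-bond grids
per (class, linkage) plus named extras (e.g. `PCae C40:8`,
`PEae C40:7`) and explicit lyso lists. Membership is a plausible
reconstruction of a typical panel of this size, not a published list.

## Problem sizes in the test suite

The statistical suites use sizes chosen to make Monte-Carlo tolerances
meaningful at interactive runtimes: null calibration over 10,180
species-contrasts (20 simulated studies of a 509-species null panel;
significant fraction within 0.05 ± 0.01), recovery of 50 planted 1.3×
effects among 200 species at a fixed seed, law-of-large-numbers checks
at 500 biological replicates, and the exhaustive Fisher sweep over all
~136,000 tables with n ≤ 40.

## Known limitations

* Pooled-variance *t* on raw ratios is sensitive to variance
  heterogeneity between groups and to strong skew at small n; a
  log-scale option is a natural extension but is off by default to
  match the implemented workflow.
* No multiple-testing correction in the labels (by design, matching
  the workflow); the BH column is informational.
* The trend tier's false-positive behaviour depends entirely on the
  variance distribution across species (see above).
* Two compartments only in the shift test; no omnibus multi-fraction
  test.
* No isotope correction, adduct handling or drift/batch correction —
  inputs are assumed to be clean per-transition intensities.
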