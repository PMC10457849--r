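---
title: "The SeDeM method in sedem: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SeDeM method in sedem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedem)
```

## The method

The SeDeM expert system scores a powdered drug substance on twelve
galenic parameters grouped into five incidence factors, and summarizes
the result as a 12-axis radar diagram plus three numeric indices that
judge suitability for direct compression (DC), i.e. tabletting without
granulation.

Each parameter value $v$, measured in its physical units, is mapped to a
radius $r \in [0, 10]$ by a fixed linear (or affine) conversion chosen
so that 10 is the best achievable value, 0 the worst, and 5 the minimum
acceptable:

| Parameter | Symbol | Units | Working limits | Radius |
|---|---|---|---|---|
| Bulk density | Da | g/mL | 0–1 | $10v$ |
| Tapped density | Dc | g/mL | 0–1 | $10v$ |
| Interparticle porosity | Ie $=(Dc-Da)/(Dc\,Da)$ | – | 0–1.2 | $10v/1.2$ |
| Carr index | IC $=100(Dc-Da)/Dc$ | % | 0–50 | $v/5$ |
| Cohesion index | Icd (mean tablet hardness) | N | 0–200 | $v/20$ |
| Hausner ratio | IH $=Dc/Da$ | – | 3–1 | $5(3-v)$ |
| Angle of repose | $\alpha$ | ° | 50–0 | $10-v/5$ |
| Flow time | t | s/100 g | 20–0 | $10-v/2$ |
| Loss on drying | %HR | % | 10–0 | $10-v$ |
| Hygroscopicity | %H | % | 20–0 | $10-v/2$ |
| Particles < 50 µm | %Pf | % | 50–0 | $10-v/5$ |
| Homogeneity index | $I_\theta$ | – | 0–0.02 | $500v$ |

All conversions clamp to $[0,10]$; out-of-limit inputs clamp with a
warning rather than erroring, because real powders do exceed the
nominal working limits (porosities above 1.2 occur in this package's own
reference data). A powder that does not flow at all carries the
sentinel `Inf` for flow time and maps to radius 0; likewise a powder
that cannot be compressed has cohesion index 0 and radius 0.

The three summary indices of a 12-radius profile are:

* **IP** (parametric index): the fraction of radii at or above 5;
* **IPP / PP** (parametric profile index): the arithmetic mean of all
  twelve radii;
* **GCI / IGC** (good-compression index): $\mathrm{IPP} \times f$,
  where $f$ is the reliability factor, the polygon-to-circle area ratio
  of the diagram. $\mathrm{GCI} > 5$ (strict) is the DC-suitability
  criterion.

Statistical validation runs on the per-replicate radii: descriptive
statistics ($\bar x$, $S^2$, $S_{n-1}$, CV%), a Levene variance check,
and a classical one-way ANOVA per parameter (plus PP and IGC), grouped
by batch (manufacturing reproducibility), by production scale
(pilot-to-industrial transposition), or by source (supplier
comparison). Because the radius conversions of most parameters are
affine, the ANOVA F statistics are identical whether computed on radii
or raw values; for the nonlinear Ie and IH this is not exactly true,
and the package follows the convention of testing radii.

## Conventions and tunable parameters

All knobs live in `sedem_config()`:

* **Cohesion divisor (default 20).** The working limit of the cohesion
  index is 0–200 N of tablet crushing hardness; dividing by 20 maps it
  onto 0–10. A divisor of 290 circulates in parts of the SeDeM
  literature but cannot reach radius 10 within the stated 0–200 N
  limit, so it is not the default; the divisor is configurable for
  users who want to match either convention.
* **Reliability factor (default the constant 0.952).** For the
  12-parameter diagram, published index tables are computed with the
  constant 0.952, which this package reproduces bit-for-bit; the exact
  regular-dodecagon ratio $3/\pi = 0.95493$ is available via
  `reliability_f = "polygon"` (`reliability_factor(k, "polygon")`
  generalizes to any $k \ge 3$ and tends to 1 as $k \to \infty$).
* **Levene centering (default median).** The variance checks printed
  alongside published SeDeM ANOVA tables are reproduced exactly by the
  median-centered (Brown–Forsythe) form of Levene's test — we verified
  several cells to four decimals — so that is the default; classical
  mean centering is available by configuration.
* **Significance level** $\alpha = 0.05$; a comparison row with all
  values identical (flow time of a uniformly non-flowing powder,
  cohesion of incompressible material) is reported `not_testable`,
  never dropped. No multiple-testing correction is applied, matching
  standard practice in this literature; the report states the number
  of tests so a reader can apply their own.
* **PSD quantile interpolation (default log-linear).**
  Laser-diffraction instruments report cumulative volume curves on
  log-spaced size grids, so D10/D50/D90 are interpolated linearly in
  $\log_{10}$(size); plain linear interpolation is available. The
  distribution breadth is reported as $F' = D_{90}/D_{10}$. $F'$ is
  used in the field without a universal printed definition; the ratio
  $D_{90}/D_{10}$ reproduces every published value we checked to three
  decimals and is documented as the inferred definition.
* **Sieve fraction diameters.** Mean fraction diameters are arithmetic
  midpoints of the bounding apertures; the pan fraction (< 50 µm) uses
  the midpoint of (0, 50) = 25 µm; the oversize fraction uses the
  coarsest aperture itself unless a nominal upper bound is configured.
  Fractions are renormalized to the recovered mass (tolerated loss 2
  percentage points, configurable), and zero-mass fractions are
  dropped.
* **Homogeneity index.** Implemented as the symmetric generalization
  $$I_\theta = \frac{F_m}{100 + \sum_{n\ge1}\left[(d_m - d_{m-n})F_{m-n}
  + (d_{m+n} - d_m)F_{m+n}\right]}$$
  over all fractions present on each side of the majority fraction,
  with diameters in µm and percentages in percent. Ties for the
  majority fraction resolve deterministically to the smallest-diameter
  fraction. The index is bounded by $F_m/100$ and decreases when mass
  moves away from the majority fraction.
* **Fines precedence.** When the dedicated 10-minute vibrated fines
  test was performed, its value overrides the pan percentage of the
  full stack test, because fines adhering to coarser particles during
  the stack test bias the pan fraction low.
* **Rounding.** All arithmetic is double precision; rounding to the
  display precisions (radii 2 dp, statistics 4 dp) happens only at
  serialization, with full-precision values carried alongside in JSON
  reports.

## The synthetic generator

`supplier_archetype()` fixes a "true" powder; `simulate_batch()` and
`simulate_study()` draw replicate measurements around it with
multiplicative lognormal noise (mean 1) at stated coefficients of
variation. Design points:

* **Two size distributions per archetype.** The laser PSD describes the
  primary particle population and drives the simulated cumulative
  curves and D-quantiles. Sieving a cohesive powder sees something much
  coarser — fine particles agglomerate and adhere to coarse material —
  so sieve fractions, fines and the homogeneity index are driven by a
  separate sieve-effective lognormal. The built-in archetypes make the
  distinction concrete: the coarse source's laser PSD puts ~43% of
  volume below 50 µm while its sieve test reports ~12% fines, and a
  single distribution cannot produce both.
* **Analytic sieving.** Sieve fractions are obtained by integrating the
  (noise-perturbed) sieve-effective lognormal over the 355/212/100/50
  µm cuts — exact and deterministic given the seed, rather than
  sampling particles.
* **Hierarchical seeding.** Every random draw uses a seed derived from
  (study seed, batch index, replicate index, quantity index), so adding
  a batch to a study never perturbs the draws of other batches, and the
  same seed reproduces a dataset byte-for-byte.
* **Noise-free identity.** With all CVs at zero the pipeline recovers
  the archetype's expected radius profile exactly (`archetype_profile()`
  is the closed form); this is the generator's round-trip test.
* **Defaults as study conditions.** Replicate CV defaults to 2% per raw
  quantity, comparable to the replicate dispersion of the reference
  radius tables (CV 1–10%). Batch-to-batch CV defaults to 0: the
  scenario emulated is a *validated, reproducible* manufacturing
  process, in which batches of one source differ only through
  measurement noise, so the batch-reproducibility null hypothesis is
  true by construction. Setting `batch_cv_pct` or `scale_shift` injects
  real effects for power studies.
* **Built-in archetypes.** The three presets invert the source-mean
  radii of the reference study (densities, hardness, angle, moisture),
  take laser-PSD parameters from its published D10/D50/D90, and use
  sieve-effective lognormals calibrated so that expected fines and
  homogeneity radii land on the source means. For the fine, needle-habit
  preset the homogeneity target sits exactly on a majority-fraction tie
  (pan and 50–100 µm fractions equal), where the index is
  discontinuous; the calibration backs off to a ~3-point majority
  margin (expected homogeneity radius 2.11 instead of 2.37, well inside
  the ±0.5-radius fidelity band) so that replicate noise cannot flip
  the majority fraction between replicates.

What the generator does *not* emulate: correlated errors between
quantities (each raw quantity's noise is independent), drift within a
replicate series, instrument quantization, multimodal size
distributions, and the physics linking particle size to flow or
compressibility (an archetype's fields are free parameters, not a
mechanistic model). Passing tests on synthetic data therefore
demonstrate the pipeline's arithmetic and statistical behavior, not
that real powders behave lognormally.

A note on the overall validation verdict: `no_difference` requires
*every* testable row (twelve parameters plus PP and IGC) to exceed
$\alpha$. Under a true null with ~8 effectively independent raw
quantities, the probability that all rows pass at $\alpha = 0.05$ is
roughly $0.95^{8} \approx 0.66$–0.75, so single-study overall verdicts
under H0 are expected to flag spurious differences in a quarter of
runs. That is a property of the uncorrected multiple-testing scheme the
method prescribes, not of this implementation; the per-test type-I rate
is calibrated (5% ± 1.5% over 1000 simulated nulls in the test suite).

## Numerical and degenerate-input choices

* Quantile requests outside a PSD curve's support are errors, not
  extrapolations.
* A sieve analysis with zero recovered mass is an error; mass loss up
  to the tolerance is accepted and renormalized away.
* `describe()` requires $n \ge 2$ and flags CV as undefined when the
  mean is zero.
* ANOVA on groups with zero between-group variance returns $F = 0,
  p = 1$; all-identical data is `not_testable`; zero within-group
  variance with differing means reports $F = \infty$, $p = 0$.
* Radius tie at the acceptability boundary: `IP` counts radii $\ge 5$
  (closed), while the DC verdict uses $\mathrm{GCI} > 5$ (open), both
  as conventionally printed.
* Batch profiles are the per-parameter mean of replicate radii (not
  the radius of mean raw values); for the nonlinear Ie/IH conversions
  these differ, and the replicate-level convention is what the
  reference tables use.

## Reference data and its two known blemishes

The package embeds the complete replicate radius tables of a
three-supplier Linezolid study (three pilot and three industrial
batches per source, triplicate measurements), its pooled summary
statistics, source-comparison table and laser-diffraction quantiles, as
machine-readable fixtures (`reference_radii()` and friends). The
acceptance suite recomputes indices, descriptive statistics, ANOVA
cells, incidence means and pooled statistics from these replicate-level
inputs. Two internal inconsistencies of the published tables are
documented and excluded rather than matched: the UQUIFA industrial
summary rows disagree with that source's own printed replicates (e.g.
pooled PP 3.9621 printed vs 3.9706 recomputed), and two USV industrial
porosity radii print a clamped 10.00 that their own printed density
radii cannot produce. One published ANOVA cell (the Glenmarck fines
F-ratio, 4.74) is not reproducible from the printed radii; the suite
pins the value the printed radii actually give (1.78).

## Problem sizes

The test suite and acceptance script run on the embedded tables (9–18
replicates per comparison), simulated studies of 18 batches × 3
replicates, a 1000-replication null simulation for type-I calibration,
and 200-replicate noise-calibration draws; everything completes in
well under a minute on one core.
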