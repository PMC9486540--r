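---
title: "Cell-based stratification of anti-AChR Myasthenia Gravis patients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-based stratification of anti-AChR Myasthenia Gravis patients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgstratify)
```

## The scientific problem

Myasthenia Gravis (MG) is driven by autoantibodies against the nicotinic
acetylcholine receptor (AChR) at the neuromuscular junction. These
antibodies act through heterogeneous mechanisms — receptor crosslinking
and endocytosis, ligand blockade, and complement activation culminating
in membrane attack complex (MAC, C5b-9) deposition and receptor loss.
Only the complement-dependent mechanism is addressed by
terminal-pathway inhibitors (anti-C5, anti-C7), so a therapy trial that
does not stratify patients by the complement-activating ability of
their autoantibodies mixes responders with non-responders.

`mgstratify` implements a cell-based stratification pipeline around a
transfected-monolayer assay: cells co-expressing AChR subunits
(α1β1δε) and the clustering scaffold Rapsyn are exposed to patient
plasma plus immunoglobulin-depleted normal human serum (NHS, the
complement source), and multi-channel fluorescence fields (nuclear,
actin, AChR via labelled α-Bungarotoxin, and a marker channel for MAC
or bound immunoglobulin) are quantified per cell. The package covers:

1. **Per-cell quantification** — nuclei and cytoplasm segmentation,
   spot detection, summed spot fluorescence, percent-positive calls.
2. **Stratification** — per-plate fold-change normalization against the
   NHS-only control, ordinal classification of AChR loss, MAC
   deposition and IgG binding, anti-C7 blockade assessment, and the
   four-way patient categorization.
3. **Dose-response support** — percent hemolysis, four-parameter
   logistic (4PL) fitting with EC50/IC50, standard-curve
   back-interpolation with dilution factors and optional 1/y²
   weighting.
4. **A seeded synthetic generator** of imaging fields and cohort
   tables, so every stage is testable without microscope data.

## The classification model

All ordinal readouts use the symbols `-` < `+` < `++` < `+++`.

* **AChR loss** — fold change of the percent AChR-positive cells
  relative to the same plate's NHS-only well: 1–0.8 `-`, 0.8–0.6 `+`,
  0.6–0.3 `++`. The scale is capped at `++`; folds below 0.3 saturate
  there and folds above 1 (no loss) map to `-`.
* **MAC deposition** — fold change of the percent MAC-positive cells
  within the AChR-positive population: 1–1.3 `-`, 1.3–1.8 `+`,
  1.8–2.3 `++`, 2.3–3.5 `+++`, saturating at `+++` above 3.5 and `-`
  below 1.
* **IgG binding** — background-corrected percent Ig-positive cells:
  0–15% `-`, 15–40% `+`, 40–65% `++`, 65–100% `+++`. The correction
  subtracts the percent Ig-positive cells within the AChR-negative
  population and floors at zero (a negative percentage is an artefact
  of subtraction).

Shared band endpoints are resolved half-open, the boundary belonging to
the **milder** class on the fold-change scales (0.8 → `-`, 0.6 → `+`;
1.3 → `-`, 1.8 → `+`, 2.3 → `++`) and to the stronger class on the
percentage scale (15 → `+`, 40 → `++`, 65 → `+++`, reading "between 15%
and 40%" as lower-bound inclusive). No assignment in the bundled
reference cohort depends on an exact boundary value, so this is a pure
tie-break convention.

**Blockade.** Whether anti-C7 blocks the AChR loss is undefined (`NA`)
when the plasma arm shows no loss. It is `yes` when the anti-C7 arm
reverts to `-` while the isotype-control arm retains the plasma arm's
class, `yes_partial` when the anti-C7 arm improves by at least one
class step without reaching `-`, and `no` otherwise. The published
labels ("Yes", "Yes (Partially)") come without a numeric criterion;
the class-step rule is this package's formalization.

**Categories.** Category 1 = high (`++`) AChR loss; category 2 = low
(`+`) AChR loss; category 3 = no loss but `++` or stronger IgG binding
(binding without complement effect); category 4 = no loss, no or low
binding. Categories 1+2 form the complement-dependent fraction — the
patients expected to respond to terminal-pathway inhibition.

```{r categories}
ref <- mg_reference_cohort()
cat_assigned <- assign_category(ref$achr_class, ref$blockade,
                                ref$mac_class, ref$igg_class)
table(cat_assigned)
cohort_summary(tibble::tibble(category = cat_assigned))$pct_complement_dependent
```

The bundled 19-patient reference cohort reproduces its published
categories exactly. Note one documented discrepancy in the source
material: the per-category figure legends report 9/3/1/7 patients
(summing to 20), while the 19 published table rows contain 6 category-4
patients (9+3+1+6 = 19, consistent with the "12 of 19" statement). The
package computes counts from the table rows and flags, rather than
resolves, the legend discrepancy.

## The image-analysis algorithm

The paper-grade description of the commercial analysis ("find the
nuclei", "draw the cell perimeter", "spots identified within each
cell") names channels and concepts but no operators; the operators here
are the standard high-content-screening recipe, asserted against
synthetic ground truth rather than against the commercial software:

* **Nuclei** — Gaussian smoothing (σ = 2 px), Otsu threshold,
  distance-transform watershed to split touching nuclei, minimum-area
  filter (30 px²).
* **Cells** — seeded Voronoi-style propagation (`EBImage::propagate`)
  on the smoothed actin channel, constrained to a foreground mask
  (Otsu on actin, united with the dilated nuclei). Exactly one cell
  region per nucleus; border-touching cells are kept by default.
* **Spots** — scale-normalized Laplacian-of-Gaussian response at the
  configured spot scale (σ = 1.6 px); connected components above the
  detection threshold are spots. The threshold defaults to
  `max(6 × MAD(response), 8)`: the MAD term tracks the noise floor,
  the absolute floor of 8 intensity units rejects the shallow edge
  response of spatially *diffuse* (Rapsyn-free, unclustered) receptor
  signal, which must yield zero spots. Integrated spot fluorescence is
  the channel sum over the component minus the median of a surrounding
  annulus (inner/outer radii 4/7 px); spots are assigned to the cell
  containing their response-weighted centroid.
* **Positivity** — a cell is positive when its summed spot
  fluorescence exceeds a threshold: either a configured number or an
  automatic Otsu split on `log1p(spot_sum)`. In the pipeline the
  automatic split is computed once per plate on the NHS-only control
  well and applied plate-wide, mimicking plate-level thresholding
  against controls.

## The synthetic generator

`generate_field()` renders a monolayer of non-overlapping cells
(Poisson-disc placement, default 500 cells on a 1024×1024 px field,
emulating a confluent well at 10× magnification) with soft-edged
nuclear and actin disks, AChR spots (count ~ Poisson(6) per transfected
cell, lognormal amplitudes, Gaussian profile σ = 1.6 px), optional
Poisson shot noise and Gaussian read noise (sd 2) over a constant
background (20 counts). Defaults were chosen once as desk-scale
realistic values: 60% transfection, spot geometry sized so an Otsu
foreground and LoG detector at the stated scales operate in their
comfortable regime.

Disease biology is parameterized by two phenotype scalars:

* `complement_activation` (ca): under patient plasma + NHS, each
  AChR-expressing cell is **hit** by complement with probability
  `0.55·ca` and loses its receptor clusters entirely, so the expected
  fold change of percent-AChR-positive equals the survival factor
  `1 − 0.55·ca` regardless of threshold details (an all-or-nothing
  model of sublytic cluster loss). MAC deposition on AChR-expressing
  cells rises from a 10% baseline (natural complement turnover under
  NHS alone) by the factor `1 + 1.8·ca³`; the cubic makes weak
  activators lose receptor measurably while staying inside the `-`
  MAC band, as the published category-2 patients do.
* `igg_binding_strength`: probability that an AChR-expressing cell is
  bound by patient immunoglobulin in the (complement-free,
  heat-inactivated) binding assay; bound Ig is rendered colocalized
  with the receptor clusters. Non-specific binding (default 3% of all
  cells) is rendered as punctate lower-amplitude aggregates so the
  background-correction step has a real signal to subtract.

The four archetypes map onto the class bands: `cat1` (ca = 1, IgG
0.95) → AChR fold ≈ 0.45, MAC fold ≈ 2.8, corrected binding ≈ 54%;
`cat2` (ca = 0.5, IgG 0.55) → ≈ 0.73 / 1.2 / 30%; `cat3` (ca = 0, IgG
0.85) → no loss, binding ≈ 48%; `cat4` (ca = 0, IgG 0.10) → no loss,
binding ≈ 3%. The anti-C7 arm reverts both complement effects to the
NHS baseline (full blockade); the isotype arm matches the plasma arm.

Stochastic per-cell decisions consume one pre-drawn uniform each at a
fixed seed, so contrasts across arms or activation levels are
common-random-number comparisons: increasing `complement_activation`
never increases the mean true AChR spot sum nor decreases the MAC
signal, field by field.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: optical point-spread functions and
illumination fields, cell-shape variability and confluent overlap,
focus drift, autofluorescence, plate-edge effects, and the continuous
(rather than archetypal) spectrum of patient phenotypes. Recovery
rates on synthetic fields bound the algorithmic error, not the
assay error.

## Dose-response calculations

Percent hemolysis is the linear map
`100 × (A_test − A_0%)/(A_100% − A_0%)` of 405 nm absorbances; it is
deliberately not clipped, since values slightly outside [0, 100] carry
information about noisy wells (an optional flag marks them).

`fit_4pl()` fits `y = bottom + (top − bottom)/(1 + (x/x_half)^hill)`
by Levenberg–Marquardt (`minpack.lm::nls.lm`, up to 500 iterations,
`x_half` bounded positive), starting from `bottom = min(y)`,
`top = max(y)`, `x_half` at the geometric median dose and `hill = ±1`
by the sign of the log-dose regression slope. Optional `1/y²`
weighting serves immunoassay standard curves; `fix_top` pins the upper
plateau (e.g. at 100% for inhibition curves reaching complete block).
The inflection is stored once as `x_half` and reported as EC50 or IC50
according to assay direction. Back-interpolation inverts the fitted
curve inside the asymptote range and multiplies by the dilution
factor; responses beyond the asymptotes are flagged below/above
detection rather than extrapolated.

On noiseless 12-point 1:3 dilution series the inflection is recovered
to better than 10⁻⁶ relative error. Under 5% (of range) Gaussian
response noise the *mean* recovered inflection over 100 replicates is
within a few percent of truth; a single 12-point fit at that noise
level carries ~10–25% sampling error in the inflection, which is a
property of the information in the design, not of the optimizer.

`spearman_correlation()` reports the two-tailed Spearman rho and
p-value (via `stats::cor.test`) with a 95% confidence interval from
the Fisher z-transform using the Fieller–Hartley–Pearson standard
error `sqrt(1.06/(n − 3))` — the standard choice for rank
correlations; the tests cross-check rho against a brute-force
rank-then-Pearson computation.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → segment → quantify → stratify. Each
patient plate carries the five complement-assay arms (NHS only, plasma
+ NHS, + anti-C7, + isotype, control plasma + NHS; marker channel MAC)
plus one binding-assay well (marker channel IgG). Per-plate positivity
thresholds come from the NHS-only well; fold changes are computed
within plate and averaged across plates (experiments) per patient
before classification, mirroring a mean-of-three-experiments design.
Outputs carry the configuration hash and seed; reruns are
byte-identical.

Problem sizes used in the validation suite were chosen to exercise
each claim at desk scale: unit tests run 40-cell 300 px noiseless or
default-noise fields (seconds), the segmentation-count test 200 cells
at 720 px, and the end-to-end check a 20-patient cohort (9/3/1/7
archetypes) at the full 1024 px, 500-cell default with one plate per
patient — 120 fields in total. Category recovery on that run is ≥ 90%;
the tabular fast path (`simulate_cohort_wells()`, which emits
well-level percentages directly) recovers 20/20 noiselessly and
≥ 18/20 at the default 2-percentage-point measurement noise with three
experiments per patient.

## Known limitations and open choices

* The uncorrected minuend of the binding correction is the percent
  Ig-positive among **all** cells by default (`ig_minuend = "all"` in
  `stratify_cohort()`); measuring within the AChR-positive population
  instead is exposed as a switch, since the assay description is
  ambiguous on this point.
* Equivalence with the commercial segmentation software cannot be
  asserted (its algorithm is unpublished); correctness is defined
  against synthetic ground truth.
* With one plate per patient and 500 cells per field, the MAC fold
  change of strong activators has ~20% relative sampling error; MAC
  class boundaries for individual patients are therefore soft at that
  design size. The patient category does not depend on the MAC class,
  so categorization is robust to this.
* Whether published fits constrained the bottom asymptote is unknown;
  both free and fixed-asymptote modes are supported.
* Cells per well and fields per well are not fixed by the assay
  description; both are configuration parameters here.
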