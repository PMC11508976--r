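---
title: "Mapping rib fracture lines: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping rib fracture lines: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribmap)
```

## The measurement model

Rib fractures in high-energy chest trauma are numerous — typically around
seven fracture lines per patient — and their positions along the ribs
carry clinical information: posterior clustering suggests scapular
involvement, anterior clustering sternal involvement, and upper-rib
involvement accompanies clavicle fractures. To pool fracture positions
across patients with different rib sizes and shapes, each fracture site is
reduced to a single dimensionless coordinate: the fraction of the rib's
along-bone length at which the fracture line sits,

$$ p = 100 \cdot \frac{d_1}{d_1 + d_2}, $$

where $d_1$ is the distance from the costovertebral joint (where the rib
meets the spine) to the fracture site and $d_2$ the distance from the
fracture site to the costochondral junction (where the bony rib meets its
cartilage). By construction $p = 0\%$ at the spine and $p = 100\%$ at the
anterior end, and $p$ is invariant to overall rib size: only the ratio of
the two measured distances matters, which is what makes a population-level
map on a single template legitimate. `percent_position()` implements this
normalization; `validate_cohort()` applies it to raw `d1`/`d2` columns and
cross-checks rows that carry both a precomputed percentage and raw
distances (they must agree within 0.01 percentage points).

For the floating ribs (11–12), which have no costochondral junction, the
anatomical rib tip serves as the 100% landmark.

### From 1D positions to a 3D heat map

The positional datum is one-dimensional, so the 3D rendering is a
*transfer*, not a source of information: each rib centerline in the
template is arc-length parameterized (`rib_curve`), a vertex at arc-length
fraction $t$ carries the aggregated frequency at position $100t$, and
colors follow a fixed monotone blue→green→yellow→red ramp. We approximate
the along-the-surface distance of a volumetric rib by the arc length of a
centerline polyline; because the stored coordinate is a fraction, the
approximation affects only the template rendering, never the statistics.

The built-in template (`default_template()`) is deliberately synthetic: 24
planar elliptical arcs whose semi-axes, sweep, tilt and vertical station
vary smoothly with rib index, sized like an adult rib cage (arc lengths of
roughly 70–290 mm). A parametric template keeps the geometry dependency-free
and exactly reproducible; patient-derived centerlines can replace it via
`read_template_csv()` (one ordered vertex row per curve point). Each curve
is planar up to a rigid tilt, which guarantees that scaling the radii
scales every arc length by exactly the same factor — a property the tests
exploit.

## Sectors, bins, densities

* **Sectors.** Chest-wall classification systems divide the rib into
  posterior, lateral and anterior sectors but leave the precise boundaries
  unstandardized. `classify_sector()` therefore takes the boundaries as a
  parameter, defaulting to equal thirds (33.33 / 66.67); intervals are
  half-open with the posterior sector `[0, b1)` and the anterior sector
  `[b2, 100]`.
* **Bins.** `bin_index()` uses left-closed 10%-wide bins numbered from 0,
  with the last bin closed at 100, so "bin 2" is the 20–30% segment. The
  bin width must divide 100.
* **Densities.** `density_profile()` smooths positions with a Gaussian
  kernel (default bandwidth 5 percentage points — narrow enough to keep
  the two anatomical modes separate, wide enough not to chase individual
  records). Kernel mass falling outside [0, 100] is reflected back across
  the boundary, so the trapezoidal integral of the profile equals the
  record count (within 1% for bandwidths up to ~15). The profile is a
  *frequency* density: rescaling to a probability density is a display
  choice left to the caller.

Multiple fracture lines on one rib are independent records; no
deduplication is performed, since multi-fragment fractures of a single rib
are common in high-energy trauma.

## Statistics

The statistical unit for positional comparisons is the **fracture
record**, not the patient: with on the order of $10^3$ records from
$10^2$ patients, rank-sum statistics on records are what published
per-line analyses report (their U statistics are of order $10^4$–$10^5$,
which only record-level sample sizes produce). `position_comparison()`
exposes `unit = "patient"` for the conservative per-patient-mean variant.
Record-level testing treats lines within a patient as exchangeable — a
simplification the null-calibration study below validates for this
generator, which draws positions independently within patients.

`mann_whitney()` computes $U$ from midrank sums. For pooled samples of at
most 12 observations the permutation null is enumerated exhaustively
(correct under arbitrary ties); above that, a normal approximation with
tie-corrected variance is used, without continuity correction.
`contingency_2x2()` delegates to the standard chi-square and Fisher exact
machinery, choosing Fisher automatically when any expected cell count
falls below 5; the chi-square is uncorrected by default, with the Yates
variant available explicitly, and the method actually used is recorded in
the result. `upper_rib_association()` reduces each patient to the
indicator "any fracture on ribs 1–3" before tabulating, so its unit is
the patient.

Report rounding (means, SDs, shares at 2 decimals) applies only to
display and serialized reports; all internal computation is full
precision.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, providing ground truth for parameter recovery. Defaults
(all overridable in `sim_params()`):

| parameter | default | rationale |
|---|---|---|
| fracture lines / patient | round of N(7, 3.87²), min 1 | matches the reported mean ± SD for high-energy cohorts; a truncated-rounded normal reproduces both moments approximately, which a one-parameter count law cannot |
| rib weights | per-rib counts 39, 78, 111, 121, 130, 108, 112, 87, 68, 37, 26, 6 (of 923) | the published per-rib distribution; ribs 3–7 each > 10% |
| side split | P(left) = 0.52 | reported 52/48 split |
| position law | 0.55·N(25, 15²) + 0.45·N(65, 15²), clipped to [0, 100] | bimodal with modes in the 20–30% and 60–70% segments; SD 15 keeps both peaks visible after clipping |
| flag prevalences | 25.5 / 19.6 / 10.8 / 3.9% (clavicle / scapula / vertebra / sternum) | reported prevalences; flags drawn independently (only marginals are published) |
| effect shifts | scapula −7.5, sternum +12 points, others 0 | location shifts reproducing the reported posterior/anterior group means; group SDs are reported nearly equal across groups, consistent with a pure location effect |
| clavicle upper-rib boost | ×2.606 on ribs 1–3 mass | solved (from the count distribution and rib weights, at design time) so that a clavicle-flagged patient has a 92% probability of ≥ 1 upper-rib fracture; the unflagged baseline works out to ≈ 78% |

Shifts are applied additively to every position of a flagged patient and
then clipped to [0, 100]; the clipped fraction is recorded in the ground
truth (≈ 4% under defaults). Clipping slightly attenuates recovered
shifts — by a few tenths of a point for the scapular shift, up to a couple
of points for the sternal shift, whose flagged group is also small — which
is why recovery is checked within ±3 and ±4 points respectively.

What the generator does **not** emulate: correlation between flags and
fracture counts, within-patient clustering of positions, bilateral
symmetry constraints, fracture displacement, and any joint distribution of
the four flags beyond independence. Passing recovery tests therefore
demonstrates that the estimators are unbiased and calibrated *under this
generative model*, not that real trauma data satisfy the model.

## Validation studies shipped in the tests

* **Oracle equivalence.** `mann_whitney()` is compared with an
  independent exhaustive-enumeration oracle (pairwise-count $U$) for every
  sample split of pooled size ≤ 8, tie-free and tied; the chi-square
  against the closed-form 2×2 formula; Fisher against direct
  hypergeometric enumeration.
* **Parameter recovery.** On 2,000-patient cohorts at defaults, the
  scapular shift is recovered within ±3 points of −7.5 and the sternal
  shift within ±4 of +12, both with p < 0.05, and the clavicle ×
  upper-rib association is detected.
* **Null calibration.** With all shifts zero, each flag's record-level
  test rejects at α = 0.05 in 3–7% of 500 replicate cohorts of 300
  patients (300 keeps even the rarest flag's group non-empty with
  overwhelming probability while staying fast).
* **Conservation and geometry.** Frequency-matrix totals equal record
  counts; density integrals equal record counts within 1%; percentage ↔
  3D point round trips hold to 1e-6; arc length is invariant under rigid
  motion to 1e-9 relative.

## Numerical and design notes

* Positions are stored at full double precision; a cohort written with
  `write_cohort_csv()` round-trips losslessly (`%.17g` serialization).
* `point_at_percent()` interpolates linearly inside the containing
  segment; `percent_at_point()` projects onto the nearest segment and
  enforces a distance tolerance (default 5 mm) so that points belonging
  to another rib fail loudly instead of being silently attributed.
* Sides are kept separate throughout; `side_scope = "mirrored"` pools
  left records onto the right hemithorax for single-side rendering. Since
  the position coordinate is measured from the spine on either side,
  mirroring changes which curves are painted, never the counts.
* Degenerate inputs: an empty cohort yields a zero frequency matrix and a
  count table with `NA` shares; a rib with no records yields an all-zero
  density profile (not an error); an upper-rib table with no variation in
  involvement reports the rates with no test (`method = "none"`).
* The heat-map color range is fixed globally across ribs within a figure,
  so between-rib frequency differences remain visible; per-rib
  normalization would erase exactly the signal the map exists to show.

## Limitations

The package analyzes fracture *lines* as 1D positions; it does not model
fracture morphology, displacement, flail segments as spatial objects, or
the volumetric geometry of real ribs. The parametric template is a
rendering surface, not an anatomical atlas. Cohort statistics assume
records are exchangeable across patients at the record level; strongly
clustered data would need patient-level units (provided) or hierarchical
models (out of scope).
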