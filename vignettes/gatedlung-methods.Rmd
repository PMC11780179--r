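---
title: "Methods: respiratory-gated micro-CT lung quantification on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiratory-gated micro-CT lung quantification on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`gatedlung` quantifies lung function and radiation-induced lung injury from
paired-phase (peak-inspiration / end-expiration) micro-CT volumes of the
mouse thorax. Because no real image set is distributed with the package, the
whole pipeline is validated against digital thorax phantoms with exact,
analytically known ground truth; the phantom generator is first-class,
tested code, not a fixture.

The physical model underlying every metric is the two-component air/tissue
mixture: lung parenchyma is treated as a mix of air (−1000 HU) and
water-equivalent soft tissue (0 HU), so a voxel with local air fraction $f$
has noiseless CT number $-1000f$ HU. For a segmented lung of volume $V$ and
mean CT number $\overline{CT}$,

$$\mathrm{FRC} = V_{exp}\frac{\overline{CT}_{exp}}{CT_{air}},\qquad
\mathrm{VT} = V_{insp}\frac{\overline{CT}_{insp}}{CT_{air}} - \mathrm{FRC},$$

with $CT_{air}$ fixed at −1000 HU (a config override exists but is not the
default: re-measuring air per scan trades a convention for extra variance).
On the phantom this mixture relation is exact by construction, which is what
lets the test suite demand FRC/VT recovery to numerical rounding
(< 10⁻⁹ relative) when segmentation and calibration are perfect, rather
than loosely "close".

Out of scope by design: CT acquisition and reconstruction (phantoms are
generated directly in voxel space), dosimetry, histology, survival analysis,
lobe separation, airway-tree extraction and visual pathology grading.

# The phantom: a stated world

The default phantom emulates a mouse thorax in a 9.6 mm field of view at
0.075 mm isotropic voxels (128³). The grid size may be reduced (e.g. 48³ for
cohort simulation); the physical geometry stays fixed in millimetres so only
the sampling coarsens. The scene contains:

| structure | geometry | intensity |
|---|---|---|
| body | cylinder, radius 4.0 mm | +40 HU |
| lung lobes | two overlapping ellipsoids, semi-axes 1.9 × 2.1 × 2.6 mm | $-1000f$ |
| trachea | tube, radius 0.35 mm, from the carina (z = 5.4 mm) upward | −1000 HU |
| spine | bone rod, radius 0.5 mm | +1500 HU |
| water insert | cylinder outside the body, radius 0.4 mm | 0 HU |
| background | air | −1000 HU |

Defaults that the package treats as its stated world (and does not revisit
per test): end-expiration air fraction 0.45 and peak-inspiration 0.62 —
mid-range aerations giving lung CT numbers near −450/−620 HU, comfortably
below the −160 HU segmentation threshold and above the −1000 HU air anchor;
additive Gaussian noise in HU (25 HU in the "noisy" test condition — low
image noise, as a well-tuned protocol would produce); raw grey values
emitted through linear air/water anchors (10 and 1510 by default, i.e.
1.5 raw units per HU) so that calibration has real work to do. Bone at
+1500 HU and body at +40 HU sit far above the threshold, making
segmentation behaviour unambiguous.

Lesions are spheres that must intersect the lung: both pneumonitis and
fibrosis multiply the enclosed parenchymal air fraction by $1-\text{severity}$
identically at both phases (no invented kinetics); fibrosis may additionally
dilate the airway tube inside the lesion, emulating the enlarged airways of
severe scarring. Ground truth — the true lung region, per-phase air volumes,
FRC and VT — is computed by exact summation over the generated air-fraction
fields before noise. The true lung region is the parenchyma plus airway
voxels below the 2-mm-above-carina plane, i.e. exactly what a correct
threshold segmentation inside the standard bounding region selects.

What the phantom does *not* emulate: reconstruction artefacts (beam
hardening, rings, projection noise correlations), cardiac motion, an
anatomically branching airway tree, or partial-volume mixing at organ
boundaries beyond the voxelized geometry itself. A green recovery test
therefore establishes that the measurement chain is correct and noise-robust
on mixture-model lungs — not that it is robust to every scanner artefact.

Cohorts draw per-animal air fractions around group means (between-animal SD
0.03, ~7 % CV, a typical inter-animal spread of aeration); treatment
effects are imposed per week either as an air-fraction scaling (diffuse
fibrosis-like loss of aeration) or as a focal lesion. All randomness flows
from one master seed through derived sub-seeds.

# Calibration and filtering

HU calibration is per image pair: the mean raw value in a box inside the
trachea maps to −1000 HU and a box inside the water insert to 0 HU,
$HU(v) = 1000\,(v - w)/(w - a)$. The reference boxes are supplied by the
phantom metadata (in a real study they would come from operator-placed
ROIs); their half-widths are chosen so every box corner stays inside the
reference cylinder even after the box centre snaps to a voxel centre.
Degenerate references (air = water) are an error, and the mapping is affine
and order-preserving, which the suite asserts on random fixtures.

The optional bilateral pre-filter runs before calibration (matching a
reconstruction-side filter placement; the order is recorded in the config).
Weights are the product of a spatial Gaussian (σ = 0.075 mm default, one
native voxel, truncated at 3σ) and a range Gaussian (σ = 100 intensity
units default — about 66 HU on the default raw scale, small enough to
preserve the ~500 HU air/tissue edges while averaging across 25 HU noise).
The range weight is evaluated through a 16 384-entry lookup table (absolute
weight error < 6 × 10⁻⁴); tests against a brute-force implementation with
exact exponentials use tolerances above that floor. In the
σ-range → ∞ limit the filter reduces to plain Gaussian smoothing and then
commutes with the affine calibration; the general bilateral case does not
commute and is not asserted.

# Segmentation conventions

The bounding ROI's superior face sits `round(2 mm / spacing)` voxel planes
above the carina (27 planes at 0.075 mm); lateral and inferior faces default
to the body extent. This deliberately admits the proximal airways below that
plane — no airway stripping is performed, a documented limitation shared
with threshold-based lung segmentation generally.

Region growing selects the maximal connected set of voxels with
HU ≤ −160 containing the seed, restricted to the ROI. Fixed conventions
(each needed for exact oracle tests): the threshold comparison is
*inclusive*; connectivity defaults to 26-neighbour (6 selectable); voxel
indices are 1-based and ROI boxes are inclusive `[lo, hi]` ranges — the
idiomatic R convention, adopted in place of 0-based half-open boxes. The
implementation is a C++ stack-based flood fill; the suite proves exact mask
equality against an independent igraph connected-components oracle on 100
random grids (≤ 64³; most sampled at 8–40 voxels per axis to keep the
oracle within budget, ten at the full 64³).

Batch-mode seeding takes the voxel *nearest the centroid* of clearly
aerated voxels (HU < −400) in the ROI — the nearest-valid fallback matters
because the centroid of a two-lobed lung can fall between structures.

Leak handling stands in for the operator's judgement, since "failure" has no
formal definition in interactive practice: a mask is flagged when it touches
more than 2 ROI faces or fills more than 90 % of the ROI (a mask reaching
only the superior face through the airway is expected). On a leak, every
touched face except the anatomically anchored superior face moves inward by
0.5 mm and the region is re-grown, up to 5 retries; a still-leaking mask is
returned flagged for review rather than erroring, and flags travel with
every downstream row so group summaries never silently average over them.

# Metrics and longitudinal analysis

Volumes are voxel count × voxel volume (mm³ → mL conversion 1000). CT
histograms use half-open 25 HU bins over [−1000, 200] with out-of-range
values clipped into the end bins, so counts always conserve the masked voxel
count. Negative VT is permitted but flagged (its usual cause is swapped
phase labels). "Endpoint" resolves per animal to its latest week, because
study arms may end at different weeks. Percent change is computed both ways
— on group means and per animal — since summary narratives are ambiguous
between the two; both are labelled in the output.

# Gating simulation

The respiratory trace is an asymmetric cycle: a raised-cosine excursion
(fast inhale/exhale) followed by an end-expiratory plateau at baseline.
Trigger detection is causal, as a real-time monitor must be: the running
amplitude is the mean of the last three observed cycle peaks (a peak is
recorded when the trace falls below 30 % of its running excursion maximum,
and the tracker re-arms only after returning near baseline — without that
hysteresis the falling tail registers spurious "peaks" and corrupts the
estimate), and the trigger fires at the first rising sample crossing
0.9 × amplitude, subject to a 300 ms refractory period. The second trigger
is the first delayed by 350 ms.

Defaults: period 600 ms (~100 breaths/min under isoflurane) and plateau
fraction **0.7**. The plateau fraction was genuinely open; 0.5 was
considered first, but with a 0.9 trigger level it places the first trigger
just outside a ±5 % peak window (0.051 of the cycle before the peak) and
sends the 350 ms delayed trigger past the plateau into the next cycle's
rise at 400 ms periods. A 0.7 plateau — defensible physiologically, since
anesthetized mice spend most of the cycle in end-expiratory pause — puts the
first trigger 0.031 cycles before the peak and keeps the delayed trigger
inside the plateau across the whole 400–1000 ms range, which is exactly the
regime the design intends. Phase scoring uses the generator's own cycle
table: peak-inspiration within ±5 % of the cycle around the peak,
end-expiration inside the plateau, transition otherwise.

# Statistics

Lung metrics are compared with classical one-way ANOVA plus Tukey HSD;
body-weight-style heteroscedastic data with Welch and Brown–Forsythe ANOVA
plus Dunnett's T3, all at α = 0.05. Numeric evaluation: F tail
probabilities via `stats::pf` and the studentized range via
`stats::ptukey` — the established incomplete-beta and quadrature
implementations of exactly those distributions; unequal group sizes use the
Tukey–Kramer standard error. The studentized maximum modulus needed by
Dunnett's T3 has no base-R implementation and is evaluated by fixed-seed
Monte Carlo (10⁶ draws by default; the seed is a documented argument).
Validation runs through independent routes: a label-permutation oracle for
the omnibus p, a raw Monte-Carlo studentized-range oracle for Tukey, the
two-group identities F = t² and q = √2·|t|, and null-simulation rejection
rates. Published per-comparison p values from real animal data are not
reproducible from a synthetic world and are not test targets; missing
animals are handled by per-week complete-case analysis (survivor-only
averaging).

# Simulation sizes and budgets

Two deliberate scale-downs keep the suite within desk-scale budgets, stated
here so that green tests are read correctly: (1) replicate cohort
simulations for effect recovery run the full image pipeline on 48³ phantoms
(same 9.6 mm field of view, 0.2 mm voxels) — 200 replicate two-arm cohorts
with an imposed 50 % FRC reduction; (2) the 2000-replicate null
rejection-rate check draws per-animal FRC values from the same cohort
model at measurement level, because 24 000 image pipelines would dwarf any
budget. Single-phantom recovery and lesion monotonicity run at the native
128³ and at 64³ respectively.

# Known limitations

- The mixture model makes FRC/VT exact on phantoms; on real scans,
  calibration bias, partial-volume effects at the pleura and vessels inside
  the mask bias both metrics.
- No airway stripping: FRC includes proximal-airway air below the ROI
  plane, consistently at both phases.
- Severe focal lesions (severity > ~0.64 at default aeration) rise above
  the −160 HU threshold and drop out of the segmented lung, so measured
  mean CT is non-monotone in severity beyond that point even though air
  content keeps falling; monotonicity tests sweep severities below it.
- The gating trace has no cardiac component and its noise is white; real
  pillow signals drift.
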