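---
title: "Methods: assessing tract segmentations against nTMS motor maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing tract segmentations against nTMS motor maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Deep-learning tract segmentation models output, for each voxel of a
diffusion MRI volume, the probability that it belongs to a white-matter
tract such as the corticospinal tract (CST). In patients with brain
tumours there is no usable ground truth for the tract's location: manual
annotation is unreliable under mass effect, and the intra-operative gold
standard (direct cortical/subcortical stimulation) is invasive. Navigated
transcranial magnetic stimulation (nTMS) motor mapping provides a
non-invasive "silver standard": cortical sites whose stimulation evokes a
motor response are causally connected to the motor system, so a good CST
segmentation should encompass positive responses near the primary motor
cortex (M1) and exclude negative responses far from it.

`cstconcord` implements that assessment as a reusable pipeline:

1. **Response masks** — classify exported stimulation responses into
   `+M1+` (positive response, inside M1), `-M1+` (positive, outside M1)
   and `-M1-` (negative, outside M1); rasterize them on the 1 mm export
   grid; remove landmark annotations with the intracranial mask; keep
   white-matter voxels.
2. **Ensemble aggregation** — collapse the T stochastic segmentation
   passes (test-time dropout / augmentation) into a mean probability map,
   a binary tract mask, and a voxelwise uncertainty map.
3. **Concordance** — overlap coefficient and Dice per subject, class and
   method; cohort aggregation; paired Wilcoxon comparison of methods.
4. **Uncertainty versus distance** — Euclidean distance of each response
   voxel to the tract mask, a 30-bin joint histogram, Spearman rank
   correlation and an OLS trend line.
5. **Synthetic phantoms** — a generator producing cohorts with the same
   statistical structure, so the full pipeline is testable without
   clinical data.

# Models and statistics

## Response classification

A response is *positive* when its amplitude is at least 50 µV. Responses
with latency outside the physiological hand-muscle window, 18–26 ms
(inclusive at both ends), are excluded, as are negative responses inside
M1 — their interpretation is biased, typically by muscles that were not
mapped. Classification is total: every record maps to exactly one of the
three classes or to `excluded`. Manual curation of false
positives/negatives is represented as a per-record flag in the input CSV,
not as an algorithm — it is human judgement.

## Overlap coefficient

For binary masks \(A\) (tract) and \(B\) (responses),

\[ \mathrm{OC}(A,B) = \frac{|A \cap B|}{\min(|A|,|B|)}, \qquad
   \mathrm{Dice}(A,B) = \frac{2|A \cap B|}{|A|+|B|}. \]

OC (Szymkiewicz–Simpson) is 1 exactly when the smaller set is enclosed by
the larger and 0 exactly when they are disjoint. A widely circulated
verbal definition says "union over the smaller set"; that ratio is always
\(\ge 1\) and contradicts both boundary behaviours, so this package
implements intersection-over-minimum and says so in every report header.
An empty mask makes OC undefined; the package returns `NA` rather than a
silent 0, because "no responses of this class" and "no overlap" are
clinically different statements. The response mask is expected to be the
smaller set; a violation warns but does not error.

## Ensemble uncertainty

The T passes are aggregated voxelwise. The binary mask is the mean
probability thresholded at \(\tau = 0.5\), with a **strict** comparison
(`> τ`): the tie case is not fixed by "threshold at 0.5", only matters on
a measure-zero set for continuous probabilities, and a documented strict
rule is testable. Uncertainty defaults to the **population** standard
deviation across passes (divide by T — the passes are the full ensemble,
not a sample of a larger one); binary entropy of the mean,
\(-p\log_2 p-(1-p)\log_2(1-p)\), is available as an alternative since
upstream tools differ in what they export. The downstream correlation
analysis is rank-based and therefore estimator-agnostic; the choice is
stamped into report metadata.

## Distance and correlation

Distances are Euclidean, in millimetres, computed in world space from the
voxel-to-world affine with an exact separable distance transform that
honours anisotropic spacing. "Distance to the tract mask" means distance
to the nearest foreground voxel centre, 0 inside the mask: for response
voxels outside the mask this coincides with distance to the boundary,
which is what the published summary figures show. Uncertainty is sampled
at the response voxel itself, matching the interpretation that low
uncertainty far from the boundary indicates a reliable exclusion.

The joint histogram uses equal-width bins on \([0, \max d]\) (the bin
range is not standardised upstream; this choice is recorded), right-open
except the last bin. Per-bin error bars are population standard
deviations, so singleton bins are 0 and empty bins are reported `NA`,
never fabricated. Spearman's ρ is computed on the pooled per-voxel pairs
across subjects (the histogram is a display summary); the bin-mean
variant is also emitted because "correlation of the joint histogram" is
ambiguous. p-values use the exact permutation null for n ≤ 8 and the
t approximation otherwise.

## Wilcoxon signed-rank

The paired method comparison drops zero differences (classic Wilcoxon,
not Pratt), uses average ranks for ties, the exact signed-rank null when
n ≤ 25 without ties, and otherwise the tie-corrected normal approximation
*without* continuity correction. The zero-handling and approximation
choices are recorded in report metadata because published analyses rarely
state them; with the bundled reference table, this configuration
reproduces the published p = 0.04 for the `+M1+` comparison (the
continuity-corrected value, 0.046, would round to 0.05). Fewer than 5
nonzero differences is an error: the test would be underpowered and a
number would mislead.

Cohort dispersion of OC uses the **sample** (n−1) standard deviation:
that is the convention that reproduces the published cohort summary
0.83(0.14) from the per-subject values (the population sd gives 0.13).

# The synthetic world

`phantom_spec()` fixes the stated world; its defaults are not tuned to
test outcomes.

| parameter | default | meaning |
|---|---|---|
| `grid_shape`, `spacing` | 96³, 1 mm | export-resolution grid |
| `tube_radius`, `fan_radius`, `fan_frac` | 4, 8 mm, 0.2 | tract tube, cortical fanning over the top 20 % |
| `boundary_tau` | 1.5 mm | sigmoid softness of the probability profile |
| `ensemble_T` | 20 | stochastic passes (protocol value) |
| `deform_sigma`, `deform_smoothness` | 1 mm, 6 mm | smooth displacement field per pass |
| `noise_sigma` | 0.05 | voxelwise probability noise, clipped |
| `n_responses` | 15 / class | stimulation responses |
| class distances | \(|N(0,2)|\), \(N(6,2)_{\ge 0}\), \(N(14,4)_{\ge 0}\) mm | `+M1+`, `-M1+`, `-M1-` targets |

The tract is the sub-zero level set of
\(\min_s (\lVert x - c(s)\rVert - r(s))\) over a smooth random centreline
\(c(s)\) running bottom-to-top, with radius \(r\) widening linearly into
the fan. Ensemble members are
\(\sigma(-(d_{\mathrm{signed}} + \delta_t)/\tau)\) where
\(d_{\mathrm{signed}}\) is the EDT-based signed distance to the tract
surface and \(\delta_t\) an independent Gaussian-correlated field; this
construction deforms the *distance field*, not the binary mask, so
members remain valid probability maps. The signed distance is defined
from the foreground/background EDT pair and has magnitude ≥ 1 voxel
everywhere, which makes the noiseless strict-threshold reconstruction of
the generating mask exact (Dice = 1) — the basis of the noiseless-limit
acceptance check.

Synthetic M1 is the top slab of the grid (where the tract fans into
"cortex"); `+M1+` voxels are drawn inside it, the negative classes
outside. Each response voxel is chosen so its distance-to-tract matches a
draw from the class target within ±0.5 mm (nearest achievable voxel
otherwise), without replacement across classes, so the three masks are
disjoint by construction. Generated amplitude/latency records round-trip
through `classify_response()` with the synthetic M1 mask — the generator
and the classifier are kept mutually consistent and that consistency is
tested.

Per-subject seeds are derived deterministically from the master seed;
every generator is a pure function of (spec, seed), restoring the
caller's RNG state.

**What a green phantom test does not establish.** The phantom has no
tumour mass effect, no registration error, no scanner noise model, no
realistic CST geometry, and its class-distance distributions are invented
(the clinical protocol fixes only their ordering). Phantom checks
validate the *pipeline machinery* — orderings, signs, exact limits,
oracle equality — not clinical performance levels. In particular the
phantom's mean `+M1+` OC (≈ 0.2 under the default distance targets) is
far below the clinical ≈ 0.83: under the stated world, a response whose
target distance exceeds half a voxel lies outside the tract by
construction. The clinical level depends on export footprints and
registration behaviour the phantom deliberately does not model.

**Ties at zero.** Under the stated `-M1+`/`-M1-` distance targets, a
response touches the tract with probability well below 1 % per draw, so
both negative-class cohort means are frequently exactly 0 — as in most
rows of real cohort tables. The cohort-ordering check therefore uses the
same tie-tolerant monotone rule as the per-subject check (strict only
where values differ beyond 1e-9), rather than a strict chain that would
fail on a tie at zero.

# Numerical choices and degenerate inputs

- Voxel indices are 0-based through the affine; world coordinates are
  voxel centres; no silent reorientation, ever — callers resample
  explicitly (`resample_to_grid`), and grid mismatches error with both
  shapes and affines printed.
- Nearest-neighbour resampling is mandatory for binary masks (linear
  would manufacture intermediate values); out-of-field voxels fill with
  0, matching mask semantics.
- 4D NIfTI with a trailing singleton is squeezed with a message; any
  other 4D shape is an error pointing at `read_ensemble()`.
- Floating-point volumes are written as float64, so round-trips are exact
  to machine precision; integer masks round-trip bit-identically.
- `rasterize_responses` footprint radius defaults to 0 (point-to-voxel);
  the vendor footprint is unspecified, so it is configurable. Note that
  at radius 1.5 mm on a 1 mm grid the footprint includes the 12 edge
  neighbours at √2 ≈ 1.414 mm (19 voxels, not a 7-voxel cross).
- All distances identical in `joint_histogram` collapses to one
  degenerate bin with a warning.
- Per-subject pipeline failures are isolated: the subject gets NA rows
  and the cohort run completes (exit status reflects the failure).

# Known limitations

- The NIfTI-1 reader/writer is minimal by design: single-file `.nii`
  (.gz), sform preferred, qform decoded as fallback; extensions are
  ignored; two-file `.hdr/.img` unsupported.
- Registration itself is out of scope; the package only applies given
  affines and resamples.
- Unsigned distances: response voxels inside the tract are all at
  distance 0, so depth inside the tract is not resolved (matches the
  analysis being emulated).
- The phantom's centreline is a smooth sinusoid mixture — adequate for
  connectivity/ordering properties, not anatomy.

# Reproducing the acceptance evidence

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes every reported quantity from scratch: the cohort summary and
overlap aggregation from the bundled reference tables, the Wilcoxon p,
and the seeded 16-subject phantom recovery (OC ordering, pooled Spearman
ρ and p, noiseless-limit exactness). The same criteria run as
`tests/testthat/test-acceptance.R`.
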