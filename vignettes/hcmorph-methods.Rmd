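---
title: "Quantifying nuclear position and envelope recruitment in cochlear hair cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear position and envelope recruitment in cochlear hair cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmorph)
```

## The measurement problem

Outer hair cells (OHCs) of the cochlea are elongated, gently curved cells
whose nucleus normally sits near the basal pole — at roughly 0.7–0.8 of the
way down the cell when position is expressed as a fraction of cell length.
When nuclear anchoring through the LINC complex fails (for example when the
KASH protein Nesprin-4 is lost), the nucleus drifts apically, and the cells
later degenerate. Quantifying that phenotype requires three distinct
measurements, each implemented as a module of this package:

1. **Relative nuclear position** along the cell's curved main axis
   (`fit_cell_axis()`, `relative_nuclear_position()`, `batch_positions()`).
2. **Nuclear-envelope recruitment** of a tagged protein, as the ratio of
   perinuclear-band to cytoplasmic reporter intensity
   (`segment_nucleus()`, `segment_cell()`, `perinuclear_band()`,
   `recruitment_index()`).
3. **Submembrane cisternae gap lengths** along the lateral membrane from
   annotated segment intervals (`gap_lengths()`, `compare_gap_groups()`).

A fourth module supplies the group-comparison statistics used for such
cohorts, and a synthetic-data module generates ground-truthed inputs so that
every claim the package makes about its own accuracy is checked against a
known truth.

## The axis model

Each cell is annotated with three landmarks: the apical surface point, the
nucleus centroid and the basal end, in physical micrometres. The cell axis
is the unique quadratic parametric curve $C(t) = a_0 + a_1 t + a_2 t^2$,
$t \in [0,1]$, that starts at the apical point, ends at the basal point and
passes through the nucleus centroid at the chord-length parameter
$t_N = d_1/(d_1 + d_2)$, where $d_1$ and $d_2$ are the apical–nucleus and
nucleus–basal chord distances. With three points, any higher-order family
would be under-determined; the chord-length parameterization makes the
interpolant reduce *exactly* to the straight segment when the landmarks are
collinear, so straight cells incur no model error at all.

Arc lengths are computed by adaptive quadrature of $\lVert C'(t)\rVert$ at
relative tolerance $10^{-6}$ — far below landmark-placement error. The
degenerate (collinear) case is detected from a vanishing quadratic
coefficient and handled in closed form. The reported statistic is

$$p = \frac{s_N}{L}, \qquad s_N = \int_0^{t_N} \lVert C'\rVert\,dt,
  \quad L = \int_0^1 \lVert C'\rVert\,dt,$$

so $p = 0$ at the apical surface and $p = 1$ at the basal end. Both the
fraction and the micrometre value $s_N$ are emitted, since published plots
of "relative nucleus position" do not always state their normalization.
A nucleus centroid lying further off the apical–basal chord than the chord
length itself (configurable) triggers a warning rather than an error:
such landmarks are suspicious but not geometrically invalid.

## The recruitment model

The nucleus is segmented from the DAPI channel by a global auto-threshold
(Otsu by default, IsoData selectable; method and value are recorded as
provenance), followed by largest-component selection and hole filling. The
whole cell is segmented the same way from the cytoplasm/microtubule channel
with an additional 0.3 µm morphological closing, because cytoskeletal
texture is patchy. Both operations are natively 3D; single-plane images are
handled as 2D.

The perinuclear band is the shell of voxels outside the nucleus whose
Euclidean distance to it is at most 1.1 µm, with distance computed in
*physical* units by an exact separable distance transform, so anisotropic
voxels (e.g. 0.5 µm z-steps against 0.1 µm pixels) produce a band ~2 voxels
thick axially and ~11 voxels thick laterally, as they should. The
recruitment index is

$$\mathrm{RI} = \frac{\overline{I}_{\text{band} \cap \text{cell}}}
  {\overline{I}_{\text{cell} \setminus \text{nucleus} \setminus \text{band}}}.$$

Excluding the band from the cytoplasmic denominator is a deliberate choice:
the literal "cell minus nucleus" region contains the band, so at strong
enrichment the envelope signal would contaminate its own reference. A flag
(`exclude_band_from_cytoplasm = FALSE`) restores the literal reading. The
index is invariant under multiplicative intensity rescaling; it is *not*
invariant under additive offsets (no background subtraction is applied by
default), and the test suite asserts that sensitivity rather than hiding it.

## Cisternae gaps

Submembrane cisternae are annotated as ordered, non-overlapping intervals
along the lateral membrane contour. Gap $i$ is
$\mathrm{start}_{i+1} - \mathrm{end}_i$; only interior gaps are measured
("between adjacent cisternae" implies pairs), so a single-segment profile
has no gaps and an undefined mean. Both per-gap and per-cell-mean
aggregations are emitted, since either could underlie a published per-group
comparison. Quantification starts from annotations, not raw electron
micrographs: no detection algorithm is part of the scope.

## The statistical battery

* `normality_check()`: Shapiro–Wilk plus Lilliefors-corrected
  Kolmogorov–Smirnov per group; "pass" means both exceed α. Because two
  positively correlated 5% tests are intersected, the joint pass rate on
  genuinely normal data is ~0.91, slightly below the single-test 0.95 —
  a property of the composite rule, asserted as such in the tests.
* `kruskal_dunn()`: tie-corrected Kruskal–Wallis H (chi-square
  approximation, via `stats::kruskal.test`) with Dunn's mean-rank z tests
  over all pairs, Bonferroni-adjusted by default — the convention of the
  analysis software commonly used for such panels. Constant data
  degenerates to H = 0, p = 1 by convention.
* `anova_tukey()`: one-way classical ANOVA, or a two-factor model with
  type-II sums of squares (`car::Anova`) for near-balanced designs with
  attrition; Tukey HSD (Tukey–Kramer at unequal n) pairwise comparisons.
* `mann_whitney()`: exact by full enumeration of group assignments when
  both arms have ≤ 8 observations (ties handled through midranks, so
  identical samples give U = n₁n₂/2 and p = 1 exactly); otherwise the
  tie-corrected normal approximation with continuity correction. The two
  regimes agree to |Δp| ≤ 0.01 in the overlap.
* `multiple_t_bky()` / `bky_step_up()`: per-condition Welch t tests with
  the adaptive two-stage linear step-up FDR procedure: a first BH pass at
  $q' = q/(1+q)$ estimates the null count $\hat m_0 = m - r_1$, a second
  pass at $q' m/\hat m_0$ yields the discoveries. Welch was chosen because
  the group sizes in such cohorts are routinely unequal. The implementation
  is checked against a literal step-by-step rendition of the published
  algorithm on fixed and random p-vectors.
* `count_cells_per_region()`: half-open window
  $[c - s/2,\, c + s/2)$, 200 µm by default, so a cell on a shared boundary
  is counted exactly once when tiling adjacent regions.
* `onset_analysis()`: `multiple_t_bky` across ages, reporting the earliest
  discovered age — the phenotype onset, which for this system coincides
  with the onset of electromotility around P12.

### A known property of the two-stage procedure

With a handful of conditions of which some carry very strong effects, the
adaptive second stage runs BH at a level inflated by $m/\hat m_0$ — with
two true effects among four ages, ≈ 0.095. One of the two null ages is then
falsely discovered in roughly 11–14 % of replicates, so the probability
that the discovery set is *exactly* the true pair is ~0.86–0.89, not 0.95.
This is a property of the published procedure (the implementation was
cross-checked against an independent one), and the corresponding validation
expectation is stated — and fails honestly — at the stricter 0.95 level in
the acceptance test, with the all-null false-onset clause (≤ 10 %)
comfortably met. Users who need tighter exact-set behaviour at small m
should prefer non-adaptive BH.

## The synthetic-data generator

`generate_cell_image()` renders a three-channel confocal-like stack: a tube
of radius 3.2 µm around a smooth midline of arc length 30 µm (defaults), a
spherical nucleus of radius 2.2 µm centred on the midline at the requested
arc fraction, and a reporter channel equal to cytoplasm intensity over the
cell body times an enrichment factor *k* in a 0.3 µm nuclear-rim shell.
Channel intensities are 100 (cytoplasm/nucleus) over a background of 10,
with Poisson photon noise (50 expected photons at cytoplasm intensity) plus
Gaussian read noise (sd 2) — typical confocal statistics. Default voxels
are 0.5 × 0.1 × 0.1 µm (z, y, x): plausible confocal sampling, declared
rather than inferred since acquisition parameters for such experiments are
rarely published.

Two choices matter for honest validation:

* The generative midline family is **sinusoidal** by default — deliberately
  *not* the quadratic family the axis fitter uses — with lateral amplitude
  `curvature × length / 2` (a 0.3 bend ≈ 4.5 µm of lateral excursion on a
  30 µm cell, a realistic gentle curve). Recovery tests therefore measure
  genuine model error, not a fitter evaluated against its own family; the
  residual quadratic-fit bias against this family is ≤ 0.003 in p.
* Ground-truth lengths and the nucleus centre are computed on the
  continuous midline by dense polyline integration, independent of the
  voxel grid, and are verified against an external re-integration of the
  same family to 0.1 %.

`generate_cohort()` draws per-cell relative positions from truncated
normals on [0, 1] by inverse-CDF sampling (bit-identical under a fixed
seed), with per-(group, age) means supporting onset designs.
`generate_cisternae_profile()` lays out segments with exactly the requested
gaps, optionally shifted by a random offset.

What the generator does **not** emulate: PSF blur and axial elongation,
multi-cell crowding, rows of cells in organ-of-Corti geometry,
depth-dependent attenuation, chromatic offsets, and real TEM texture.
Passing tests therefore demonstrate correctness of the *computations* under
controlled imaging statistics, not robustness to every real-microscope
artefact; on real data the landmark and annotation steps remain
semi-automatic by design.

## Numerical choices

* Distance transform: exact separable squared-EDT in physical coordinates;
  band membership uses d² ≤ w² + 10⁻⁹ µm² as a floating-point guard, and
  equals a brute-force all-pairs oracle exactly on small stacks.
* Arc-length quadrature: `stats::integrate`, rel.tol 10⁻⁶; collinear
  landmarks short-circuit to closed form (detected at ‖a₂‖ ≤ 10⁻⁹ × scale).
* Thresholds: 256-bin global histogram; Otsu returns the bin *boundary*
  after the optimal split so a two-valued image is separated cleanly;
  IsoData iterates the intermeans rule to a 10⁻⁹ fixed point.
* Mann–Whitney switches from enumeration to the normal approximation above
  8 observations per arm; with all values tied the approximation
  degenerates and p = 1 is returned with a flag.
* Degenerate inputs are rejected with named errors (coincident apical/basal
  landmarks, empty masks, constant images, overlapping cisternae segments
  with the offending pair named); batch operations record per-row failures
  and never abort the cohort.

## Problem sizes used in validation

The shipped validation suite uses 50 synthetic cells at default resolution
for curved-position recovery, 200 replicate cohorts (n = 10 per group per
age) for the onset design, 2000 null simulations per statistical test for
type-I calibration, a 90³-voxel sphere for the analytic band check, and
brute-force distance oracles on ≤ 64³ stacks. These sizes give Monte-Carlo
standard errors well below the tolerances they are checked against.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
every quantity above from scratch — straight-cell exactness, curved-cell
recovery error, onset recovery rates, recruitment calibration against the
generative-field oracle, band-volume error, type-I rates, cisternae
round-trip error and pipeline determinism — and writes them as JSON. The
pipeline itself is exposed as `run_pipeline()` and as the thin command-line
wrapper in `inst/cli/hcmorph`.

## Known limitations

* One cell per cropped stack; no instance segmentation of crowded fields.
* No deconvolution, background subtraction or illumination correction.
* The axis model is a single quadratic: S-shaped cells (two inflections)
  would be under-fitted, though three landmarks cannot express them anyway.
* Cisternae measurements start from interval annotations; raw TEM
  segmentation is out of scope.
* 2D inputs are supported by embedding at z = 0; mixed 2D/3D cohorts are
  the caller's responsibility to keep consistent.
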