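# hcmorph

Morphometry of nuclear position and nuclear-envelope recruitment in
cochlear hair cells.

Outer hair cells (OHCs) are elongated, curved cells whose nucleus is
normally anchored near the basal pole — at a relative position of roughly
0.7–0.8 along the cell. When LINC-complex anchoring fails (e.g. loss of the
KASH protein Nesprin-4 encoded by *Syne4*), the nucleus mislocalizes
apically and the cells degenerate, causing deafness. This package
implements the measurements needed to quantify that phenotype from
fluorescence stacks and annotations, plus the statistics used to compare
genotype/age cohorts:

* **Relative nuclear position** `p = s_N / L`: a quadratic parametric curve
  `C(t)` is fitted through three landmarks (apical surface, nucleus
  centroid at chord-length parameter `t_N`, basal end); `L` is the total
  arc length of the curve and `s_N` the arc length from the apical point
  to the nucleus, both by adaptive quadrature of `‖C′(t)‖` (rel. tol 1e-6).
* **Recruitment index** `RI = mean(I_band) / mean(I_cytoplasm)`: nucleus
  (DAPI) and cell (microtubule channel) segmented by global
  auto-threshold; the band is the 1.1 µm shell outside the nucleus under
  an exact anisotropic Euclidean distance transform; the cytoplasmic
  reference is the cell minus nucleus minus band.
* **Cisternae gap lengths** `g_i = start_{i+1} − end_i` between adjacent
  submembrane cisternae intervals annotated along the lateral membrane.
* **Cohort statistics**: Shapiro–Wilk + Lilliefors normality pre-tests,
  Kruskal–Wallis with Dunn's post hoc, one/two-way ANOVA (type-II) with
  Tukey HSD, Mann–Whitney (exact at small n), per-condition Welch t tests
  under the two-stage step-up (Benjamini–Krieger–Yekutieli) FDR procedure,
  hair-cell counts per 200 µm region, and phenotype-onset analysis across
  ages.
* **Synthetic data with ground truth**: curved 3-channel cell stacks
  (Poisson + Gaussian noise, anisotropic voxels), position cohorts and
  cisternae profiles, so every stage is testable without microscope data.

## Worked example

```r
library(hcmorph)

# --- relative nuclear position from manually placed landmarks (µm) ---
lm <- cell_landmarks(apical = c(2.1, 0.5, 0),
                     nucleus_centroid = c(6.8, 21.0, 0.4),
                     basal = c(4.0, 28.6, 0.2), cell_id = "OHC_01")
fit <- fit_cell_axis(lm)
fit
#> cell_axis_curve [OHC_01]: L = 29.709 um, nucleus arc = 21.576 um (p = 0.7262)
relative_nuclear_position(fit)
#> [1] 0.7262428
```

The cell is 29.7 µm long along its fitted axis and the nucleus sits 21.6 µm
from the apical surface: `p = 0.73`, a normally positioned OHC nucleus.

```r
# --- recruitment of an envelope reporter, on a synthetic ground-truthed cell ---
sim <- generate_cell_image(
  cell_spec(axis_curvature = 0.3, true_relative_position = 0.62,
            ne_enrichment_factor = 3), seed = 42)
st <- sim$stack
masks <- reconcile_masks(segment_nucleus(st$channels$dapi, st$voxel_size),
                         segment_cell(st$channels$cell, st$voxel_size))
recruitment_index(st$channels$reporter, masks,
                  band_width = 1.1, voxel_size = st$voxel_size)
#> recruitment index 1.300 (perinuclear 129.96 / cytoplasm 99.95, band 1.10 um)
```

The generative rim enrichment is k = 3 over a 0.3 µm shell; averaged over
the full 1.1 µm band the expected index is ~1.30, and that is what is
measured. Feeding the segmented nucleus centroid back into the axis fit
recovers the planted position:

```r
lmk <- landmarks_from_truth(sim$truth, st, nucleus_from = "segmented")
relative_nuclear_position(fit_cell_axis(lmk))
#> [1] 0.6185656    # ground truth: 0.62
```

```r
# --- cisternae gaps ---
g <- generate_cisternae_profile(30, segment_lengths = c(2, 2, 2),
                                gap_lengths = c(1.2, 0.8))
gap_lengths(g$profile)$gaps
#> [1] 1.2 0.8
```

The end-to-end pipeline (simulate → quantify → compare) is `run_pipeline()`;
a thin CLI wrapper lives in `inst/cli/hcmorph`
(`hcmorph run --config cfg.yaml --seed 1 --out results/`).

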