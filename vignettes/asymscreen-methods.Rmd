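---
title: "Methods: models, conventions and design choices in asymscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in asymscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymscreen)
```

`asymscreen` packages four analyses used to quantify left-right (L/R)
asymmetry in early mouse heart development — a paired L/R transcriptomic
screen, quantitative 3D in situ hybridization (ISH) spot counting,
landmark-based heart-loop morphometry, and an ultrarare-variant severity
filter — together with the exact nonparametric statistics they rely on and
seeded generators that synthesize inputs for every stage. This vignette is
the package's own account of the underlying models, the parameters that
matter, and the design choices that were genuinely open.

## 1. The paired left/right screen

### Model and procedure

The screen's substrate is a gene x sample count matrix in which each
embryo contributes one left and one right heart-field sample. The pipeline
is:

1. **Normalization to mean coverage.** Sample $j$ is scaled by
   $\bar T / T_j$ where $T_j$ is its total count and $\bar T$ the mean of
   all totals. All column totals then equal $\bar T$, and the grand total
   is conserved.
2. **Expression flags.** Flag = 1 where the normalized count is $\ge 20$
   (signal), 0 below (background). The boundary is inclusive.
3. **P50 filter.** A gene is retained when flagged in at least half of the
   samples, i.e. $n_\text{flagged} \ge \lceil S/2 \rceil$; the ceiling
   handles odd $S$, which a paired design never produces but external
   data can.
4. **Paired test.** Per gene, per-embryo differences
   $d_e = \log_2(L_e + c) - \log_2(R_e + c)$ with pseudocount $c = 0.5$;
   the statistic is $\bar d / \sqrt{\tilde s^2 / n}$ against a $t$
   reference.
5. **Thresholds.** Fold change $2^{|\bar d|} \ge 1.2$ and $p \le 0.05$,
   both inclusive; `consensus_union()` merges gene lists when several
   engines are run (this package ships one engine; the union mirrors how
   multi-engine consensus lists are assembled).

### Why the default test is the classical paired t

`paired_lr_test()` exposes empirical-Bayes variance moderation
(`prior_df`), with the prior variance either pooled or, by default, a
lowess trend in average log2 expression, bias-corrected by
$E[\log(\chi^2_f/f)]$. However, **the shipped default is `prior_df = 0`**,
the classical paired t. The reason is measurable: at 4 embryo pairs the
per-gene mean of log-transformed negative-binomial counts is heavy-tailed.
In fully symmetric simulations (500 genes x 50 seeds), the fraction of
genes at $p \le 0.05$ was 0.055 for pooled-prior moderation (0.105 in the
lowest-expression quartile), 0.037 for trend-prior moderation, and 0.056
even for a z-test using the *true* delta-method variance — whereas the
classical paired t measured 0.048, within the binomial 95% band. A
near-deterministic denominator cannot absorb the tails; the classical t's
random denominator co-varies with them. Moderation stays available for
users with more pairs, where its power advantage returns and the tail
problem fades.

### Small expression utilities

`classify_background()` applies the strict below-5.6 normalized-count rule
used to call background expression; `coexpression_fraction()` computes,
among cells positive for gene A, the fraction also positive for gene B
(the 234/309 = 75% worked example in the test suite); and
`relative_expression_ddct()` is the standard $2^{-\Delta\Delta C_t}$
quantification against a reference gene and calibrator sample.

## 2. Spot quantification in 3D volumes

### Detector

`detect_spots()` is a single-scale Laplacian-of-Gaussian (LoG) detector:
the response is $-\sigma^2 \nabla^2 (G_\sigma * I)$ with
$\sigma = r/\sqrt{3}$ per axis for spot radius $r$ (the scale at which a
Gaussian blob of that size maximizes the normalized response), computed
with separable, DC-zero second-derivative kernels honouring anisotropic
voxel sizes. Candidates are 26-neighborhood local maxima above a response
percentile (default 99.5, taken within the analyzed region when a mask is
supplied), then greedily non-maximum-suppressed within one spot radius.
A radius smaller than one voxel on any axis is refused with advice to
resample. The commercial "spot detector" the procedure stands in for is
proprietary; LoG + NMS is its standard open equivalent.

### Side normalization and the L/R ratio

`bisect_mask_by_midline()` splits a region's voxels by the sign of the
midline-plane equation; voxels exactly on the plane go left (documented
tie-break, covered by a one-voxel-slab tolerance in symmetry tests).
`hoechst_normalization_score()` counts nuclear-scale candidate maxima per
side and keeps, per side, those above the highest threshold retaining at
least 50% of that side's candidates; the score is $H_L / H_R$. Because the
retention rule is *relative to each side's own response distribution*, a
one-sided multiplicative intensity bias — the lightsheet attenuation this
normalization exists to cancel — drops out of the score. The exact meaning
of the original software's "coverage of 50% of spots on each side" is not
recoverable from public sources; our reading (per-side maxima, NMS at one
nuclear radius, a 10%-of-max response floor, a one-nuclear-radius
exclusion band at the midline to reject the blob-scale edge ridge an
intensity step creates, then 50% retention) is isolated in that one
function.

`lr_asymmetry()` assembles the enrichment ratio
$$\log_2 \frac{S_L / (H_L V_L)}{S_R / (H_R V_R)},$$
storing every component so Hoechst-only or volume-only variants can be
recomputed. `stage_profile()` aggregates measurements by stage and
genotype, tests each group against the symmetry hypothesis
(signed-rank vs 0), compares genotypes per stage (Mann-Whitney), and
applies Benjamini-Hochberg across the reported family.

### What the synthetic volumes emulate — and what they do not

`simulate_embryo_image()` renders two channels over two box regions
mirrored across a planar midline: Gaussian nuclei (sigma 2 um) and
transcript spots (sigma 0.4 um) under a configurable PSF, Poisson shot
noise (Gaussian read noise optional), and an optional one-sided intensity
bias. Expected spot count per side is density x volume with the left
density `lr_fold` x the right. Defaults: a 56 x 56 x 28 um field at 0.5 um
voxels, 120 nuclei per side, right-side density 0.005 spots/um^3 — an
optically *resolvable* regime, which is the validity condition of
single-molecule spot counting itself. Nuclei are placed with a hard-core
exclusion of one nuclear diameter: real interphase nuclei cannot overlap,
and uniform placement without exclusion produces merged blobs no detector
(nor the original software) could separate. Spots, by contrast, are
genuinely Poisson-uniform, so a small density-dependent merge loss
(~2-8%) remains and biases recovered folds slightly toward 1; at the
E8.5d preset (`image_sim_preset("E8.5d")`, true fold 4.5) the pipeline
recovers ~4.2-4.3 on average. The generator does not emulate embryo-shape
realism, clearing artifacts, or optical aberrations beyond the bias
factor, so a green test establishes correctness of the quantification
chain, not robustness to every imaging pathology.

## 3. Heart-loop morphometry

### Frame and conventions

`align_to_embryo_frame()` maps the total-least-squares line through the
notochord points to the Z axis (cranial positive), the dorso-ventral
reference into the +X half-plane (ventral positive), and completes a
right-handed frame with +Y the embryo's left. Cranial orientation comes
from the hemisphere containing the outflow exit, which is order-free (the
caudal-to-cranial ordering of notochord points is only a fallback).
Embryos under 18 somites, or with unknown somite count, are rejected as a
staging QC failure — loudly, not silently.

The published figures do not restate the angle construction (it lives in
earlier work), so the convention is fixed here and anchored by tests:
**the RV/LV angle is the signed angle in the transverse plane from the +Y
(leftward) axis to the vector RV to LV, counter-clockwise positive viewed
from cranial, range (-180, 180]**. A normal rightward loop (RV on the
embryo's right) reads 0 degrees; a mirrored loop reads 180. Tube length is
the polyline through the eight landmarks in anatomical order; venous-pole
displacement is its Y coordinate divided by tube length (left positive);
the looping-direction call is the sign of $Y_{RV} - Y_{LV}$ with a 1 um
indeterminate band. `direction_frequency_test()` compares an observed
rightward count against an expected proportion with the 1-df Yates
chi-squared.

`simulate_landmarks()` builds the eight landmarks directly in this frame
so that angle, offset fraction and tube length are realized *exactly* at
zero noise (a fixed-point rescaling pins tube length while holding the
venous-pole offset), then applies isotropic Gaussian noise and optionally
a uniform random rigid motion that alignment must undo. Defaults (0
degrees, +0.15 offset, 700 um tube, 25 somites) describe a normal E9.5
rightward loop.

## 4. Variant filtering

A variant passes when it is ultrarare — minor allele count $\le 2$ in
*every* population dataset listed (the conservative per-dataset reading;
whether the original criterion pooled datasets is not stated) — and is
either protein-truncating (stop gain, frameshift, canonical +/-1,2 splice
site; splice-*region* consequences are "other") or protein-altering
(missense, inframe indel) with REVEL $\ge 0.932$ or CADD Phred
$\ge 28.1$, all boundaries inclusive as printed. Missing REVEL/CADD fails
that branch rather than erroring, matching incomplete real-world
annotation coverage. ACMG labels are carried as text, never computed.
`simulate_variant_table()` constructs eight records covering every filter
branch, including the three printed boundary values exactly, and records
expected pass flags derived from the filter's definition (not by calling
the filter — the agreement is a cross-module test).

## 5. Exact statistics

`mann_whitney_u()` and `wilcoxon_signed_rank_vs_zero()` enumerate the
exact two-sided permutation distributions for small samples
($n_x + n_y \le 20$ without ties; $n \le 15$ sign patterns, valid under
ties in $|d|$ because realized midranks are enumerated), switching to
tie- and continuity-corrected normal approximations beyond — thresholds
chosen for desk-scale enumeration cost. The "compare with a symmetry
hypothesis (log2 ratio = 0)" usage is read as the one-sample signed-rank
test against 0 (a two-sample test against a constant is degenerate); both
tests ship. `bh_adjust()` is the step-up FDR adjustment; note that BH is
*not* idempotent in general (re-adjusting can only raise values), which
the tests assert in its correct one-sided form. `chi_squared_gof()`
implements the Pearson statistic with the per-cell Yates correction
$(|O - E| - 0.5)$ floored at 0 to prevent over-correction, permitted only
for 2 cells.

## 6. Numerical and I/O choices

- All randomness flows from per-generator integer seeds; generators save
  and restore the session RNG state, and the pipeline derives per-stage
  sub-seeds from one configuration seed.
- Tabular interchange is TSV with a header; nested metadata and ground
  truth are JSON (the configuration format is JSON rather than YAML — no
  YAML parser is a hard dependency of this stack). A minimal site-level
  VCF reader/writer covers the variant interchange (`MAC_<dataset>`,
  `REVEL`, `CADD_PHRED`, `CSQ` INFO keys); TSV is the primary route.
- Image volumes are in-memory R arrays with a 0-based voxel-to-micrometer
  convention (voxel $i$ at $(i-1) \times$ voxel size); masks and volumes
  share one frame and are never resampled implicitly.
- `run_pipeline()` writes the fully resolved configuration and a manifest
  (package version, seed, per-stage counts, md5 of every output) into each
  run directory; unknown configuration keys are rejected before any work.

## 7. Known limitations

- One differential-expression engine ships; the three-engine consensus of
  the original screen is represented by the union operation with
  pluggable inputs.
- The spot-density regime is deliberately resolvable; very dense real
  signals would undercount on the enriched side and compress ratios
  toward symmetry, as partially visible already at the E8.5d preset.
- The landmark generator produces one fixed, plausible loop geometry
  family; it varies the quantified parameters, not overall heart shape,
  so it cannot exercise shape-classification questions (out of scope).
- Exact-test enumeration is exponential; the switchover thresholds cap
  cost but mean large-sample p-values are approximations (with tie and
  continuity corrections).
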