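# asymscreen

Quantifying left–right asymmetry in early heart development, from a paired
transcriptomic screen to 3D image quantification, loop morphometry and
human variant filtering — with seeded synthetic data so the whole pipeline
is testable on a laptop, offline.

## The scientific problem

The first visible left–right asymmetry of the vertebrate body is the
rightward looping of the embryonic heart tube (mouse E8.5). Finding the
genes behind it requires comparing the *left* and *right* halves of the
heart-progenitor field within single embryos (pooling embryos blurs the
transient signal), validating candidates by counting single-transcript
spots in 3D image volumes on each side of the midline, measuring the loop
geometry itself from anatomical landmarks, and asking whether rare human
variants in a candidate gene are severe enough to matter clinically. This
package implements each of those four analyses as reusable, tested
components for developmental biologists working on laterality:

| Module | What it does |
|---|---|
| `lr_screen` | paired L/R screen: mean-coverage normalization, flags (≥ 20), P50 lists, paired t on log2 ratios, FC ≥ 1.2 & p ≤ 0.05 thresholds, engine-consensus union, MA statistics, background call (< 5.6), co-expression fraction, ΔΔCt |
| `spot_quant` | 3D Laplacian-of-Gaussian spot detection, midline bisection, Hoechst per-side normalization score, log2[(S_L/(H_L·V_L))/(S_R/(H_R·V_R))], stage profiles with signed-rank and Mann–Whitney tests |
| `loop_morphometry` | notochord-frame alignment (Z = notochord, +X ventral, +Y left), signed RV/LV axis angle, venous-pole displacement / tube length, looping-direction calls and Yates chi-squared frequency tests, < 18 somite QC |
| `variant_filter` | ultrarare (MAC ≤ 2 in every dataset) AND (protein-truncating OR missense with REVEL ≥ 0.932 / CADD ≥ 28.1) |
| `stats_core` | exact small-sample Mann–Whitney and signed-rank (full enumeration), Benjamini–Hochberg, chi-squared GOF with floored Yates correction |
| `synthetic_data` | seeded generators for paired NB counts, two-channel 3D volumes with ground-truth spot coordinates, landmark sets, and variant tables covering every filter branch |
| `pipeline_io` | TSV/JSON/VCF readers and writers, validated run configuration, a deterministic end-to-end runner with manifests, and a CLI |

The core statistic of the imaging arm is the normalized left/right
enrichment ratio

```
log2[ (S_L / (H_L · V_L)) / (S_R / (H_R · V_R)) ]
```

with S the transcript spot counts, H the per-side Hoechst (nucleus)
counts and V the region volumes; the Hoechst term cancels one-sided
imaging bias because its threshold is chosen per side (50% candidate
retention).

## Worked example

```r
library(asymscreen)

## 1. Paired screen on synthetic data (100 truly left-enriched genes of
##    2000, fold 2, 4 embryo pairs)
sim  <- simulate_paired_counts(count_sim_params(n_genes = 2000, n_pairs = 4,
                                                n_asym = 100, asym_fold = 2,
                                                seed = 1))
norm <- normalize_to_mean_coverage(sim$counts)
p50  <- p50_filter(compute_flags(norm, threshold = 20))
res  <- paired_lr_test(norm, genes = p50, in_p50 = p50)
hits <- apply_thresholds(res, min_fold = 1.2, max_p = 0.05)
length(p50); length(hits)
#> [1] 1733
#> [1] 126
mean(sim$truth$asym_genes %in% hits)     # sensitivity
#> [1] 0.63

## 2. Image quantification at the E8.5d preset (true L/R fold 4.5)
img <- simulate_embryo_image(image_sim_preset("E8.5d", seed = 1))
lr_asymmetry(img$image)
#> asym_measurement 'sim000001' (E8.5d, heart_field): S 646/151, H 38/43, log2 L/R = 2.275
2^2.275                                  # recovered fold, true 4.5
#> [1] 4.84

## 3. Loop morphometry: exact parameter recovery at zero noise
lm <- simulate_landmarks(landmark_sim_params(rvlv_angle_deg = -20,
                                             venous_offset_frac = 0.15,
                                             seed = 2))
loop_metrics(align_to_embryo_frame(lm$landmarks))[c("rvlv_angle_deg",
    "venous_displacement_norm", "tube_length", "direction")]
#> angle -20.00 deg, venous displacement 0.150, tube 700.0 um, rightward

## 4. Looping-direction frequency vs a randomized (50:50) expectation
direction_frequency_test(30, 76)
#> X-squared = 2.96053, p = 0.0853202 (chi-squared GOF, Yates corrected, df = 1)

## 5. Variant filter
vs <- simulate_variant_table(12, seed = 1)
length(filter_variants(vs$records)$passing)
#> [1] 9
```

Reading the numbers: the screen keeps 1,733 expressed genes (P50), calls
126 at the printed thresholds and recovers 63% of the truly asymmetric
ones from only 4 embryo pairs; the image pipeline recovers a 4.8-fold
left enrichment on one volume whose ground truth is 4.5 (the mean over 10
seeds lands at ~4.2–4.3); the morphometry returns the simulated −20°
RV/LV angle and +0.15 venous-pole offset exactly at zero noise; 30/76
rightward loops do not significantly deviate from a randomized direction
under the Yates-corrected chi-squared.

## CLI

```sh
CLI=$(Rscript -e 'cat(system.file("cli","asymscreen.R", package="asymscreen"))')
Rscript "$CLI" simulate counts --seed 1 --out out/
Rscript "$CLI" screen --counts out/counts.tsv --samples out/samples.tsv --out out/
Rscript "$CLI" filter-variants --variants variants.tsv --out out/
Rscript "$CLI" morphometry --landmarks landmarks.json --out out/
Rscript "$CLI" run --config config.json
```

See `vignettes/asymscreen-methods.Rmd` for the models, conventions
(including the RV/LV angle sign convention) and the reasoning behind every
tunable default.
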