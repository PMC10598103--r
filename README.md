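# segagree

Interobserver agreement (IOA) metrics for radiotherapy target volumes.

When several radiation oncologists delineate the same tumour — the gross
tumour volume (GTV), its respiratory motion envelope (ITV), and the
planning target volume (PTV) — their contours disagree, and that
disagreement propagates straight into treatment planning. `segagree`
quantifies it with four complementary geometric metrics computed between
every pair of observers, and aggregates the pairwise values into the
per-case and pooled summary tables used in multi-observer delineation
studies (stereotactic body radiotherapy of pancreatic cancer being the
motivating setting: 3 cases × up to 19 observers × GTV/ITV/PTV).

## The metrics

For two binary masks A, B on a shared voxel grid, with `tp = |A∩B|`,
`fp = |A\B|`, `fn = |B\A|` (true negatives are never used — background
padding cannot change any metric):

| metric | formula | range | better |
|---|---|---|---|
| Dice–Sørensen coefficient (DSC) | 2·tp / (2·tp + fp + fn) | [0, 1] | higher |
| symmetric Hausdorff distance (HD) | max over both directions of the largest nearest-voxel distance, in mm (anisotropic spacing) | [0, ∞) | lower |
| probabilistic distance (PBD) | (fp + fn) / (2·tp) = (1 − DSC)/DSC | [0, ∞] | lower |
| volumetric similarity (VS) | 1 − \|fp − fn\| / (2·tp + fp + fn) | [0, 1] | higher |

plus the Jaccard index, JCI = DSC / (2 − DSC). DSC measures overlap, HD
spatial outliers, PBD alignment of correctly sized volumes, VS size
alone — together they separate failure modes a single metric conflates.

## Worked example

```r
library(segagree)

# two delineations of the same lesion, 2 mm isotropic grid
g <- image_grid(c(48, 48, 48), spacing_mm = c(2, 2, 2))
a <- make_base_tumor(case_template("demo", 31.75, shape = g$shape), seed = 7)
b <- simulate_observer_gtv(a, observer_model("obs2", systematic_bias_mm = 1.5,
                                             roughness_mm = 2, seed = 99))
metric_quartet(a, b)
#> <metric_quartet> DSC 0.8370 | HD 7.2111 mm | PBD 0.1947 | VS 0.8766
```

DSC 0.84: the two contours share 84% of their combined volume (by the
Dice weighting). HD 7.2 mm: the worst local disagreement — some point of
one surface is 7.2 mm from the other. PBD 0.19: mismatched volume is
about 19% of twice the overlap. VS 0.88: the two volumes differ in size
by about 12%.

A full synthetic cohort, end to end:

```r
cohort <- generate_cohort(cohort_sim_config(base_seed = 42))
report <- table1_report(cohort)
report$kinds$GTV$pooled
#>   metric   minimum    maximum      mean    median        std n_pairs
#> 1    dsc 0.5729155  0.8917819 0.8005040 0.8143916 0.06001444     513
#> 2  hd_mm 6.0000000 16.6132477 8.7788352 8.4852814 1.55883492     513
#> 3    pbd 0.1213504  0.7454582 0.2571362 0.2279105 0.10671709     513
#> 4     vs 0.5729155  0.9991986 0.8685278 0.8877702 0.09316054     513
```

513 = 3 cases × C(19, 2) pooled pairwise comparisons. Medians (DSC
≈ 0.81, PBD ≈ 0.23) sit in the band reported by expert delineation
studies of pancreatic SBRT targets (median pairwise GTV Dice roughly
0.6–0.81).

## Command line

```sh
IOA=$(Rscript -e 'cat(system.file("cli/ioa.R", package = "segagree"))')
Rscript $IOA simulate --observers 19 --seed 42 --out cohort/
Rscript $IOA compute  --input cohort/ --out report.csv
Rscript $IOA pairs    --input cohort/ --out pairs.csv
```

Directory layout: `case_<id>/observer_<id>/{GTV,ITV,PTV}.nrrd` (masks),
or per-observer `structset.json` contour files plus a root `grid.json`
with `--format contours`. Reports are byte-deterministic for a given
seed.

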