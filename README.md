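# ihcsubtype

Rule-based diagnosis of breast-cancer molecular genetic subtypes from
immunohistochemical (IHC) microscopy images.

A case is a stack of four RGB images of the same tissue, one per
biomarker: estrogen receptor (ER), progesterone receptor (PR), the
HER2/neu oncoprotein, and the proliferation marker Ki-67. For each image
the package computes two indicators:

* **relative positive area** — δ<sub>S</sub> = S<sub>p</sub>/S<sub>w</sub>,
  the fraction of the field of view covered by positively stained nuclei,
  obtained by a biomarker-specific luma threshold band plus
  marker-controlled watershed segmentation of the adaptively preprocessed
  image (PSNR-probed median filtering, step-table brightness gain
  IIII = α·III);
* **staining intensity** — K<sub>I</sub> ∈ {1, 2, 3} from the mean luma
  of the segmented regions on the unenhanced input
  (≤15 → 1, (15, 30] → 2, >30 → 3).

The eight indicators feed four fixed rule systems (all inequalities
strict):

| subtype | conditions |
|---|---|
| Luminal A | ERσS > 0.66, ERKI = 3, PRσS > 0.2, HER2σS < 0.1, KI67σS < 0.2 |
| Luminal B | ERσS < 0.66, ERKI = 3, PRσS < 0.2, HER2σS < 0.1, KI = 1, KI67σS > 0.2 |
| HER2-amplified | HER2σS < 0.1, KI = 1, ERσS < 0.1, PRσS < 0.1 |
| basal-like | ERσS < 0.1, PRσS < 0.1, HER2σS < 0.1, KI67KI = 3 |

Exactly one satisfied system gives the diagnosis; zero or several give
`Indeterminate` with full per-condition detail. The result is advisory
for a diagnostician. An optional histological grade (G1–G3, user input)
only adds consistency warnings.

Because clinical IHC image sets are rarely shareable, the package ships a
seeded synthetic generator (`make_ihc_image()`, `make_subtype_case()`)
that emulates stained frames with exact ground truth, so every stage is
testable offline. See the methods vignette
(`vignettes/ihc-subtype-pipeline.Rmd`) for the model, parameter
rationale, and what the synthetic tests do and do not establish.

## Worked example

```r
library(ihcsubtype)

# a synthetic Luminal-A case: four biomarker images plus ground truth
cs  <- make_subtype_case("LuminalA", seed = 11)
cfg <- ihc_config(cs$config)       # this case segments the filtered stage
ind <- compute_indicator_set(cs$stack, cfg)
print(ind)
#> <indicator_set>
#>   PR   sigmaS = 0.2445  KI = 3
#>   ER   sigmaS = 0.7028  KI = 3
#>   HER2 sigmaS = 0.0235  KI = 3
#>   KI67 sigmaS = 0.0636  KI = 3

classify(ind, grade = "G1", config = cfg)
#> <subtype: LuminalA>
#>   LuminalA      SATISFIED  [er_sigma_gt_0.66=T er_ki_eq_3=T pr_sigma_gt_0.2=T her2_sigma_lt_0.1=T ki67_sigma_lt_0.2=T]
#>   LuminalB      not satisfied  [er_sigma_lt_0.66=F er_ki_eq_3=T pr_sigma_lt_0.2=F her2_sigma_lt_0.1=T her2_ki_eq_1=F ki67_sigma_gt_0.2=F]
#>   HER2Amplified not satisfied  [her2_sigma_lt_0.1=T her2_ki_eq_1=F er_sigma_lt_0.1=F pr_sigma_lt_0.1=F]
#>   BasalLike     not satisfied  [er_sigma_lt_0.1=F pr_sigma_lt_0.1=F her2_sigma_lt_0.1=T ki67_ki_eq_3=T]
```

ER covers 70% of the frame with strong staining, PR 24%, HER2 and Ki-67
are low — only the Luminal A system is fully satisfied, and grade G1 is
consistent, so no warning is emitted.

Single stages are just as accessible:

```r
fx  <- make_ihc_image(fixture_spec(height = 256, width = 256,
                                   positive_fraction = 0.25,
                                   positive_luma = 195,
                                   impulse_noise_density = 0.02, seed = 7))
pre <- preprocess(fx$image)
print(pre$provenance)
#> <provenance: probe PSNR 20.70 dB -> window 3; Y = 229.47 -> alpha 4>

seg <- segment(pre$stages$III, "ER")   # ER band (180, 210) on the filtered stage
print(seg)
#> <segmentation: 61 objects, Sp = 13372 / Sw = 65536 (deltaS = 0.2040)>
```

The recovered δS (0.204) sits 0.039 below the generator's exact ground
truth (0.2425): the watershed ridge costs about one pixel of perimeter
per nucleus, a known, bounded bias discussed in the vignette.

From the command line:

```sh
Rscript -e 'ihcsubtype::ihc_main()' run \
  --er er.png --pr pr.png --her2 her2.png --ki67 ki67.png \
  --grade G1 --out results --save-masks
Rscript -e 'ihcsubtype::ihc_main()' simulate --out fx --seed 4 --fraction 0.25
```

`run` writes `report.json` (indicators, thresholds used, preprocessing
provenance with per-stage digests, per-condition rule detail, config
digest) and, with `--save-masks`, the segmentation masks as PNGs.

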