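---
title: "Methods: rule-based subtype diagnosis from IHC images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based subtype diagnosis from IHC images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcsubtype)
```

## The problem

Immunohistochemical (IHC) staining marks cells expressing a target
protein. For breast cancer, four biomarkers — estrogen receptor (ER),
progesterone receptor (PR), the HER2/neu oncoprotein, and the
proliferation marker Ki-67 — are read together to assign one of four
molecular genetic subtypes (Luminal A, Luminal B, HER2-amplified,
basal-like), which drives therapy choice. A pathologist estimates, per
biomarker image, how much of the field of view is covered by positively
stained nuclei and how intense the staining is. This package automates
that reading: it quantifies each image into two indicators and applies a
fixed rule system to the indicator vector. The output is advisory — an
`Indeterminate` result is a legitimate, successful outcome, not an error.

## The pipeline

For each of the four images \(I\):

1. **Adaptive preprocessing.** A 3×3 median probe \(II = M(I)\) estimates
   the impulse-noise level via the peak signal-to-noise ratio
   \(\mathrm{PSNR} = 10\log_{10}(255^2/\mathrm{MSE}(II, I))\), with MSE
   averaged jointly over all pixels and channels. Probe PSNR ≤ 20 dB
   selects a 5×5 working window, otherwise 3×3; the working median is
   applied to \(II\), giving \(III\). The mean luma
   \(Y = \overline{0.299R + 0.587G + 0.114B}\) of \(III\) selects a
   multiplicative gain α from a step table (20, 12, 8, 6, 4 for
   \(Y \le 10\), \((10,40]\), \((40,150]\), \((150,200]\), \(>200\));
   \(IIII = \alpha \times III\) with half-up rounding, saturating at 255.
2. **Segmentation.** A biomarker-specific luma band — PR (160, 180),
   ER (180, 210), HER2 (40, 230), Ki-67 (160, 180), both bounds
   inclusive — proposes candidate positive pixels. A marker-controlled
   watershed then regularizes the candidate: morphological opening (3×3
   cross, 2 iterations), sure background from a 3-iteration dilation,
   sure foreground where the exact Euclidean distance transform exceeds
   0.4 × its maximum, Meyer flooding on the Sobel gradient of luma,
   ridge pixels assigned to background, objects under 30 px discarded.
3. **Indicators.** Relative positive area \(\delta_S = S_p / S_w\) with
   \(S_w\) the full frame; staining intensity \(K_I \in \{1,2,3\}\) from
   the mean luma of the segmented regions measured on the *unenhanced*
   input (\(K_I = 1\) for \(Y \le 15\), 2 for \((15, 30]\), 3 for
   \(Y > 30\); the printed integer gap at (15, 16) is closed half-open).
4. **Classification.** Four rule systems over the eight indicators, all
   inequalities strict as printed:
   * Luminal A: ERσS > 0.66, ERKI = 3, PRσS > 0.2, HER2σS < 0.1, KI67σS < 0.2
   * Luminal B: ERσS < 0.66, ERKI = 3, PRσS < 0.2, HER2σS < 0.1, KI = 1, KI67σS > 0.2
   * HER2-amplified: HER2σS < 0.1, KI = 1, ERσS < 0.1, PRσS < 0.1
   * Basal-like: ERσS < 0.1, PRσS < 0.1, HER2σS < 0.1, KI67KI = 3

   Exactly one satisfied system yields that subtype; zero or several
   yield `Indeterminate` with full per-condition detail. A user-supplied
   histological grade (G1/G2/G3) never changes the decision; it only
   triggers a consistency warning (Luminal A ↔ G1/G2, Luminal B ↔ G2/G3,
   HER2-amplified ↔ G3; no association is stated for basal-like).

All parameters live in one configuration (`ihc_config()`), which also
backs the IF–THEN knowledge base (`load_rules()`/`fire()`): the window
rule, the threshold table and the gain table are each a rule family whose
conditions must partition their input space, so exactly one rule fires
per decision and the fired rule id is logged.

## Design decisions where the method description was open

* **Probe window.** The chain defines \(II = M(I)\) without a window;
  the probe is fixed at 3×3 and the selected window is applied to
  \(II\), not \(I\), following the literal chain \(III = m_w \times II\).
* **Band semantics.** How the two thresholds combine is unstated; the
  simplest reading — inclusive luma band membership
  \(T_L \le g \le T_H\) — is used, on luma rather than a
  stain-deconvolved channel, because luma is the only channel transform
  the method defines.
* **Watershed recipe.** Opening/dilation iterations, the 0.4 distance
  fraction and the 30 px minimum object size are not specified upstream;
  the values follow the standard marker-controlled recipe built from the
  stated components (threshold, erode/dilate, markers, watershed) and are
  all exposed in the configuration. Ridge pixels count as background
  (conservative area). Connectivity is 4-connected to avoid diagonal
  bridging of touching nuclei. Because sure-foreground markers use a
  *global* distance maximum, nuclei whose radius is below 0.4 × the
  largest nucleus radius can lose their marker; the generator's default
  radius spread (10 ± 2 px) stays well clear of that regime.
* **KI = 1 binding.** The unqualified "KI = 1" in the Luminal B and
  HER2-amplified systems is bound to HER2's intensity — the most local
  reading, since it directly follows the HER2 area condition in both
  printed systems. The binding is configurable (`bcb_ki_binding`).
* **Empty masks.** With no positive pixels, masked mean brightness is
  undefined; KI becomes `NA` with a `no_positive_cells` flag, and any
  rule condition on an `NA` KI evaluates false. The alternative (scoring
  an empty mask as KI = 1) would make a completely blank quadruple
  satisfy the HER2-amplified system, which is clearly wrong.
* **Boundary equality.** An indicator sitting exactly on a rule boundary
  (e.g. ERσS = 0.66) satisfies neither strict inequality; no epsilon is
  added, and `Indeterminate` is the honest output.
* **HER2 direction.** The printed HER2-amplified system requires
  HER2σS < 0.1, which is biologically inverted for an *amplified*
  subtype; it is implemented as printed, with a configuration override
  (`her2_amplified_area_direction = "gt"`) for users who want the
  biologically expected direction.
* **Intensity source.** KI is measured on the original input so that it
  is independent of the brightness gain; `intensity_source = "amplified"`
  selects the alternative reading.

## The gain/band tension, and what the synthetic cases do about it

The published chain thresholds the α-amplified image, while KI is scored
on the raw input with bins (≤15, 16–30, >30) that sit far below every
band's lower threshold. These two facts interact:

* `KI = 1` (raw mean ≤ 15) is reachable **only** through the amplified
  chain: near-black nuclei (raw luma ≈ 12) are lifted by the ×4 gain into
  the wide HER2 band (40–230) while their raw mean stays ≤ 15. This is
  the regime the published parameters jointly imply — dim microscope
  frames whose staining becomes thresholdable only after gain.
* Luminal A's ERσS > 0.66 together with ERKI = 3 is **arithmetically
  unreachable** through the amplified chain: a stain that lands in the ER
  band (180–210) after gain α has raw luma in \([180/\alpha,
  210/\alpha]\); ERKI = 3 needs raw mean > 30, forcing α ≤ 6, which the
  gain table grants only when frame brightness Y > 150 — impossible when
  dark nuclei cover two thirds of the frame (Y ≤ 0.34·246 + 0.66·35 ≈
  107).

The synthetic subtype quadruples (`make_subtype_case()`) therefore state
two worlds: Luminal B, HER2-amplified and basal-like cases run the full
literal chain (dark stains, default configuration); the Luminal A case
uses bright in-band stains and classifies with
`segment_stage = "filtered"`, the package's documented switch for
thresholding the unamplified filtered image. Both parameterizations are
fixed a priori from the band/gain arithmetic above, not tuned.

## The synthetic generator: what it emulates, what it does not

`make_ihc_image()` emulates the structure of the closed clinical dataset
at desk scale (default 512×512 instead of 4096×3286): a bright field
(luma ≈ 245), brown-ish elliptical positive nuclei whose luma is
controlled exactly (the hue offset is orthogonal to the luma weights, so
the rendered luma equals the requested level up to rounding), cool-blue
negative nuclei, and whole-pixel salt-and-pepper noise at an exact count.
Positive nuclei are non-overlapping by default; above 45% coverage
random non-overlapping placement cannot converge (the jamming limit for
random sequential placement of discs is ≈ 0.55), so overlap is then
permitted and the exact union mask remains the ground truth. The last
nucleus is shrunk to land the coverage within ±0.01 of the target.

It does **not** emulate chromatin texture, stain-physics (DAB/hematoxylin
absorbance), uneven illumination, out-of-focus blur, or touching-nucleus
chains beyond tangency. A green recovery test therefore establishes that
the pipeline recovers area and intensity under controlled geometry and
noise — not that it matches a pathologist on clinical material. The
upstream study's clinical accuracy figures are unreproducible here (its
image base is closed) and are deliberately not asserted anywhere.

## Numerical choices

* Median filter borders use half-sample symmetric (reflect) padding; the
  brute-force test oracle implements the same rule independently.
* MSE/PSNR use MAX = 255 and joint averaging over channels; PSNR of
  identical images is `Inf`, which the window rule maps to 3×3.
* `apply_gain()` rounds half-up (`floor(x + 0.5)`), so integer gains are
  exact integer multiplications before saturation.
* The distance transform is the exact Euclidean transform (two-pass
  parabolic envelope), not a chamfer approximation.
* Watershed flooding breaks priority ties FIFO, making label assignment
  deterministic; labels are assigned in column-major scan order.
* δS is an exact ratio of integer pixel counts.

## Known limitations

* The watershed ridge ring costs roughly one pixel of perimeter per
  object, a relative area loss of ~1.3/r for radius-r nuclei: ~5% for
  r = 30, ~13% for r = 10. The recovery tolerance (±0.05 absolute on δS
  at 25% coverage) absorbs this, but very small nuclei bias δS low.
* α = 20 (and any gain on a bright frame) saturates most pixels; the
  literal chain is kept as published, with `segment_stage = "filtered"`
  as the documented escape hatch.
* PRKI is computed and reported but used by no published rule system.
* Only 8-bit PNG/TIFF/JPEG input is supported; whole-slide formats and
  color management are out of scope, as is deriving the histological
  grade from the histology image (the grade is user input).
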