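---
title: "CTC enumeration and purity-adjusted somatic calling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CTC enumeration and purity-adjusted somatic calling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcflow)
```

`ctcflow` covers the two computational halves of a circulating-tumor-cell
(CTC) assay downstream of microfluidic enrichment: counting CTCs on
three-channel immunofluorescence images, and calling somatic mutations
from amplicon deep sequencing of the same enrichment output. This
vignette is the package's account of the underlying models, the defaults
and why they were chosen, and what the synthetic benchmarks do and do not
demonstrate.

## The enumeration model

A stained enrichment slide carries three channels: DAPI (DNA, all
nucleated cells), CK/EpCAM (epithelial markers, labeling CTCs), and CD45
(pan-leukocyte marker, labeling WBCs). Enumeration proceeds in seven
steps, each an exported function:

1. **Segmentation** (`segment_primary`). A single global threshold over
   the DAPI channel separates nuclei from the uniform fluorescent
   background. The *strategy* is pluggable — `"otsu"` (default),
   `"fixed"`, `"quantile"` — because a global threshold is a family of
   estimators, not one; Otsu's criterion is the natural default for
   bimodal fluorescence histograms. Foreground is split into 4-connected
   components, holes are filled, and objects touching the image border
   are removed, since a cell cut by the field of view cannot be measured.
2. **Size filtering** (`filter_primary`). Nuclear equivalent diameter
   `2·sqrt(area/π)·pixel_size` must lie in the closed interval
   [9, 36] µm. The bounds are inclusive: "9 to 36 µm" reads as a closed
   interval, and half-open variants would silently drop boundary nuclei.
3. **Shape filtering** (same call). Eccentricity of the best-fit ellipse
   (via second central moments; ratio of between-foci distance to major
   axis length; 0 = circle, values guaranteed in [0, 1]) must not exceed
   `eccentricity_max`. This excludes granulocytes and other WBCs with
   lobed, irregular nuclei. No published cutoff exists for this filter,
   so the package requires it in `gate_config` with a default of **0.80**
   and reports it in output metadata: 0.80 sits between rasterized round
   nuclei (ecc ≲ 0.2 at these sizes) and the two-lobe footprint
   (ecc ≈ 0.78–0.9 for lobe spacing 0.6 diameters).
4. **Secondary objects** (`expand_secondary`). Marker intensity is
   measured slightly beyond the nuclear mask, since CK/EpCAM and CD45 are
   cytoplasmic/surface stains. With no membrane channel in the panel,
   secondary objects are a distance-limited expansion (default 3 px) with
   contested pixels assigned to the nearest primary object (ties to the
   lower label, deterministically) — not a watershed, which would need a
   gradient image that this panel cannot provide. Expansion never merges
   objects.
5. **Intensity measurement** (`measure_intensity`): the arithmetic mean
   of channel pixels under each secondary label.
6. **Gate calibration** (`calibrate_gates`). Positive thresholds are
   `mean + k·SD` of an isotype-control (negative) population per channel,
   the standard flow-cytometry-style negative-control gate; `k = 3` by
   default. If fewer than 90% of a positive-control population exceeds
   the CK/EpCAM gate, a calibration warning is raised.
7. **Classification and enumeration** (`classify_cells`,
   `enumerate_cells`). CTC = CK/EpCAM > gate and CD45 ≤ gate;
   dual-positive = both above; WBC = CD45 only; negative otherwise — a
   partition, every cell in exactly one class. CTC purity is
   CTC/total; with zero cells it is *undefined* (flagged), never 0,
   because a purity of 0 is a meaningful measurement and an empty slide
   is not.

Pixel↔µm conversion is always explicit through `pixel_size` (default
0.5 µm/px, configurable everywhere): no imaging metadata is assumed.

## The synthetic image generator

`generate_fixture` renders cells as constant-intensity disks on a
constant background, adds i.i.d. Gaussian noise (clipped at zero), and
returns the ground-truth cell table. Lobed WBC nuclei are unions of
`n_lobes` overlapping disks spaced 0.6 diameters apart — a controllable
way to produce elongated footprints without modeling real neutrophil
morphology. Cells are placed by rejection sampling (up to 1000 retries)
with an 8 px margin between bounding footprints so that rasterized nuclei
and their 3 px secondary expansions never touch.

What the generator deliberately does **not** emulate: point-spread
functions, illumination gradients, autofluorescence, staining
heterogeneity within a cell, and cell clumps/doublets. Passing the
end-to-end recovery test on these fixtures therefore shows that the
pipeline's geometry, measurement and gating logic are correct — not that
the default gates would separate classes on real microscopy data, where
calibration against the two staining controls is essential.

## Biomarker statistics

`roc_curve` computes AUC by the rank (Mann–Whitney) statistic — the
probability that a random cancer sample outscores a random healthy one,
ties counting ½ — rather than by curve integration, so tied integer
counts are handled exactly; the two agree (a property test checks the
trapezoid identity, and pROC is a cross-check). Operating points use the
strict rule "count > cutoff is positive", matching half-integer cutoffs
on integer counts. `reproducibility_cv` uses the sample SD (n−1) and
flags CV as undefined when the replicate mean is 0.

## The sequencing model

**Library.** The two-step PCR construct is
`[P5][diversifier][fwd primer][insert][rc(rev primer)][diversifier][rc(P7)]`,
coordinates 0-based half-open, segments tiling the sequence exactly. The
diversifier is 10 i.i.d. uniform random bases; whether it sits on both
ends or only the P5 side is flag-controlled (`diversifier_both_ends`,
default both, the symmetric design). Default adapters are labeled
placeholders of realistic lengths (28/24 nt); real panels supply their
own via YAML. Trimming matches the P5 adapter as a prefix with ≤2
substitutions and no indels (synthetic reads carry no indels), then
locates the reverse primer to delimit the insert, tolerating partial
3'-truncated matches with a mismatch budget that scales with overlap
length.

**Read counts.** Alignment is out of scope — amplicon positions are known
by construction — so the simulator works at pileup level: tumor variant
reads ~ Binomial(coverage, VF + e·(1−VF)) and normal variant reads ~
Binomial(coverage, e), with e the probability of an error producing the
specific alt allele (default 1×10⁻⁴, post-filter Illumina-like; reported
in benchmark metadata). Default coverage is 4×10⁵, the magnitude of the
clinical amplicon coverages. The spiked cell-line variant is treated as
homozygous, so spike fraction = expected VF — the only mapping consistent
with the published dilution levels (0.08%, 0.8%, 2.68%, 8% at spike
fractions of the same values); heterozygous loci contribute VF/2.

**Caller.** The somatic test is the one-tailed Fisher's exact test on the
2×2 tumor/normal × ref/var table. Conditioned on margins the tumor
variant count is hypergeometric and the p-value is the exact upper tail,
evaluated through the log-space hypergeometric tail (`phyper`), finite in
log form even when the p-value underflows doubles (`log = TRUE`). One
tail, not two, because somatic calling is directional (tumor
enrichment). Purity adjustment is implemented as multiplicative scaling:
`effective_min_vf = base_min_vf × purity` (floored at 10⁻⁴). The
upstream description of "adjusting the VF threshold by purity" does not
state a formula; multiplicative scaling is the natural reading — a
clonal variant in a sample of purity ρ appears at ρ times its
cell-level VF — and it is documented, configurable, and overridable by a
fixed threshold (set `purity = 1`). The germline guard
(normal VF ≤ 1%) exists because at coverage 4×10⁵ even a tiny tumor/normal
VF imbalance at a germline het site is "significant"; significance alone
must not suffice. Consensus requires the call in **all** replicates with
p < 0.05 each — the published duplicate rule generalized to k ≥ 2.

## Benchmarks and problem sizes

The package's own test suite runs everything at the assay's stated
conditions, sized to finish in well under a minute per block:

- end-to-end enumeration on 100 noise-free, separable fixtures
  (192×192 px, 2–15 round-nucleus cells each) demands exact ground-truth
  recovery. Round nuclei are used because `ground_truth_counts` counts
  *all* rendered cells while the eccentricity filter intentionally drops
  lobed ones — that exclusion is tested separately;
- Fisher p against a full lchoose-based enumeration over every 2×2 table
  with per-sample coverage ≤ 30 (~244k tables, max relative error
  observed ~3×10⁻¹⁴);
- build→read→trim round-trip identity over 10⁴ random inserts of 15–60 nt;
- dilution linearity over 100 seeded series (10 points across the four
  non-zero published levels, coverage 4×10⁵): slope ≥ 0.966 and
  R² ≥ 0.997 required in ≥95 runs;
- duplicate consensus at 0.8% VF, 5 samples, 100 seeds: sensitivity 100%
  and consensus FDR ≤ single-replicate FDR in every run.

Under this error model the decoy loci sit at VF ≈ 10⁻⁴, far below the
purity-adjusted threshold (1.6×10⁻³ at purity 0.8%), so false positives
are essentially absent and both FDRs are typically 0. Real sequencing
adds alignment artifacts, strand bias and context-dependent errors that
this simulator does not model; the published gain of consensus calling
(PPV rising from 25% to 75% in duplicates) reflects exactly the error
classes that are out of scope here, so the benchmark checks the
direction of the effect (consensus never worse) and the sensitivity,
not those PPV magnitudes.

## Numerical and degenerate-input choices

- Constant DAPI images yield zero objects, not an error; empty masks
  yield empty measurement tables; an empty record list gives
  purity = undefined.
- Eccentricity is clamped into [0, 1] against floating-point excursions.
- Secondary-expansion ties go to the lower label; relabeling after
  border removal keeps labels contiguous, so label k is always row k.
- Sub-seeds for replicate r and series point i are derived linearly from
  the master seed modulo 2³¹−19, keeping every derived seed a valid R
  integer; replicate 1 reproduces the single-draw result exactly.
- `fit_linearity` computes R² as 1 − SSres/SStot directly, avoiding
  `summary.lm`'s perfect-fit warning on exact lines.

## Known limitations

Enumeration assumes non-touching cells (no declumping/watershed);
heavily confluent slides violate the generator's own placement rule.
The intensity model has no spatial structure, so gate separability on
fixtures is optimistic. The caller handles SNVs only — no indels, LOH
tiers, or strand-bias filters — and the purity scaling is a documented
interpretation, not a published formula. Survival analysis, logistic
regression and cohort-level clinical statistics are intentionally not
implemented.
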