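---
title: "Quantifying phase-separation assays: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phase-separation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condquant)
```

This vignette is the package's account of the science behind each
quantification step: the models and their assumptions, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, and the numerical decisions taken where the conventional
descriptions of these analyses leave room.

## Droplet segmentation and partitioning

In vitro phase-separation assays image fields containing bright liquid
droplets (the dense phase) on a dim background (the dilute or light phase).
The pipeline is:

1. **Dark-frame subtraction.** A shutter-closed calibration image estimates
   the camera offset; its *scalar mean* is subtracted from every pixel.
   Negative results clamp to zero, because detector counts are
   non-negative. No flat-fielding or photometric calibration beyond this is
   attempted: partition coefficients are intensity *ratios*, so a uniform
   gain cancels.
2. **Threshold.** `T = mean(image) + k · sd(image)` with the dimensionless
   user parameter `k = 3` by default. A k·σ rule is the conventional
   reading of a single unitless threshold parameter; `k` is exposed in
   `mask_params()` because dim, low-contrast condensates can require
   lowering it.
3. **Despeckle.** A median filter of radius 2 pixels (circular window, 13
   pixels, as rank filters in Fiji-style tools use) identifies spurious
   detections. We deliberately use the filter as a *detector* of speckle
   rather than as a mask transform: connected components of the raw
   threshold mask that vanish entirely under the median (isolated hot
   pixels, shot-noise islands) are removed, while components that survive
   keep their full thresholded extent. A literal median of the binary mask
   erodes the rim of every small droplet (a hard-edged 5-pixel-radius disk
   loses ~15 % of its pixels), which would bias measured areas and push
   rim pixels at dense-phase intensity into the light-phase average,
   corrupting both PC and RC. With the component-survival rule, segmented
   areas equal the true rasterized droplet areas on synthetic fields, and
   the package's exactness tests (below) hold. Both alternatives remain
   available (`median_on = "mask"` is this default; `median_on = "image"`
   median-filters the grayscale image before thresholding).
4. **Labeling.** 8-connected components, labeled `1..n` in raster-scan
   order of their first pixel so labels are reproducible; components
   smaller than `min_area_px = 4` pixels are dropped (single-pixel
   survivors carry no area information). Droplets touching the border are
   retained — excluding them would bias fields with large droplets, and the
   standard analysis states no such exclusion.

Per field and channel: `I_DP` is the *unweighted* mean of per-droplet mean
intensities (each droplet counts once, regardless of size), `I_LP` the mean
over every unmasked pixel (no exclusion buffer around droplets), and

$$PC = I_{DP}/I_{LP}, \qquad RC = I_{in}/(I_{in}+I_{out}),$$

with `I_in`/`I_out` the integrated intensities inside/outside the mask. A
field with no droplets has `RC = 0` by convention and an undefined `PC`
(reported `NA` with a flag). In two-channel experiments the mask is built
from the protein channel only and applied to the RNA channel, so RNA
enrichment is measured inside protein-defined droplets — this is what lets
a uniform (non-partitioning) RNA report `PC ≈ 1` rather than failing to
segment.

```{r droplets}
f <- gen_droplet_field(droplet_field_spec(n_droplets = 6, seed = 1),
                       channel2 = list(I_dense = 50, I_dilute = 5))
tc <- field_quant_two_channel(f$image, f$channel2)
c(protein_PC = tc$protein$PC, rna_PC = tc$rna$PC, truth_PC = f$truth$pc)
```

## FRAP correction and recovery fitting

Fluorescence recovery after photobleaching reports molecular exchange
between a condensate and its surroundings. Three region-mean traces are the
input contract (ROI extraction from images is out of scope): the bleach
region `BL`, an unbleached reference `REF`, and a background `BG`. The
double normalization

$$BL_{corr2}(t)=\frac{BL(t)-BG(t)}{REF(t)-BG(t)},\qquad
  BL_{corr3}(t)=\frac{BL_{corr2}(t)}{\langle BL_{corr2}\rangle_{pre}}$$

has two exact properties the tests rely on: any *multiplicative*
acquisition photobleaching shared by `BL` and `REF` cancels identically,
and the pre-bleach mean of `BL_corr3` is 1 by construction (the "100 %
fluorescence" level). The pre-bleach level is taken as a mean over all
pre-bleach frames rather than a single frame — with typical frame noise
this halves the variance of the normalization constant and costs nothing.

The recovery model is a single exponential,
$f(t') = plateau - (plateau - f_0)e^{-t'/\tau}$, fit by Levenberg–Marquardt
least squares (`minpack.lm`) on the post-bleach frames with `t'` measured
from the first post-bleach frame. A single exponential is the minimal model
for an "exponential-recovery-shaped" curve; reaction-diffusion FRAP models
and double-exponential selection are deliberately out of scope. `f0` is
pinned to the first post-bleach observation by default (it is a measured
quantity, and freeing it trades bias for variance on short traces); a
free-`f0` fit is available via `fix_f0 = FALSE`. Starting values are the
tail mean (plateau) and the 63 %-crossing time (τ); on noiseless synthetic
traces the fit recovers the generating parameters to ~1e-6.

The mobile fraction is $(plateau - f_0)/(1 - f_0)$ on the normalized scale.
Degenerate inputs are handled explicitly: a flat post-bleach trace returns
mobile fraction 0 with a `"flat"` flag (and no τ), and a fitted plateau
below `f0` is reported with mobile fraction 0 and a flag rather than a
negative fraction.

```{r frap}
g <- gen_frap_trace(frap_trace_spec(f0 = 0.3, plateau = 0.7, tau_s = 10,
                                    acquisition_bleach_rate = 0.002))
fit <- fit_recovery(correct_trace(g$trace))
unlist(fit[c("f0", "plateau", "tau_s", "mobile_fraction")])
```

## Puncta dissolution

Aliphatic alcohols such as 1,6-hexanediol dissolve liquid-like condensates;
the readout is the number of puncta surviving over time, with the moment of
addition as time 0. We read "surviving puncta" as per-frame object counts
normalized to the count at `t = 0` — no frame-to-frame identity tracking —
because per-field counts are what a survival plot needs and tracking would
add failure modes without changing the statistic. Counting reuses the
droplet mask (so survival is invariant under uniform intensity rescaling:
the threshold is an image statistic), frames before `t = 0` get negative
times and are excluded from normalization, and `dissolution_half_life()`
estimates a first-order rate by log-linear regression on the nonzero
post-treatment counts.

## Sequence profiles and mutants

The net-charge-per-residue (NCPR) profile uses a 5-residue sliding window
with R/K = +1 and D/E = −1. Histidine is scored 0: at cytosolic pH its
charge is partial at best, and the basic-residue mutagenesis class in this
line of work is defined as arginine/lysine. Values are reported at window
centers (a window starting at `i` reports at `i + 2`), and terminal
positions without a full window are omitted rather than padded — padding
fabricates values at exactly the positions where charge clusters at a
domain boundary matter.

Substitution rules are residue-class rewrites over a 1-based interval
(e.g. every Y in residues 128–324 replaced by S). The "Y to S/A" naming
ambiguity for the cellular construct is resolved as all-tyrosines-to-serine
by default — the purified-protein construct is named "Y to S" — and an
alternating or custom mapping can be expressed through
`substitution_rule()` directly. `ctd_substitution_rules()` provides the
canonical set (Y→S, Y→A, RK→G, DE→G, QN→G, VMF→A) over residues 128–324,
the C-terminal disordered domain in the standard 324-residue numbering.
Disorder prediction itself (IUPred-style) is an external published tool and
is not reimplemented.

## Overlap and enrichment statistics

Gene-set overlaps are exact set intersections after deterministic
normalization (trim, upper-case, de-duplicate); percentages are relative to
the *reference* set (the published proteome whose size is the denominator,
e.g. 125 P-body or 411 stress-granule proteins). No alias or ortholog
resolution is attempted — determinism and auditability beat recall here —
but a user-supplied alias map is accepted. No significance testing is
attached, as none is standard for these descriptive percentages.

qPCR fold changes use `2^(Ct_cell − Ct_exo)` with measurements above Ct 40
flagged negative instead of being given a numeric value. Normalization of
RT input mass (e.g. 10 ng cellular vs 2 ng exosomal RNA) is left to an
explicit user-side scaling, since it belongs to the assay design rather
than the ΔCt arithmetic.

## The synthetic-data generator

Every generator is a pure function of its spec and seed (bit-identical
reruns, seeds restored afterwards), and every dataset ships with ground
truth computed *analytically from the spec*, never from the rendered
pixels.

- **Droplet fields**: hard-edged rasterized disks at `I_dense` on an
  `I_dilute` background, camera offset everywhere, optional additive
  Gaussian read noise, optional second channel on the same disks, and a
  matching dark frame. Hard edges are the default precisely so that
  `PC = I_dense/I_dilute` and
  `RC = A_{in}I_{dense}/(A_{in}I_{dense}+A_{out}I_{dilute})` are exact;
  an optional Gaussian blur exists for realism tests, at the cost of those
  identities. Disks are placed non-overlapping (and non-adjacent) by
  rejection sampling, so the component count equals the droplet count.
  Noise is additive Gaussian (read noise); Poisson shot noise is omitted by
  default for analytic tractability.
- **FRAP traces**: the normalized recovery curve, times a per-frame
  multiplicative acquisition-bleach factor and an arbitrary scale, plus
  background and noise; the reference region sees the same bleaching
  factor. Default acquisition geometry is 2 s/frame × 120 frames (a
  live-cell protocol); 1 s × 60 and 30 ms × 40 variants are spec changes.
- **Dissolution stacks**: each punctum independently survives each frame
  interval with probability `exp(−λΔt)`; expected survival is `exp(−λt)`.
- **Gene sets**: synthetic identifiers (prefixed `SYN-`) with an exactly
  constructed intersection.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: optical blur and the microscope PSF, shot noise,
uneven illumination, out-of-focus light, droplet coalescence or motion
during acquisition, diffusion physics within the bleach spot, and biological
heterogeneity between fields. The generator validates the *arithmetic* of
the pipeline under its stated model; accuracy on real images still depends
on acquisition quality and threshold choice.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 128×128- to
256×256-pixel fields with 3–8 droplets of radius 3–10 px, 50–100 fields per
exactness sweep, 50 noisy FRAP traces (normalized noise sd 0.02), and 50
dissolution stacks of 30 puncta × 8 frames. These sizes were chosen so the
whole validation runs in well under a minute on a laptop while keeping the
Monte-Carlo error of recovered parameters a few-fold below the tolerances
being asserted; all statistics scale to larger fields unchanged.

## Known limitations

- The k·σ threshold assumes droplets occupy a minority of the field; very
  dense fields raise the threshold and under-segment (lower `k_user`).
- Touching puncta merge under 8-connectivity and count as one object; no
  watershed splitting is attempted.
- `I_LP` uses every unmasked pixel with no perimeter buffer; a bright halo
  around droplets (out-of-focus light) would inflate it and depress PC.
- The single-exponential FRAP model summarizes, but does not resolve,
  multi-component exchange; τ from visibly bi-phasic traces should be
  treated as an effective time constant.
- Exact reproduction of published overlap counts depends on matching the
  identifier space (gene symbol vs accession) of the source lists; the
  normalization here is deliberately minimal.
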