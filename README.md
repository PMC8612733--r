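# condquant

Quantification toolkit for liquid-liquid phase separation (LLPS) experiments
on RNA-binding proteins and their condensates. It covers the desk half of a
typical condensate study: turning fluorescence microscopy of in vitro
droplets and cellular puncta, FRAP acquisitions, protein sequences, and
qPCR/proteomics tables into the numbers a paper reports — partition
coefficients, condensed fractions, recovery kinetics and mobile fractions,
puncta survival curves, charge profiles of disordered regions, and gene-set
overlap statistics.

It is written for bench scientists and analysts who have (or simulate)
two-phase droplet images and FRAP region traces and want reproducible,
tested implementations of the standard quantification rules, plus a
synthetic-data generator with *analytic* ground truth so every stage of the
pipeline can be validated end to end without any raw data.

## The quantities

**Droplet segmentation and partitioning.** After dark-frame subtraction, a
droplet mask is built by thresholding at `T = mean + k·sd` (user parameter
`k`, default 3), despeckling with a radius-2 circular median filter, and
8-connected component labeling. For each field and channel:

- `I_DP` — average of the per-droplet mean intensities (dense phase),
- `I_LP` — mean intensity outside the mask (light phase),
- partition coefficient `PC = I_DP / I_LP`,
- relative condensed fraction `RC = I_in / (I_in + I_out)`, the share of the
  field's integrated fluorescence inside the mask (`RC = 0` when no droplet
  is present).

For two-channel assays (e.g. a GFP-tagged protein with a Cy5-labeled
miRNA), the mask comes from the protein channel only and is applied to both
channels, so the RNA's `PC`/`RC` measure its recruitment into
protein-defined droplets.

**FRAP.** Region-mean traces (bleach `BL`, reference `REF`, background
`BG`) are double-normalized,

    BL_corr2(t) = [BL(t) − BG(t)] / [REF(t) − BG(t)]
    BL_corr3(t) = BL_corr2(t) / ⟨BL_corr2⟩_prebleach,

which cancels multiplicative acquisition photobleaching exactly and pins the
pre-bleach level to 1. The post-bleach trace is fit with a single
exponential `f(t′) = plateau − (plateau − f0)·exp(−t′/τ)` (`f0` pinned to
the first post-bleach point), giving `τ`, the half-time `τ·ln 2`, and the
mobile fraction `(plateau − f0)/(1 − f0)`.

**Puncta dissolution.** Per-frame puncta counts after a condensate-dissolving
treatment (e.g. 1,6-hexanediol), normalized to the count at the treatment
time (`t = 0`), with a log-linear estimate of the dissolution rate and
half-life.

**Sequence features.** Net charge per residue (NCPR) with a 5-residue
sliding window (R/K = +1, D/E = −1, H = 0), residue-class composition of a
region (Y, R/K, D/E, Q/N, V/M/F), and construction of residue-class
substitution mutants (e.g. "CTD-Y to S", "CTD-RK to G" over residues
128–324) and deletion variants.

**Tabular statistics.** Gene-set overlaps with percentages relative to a
reference proteome, qPCR fold changes `2^(Ct_cell − Ct_exo)` with the Ct>40
negativity rule, and relative exosomal enrichment as a ratio of fold
changes.

## Worked example

Simulate a dual-channel droplet field with known ground truth, quantify it,
and fit a FRAP trace:

```r
library(condquant)

spec <- droplet_field_spec(shape = c(256L, 256L), n_droplets = 8,
                           I_dense = 100, I_dilute = 10,
                           camera_offset = 20, noise_sd = 2, seed = 42)
field <- gen_droplet_field(spec, channel2 = list(I_dense = 50, I_dilute = 5))

img  <- subtract_dark_frame(field$image,    field$dark)
rna  <- subtract_dark_frame(field$channel2, field$dark)
mask <- make_droplet_mask(img, mask_params(k_user = 3, median_radius_px = 2))
mask
#> <droplet_mask> 256 x 256 px, 8 droplets

field_quant(img, mask, channel_name = "protein")
#> <field_quant> [protein] 8 droplets; I_DP = 99.9, I_LP = 10.02, PC = 9.974, RC = 0.1372
field_quant(rna, mask, channel_name = "miR-223")
#> <field_quant> [miR-223] 8 droplets; I_DP = 49.95, I_LP = 4.992, PC = 10.01, RC = 0.1376

g   <- gen_frap_trace(frap_trace_spec(f0 = 0.2, plateau = 0.7, tau_s = 15,
                                      frame_interval_s = 2, n_frames = 120,
                                      acquisition_bleach_rate = 0.001,
                                      noise_sd = 10, seed = 42))
fit <- fit_recovery(correct_trace(g$trace))
fit
#> <frap_fit> f0 = 0.197, plateau = 0.691, tau = 15 s (t1/2 = 10.4 s), mobile fraction = 0.615
recovery_at(fit, 90)
#> [1] 0.6895225
```

The protein partitions ten-fold into the droplets (`PC ≈ 10`, the generating
dense/dilute ratio), the RNA channel is read against the protein mask, and
the fitted recovery says ~69 % of the bleached fluorescence returns within
90 s — the kind of value that distinguishes a liquid-like condensate from a
gel.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "condquant", package = "condquant")` with
subcommands `droplets`, `frap`, `puncta`, `ncpr`, `mutate`, `overlap`,
`enrich`, and `simulate`; every run writes a JSON manifest recording inputs,
flags, and seed.

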