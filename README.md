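# bnbquant

Semiquantitative analysis of tight-junction protein (TJP) immunofluorescence
at the blood-nerve barrier.

After traumatic peripheral-nerve injury the perineurium — the cell sheath
sealing each nerve fascicle — loses its barrier organization: claudin-1 and
ZO-1 leave the perineurial cell-cell contacts, overall immunoreactivity
drops, and TJP mRNA is downregulated. `bnbquant` implements the full
measurement chain used to quantify these changes on 8-bit RGB TIFF z-stacks
of immunostained nerve cross sections, together with a synthetic image
generator with known ground truth so the whole chain is testable without a
deposited dataset.

## What it computes

**Normalized immunofluorescence intensity (NIFI)** per compartment ROI
(perineurium, endoneurium, whole fascicle), with three-area background
correction:

    IntD = area × mean intensity
    IntC = IntD − area × mean(3 background-area means)
    NIFI = IntC / area = mean − background mean

aggregated by nested means over up to 3 z-slices and up to 3 fascicles per
animal.

**Contact-peak analysis** — an algorithmic score of junctional TJP
localization: perineurial gray statistics → QC discard at mean gray ≥ 143.33
→ subtraction of 1.5 × mean (8-bit floor) → Gaussian blur (σ = 2 px) → five
line profiles over the perineurium (bilinear, 1-px steps) → peak calling
(height ≥ 40, prominence ≥ 1.5 × SD, spacing ≥ 1 µm, greedy suppression) →
mean peak count over the five lines.

**Delta-Ct qPCR expression**: replicate averaging on the Ct scale,
GAPDH-normalized ΔCt per animal, group ΔΔCt, fold change `2^−ΔΔCt`, percent
change.

**Group statistics**: Friedman ANOVA on ranks with Holm-Šidák step-down post
hoc, Kruskal-Wallis with one-sided Dunn post hoc (reduction vs. sham), paired
t for qPCR, and per-reviewer blinded-rater questionnaire analysis.

**Synthetic cohorts**: seeded fascicle renders (perineurial annulus, diffuse
band signal, Gaussian contact spots on the midline, signal-conserving
internalization, additive noise, 3 z-slices) with ground-truth ROIs, contact
positions, Ct tables and rater tables; per-group effect multipliers on
contact density and staining intensity.

## Worked example

```r
library(bnbquant)

# one synthetic sham fascicle (208×208 px, 0.5 µm/px, 11 true contacts)
fas   <- generate_fascicle(fascicle_params(seed = 7))
masks <- compartment_masks(fas$truth$rois, 208, 208)
img   <- fas$stack$slices[[1]][, , 1]          # claudin-1 channel, slice 1

r <- nifi(img, masks$perineurium, masks$background)
r$NIFI
#> [1] 17.96219

rep <- peak_report(img, fas$truth$rois, pixel_size_um = 0.5)
c(rep$qc_pass, rep$mean_peak_count)
#> [1] 1.0 2.2

tab <- generate_ct_table("claudin-1", n = 8, group_shift = 1.943,
                         noise_sd = 0.3, seed = 1)
delta_ct_expression(tab, "claudin-1")$percent_change
#> [1] 73.60186
```

The perineurial NIFI of 17.96 is the band's mean gray (23.10) minus the mean
of the three background means (5.14) — the staining signal above background.
The mean peak count of 2.2 over five lines recovers the 11 ground-truth
contacts (5 × 2.2 = 11) — each contact crossed by exactly one profile line.
The recovered expression reduction of 73.6% matches the configured ΔΔCt of
1.943 (true reduction 74%) up to Ct noise.

An end-to-end run (simulate → NIFI → peaks → qPCR → statistics → summary,
all artifacts and a parameter manifest written to `outdir`):

```r
res <- run_pipeline(seed = 1, outdir = "bnb_run")
res$summary
```

or from a shell via the thin wrapper:

```sh
Rscript inst/cli/bnbquant.R --config config.yaml --seed 1 --outdir bnb_run
```

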