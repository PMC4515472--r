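# gutquant

Quantification toolkit for studies of adult *Drosophila* midgut remodelling:
image-based counting of lineage-traced intestinal cells, gut morphometry,
lipid staining and TLC densitometry, DART-MS juvenile-hormone titres,
comparative-Ct qPCR, and the statistical layer applied to each readout — all
validated end to end against a ground-truthed synthetic-data generator.

## Who this is for

Labs using the ReDDM (repressible dual differential marker) tracing system,
or similar dual-reporter designs, to measure epithelial turnover. In ReDDM,
intestinal progenitors (stem cells and enteroblasts) carry a membrane GFP
and a persistent nuclear H2B::RFP; progeny born during the tracing window
keep only the RFP. A confocal field of DAPI/GFP/RFP therefore encodes, per
nucleus, both cell identity and birth date — and turning fields into
reliable per-gut counts is exactly the kind of scoring that should not be
done by eye.

## What it computes

For each gut image (multi-page TIFF via `read_stack_tiff`, or any
`channel_stack`), `reddm_quantify()` produces:

- **nucleus segmentation** from DAPI (Gaussian smoothing, half-maximum
  threshold above the tissue floor, watershed splitting);
- **ploidy classes** from nucleus area (polyploid = enterocyte), with an
  automatic two-class split of log-areas;
- **lineage classes** from marker overlap: GFP⁺RFP⁺ progenitors, GFP⁻RFP⁺
  newly generated progeny, RFP⁻ pre-existing cells (the ReDDM logic), with
  biologically impossible GFP⁺RFP⁻ nuclei surfaced as an anomaly count;
- **morphometry**: tissue area from background staining, cell density,
  gut diameter along the image-centre line.

Companion assays: `oro_score` (Oil Red O `max(R−G, 0)` within an ROI),
`tlc_quantify` (band densitometry above a linear baseline), `signature_mz` /
`extract_ion_intensity` / `fit_calibration` / `quantify_sample` (DART-MS
juvenoid quantification in ng per mg haemolymph), `comparative_ct`
(2^−ΔΔCt with rp49 normalisation), and `nb_glm_lrt`, `welch_t`, `paired_t`,
`mann_whitney`, `holm_adjust`, `hatch_fraction` for the statistics.

The m/z of the signature ions used for juvenoid detection follows from
standard monoisotopic masses: for a molecule M, the protonated ion is
m/z(M + H⁺) and the dehydrated fragment m/z(M + H⁺ − H₂O); for juvenile
hormone III (C₁₆H₂₆O₃) these are 267.20 and 249.18 Th, for methylfarnesoate
(C₁₆H₂₆O₂) 251.20 Th, and for JHIII bisepoxide (C₁₆H₂₆O₄) 283.19 Th.

## Worked example

Every analysis stage can be exercised without microscope data through the
synthetic generator, which renders ground-truthed midgut scenes:

```r
library(gutquant)

p <- scene_params(noise_sd_fraction = 0.1)          # 10% noise, defaults otherwise
scene <- generate_scene(p, condition = "mated", seed = 42)
res <- reddm_quantify(scene$stack)
res
#> ReDDM gut quantification
#> Per-gut cell-class report
#>   nuclei: 122 total | 78 EC (polyploid) | 30 RFP+ | 17 GFP+ | 14 new progeny | 1 anomalous (GFP+ RFP-)
#>   area: 66502 um^2 | density: 1834.5 nuclei/mm^2 | diameter: 222.8 um

truth_report(scene$truth)
#> Per-gut cell-class report
#>   nuclei: 124 total | 78 EC (polyploid) | 32 RFP+ | 18 GFP+ | 14 new progeny
#>   area: 65925 um^2 | density: 1880.9 nuclei/mm^2 | diameter: 219.8 um
```

Reading the numbers: the mated scene truly contains 124 nuclei, of which 14
are newly generated progeny (RFP-only); at 10% noise the pipeline recovers
122 nuclei and the exact new-progeny count. The one anomalous nucleus is a
pre-existing cell that inherited enough ring GFP from an adjacent progenitor
to be flagged — reported, never reassigned. At zero noise the recovery is
exact; `score_scene()` gives per-class precision/recall/F1 against the
truth. `summary(res)` returns the report as a one-row data frame and
`write_reddm_csv()` exports per-nucleus records.

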