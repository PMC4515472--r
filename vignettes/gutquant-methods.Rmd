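---
title: "Quantifying mating-induced midgut remodelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mating-induced midgut remodelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutquant)
```

# The biological measurement problem

After mating, the *Drosophila* female midgut grows: intestinal stem cells
(ISCs) divide more, and newly born enterocytes (ECs) and enteroendocrine
cells accumulate. The ReDDM dual-marker tracing system makes this visible in
a single confocal field: progenitors (ISCs and enteroblasts) express a
membrane-bound GFP and a persistent histone-bound nuclear RFP; progeny born
during the tracing window have switched off the GFP driver but retain the
stable H2B::RFP, so an RFP-only nucleus dates the cell's birth to the
window. `gutquant` turns such fields into per-gut counts, and implements the
companion assays of the same study design — gut morphometry, Oil Red O and
TLC lipid quantification, DART-MS juvenile-hormone titres, comparative-Ct
qPCR — together with the statistical layer used on each readout.

# The ReDDM quantification pipeline

`reddm_quantify()` chains five stages, each available separately:

1. **Maximum projection** (`max_project`): confocal z-stacks collapse by
   per-pixel maximum.
2. **Tissue detection** (`detect_gut_area`): the gut is located by its
   diffuse background staining. The summed channels are smoothed with a
   Gaussian specified in physical units (`gut_blur_sigma_um`, default 6 µm,
   so the boundary localisation does not change with magnification) and
   thresholded 45% of the way from the empty-background level (1st
   percentile) to the median tissue level. A global histogram split (Otsu)
   is the wrong tool here — when tissue fills most of the frame it splits
   the within-tissue variation instead of tissue against background. The
   mask is closed (disc radius `gut_close_radius_um`, default 8 µm, with
   replicate padding so tissue touching the frame edge is not eroded),
   hole-filled, and reduced to its largest connected component.
3. **Nucleus segmentation** (`segment_nuclei`): Gaussian smoothing
   (`smoothing_sigma_px`, default 1 px), then a threshold at the midpoint
   between the tissue floor (within-mask median) and the robust peak level
   (99.9th percentile) — the half-maximum above background, which stays put
   however small a fraction of the tissue the nuclei cover, where a
   histogram split would collapse. A distance-map watershed
   (`watershed_tolerance_px`, default 0.5 px) splits touching nuclei, and
   objects below `min_nucleus_area_um2` (default 6 µm²) are removed.
   Thresholding runs on the full frame and tissue membership is decided by
   each object's centroid against the mask dilated by half the detection
   blur sigma — the tissue boundary is only localised to about that scale,
   and clipping nuclei by an approximate boundary would corrupt their areas.
4. **Ploidy classification** (`classify_ploidy`): a nucleus is polyploid
   (an EC) iff its area reaches `ploidy_area_threshold_um2`. The default
   `"auto"` mode places the threshold at the midpoint of the two-class
   minimum-within-variance split of log-areas, exploiting the strong
   bimodality of diploid (~20 µm²) versus polyploid (~110 µm²) nuclei. With
   fewer than four nuclei the split is undefined; the pipeline then falls
   back to a fixed 50 µm² cut, which sits between typical diploid midgut
   nuclei and polyploid ECs.
5. **Lineage classes** (`assign_cell_classes`): H2B::RFP is nuclear, so RFP
   positivity defaults to mask overlap — at least `overlap_fraction`
   (default 0.5) of the nucleus inside the Otsu-thresholded RFP mask.
   mCD8::GFP marks membranes, so GFP is scored in a perinuclear annulus
   (width `gfp_annulus_px`, default 3 px): the mean annulus intensity must
   exceed the GFP channel threshold. Classes follow the tracing logic:
   GFP+ RFP+ = progenitor, GFP− RFP+ = newly generated progeny,
   RFP− = pre-existing cell. GFP+ RFP− combinations are biologically
   impossible under the tracer and are reported as an anomaly count — they
   diagnose segmentation failure and are never silently reassigned.

Channel thresholds carry a signal-presence guard: Otsu is accepted only when
the foreground mean exceeds the background mean by at least four background
SDs; otherwise the channel is treated as unstained and nothing is positive.
This keeps blank or noise-only reporter channels from generating spurious
positives.

The per-gut report gives total nuclei, ECs (polyploid), RFP+ cells, GFP+
cells, new progeny, tissue area (µm²), density (nuclei/mm²) and the gut
diameter measured as the mask extent along the image-centre line — a
reproducible stand-in for the manual line tool.

# Companion assays

**Oil Red O** (`oro_score`): droplet signal is `max(R − G, 0)` averaged over
the hand-drawn ROI. Grey background (R = G = B) cancels exactly; negatives
are clipped so blue/green artefacts cannot register as negative lipid. An
optional minimum-particle-area filter (off by default) mirrors
particle-analysis workflows whose exact role in the original scripts is
unclear.

**TLC densitometry** (`tlc_quantify`): per-lane row profiles with per-band
integrals above a linear baseline interpolated between 3-row medians at the
band-window edges. Raw integrals are reported; per-sample loading
normalisation is the caller's responsibility, as it happens upstream of the
plate.

**DART-MS** (`signature_mz`, `extract_ion_intensity`, `fit_calibration`,
`quantify_sample`): signature ions are computed from molecular formulae with
CODATA monoisotopic masses — protonated molecules, plus the water-loss
fragment for hydroxy/epoxide compounds such as JHIII. Peak abundance is the
maximum within ±`tol` of the target (default 0.05 Th: at resolving power
~6000 the peaks are ~0.04 Th FWHM, and a maximum is robust to the window
width where an integral is not). Quantification averages the technical
replicate intensities first, inverts the free-intercept OLS calibration line
(clipping at zero with a below-LOD flag), then normalises to haemolymph
weight. For a linear curve, averaging intensities before inversion and
inverting per replicate give identical answers; intensities-first is
implemented.

**Comparative Ct** (`comparative_ct`): technical triplicates are averaged
per (sample, gene) before any subtraction — the reduction order is a
declared default. ΔCt subtracts the housekeeping gene (rp49) per sample;
ΔΔCt contrasts matched mated and virgin samples within a batch; fold change
is 2^(−ΔΔCt). Any per-sample additive Ct shift applied to all genes cancels
exactly. No amplification-efficiency correction is applied.

**Statistics** (`welch_t`, `paired_t`, `mann_whitney`, `nb_glm_lrt`,
`holm_adjust`, `hatch_fraction`): thin, convention-fixing wrappers over the
canonical R implementations. Mitosis counts are over-dispersed, so groups
are compared by a negative-binomial GLM (variance µ + µ²/θ, θ by ML) with a
likelihood-ratio test against the intercept-only model; when θ estimation
diverges on under-dispersed data the Poisson limit supplies the boundary
likelihood. Mann–Whitney uses the exact U distribution when the combined n
is at most 12 and there are no ties, otherwise the tie-corrected normal
approximation. Holm families are always declared explicitly by the caller;
the package never guesses which comparisons form a family. Multi-group count
panels are analysed as pairwise fits with Holm correction, mirroring how
such comparisons are conventionally reported.

# The synthetic-data generator

Every pipeline stage is validated against `synthetic_*` generators with
known ground truth, because the assays' raw images are not redistributable
and desk-scale re-runs of fly experiments are impossible. All generators are
pure functions of (parameters, seed).

`generate_scene()` renders a midgut field: a horizontal tissue band with
diffuse DAPI background staining (15% of nucleus amplitude — the signal by
which real guts are outlined), nuclei placed by hard-core rejection
sampling, DAPI disks for all nuclei, RFP disks for RFP+ nuclei, GFP
membrane rings (1.5 µm) for progenitors, then PSF blur (σ 1 px), optional
linear background gradient, and additive Gaussian noise clipped at zero.

Default composition (a declared knob, not a measured biological magnitude —
the study reports directions and significance, not per-field counts): 60
pre-existing ECs, 25 pre-existing diploids, 12 progenitors, 4 new ECs, 2 new
EECs per virgin field of 300 × 300 µm (400² px at 0.75 µm/px, band height
220 µm); mating multiplies the new-progeny means by 3 and the progenitor
mean by 1.5. Radii are truncated normal at ±2 SD (diploid 2.5 ± 0.3 µm,
polyploid 6 ± 0.8 µm): truncation keeps the two size classes disjoint so
that ploidy is decidable from area, which in turn makes exact zero-noise
recovery a meaningful test rather than a coin flip on tail draws. Default
noise is 10% of the signal amplitude.

What the generator does *not* emulate: staining heterogeneity within nuclei,
z-dependent attenuation, EEC/EB morphology differences, regionalisation
(R1–R5), autofluorescent debris, and nucleus shapes beyond disks. Passing
closed-loop tests therefore demonstrates the correctness of the
quantification logic under controlled degradation, not performance on real
micrographs.

# Validation suite design and problem sizes

The package's central property is the closed loop: for every generator, the
matching analysis stage at zero noise recovers the programmed truth exactly,
and degrades gracefully with noise. The main suites, with the problem sizes
the tests run at:

- **Zero-noise scene recovery**: scenes with a 1.5 µm placement clearance
  (the exactness property concerns non-touching nuclei; tangent disks merge
  under any finite PSF) reproduce all five report counts exactly.
- **Noisy recovery**: at the default 10% noise with hard-core placement,
  per-class F1 pooled over 20 scenes is at least 0.95.
- **Virgin/mated discrimination**: 100 meta-replicates of 10 virgin + 10
  mated scenes, run at generator scale 0.5 (counts and field area jointly
  halved, preserving density) so that 2,000 full pipeline runs complete in
  a practical time; the negative-binomial LRT on reported new-progeny
  counts must reject at α = 0.05 in at least 90% of meta-replicates.
- **Statistical oracles**: the exact Mann–Whitney path is checked against
  full enumeration for combined n ≤ 10; Holm against hand-stepped values;
  the NB LRT's type-I error over 1,000 null simulations (two groups of 50,
  mean 5, θ = 2) must lie in [0.03, 0.07].
- **Quantification oracles**: ΔΔCt housekeeping-shift invariance and exact
  fold recovery at zero noise; calibration slope recovered within 2% at 1%
  intensity noise; Oil Red O score equal to coverage × ΔRG within 3%; TLC
  Gaussian band integral within 2% of A·s·√(2π).

# Numerical choices and degenerate inputs

- Coordinates are (row, col), 0-based, pixel-centre semantics throughout;
  areas in µm² via the squared pixel size.
- Gaussian smoothing is separable with kernels truncated at 3σ; small
  kernels run as shift-and-add passes with replicated edges, wide kernels as
  banded-matrix products with border renormalisation. Both match FFT
  convolution in the interior to machine precision without wrap-around.
- Otsu thresholds are computed on a 256-bin histogram of the actual value
  range, so planes need not be pre-scaled to [0, 1].
- `adjust_levels` on a constant image warns and returns zeros rather than
  dividing by zero; segmentation of a blank plane warns and returns an
  empty record set; `detect_gut_area` on an all-zero frame errors
  ("no tissue"), and on a constant positive frame returns the full frame.
- Polygon rasterisation uses the even-odd rule with boundary pixels
  included; degenerate (zero-area) and self-intersecting polygons are
  rejected.
- Ties in intensity ranking keep input order, receive mid-ranks, and are
  flagged rather than broken arbitrarily.
- Mann–Whitney switches to the approximate path whenever ties are present,
  regardless of sample size, since the exact U distribution assumes
  continuity.

# Known limitations

- The pipeline is 2-D: it quantifies projections, not volumes, and cannot
  separate nuclei that overlap along z.
- The GFP annulus rule scores membrane signal around each nucleus; in very
  dense progenitor clusters a pre-existing nucleus adjacent to progenitors
  can inherit enough ring signal to be flagged GFP+ (surfacing as the
  anomaly count when RFP−).
- Auto ploidy thresholding assumes a genuinely bimodal area distribution;
  fields dominated by one class should use a fixed threshold.
- TLC lane and band windows are caller-declared; there is no automatic lane
  finding.
- The DART-MS module quantifies a single signature ion against a linear
  calibration; isotope-pattern matching and non-linear response are out of
  scope.
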