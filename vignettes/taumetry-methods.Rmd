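---
title: "From tau-positive cells to tau-PET signal: the taumetry methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tau-positive cells to tau-PET signal: the taumetry methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taumetry)
```

## The problem

In 4R-tauopathies such as progressive supranuclear palsy (PSP), tau
aggregates accumulate in several cell types with very different morphology:
dense neurofibrillary tangles (NFT) in neurons, coiled bodies (CB) in
oligodendrocytes, diffuse tufted astrocytes (TA), and small tau fragments
(TF). Second-generation tau PET tracers produce an in vivo signal, but the
signal's cellular origin is not observable in the scanner. `taumetry`
implements, as one reusable and testable chain, the quantitative steps that
connect the two scales:

1. **IHC morphometry** — segment AT8-stained objects, describe their shape
   and intensity, and split the tau load into a dense (NFT/CB) and an
   astrocytic (TA/TF) analysis channel;
2. **autoradiography quantification** — subfield binding ratios against an
   AT8-negative white-matter reference, plus the correlation/regression
   battery relating binding to the two channels;
3. **PET kinetics** — Logan graphical analysis with image-derived input
   functions, VT ratio and SUVR readouts, effect sizes, and voxelwise
   regression with cluster filtering;
4. **scRadiotracing arithmetic** — per-cell tracer uptake from sorted cell
   pellets and the census-based extrapolation that predicts the brain-level
   PET increment;
5. **layered cortical sampling** — SUVR profiles on surfaces shifted from
   the GM/CSF boundary to below the GM/WM boundary, where oligodendroglial
   tau concentrates.

Because the underlying real data (animal scans, autopsy tissue) are not
publicly deposited, the package ships a first-class synthetic-data module
that emulates the statistical structure of each input with ground truth
attached. Every claim the test suite makes is a property of the method, not
a reproduction of a tissue measurement.

## Morphometric classification

Objects are connected components (8-connectivity) of the thresholded AT8
raster. The default threshold is Otsu's; a fixed manual threshold can be
supplied, which is how the original workflow operated. Per object we
compute area, equivalent diameter, ellipse axes, perimeter, mean intensity,
circularity $4\pi A/P^2$, roundness $4A/(\pi\,\mathrm{major}^2)$ and
compactness $\sqrt{4A/\pi}/\mathrm{major}$. These names are used by several
commercial packages without published formulas; the definitions above are
the common image-morphometry conventions and are fixed here so results are
reproducible.

Numerical choices worth knowing:

* **Perimeter** uses the 4-direction Crofton intercept estimator
  $P = \tfrac{\pi}{8}\left(c_h + c_v + (c_{d1}+c_{d2})/\sqrt{2}\right)$,
  which is asymptotically exact for smooth shapes (a rasterized disk of
  radius 20 px yields circularity 0.998) but biased for polygons with
  axis-aligned edges (a 10×10 square yields 0.927) and *over*-unity
  circularity for few-pixel specks. Interval rules are calibrated on
  exemplars processed identically, so the bias cancels.
* **Ellipse axes** come from second central moments with the single-pixel
  variance term $1/12\ \mathrm{px}^2$ added, so single-pixel objects have
  finite axes and near-unity roundness instead of degenerate zeros.
* **ROI membership** is pixel-center-in-polygon (even-odd rule), with
  0-based pixel coordinates and the origin at the top-left corner. This
  makes every count in the package an exact integer statement.

Classification is deliberately an axis-aligned interval rule per channel —
the automated analogue of manually derived object thresholds applied
uniformly to all sections — not a trained discriminator. Rules are
calibrated from labelled exemplars (15–20 per class is the intended
regime): NFT and CB exemplars pool into the NFT/CB channel, TA and TF into
TA/TF, because the two pairs overlap too much to separate. An object must
satisfy *all nine* feature intervals of a channel; if both channels match,
mean intensity at or above the NFT/CB intensity threshold routes it to the
dense channel (the tie is broken toward "high density" by definition of
that channel). The rule for combining intensity with shape is not published
anywhere; this tie-break is our documented choice.

The default interval `expansion` is 0.25 of the observed exemplar range per
side. The empirical min/max of $n$ exemplars misses roughly a $1/(n+1)$
tail per side *per feature*, and an object must pass all nine features, so
unexpanded boxes systematically under-assign. With the default generator
morphologies the channels are separated well enough that the widened boxes
stay disjoint; the package's recovery invariant (≥ 95 % agreement with
ground truth) is tested at these defaults.

## The synthetic world

`gen_ihc_section()` renders NFT/CB as filled ellipses (radius 3–7 px, axis
ratio 1–2, intensity ≈ 0.8–0.85 a.u.), TA as stellate radial-arm polygons
(outer radius 12–20 px, 5–8 arms, intensity ≈ 0.35) and TF as ≤ 5 px
specks, on a 0.05 a.u. background at 1 µm/px — the "compact and bright vs
large, faint and spiky" contrast the classifier exploits. Objects are
non-overlapping by rejection sampling, and each planted object is exactly
one 8-connected component. The morphology distributions are stated
conventions: no quantitative morphometric distributions are published for
these lesion types, so the defaults encode the qualitative contrast at
magnitudes plausible for 20× digitized sections. Planted intensities are
clamped to ≥ background + 0.2 so that pixel jitter (sd 2 %) can never
straddle a sensible foreground threshold — without the clamp an object
sitting exactly at threshold fragments unpredictably, which is a
degenerate tie, not an interesting hard case.

`gen_autorad_section()` makes the binding raster a *linear mixture* of the
channel density maps: `background + 40·NFT/CB + 8·TA/TF + noise` by
default. Embedding a much stronger dense-channel gain is the generative
form of the study's central observation — autoradiography signal follows
NFT/CB tau far more than TA/TF tau — so correlation orderings recovered
downstream are recoveries of a planted truth, not discoveries.

`gen_dynamic_pet()` simulates one-tissue-compartment kinetics
$C_T(t) = K_1 e^{-k_2 t} \circledast C_p(t)$ with $V_T = K_1/k_2$ as
ground truth, using the exact exponential-decay trapezoid recursion on a
0.005-min grid (agrees with the closed form for exponential inputs to
≈ 10⁻⁵ relative). The plasma curve is a fast first-pass peak plus a slow
washout tail. Two acquisition schedules are built in; note that the rodent
frame list (6×10, 2×30, 3×60, 5×120, 5×300, 5×600 s — 26 frames) sums to
90 min even though such protocols are commonly described as 0–60 min
windows; the frames are implemented as listed.

`gen_scrad_cohort()` draws per-mouse, per-cell uptake with a lognormal
30 % between-mouse CV around genotype means anchored to the three reported
ratios: transgenic/wild-type neuron uptake 1.89×, neuron/astrocyte 27× in
transgenics and 5× in wild-types. Those three ratios jointly imply an
astrocyte genotype ratio of 1.89·5/27 ≈ 0.35, whereas the source study
reports no significant astrocyte difference — the ratio set is not exactly
self-consistent, and the generator treats the three printed ratios as
primary. Wild-type neuron uptake (1.6×10⁻⁴ Bq/cell) is chosen so that
transgenic per-animal cellular radioactivity lands inside the reported
7.7–36.5 kBq window. With `noise_sd = 0` the PET increment *equals* the
census extrapolation per mouse by construction, which is what makes the
conservation identity a meaningful end-to-end test.

`gen_cortical_slab()` builds a flat-topology slab — CSF, gray matter
(3 mm), white matter — with smoothly undulating boundaries, a 200-parcel
tiling of the sheet (a Schaefer-like resolution), and a PET volume equal to
a profile of signed distance to the GM/WM boundary (default: Gaussian bump
of width 0.75 mm and height 0.8 over a baseline of 1). What the slab does
*not* emulate: folded cortical geometry, partial-volume effects, scanner
resolution, registration error. A green layer test therefore establishes
that the sampling and statistics localize a boundary-concentrated signal,
not that a real MRI/PET pipeline would.

All generators are deterministic given `seed`; a single global seed fans
out to stage seeds via the documented rule in `fan_seed()`.

## Logan analysis

The Logan transform uses trapezoidal integrals at frame mid-times with an
implicit (0, 0) origin. The equilibration time $t^*$ is the earliest frame
mid-time such that *every* later point deviates from the OLS line by at
most `max_rel_error` (default 10 %, the maximum-error criterion); the scan
runs from early to late and accepts the first hit. Negative slopes are
clamped to the configured threshold (default 0). If no $t^*$ satisfies the
bound the fit *errors*, carrying the best achieved error — silent
extrapolation would be worse. For voxelwise maps a designated
tissue-region curve can fix $t^*$ once, which is then applied to every
voxel; per-voxel failures become `NA`, never zero. One vendor-specific
switch of the original workflow ("percentage of masked pixels = 0 %") has
no public definition and is recorded but not emulated; regional (not
voxelwise) division is used for VT ratios.

## Statistics

The correlation battery reports two-sided p-values and applies no
multiple-testing correction, matching how the original analyses were
reported (raw r and p per analysis). Undefined estimates (zero variance,
too few subfields) propagate as missing, never as zero. Pooled
(subfields-across-subjects) and per-subject analyses are separate code
paths that never mix implicitly. Partial correlation residualizes both
variables on the covariates and uses $n - 2 - k$ degrees of freedom;
whether the pooled n = 129 analysis of the original should treat subject
as a random effect is unknowable from the text, so a plain pooled Pearson
is implemented and documented as such. The per-subject relation between
within-subject correlation and mean abundance is fitted linearly — the
original's "function of overall tau abundance" is not specified further —
with a sensitivity summary anchored at the reported 0.2 area-% threshold.

The repeated-measures layer comparison computes the classical
within-subject one-way ANOVA by sums of squares, reports the unadjusted F
by default with a Greenhouse–Geisser-corrected p alongside (sphericity is
not tested), and performs all 10 pairwise layer contrasts with
studentized-range (Tukey) adjustment via `ptukey` on the within-subject
error term. Effect sizes use Cohen's d with pooled n−1-weighted SD,
computed per (parcel, layer) over subject-level parcel means; whether to
pool parcels before or after subject averaging is unspecified in the
source, and subject-level means are used here.

Layer placement: the GM/CSF boundary, 25 % and 75 % fractional cortical
depth, the GM/WM boundary, and 1 mm below it. The real shift distances of
the original surface pipeline are unreported; 25/75 % gives even spacing
within cortex and 1 mm is about one PET voxel.

## scRadiotracing conventions

Activities are stored in Bq; doses enter in MBq and are converted. Decay
correction uses the F-18 half-life 109.77 min. The %ID·BW formula is
nowhere written out in the source literature; the conventional reading
$(\mathrm{Bq/cell} / \mathrm{dose}_{Bq}) \times 100 \times \mathrm{BW}_g$
is implemented and flagged as a convention. Background is *thresholded*
(pellet ≥ 2× background) but never subtracted, matching the original QC;
subtraction can be layered on by the caller. PET increments are taken as
an input in Bq — how the original derived per-mouse Bq increments from
VT-ratio/SUVR images (calibration factor, region) is not fully specified,
and the package does not guess.

## What the tests establish

The acceptance suite is property-based: Logan identities and 1TCM
recovery within 2 %; exact conservation of the extrapolation identity on
noise-free cohorts plus the worked 5-mouse sum (72,050 Bq) by independent
arithmetic; ≥ 95 % classifier recovery at default generator settings;
exact subfield area-% and scale-invariant binding ratios on phantoms;
nominal CI coverage of planted regression effects and partial-r recovery
of a planted within-region correlation; cluster detection of a planted
30-voxel effect with a quiet null; and boundary localization in the layer
analysis. The headline numbers of the source study (group contrasts,
specific r and β values, effect sizes) are properties of undeposited
tissue and scans and are *not* reproduction targets at desk scale; the
generator mirrors their structure, not their values.

```{r example, eval = FALSE}
# the end-to-end flavour, condensed
sec  <- gen_ihc_section(n_objects = c(NFT = 50, CB = 50, TA = 80, TF = 20),
                        seed = 1)
arg  <- gen_autorad_section(sec$truth, noise_sd = 5, seed = 2)
pet  <- gen_dynamic_pet(list(ctx = list(K1 = 0.5, k2 = 0.1)))
fit  <- logan_vt(pet$tacs$activity, pet$input$activity, pet$tacs$mid)
co   <- gen_scrad_cohort(seed = 3)
slab <- gen_cortical_slab(seed = 4, noise_sd = 0.1)
prof <- sample_layer_suvr(slab$volume, build_layer_surfaces(slab),
                          slab$parcels)
```

## Known limitations

No stain deconvolution, registration, or whole-slide tiling; no scanner
physics or partial-volume correction; no reference-tissue kinetic models
beyond ratios; no spatial autocorrelation between neighboring subfields;
no mesh-based surface reconstruction (the slab geometry substitutes for
it); flat-topology slabs only. Images and volumes round-trip through
plain-text containers (`write_stain_image()`), as no TIFF/NIfTI reader is
available in the supported dependency set — the in-memory contracts are
container-agnostic.
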