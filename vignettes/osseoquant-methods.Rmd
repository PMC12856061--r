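---
title: "Quantifying scaffold osseointegration: methods and design notes"
author: "osseoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scaffold osseointegration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseoquant)
```

osseoquant quantifies how well a ceramic cranioplasty implant integrates
with the surrounding skull, from three independent kinds of evidence:
stained histological sections, CT imaging of the implant-bone interface,
and nanoindentation of the regenerated bone. Each stage is usable on its
own; a synthetic-data module generates every input with known ground
truth, so the entire stack can be validated end to end without animal
data. This vignette records the models, the tunable parameters, and the
design decisions behind each stage.

## Color-gate histomorphometry

Resin-embedded sections stained with Stevenel's blue and van Gieson's
picro fuchsin show the ceramic scaffold as a dark lattice, mineralized
bone in orange-to-purple tones, and soft tissue in blues. Pixel
classification is by inclusive axis-aligned boxes ("gates") in 8-bit HSV
space, with hue on a halved wheel in [0, 179] and saturation/value in
[0, 255] — the convention the stock gate magnitudes are quoted in. The
defaults are scaffold `[0,0,0]..[70,67,90]` and bone
`[155,57,67]..[179,202,187]`. The two bone triplets are interpreted as
the lower and upper corners of one box; gates are validated to be
pairwise disjoint. Both bounds are inclusive, so a pixel exactly on a
gate corner belongs to the gate.

The scaffold envelope ("hull") is obtained by morphological closing of
the scaffold mask with a square structuring element whose side,
`kernel_px` (default 25 px, odd), the analyst chooses to bridge the pore
openings of the printed lattice, followed by hole filling. From the hull
we take the centroid (arithmetic mean of hull pixel coordinates), the
four extreme points, and a horizontal centerline through the centroid.
Coordinates are 0-based, origin top-left, x rightward, y downward;
sections are assumed mounted superficial-side up (the deep surface faces
the dura), with an `orientation` flag to flip the split.

The named reporting regions carry the program's output vocabulary, but
their spatial bounds are this package's own, configurable definitions —
the protocol names the regions without bounding them:

* **circumference** — hull pixels within `band_px` (default `kernel_px`)
  of the hull boundary, by Euclidean distance transform;
* **interior** — hull minus the circumference band, split at the
  centerline into **superficial** (above) and **deep** (below; ties go
  to deep);
* **sides** — exterior pixels within `band_px` (Chebyshev) of the left
  or right extreme point;
* **center** — an auxiliary disk of radius `0.25 * min(hull width,
  height)` about the centroid, overlaying the other labels;
* **exterior** — everything else.

The five primary labels are mutually exclusive and tile the raster
exactly; this is asserted in the test suite. Percent bony ingrowth per
region is `100 * bone pixels / non-scaffold pixels` in the region; a
region whose denominator is zero reports `NA` and is flagged rather than
silently scored 0. An overlay renderer draws the hull boundary,
centroid, centerline, and region tints for visual QC.

## Synthetic micrographs

The generator emulates what the pixel-counting analysis can see, not
histology itself: an axis-aligned square strut lattice (pitch mapping
the 0.9 mm pore spacing of the printed scaffold) in a scaffold-gate
color, pore pixels bone-colored at requested per-region fill fractions,
soft tissue elsewhere, and optional Gaussian HSV noise. Two properties
matter for validation. First, filling is exact-count: `round(f * n)`
pore pixels per region are chosen uniformly under the seed, so the
realized fraction is within half a pixel quantum of the request. Second,
ground truth is *recounted from the emitted pixels* by gating the
rendered image — never echoed from the request — so color quantization
is already folded into the truth. Identical seeds give byte-identical
images. What the generator does not emulate: stain gradients,
out-of-plane struts, curvature of real sections, cellular detail. A
passing recovery suite therefore demonstrates correct counting and
geometry, not robustness to real staining variability.

## Nanoindentation

Load-displacement curves follow a trapezoidal profile: loading at 60
uN/s for 5 s to a 300 uN peak, a 10 s hold, and a 2 s unload, sampled at
100 Hz (at least 100 points per segment for stable fits). Analysis is
the standard unloading-branch treatment: fit
$P = \alpha (h - h_f)^m$ to the upper portion of the unloading branch
(default window: loads between 20% and 95% of the peak unloading load)
by Levenberg-Marquardt least squares, evaluate the contact stiffness
$S = dP/dh$ at peak depth, and form

$$E_r = \frac{\sqrt{\pi}}{2} \frac{S}{\sqrt{A(h_c)}}, \qquad
  H = \frac{P_{max}}{A(h_c)}, \qquad
  h_c = h_{max} - \varepsilon \frac{P_{max}}{S},$$

with the ideal Berkovich area function $A = C_0 h_c^2$, $C_0 = 24.5$,
and $\varepsilon = 0.75$; a calibrated polynomial area function can be
supplied instead. The bone modulus inverts the compliance identity
$1/E_r = (1-\nu_b^2)/E_b + (1-\nu_i^2)/E_i$ with diamond-indenter
defaults $E_i = 1140$ GPa, $\nu_i = 0.07$, and bone Poisson ratio
$\nu_b = 0.3$. None of $\varepsilon$, $C_0$, or the Poisson ratios is a
measured quantity here; all are standard defaults, exposed in
`indenter_spec()` and recorded with every result. Internal units are
fixed to uN, nm, nm²; moduli are emitted in GPa via
1 uN/nm² = 1000 GPa.

The synthetic generator inverts this pipeline: given target $(E_r, H)$,
the exponent $m$, the profile, and the indenter, it constructs the
unique noiseless curve whose analysis returns the targets exactly. Note
that the residual depth is then pinned, $h_f = h_{max} - m P_{max}/S$,
so it is reported with the realized truth rather than accepted as an
input. Noise is additive Gaussian on load only — the simplest model that
exercises the fitter; displacement noise, thermal drift, and frame
compliance are out of scope. The recovery tests run a
$E_r \in \{5,10,15\}$ GPa $\times$ $H \in \{0.2,0.5\}$ GPa grid at the
1% tolerance, and Monte-Carlo checks at 1 uN load noise.

Segmentation of raw curves finds the hold as the contiguous run of
samples within `plateau_tol` (default 2%) of the peak load. The default
tolerates realistic load noise; recovering the hold duration to within
a couple of samples on clean traces needs a tighter setting (the tests
use `1e-3`).

## Bridging scores and rater agreement

The implant-bone interface is modelled as a binary contact function on
the perimeter: disjoint bridged arcs in degrees. Segment scoring divides
the circle into `n` equal segments (12 for the longitudinal clock-face
protocol, 8 for the peripheral micro-CT landmarks); each segment scores
the percent of its span covered, and the overall score — the unweighted
segment mean — equals the total bridged fraction for every `n`, which is
why 12- and 8-segment protocols agree on the overall number. Segment 0
starts at 0 degrees (the anterior anchor by convention, since the
protocol does not state one) proceeding clockwise; `rotate_interface()`
re-anchors. Real raters judge bridging visually on slices; that
subjectivity is modelled only as the arc content plus optional noise,
so the shipped scores are continuous, not binned.

Inter-rater agreement uses ICC(2,1): two-way random effects, absolute
agreement, single rater, from the mean-squares decomposition
$(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n)$. Raters are
treated as a random sample of possible reviewers, and absolute
agreement (offset-sensitive) is the relevant criterion for averaged
scores. Tables with zero total variance are flagged undefined.

## CT volumetrics

Volumes are segmented by an inclusive Hounsfield window, default
225-3070 HU (the bone-density window of the imaging protocol), with
native bone and heterotopic ossification removed by a caller-supplied
exclusion mask — outlining those structures was a manual step in the
protocol and is not automated here. Volume is voxel count times voxel
volume; no partial-volume weighting is attempted, so accuracy is limited
by voxel size (the synthetic sphere check passes at 2% with a 10-voxel
radius). NIfTI I/O preserves spacing.

## Statistical battery and table reproduction

The cohort statistics mirror small-sample comparative practice:
Shapiro-Wilk normality screening (advisory only — the branch actually
taken for each published comparison is not recorded, so the package
logs normality rather than auto-switching tests), one-way ANOVA with
Tukey HSD, pooled-variance t tests with optional Bonferroni correction,
and rank-based alternatives (Mann-Whitney with exact small-sample p
values, Kruskal-Wallis, and a hand-implemented Dunn post hoc with tie
correction, since no pre-installed implementation exists). Degenerate
inputs follow fixed conventions: zero within-group variance with equal
means gives F = 0, p = 1; identical constant samples give t = 0, p = 1;
fully tied rank tests give p = 1.

`reproduce_tables()` recomputes every derivable summary from the
shipped per-subject fixtures and flags each against its published
counterpart at printed precision. Three findings are reported as
discrepancies rather than forced: the published SDs of the explant
volumes (145/663/693 mm³) do not equal the sample SDs of the published
per-subject values (128/586/613 mm³); some published group means are
inconsistently rounded (66.67 printed as 66, but 24.67 as 25); and the
secondary ANOVA p values differ from recomputation by up to ~0.015
(e.g. interior histology 0.230 recomputed vs 0.226 published),
consistent with upstream software rounding. All headline quantities —
group means, the volume ANOVA p = 0.036, bridging p < 0.001, and the
pairwise volume t tests (0.021, 0.033) — reproduce exactly at printed
precision.

## Problem sizes and numerical choices

Validation micrographs are 160x160 px (tests) and 240x240 px (default
spec) with a 20-25 px pitch — large enough for several thousand pore
pixels per region, small enough for brute-force per-pixel oracles.
Null-calibration runs use 10,000 simulated cohorts of 3 groups x 3
subjects at a fixed seed, matching the study's group sizes. Unloading
fits bound $m \in [1, 4]$ with starts $(m_0 = 1.5)$; convergence
failures surface as errors with diagnostics rather than silent
fallbacks. Ties in the superficial/deep split go to deep; extreme-point
ties resolve to the smallest y for determinism.

## Known limitations

* Region bounds (circumference width, sides neighborhoods, center disk)
  are package definitions, configurable but not protocol facts.
* The synthetic stack validates counting and geometry, not biological
  realism; no claim is made about stain-robustness on real slides.
* Published per-animal measurements, the published inter-rater ICCs
  (0.998/0.995), and the published group moduli depend on unpublished
  raw data; they appear here only as sanity magnitudes for synthetic
  round trips.
* Viscoelastic unloading, thermal drift, and area-function calibration
  are out of scope for the indentation stage, as are DICOM ingestion
  and cross-timepoint registration for CT.
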