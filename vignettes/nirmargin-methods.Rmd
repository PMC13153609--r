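---
title: "Methods: simulating and calling tumor margins from microwell NIR fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling tumor margins from microwell NIR fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmargin)
```

# The problem and the workflow

Intraoperative assessment of tumor-positive margins usually relies on
frozen-section histopathology, which is slow and subjective.  An
alternative is a chemically selective near-infrared labeling workflow:
a chlorine-bearing cyanine dye (absorption ~787 nm, emission ~822 nm)
inserts into hydrophobic pockets of tumor-associated proteins and forms
a covalent bond with an accessible pocket cysteine, producing bright
dye–protein adducts ("NIR fluorescent proteins").  A tissue section is
lysed in situ on a microwell array (20×20 or 40×40 wells), each well's
lysate is electrophoresed in the z-direction into a stack of gel layers
ordered by protein mass, and the layers corresponding to the 60–75 kDa
target-protein window are imaged.  Per-well tumor-to-reference
fluorescence ratios, thresholded at a ROC-calibrated cutoff, yield a
tumor-positive mask whose contour is compared with the
pathologist-drawn margin.

`nirmargin` implements this workflow end to end as a forward simulation
plus the margin-calling analysis, so that every stage is testable
without patient data.  A seeded tissue-phantom generator stands in for
biopsies; the analysis side (ratio maps, ROC/Youden cutoff, contouring,
similarity scoring, chemoproteomic filtering) consumes either simulated
or externally supplied grids.

# The forward model, stage by stage

## Tissue phantom

A section is a grid of wells, each labeled tumor, paracancerous or
normal.  Geometry is defined in continuous unit coordinates and then
rasterized, so one seed describes one tissue regardless of resolution;
`oversample` controls sub-well resolution.  Supported shapes are a disc,
a "blob" (a disc perturbed by three low-order radial harmonics, giving
an irregular but smooth outline), and a needle-biopsy core
(`punch_core`): a strip of width `core_width_frac` of the section side
(4 wells on a 40-grid, 2 on a 20-grid) in which a contiguous segment is
tumor — for this geometry `tumor_fraction` is the tumor fraction *of the
core*, not of the section.  Paracancerous tissue is a rim of
`rim_wells = 2` wells around the tumor.  Published descriptions pair
tumor with paracancerous and normal sections but give no well-level
geometry, so the rim width and the default `tumor_fraction = 0.25` are
modeling choices that keep the tumor/reference contrast well posed;
they are fixed once here and used everywhere.

## Region proteomes and per-well abundances

Each region expresses `n_common = 30` common species with molecular
weights uniform over 15–100 kDa and equal abundance in all regions,
plus `n_signature = 5` tumor-signature species confined to the 60–75 kDa
target window and enriched `fc = 3`-fold in tumor over
paracancerous/normal tissue.  The signature definition (fold change
strictly above 2, mass inside 15–100 kDa) is enforced by the generator
and never relaxed.  Species base abundances scatter log-normally
(log-sd 0.3) around a unit median.  Per-well abundances are drawn
log-normally around the region mean with coefficient of variation
`noise_cv = 0.1`; the log-normal keeps abundances positive and its
parameters are solved from the mean and CV, so `noise_cv = 0` returns
region means exactly.  The default CV and the 3-fold enrichment are the
one place the generator sets its own "realistic" dial: a 3-fold change
is just above the 2-fold candidate threshold, and 10 % well-to-well
variation is typical of replicate densitometry.

## Covalent labeling kinetics

Labeling is modeled as sequential irreversible mass action: a protein
with $n$ reactive pockets passes through occupancy states
$P_0 \to P_1 \to \dots \to P_n$, consuming one free dye molecule per
step, with rate constants $k_1$ for the first site and
$k_i = c\,k_1$ ($c = $ `coop`) thereafter.  All rates share the
temperature law $k \propto e^{a(T-37)}$ with `ea_like` $a = 0.06$/°C,
so 60 °C runs about four times faster than 37 °C.  The observation the
kinetics must reproduce is qualitative: at a 1:1 dye:protein ratio the
two-pocket model protein ends up either doubly labeled or untouched,
with a large unlabeled pool, and 1:2 is the smallest complete ratio.
Independent identical sites cannot produce that bimodality, so the
package adopts cooperative kinetics with `coop = 100` by default: once
a first dye binds, the second site reacts two orders of magnitude
faster.  This is a deliberate resolution of an ambiguity — the binding
sites have also been described as independent — and `coop` is exposed
so the alternative ($c = 1$) can be explored.

Two numerical modes exist:

* **Finite time** integrates the full ODE system (states $P_0..P_n$ and
  free dye $D$) with `deSolve::lsoda` at tight tolerances; dye
  conservation holds to $10^{-9}$ relative.
* **Run to completion** uses the substitution
  $u = \int k_1 D\,dt$: because every rate is proportional to $D$, the
  chain becomes linear in $u$ with $P_0(u) = e^{-u}$, and the completion
  state is the root of "bound dye = supplied dye" in $u$.  This avoids
  integrating a singular $t \to \infty$ endpoint and makes the minimal
  complete-ratio sweep exact: supplying at least one dye equivalent per
  site drives the unlabeled fraction to zero analytically.

Occupancies are deterministic expectations; a seeded Gillespie mode
(`site_occupancy_stochastic`) exists to validate them at finite
molecule numbers.  Controls behave categorically: the chlorine-blocked
analog and ICG form no covalent bond under any conditions, trypsin
digestion destroys the pockets (zero signal), and heat denaturation
preserves covalent binding at `denature_scale = 0.5` brightness — the
published result states a decrease without a magnitude, so 0.5 is a
fixed stand-in.  Stoichiometry is expressed as the dye:protein ratio
throughout; absolute concentrations (the 20 µM observation) are outside
the model.

## Electrophoretic fractionation

Migration distance in SDS-PAGE is close to linear in log mass, so the
13-layer stack is calibrated by log-spacing mass boundaries between the
ladder anchors 100 kDa (top) and 15 kDa (bottom):
$b_k = 100 \cdot 0.15^{k/13}$.  Layer 1 is the top of the stack and
holds the heaviest interval; layer $k$ owns $[b_k, b_{k-1}]$, and a
mass exactly on a boundary belongs to the lighter (higher-index) layer.
Consistently with that tie-break, a mass *window* intersects a layer
only when the overlap has positive length, so a window equal to one
layer's interval selects exactly that layer.  Under this calibration
the 60–75 kDa window spans 3 contiguous layers (indices 2–4).  Reported
layer indices for the same window are 3–5; whether the first stack
positions are loading/stacking layers is unspecified, so the package
anchors the *count* (3 contiguous layers) and leaves absolute alignment
configurable via the ladder anchors.  A `dispersion_sigma = 0.05`
fraction of each species' signal leaks to adjacent layers (split
equally; an end layer passes all of it to its single neighbour), which
keeps conservation tests non-trivial while preserving discrete bands.
Analysis retains fractions 3–13 — eleven layers — as the standard
quantification window.

## Microwell imaging

Rasterization block-sums the (possibly oversampled) field into
`array_size`² wells, conserving signal exactly and remaining linear.
Degradation then applies a Gaussian point-spread blur
(`psf_sigma = 0.5` wells), a uniform background equal to 2 % of the
mean tumor-well signal, optional Poisson shot noise (off by default —
the scanner's photon calibration is unknown), and Gaussian read noise
at 1 % of the same scale, with clamping at zero.  No published optics
model exists for the NIR scanner, so these magnitudes are stand-ins
chosen at desk scale; each layer's noise uses a sub-seed derived from
the master seed by fixed arithmetic, so adding layers never reshuffles
earlier ones.

# The margin analysis

Per-well ratios are the aggregated (default mean) signal of the
target-window layers inside the retained fractions — layers 3 and 4
under the default calibration — divided by the median aggregated signal
over the annotated reference wells (paracancerous + normal).  The
median is robust to the blur leaking tumor signal into the rim; a
non-positive reference median is a hard error, not a silent NA.

The classifier cutoff defaults to 1.330, the ROC-calibrated ratio
threshold of the published clinical analysis, and is recomputed from
data when calibration pools are available: `roc_cutoff()` evaluates
sensitivity and specificity at every midpoint between consecutive
distinct pooled values (so ties are handled exactly), computes AUC by
trapezoid, and picks the cutoff maximizing the Youden index
$J = \text{sens} + \text{spec} - 1$, breaking ties toward higher
specificity and then the higher cutoff.  When the package recalibrates
on its own synthetic pools the recovered cutoff sits just above 1 and
is stable across seeds: the synthetic negative pools are
tighter than clinical normal/normal sections, so the Youden optimum
hugs the noise ceiling rather than the clinical 1.330.  Both numbers
are reported by the tests; the default *applied* cutoff stays at 1.330.

Margin calling thresholds the ratio map (wells ≥ cutoff), removes
4-connected components smaller than 3 wells, fills interior holes and
traces each component's boundary (EBImage's labeling, hole-filling and
contour tracing back these steps).  "Similarity" to the ground-truth
mask is undefined in the source workflow; the package adopts the Dice
coefficient ×100 (two empty masks score 100) and reports the simple
overlap $|A \cap B|/|B|$ alongside.  ROI inclusion is all-wells-inside,
the criterion used for pathologist-marked regions.

Cohort comparison pools per-layer tumor/normal and normal/normal
ratios.  Pooling per-layer values across phantoms (rather than
per-sample summaries) matches the "n = 11 fractions per biopsy"
reporting convention; the per-sample alternative would shrink the
pools 11-fold.  The rank-sum test is `stats::wilcox.test` — exact for
small tie-free samples, normal approximation with tie correction
otherwise.

# Problem sizes, determinism and degenerate inputs

The default study sizes are chosen as desk-scale analogs: batches of
17–20 phantoms at 40×40 wells (the clinical margin study used 17
samples × 11 fractions), eight paired seeds for the 20×20 vs 40×40
puncture comparison at a common 80×80 field, 10⁴-well grids for
noise-CV checks and 10⁵-point samples for the closed-form AUC check.
A full simulate-evaluate cycle takes about a second, so the whole test
suite and the batch studies run in well under a minute.

Every stochastic stage draws from a sub-seed derived from the master
seed by fixed offsets (`derive_seed`), making runs bit-reproducible and
stage-isolated; re-evaluating a stored run reproduces its report
bit-for-bit.  Degenerate inputs are defined, not patched: a
`tumor_fraction` of 0 yields an all-normal section and an empty margin
call; zero reactive sites with positive dye is a valid no-reaction
state; an all-below-threshold ratio map is a valid empty call; an
empty ROI makes inclusion undefined and errors.

# Limitations

The phantom emulates region-level composition, not cells: no spatial
abundance gradients within a region, no infiltrating margins, no 3D
tissue structure, and no registration to real H&E images.  The noise
model is a stand-in — passing the ≥ 90 % similarity batch shows the
analysis chain is correct and robust at these noise levels, not that
real scanners behave this way.  The kinetic constants reproduce
qualitative observations (temperature dominance over time, bimodal
substoichiometric labeling), not measured rate constants.  Docking,
molecular dynamics, immunohistochemistry quantification and
peptide-spectrum matching are out of scope; the chemoproteomics module
covers only the bookkeeping (fold-change/mass filters, Venn logic,
modification-mass arithmetic).  On that last point: the printed adduct
formula C42H48ClN2I does not sum to the printed 581.87 Da under
standard atomic weights, while C42H49N2 — the dye cation after
chloride displacement by the cysteine thiol, plus the transferred
proton — does; the calculator computes both and the discrepancy is
documented rather than silently resolved.
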