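---
title: "Quantifying a receptor's levels across brain cell types: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a receptor's levels across brain cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Immunofluorescence surveys of a receptor such as IGF-2R (CI-M6PR) across
brain cell types face a chain of quantification problems: counting nuclei in
fields of very different cell density; turning raw region intensities into
background-corrected per-cell scores that can be compared across regions;
measuring how much of the receptor's signal lies on a compartment marker
(dendrites, spines) at increasing distance from cell-body layers; and, in
multiplex panels, assigning a per-cell intensity to each of many cell
classes when the receptor is concentrated in a small perinuclear domain
(Golgi/TGN) rather than filling the soma.  `discquant` implements that
chain as composable, tested operations, together with a synthetic-scene
generator that provides ground truth for every stage.

## The quantification model, stage by stage

**Nuclei counting.**  DAPI images pass through a difference-of-Gaussians
band-pass, binarization at a triangle-algorithm threshold, watershed
separation of touching nuclei, and a particle filter keeping areas of
10--250 pixels (closed interval).  The DoG sigmas are not fixed by the
published chain; the defaults are 0.3x and 1.0x the expected nucleus radius
in pixels and are exposed in `nuclei_count_params()`.  The size filter is
applied after the watershed, matching the stated order of operations.
Because the DoG subtracts a constant exactly (normalized kernels,
edge-replicating boundary), counts are invariant to additive offsets.

**Regional scores.**  `intensity_per_cell()` computes
`(mean(stained) - mean(control)) * area / nuclei_count` per region, where
the control mean comes from the same region of a section processed without
primary antibody.  Negative corrected means are kept, not clipped, so that
control-dominated regions sort to the bottom of a cohort.
`classify_quartiles()` splits a cohort at its 25/50/75th percentiles into
low, moderately low, moderately high and high levels.

**Colocalization.**  `manders_coefficients()` computes the Manders split
coefficients on background-subtracted images, clipping negatives to zero
(required for coefficients bounded in [0, 1]).  A channel with zero total
intensity yields a missing coefficient, never 0.  `band_roi()` divides a
region by Euclidean distance from a reference layer into proximal
(0--30 um), medial (30--60 um) and distal (>70 um) sub-regions; pixels at
60--70 um are unassigned by default because the printed band edges leave
that gap, with an option to fold them into the distal band.

**Per-cell discs.**  The multiplex pipeline detects nuclei with a
median filter (1.5 um radius), Gaussian smoothing (sigma 1.6 um),
background subtraction by morphological opening-by-reconstruction (8 um
disc), a fixed intensity threshold (1.0 AU), optional shape-based
watershed splitting, and an inclusive 10--100 um^2 area filter, at a
working resolution of 0.5 um/pixel.  Detection is restricted to
classifier-derived DAPI+ areas.  Each nucleus is expanded by 2 um into a
"disc", the quantification area capturing the perinuclear signal.  Discs
are classified per marker by whether their centroid pixel falls in that
marker's classifier-positive area; discs positive for more than one marker
are excluded from single-positive summaries.  Per region, a high/low
target-area classifier isolates diffuse staining and the median target
intensity of the low area is subtracted from every disc mean (the
corrected value may be negative; clipping is available behind a flag).
Corrected means are normalized by the 75th percentile of all DAPI-derived
discs in the same region and image; discs detected from IBA1 staining
itself (see below) are normalized by the same DAPI-based denominator.

**IBA1 mode.**  Microglia frequently lie against neuron somas, so a
DAPI-derived disc expanded by 2 um picks up neuronal signal.  For such a
marker the pipeline can re-detect cells from the marker staining itself
(`detect_cells_iba1()`), restricted to the classifier-positive area and
without downstream expansion, so the quantification area is the
marker-positive soma.

**Statistics.**  `oneway_anova_tukey()` and `twoway_anova_blocked()`
provide the inferential layer: classical fixed-effects one-way ANOVA per
region, and a two-way marker x region fit with an additive subject block
and a single residual stratum.  Tukey HSD p-values use the studentized
range with the Tukey--Kramer standard error for unbalanced cells.
`assumption_checks()` reports Shapiro--Wilk normality of residuals,
Levene's test centred at the group mean, and Mauchly's sphericity statistic
on orthonormal contrasts (trivially satisfied for two conditions).

**Expression classes.**  `assign_classes()` groups published
cluster-level expression tables into major cell classes by canonical
markers (astrocytes *Aldh1l1*; ependymal *Ttr*/*Foxj1*/*Aqp1*; endothelial
*Pecam1*; mural *Pdgfrb*/*Acta2*; fibroblasts *Dcn*/*Col1a1*/*Pdgfra*;
OPCs and oligodendrocytes *Sox10*/*Olig2*/(*Pdgfra*/*Mog*); immune *Aif1*;
neuroblasts *Sox4*; excitatory *Slc17a7*/*Slc17a6*; inhibitory
*Gad1*/*Gad2*; cholinergic *Chat*).  Class summaries are unweighted means
over member clusters (each subpopulation counts once) with SEM over
clusters; `rank_consistency()` compares rankings across datasets by
Spearman correlation over shared classes.

## The synthetic-scene model

`generate_tissue_image()` emulates one imaging plane: axis-aligned
elliptical nuclei (aspect at most 1.6) with areas drawn from a configured
range; a cytoplasmic soma obtained by expanding the nucleus outline
(default 3 um); marker channels stained somatically, membranously (a 1 um
rim), nuclearly, or as vessel rings (a lumen with an inner endothelial ring
and an outer mural ring, for adjacency tests); and a target channel built
from a uniform control background, a uniform diffuse neuropil layer, and a
per-cell perinuclear signal.  When `golgi_polarized` is on, the per-cell
signal is a Gaussian blob of 1.5 um width whose centre sits 1--2 um beyond
the nucleus edge on a random side; either way the signal is scaled so the
mean over the soma mask equals the configured `true_target_mean` exactly
before noise.  Noise is additive Gaussian with standard deviation 2% of
the local mean, clipped at zero; autofluorescent puncta are added
identically to every channel.  Intensity scales are fixed at 100 AU for
DAPI and 50 AU for markers: the study reports only relative per-class
target levels, so absolute simulator intensities are configuration, not
reproduced fact.

Two modelling decisions deserve emphasis:

* **The diffuse layer underlies somas.**  In a projected section, neuropil
  signal overlaps cell bodies, and the low-area median correction exists
  precisely to remove that baseline from disc means.  A model in which
  diffuse signal stopped at soma outlines would make the correction
  over-subtract and could not satisfy the diffuse-robustness property the
  pipeline is tested against.
* **Occlusion compositing.**  Overlapping cells are drawn in configuration
  order and later classes overwrite earlier ones on their soma pixels, as
  for a small cell lying over a larger one.  The `overlap` option places a
  fraction of one class's nuclei inside host-class somas at a configurable
  offset from the host nucleus; this is what lets scenes reproduce the
  DAPI-disc contamination that motivates IBA1-mode detection, while the
  overlapping cell's own soma pixels stay uncontaminated.

What the generator does **not** emulate: optical blur (no PSF), 3-D
z-structure, spectral bleed-through (unmixing is out of scope), staining
heterogeneity within a class, irregular cell shapes, and tissue artefacts
such as folds.  A green test therefore establishes that the operator chain
is implemented correctly and recovers known ground truth under a clean but
plausibly scaled scene; it does not establish robustness to optics or
staining pathology.

## Numerical choices and conventions

* Percentiles everywhere (quartile levels, upper-quartile normalization)
  use the linear-interpolation rule (R type 7); the rule is documented and
  the boundary convention is that a value exactly at a percentile joins the
  upper level, so a degenerate all-equal cohort is uniformly "high".
* The triangle threshold breaks ties toward the lowest qualifying bin and
  returns a value strictly between the histogram peak and the farthest
  nonempty tail.
* Watershed splitting floods the negated, lightly smoothed (sigma 1 px)
  Euclidean distance transform from regional maxima merged within a
  1-pixel radius; smoothing stabilizes the ridge plateaus of digital
  ellipses.  Components with a single seed are left whole.
* Disc expansion is Voronoi-constrained: contested pixels join the nearest
  nucleus, so disc labels never overlap and every disc contains its
  nucleus.  Whether the original tool constrained expansion this way is
  not stated; the constraint is adopted here and documented rather than
  asserted as the source behaviour.
* Regional percentile cohorts are built from subject means per region
  (pooling across subjects is available), matching how the published
  cohort figures present points per subject.
* Both Manders directions are computed; which direction a given figure
  reports is left to the caller, since the source leaves it ambiguous.
* The blocked two-way fit defaults to Type II sums of squares (designs are
  near-balanced after exclusions) with Type I/III available, and uses a
  single residual stratum; a full within-subject error-strata model is a
  documented alternative the source wording does not disambiguate.
* The pixel classifier is a seeded single-hidden-layer feed-forward
  network (tanh, softmax, full-batch Adam, 300 iterations, hidden width 8)
  over the exact stated feature bank (Gaussian, Laplacian of Gaussian,
  gradient magnitude, Hessian determinant, Gaussian-weighted standard
  deviation at 0.5--8 um scales, with optional local-mean subtraction at
  32 or 20 um).  Any classifier satisfying the training contract can be
  substituted.
* Cluster-level expression values are consumed on each dataset's published
  scale without cross-dataset renormalization: rankings, not magnitudes,
  are compared across datasets.  Class-assignment ties break
  cholinergic > inhibitory > excitatory > remaining classes
  alphabetically, deterministically, and every tie is flagged.
* Counts and class assignments of "other" (monoaminergic, peptidergic,
  mixed) neurons are handled by explicit overrides, never heuristics.

## Known limitations

The per-cell pipeline quantifies a 2-D plane; volumetric effects (nuclei
cut at different heights) appear only as the configured area range.  The
classifier is intentionally small: on real images with heavy artefacts a
stronger model may be needed, and the training contract admits one.
Exclusion of unreliable regions (folds, uneven staining) is the caller's
responsibility via exclusion polygons; the nuclei counter only emits a
density warning rather than reproducing manual visual inspection.
Cortical nuclear-marker populations that co-localize with neuron somas
cannot be resolved by centroid classification, mirroring the corresponding
limitation of the source method.
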