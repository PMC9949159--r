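---
title: "Models and methods behind the rolony pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the rolony pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rolony)
```

This vignette documents the models, parameter choices and numerical
decisions behind each stage of the package, in the order data flows
through it. Default values are stated with units; every tunable is an
exported function argument or a `SimConfig` field.

## The measurement model

A neuron carries one barcode, a string over {G, T, A, C} read out over
`nCycles` sequencing cycles (default 17, one nucleotide per cycle; the
library holds positions 9–10 fixed, here to "GG", leaving 15 variable
positions). Each axonal rolony is a point source that should produce one
diffraction-limited spot per cycle, imaged at 0.55 µm/px in the channel
of that cycle's nucleotide. The failure modes the pipeline must absorb
are: per-cycle signal loss (dropout), wrong-channel calls
(substitution), sub-pixel positional wobble between cycles (jitter),
bleed-through and gain differences between channels, phasing carry-over
in somata, rolonies displaced from their soma before capture (floating
rolonies), and barcodes expressed by secondarily infected non-neuronal
cells in target regions.

## Synthetic data generator

`simulateNeurons()` draws neurons from a four-class mixture
(CT/ET/ITi/ITc, default 0.15/0.10/0.45/0.30, echoing the relative
abundances such experiments report) and emits per-neuron rolony clouds
inside axis-aligned region boxes (`regionBoxes()`): the injection site
(AudI), an ipsilateral cortical target (VisI), contralateral cortex
(CtxC), thalamus, striatum, midbrain, and the striatal-thalamic fiber
zone used for ET/CT typing. The class geometry encodes the biology the
classifier relies on:

* CT neurons run a **dorsal** fiber-zone bundle (y ≈ 4000 ± 150 µm) and
  terminate in the thalamic stratum continuous with it; somata peak at
  90% cortical depth (L6-like).
* ET neurons run the **ventral** bundle (y ≈ 4500 ± 150 µm), terminate
  in the complementary thalamic stratum, add midbrain rolonies, and
  have somata peaking at 60% depth (L5-like). The 500 µm bundle
  separation at SD 150 µm yields roughly 10% spatial overlap at the
  median split, the regime the kNN classifier is validated in.
* ITi/ITc neurons project to cortex with laminar profiles tied to soma
  depth (upper somata project superficially and focally, spread SD
  60 µm; deep somata project deep and diffusely, SD 250 µm); ITc
  neurons always receive ≥ 5 contralateral rolonies, ITi none.

Defaults are study conditions, chosen once: 30 rolonies per neuron
(median per-barcode counts in such data are ~40; 30 keeps desk-scale
runs fast without changing any qualitative behaviour), dropout
5%/cycle, substitution 0.5%/base, jitter 0.5 px, 2 floating rolonies
per soma at ≤ 500 µm tangential scatter on the soma section ± 1
(weighted 0.6/0.2/0.2), and 2 secondary-infection barcodes emitted as
compact (SD 20 µm) glial-like clusters. Validation experiments override
the noise terms they probe (e.g. the noisy-recovery check uses 10%
dropout and 1% substitution; the planted-floater check sheds 12
floaters per soma, since a shower of ~2 floaters spread over three
sections is undetectable *by construction* under the ≥ 3-cluster rule
and a real floating event deposits many rolonies).

The generator emulates class-level statistics only: no axon morphology
beyond z-extended target columns, no tissue distortion, no optical
aberrations, no section-to-section registration error. Passing tests
therefore demonstrate algorithmic correctness under the stated noise
model, not robustness to every artefact of real microscopy.
`renderImageStack()` optionally rasterizes dots into 4-channel z-stacks
(Gaussian blobs, σ = 0.9 px, z-profile peaked on a contiguous slab)
with additive noise, linear bleed-through, uneven illumination and
phasing carry-over; the dot-table path is the canonical fast test path.

## Spot detection

`floorSubtractedProjection()` computes, per pixel and channel, the
maximum over z minus the 3rd-lowest plane, clipped at zero — pixels
without a rolony have discontinuous z-profiles, so this removes fixed
pattern and tissue background while keeping blob peaks.

`correctChannelIntensities()` standardizes each channel as
(I − median(channel)) / SD(local-maxima intensities). Anchoring the
*scale* on detected local maxima equalizes the spread of true-dot
intensities across channels of different gain, while anchoring the
*offset* on the channel median keeps the background near zero — so the
detection threshold (default 3.0) reads as "maxima-SDs above
background". Standardizing location *and* scale on the maxima would put
every true dot at z ≈ 0 and make a positive threshold meaningless,
which is why the offset is the background median. Channels with fewer
than `minMaxima` (50) maxima fall back to identity correction with a
warning. Optional linear unmixing estimates bleed-through coefficients
as median off/on ratios at spectrally pure maxima (ratio2nd < 0.5) and
inverts the 4×4 mixing matrix.

`detectDots()` accepts a local maximum (circular neighbourhood,
diameter 5 px — rolonies are 3–7 px across; plateau ties break to the
lexicographically first pixel) iff (1) the z-plane of highest intensity
is adjacent to the plane of 2nd **or** 3rd highest (a `bothAdjacent`
flag gives the stricter variant), (2) its channel is the argmax both
before and after correction, (3) 2nd-max/1st-max channel ratio is
strictly below 0.95 (computed on corrected intensities clipped at 0),
and (4) the corrected intensity passes the threshold. Subpixel
positions come from 1-D quadratic interpolation of the 3×3
neighbourhood, clamped to ± 0.5 px. Perisomatic regions are *not*
treated specially here; their exclusion happens at base-calling.

## Registration

Coarse alignment is frequency-based throughout: the peak of the
normalized cross-power spectrum (phase correlation), with parabolic
subpixel refinement and wrap-around handling. Dot tables are rasterized
at 1 px bins (matching the chaining gate). A peak below 0.1 flags the
transform low-confidence (uncorrelated sparse rasters peak near
0.03–0.06; genuine overlaps far higher). `registerPointClouds()`
refines by iterated gated nearest-neighbour pairing (gate 5 px) and
least-squares fits — affine by default, projective (normalized DLT)
only when support reaches 50 pairs — to convergence of the rms residual
(tolerance 0.01 px, cap 20 iterations). Cycles are registered
neighbour-to-neighbour toward the mid-sequencing reference cycle and
composed; a cycle that cannot be registered keeps its pre-alignment
(identity) transform, flagged. Tiles are stitched in descending
rolony-count order against the union of already-placed neighbours, so
sparse tiles are always registered to dense ones; overlap duplicates
are retained and deduplicated per barcode downstream. No non-linear
transforms anywhere; externally fitted displacement fields can be
applied with `applyDisplacementField()`.

## Base-calling

`chainDots()` matches dots of cycle *t* one-to-one to the closest
available dots of cycles *t−1*, *t−2*, *t−3* within 5 px, greedily by
ascending pair distance with (distance, from-id, to-id) tie-breaks.
`assembleSequences()` merges matches by target cycle, interval
ascending (3-4, 2-4, 1-4, 4-5, …). Non-consecutive matches fill the
skipped cycles with N. A match disagreeing with a chain's existing
entry duplicates the chain's *full prefix* up to the earlier cycle
(duplication of only the conflicted suffix would fabricate
prefix/suffix combinations no match supports); both forks are retained
for codebook voting and condensed after lookup. A chain that forks more
than 4 times is dropped with a log message — fork explosion indicates
an unresolvable tangle, not signal. Reads with more than 3 consecutive
Ns are discarded. The read position is the reference-cycle dot when
present, else the chain centroid. Reads within 20 µm of ≥ 35 soma
pixels in > 2 cycles are excluded (`excludePerisomatic()`): base-calls
in the dense perisomatic halo are unreliable.

`basecallSoma()` works per pixel, not per maximum (somata are far
larger than rolonies), subtracting the previous cycle's intensities —
50% for the channel that was the previous argmax, 100% for the rest,
clipped at zero — before taking the argmax; an all-zero pixel calls N.

## Codebook and matching

Two Hamming conventions coexist deliberately. The **permissive**
convention (N matches all four nucleotides; fixed positions 9–10
excluded) governs codebook separation and contaminant screening. The
**strict lookup** convention — with *m* mismatches at doubly-called
positions and *k* positions where either string has N, distance = m if
m = 0 else m + k — governs read-to-codebook matching with *all*
positions included: an uncertain position is forgiven only for an
otherwise perfect match. A position where both strings have N counts
once (the worst case over substitutions is a single mismatch there).

`buildCodebook()` aggregates reads by exact string, then collapses
partially called variants by permissive-N consensus clustering: the
strongest remaining candidate (support, then called positions, then
lexicographic order) absorbs every candidate it matches at permissive
distance 0, and its N positions are resolved by the support-weighted
majority of the absorbed reads. This is the operational meaning of "a
true barcode has a higher count than its erroneous versions": without
it, a barcode none of whose reads happens to be fully called (a ~1%
event per neuron at 10% dropout with ~30 reads) would splinter its
support across N-patterns and could be hijacked by a 1-substitution
variant. Acceptance is then greedy by support: ≥ 3 rolonies,
composition limits (< 14 identical called nucleotides, counted
including the fixed positions; ≥ 13 of 15 variable positions called;
N-runs ≤ 3), and no accepted entry within permissive Hamming distance
1; the support of rejected 1-neighbours is attributed to their accepted
neighbour and flagged in the `attributed` column so counts stay
interpretable.

`matchToCodebook()` returns the nearest entry when unique at strict
distance ≤ 2, `ambiguous` (discarded) on ties at the minimum, and
`unmatched` beyond. `condenseReads()` then (1) blanks to N any dot
claimed by reads matched to different barcodes, (2) re-applies the
length/N-run limits, and (3) collapses reads of one barcode whose dot
sets overlap at Jaccard ≥ 0.8 (the spec's "similar sets" left the
threshold open; 0.8 keeps genuinely distinct rolonies ≥ a few dots
apart while collapsing forks) into the read with most called digits.

## Quality control

Filters run in the pipeline's order with a telescoping ledger
(`runQcChain()`; input = kept + removed at every stage). Numbers worth
restating: error-prone barcodes are dropped for > 6 continuous
identical nucleotides, > 14 called nucleotides in channels 1/2 (G/T) or
3/4 (A/C), or more 1–2-mismatch rolonies than exact ones; count gates
require ≥ 10 rolonies in some target region (after zeroing sub-minimum
region counts: 5 for cortex/thalamus, 3 for striatum/midbrain), 3–1000
axonal rolonies and ≤ 7000 somal pixel counts; contaminant screening
removes barcodes within permissive Hamming 4 of a supplied secondary
infection list; overlap dedup keeps one copy per barcode among
cross-field pairs closer than 25 µm on a section. A soma is the
brightest pixel on the section with the highest summed soma-pixel
intensity, valid only with ≥ 80 same-barcode counts within 100 µm.

The floating-rolony detector encodes "the only section with rolonies in
an area, widely and sparsely covered": candidates are rolonies with no
same-barcode neighbour within 140 µm (tangential — sections are
compared in-plane) on any section > 1 away; a section qualifies with
≥ 3 single-linkage clusters at a 50 µm cut (single linkage is the
natural reading of "rolonies/clusters … beyond 50 µm"); among
qualifying sections the widest tangential bounding-box diagonal wins.
Exclusion then removes scanned-region rolonies within 2 sections
(configurable to 3) of the anchor — the soma section when known, the
flagged section otherwise. Non-neural cells are removed unless ≥ 3
rolonies lie ≥ 200 µm (3-D) from the soma or rolony centroid.

## Cortical flatmap

Columns run from each outer-boundary voxel of the labeled volume
(cortex voxels with a 6-neighbour carrying the outside label) to the
nearest inner-boundary voxel; every cortical voxel joins its nearest
column segment and takes depth% as its fractional arc position. The
reference plate is the column intersections at 50% depth. Per
hemisphere, PCA defines axis 1 = AP and axis 2 = ML, with signs fixed
so the largest-magnitude loading is positive; an explicit 2×3 basis can
replace the PCA, which matters for compact synthetic shells whose
principal axes need not align with anatomy. The AP value is the signed
graph-geodesic distance to the median-AP contour over the plate
adjacency graph (edges within 2.9 voxel lengths — a 5×5 neighbourhood
keeps the metrication error of shortest paths on digitized surfaces to
~1–2%, against ~8% for plain 8-connectivity); the ML value is the
distance to the median-ML contour along paths penalized for AP change
(edge weight = length + 5·|ΔAP|; an iso-AP mode that simply forbids
AP steps larger than one voxel is available via `mode = "iso"`). One
averaging pass over plate neighbours smooths both axes; each
hemisphere's minimum is shifted to 1. Point conversion is NA-aware
trilinear interpolation backed by a 50 µm non-zero average fill at the
cortical edge; extracortical points return NA.

Validation uses analytic fixtures built in code: a flat slab (exact
perpendicular columns, exactly linear depth, exactly unit-spaced plate
coordinates when medians fall on grid lines) and a half-cylindrical
shell (inner radius 300 µm, outer 900 µm, 24 slices at 25 µm voxels for
the headline run), where depth has the closed form (R−ρ)/(R−r) and
plate geodesics are cylinder geodesics. Residual errors are dominated
by half-voxel boundary quantization, which is why the depth check is on
the mean absolute error.

## Cell typing

CF cells have gated thalamic or midbrain counts; the rest are IT, split
into ITc at ≥ 5 contralateral rolonies. The ET/CT split seeds labels by
the median-y split of rolonies inside the fiber box (x 8250–9000,
y 3500–5000, z 6750–7500 µm; top half CT), then alternates (a) each ROI
rolony takes the modal label of its 10 nearest neighbours (3-D
Euclidean, registered µm) and (b) each cell takes the modal label of
its rolonies, which the rolonies inherit — until no label changes or
100 iterations (the cap guarantees termination; hitting it is logged).
Propagation stays ROI-scoped during iteration, matching the seeding
contract. Ties (5–5 of 10) keep the previous label, falling back to CT
— a deterministic, seed-order-independent rule. Finalization is a
single pass assigning every thalamic rolony the modal label of its 10
nearest labeled rolonies; a cell's type is the mode over its thalamic
rolonies, `unassigned` without any.

## Projection statistics

Laminar profiles are depth histograms on 1% (or 5%) bins. The
permutation KS test takes the maximal CDF gap on the 1% grid and
shuffles rolony depths between the two regions (sizes preserved, 1000
shuffles, RNG seeded per cell for reproducibility); p is the plain
fraction of shuffle distances ≥ the observed one — the (k+1)/(n+1)
correction is available via `plusOne` but off by default, matching the
fraction definition; the discreteness of binned KS values makes the
plain fraction mildly conservative, which the null-calibration check
quantifies. Groups are summarized as the percentage of cells with
p ≤ 0.05 plus a 2000-iteration percentile bootstrap CI (2.5/97.5%);
non-overlapping CIs flag group differences. (The percentage counts
cells with p ≤ 0.05 — i.e. *different* — consistent with the
classification rule.)

Cortical rolonies are prepared by dropping depths > 95% and everything
inside the injection disk on the ML-AP plate — centred on the median
soma location with radius the 95th percentile of soma distances to that
centre (the natural reading of the percentile exclusion; a fixed-radius
override exists), optionally mirrored contralaterally as a
local-exclusion control. Soma-depth groups split at ≤ 35 / (35, 60] /
> 60%; cells without somata are excluded.

The focal projection distance of a rolony is the mean of its shortest
⌈0.33·(n−1)⌉ pairwise plate distances (self excluded) — the 33% cap
tolerates up to about three focal clusters per cell — and the cell
value is the mean over rolonies; cells with fewer than 55 rolonies are
excluded, the size at which the subsampling error curve
(`subsamplingErrorCurve()`, 100 resamples per size, median relative
error) levels off. Simulated retrograde tracing selects IT cells with
a soma and ≥ 10 rolonies within a 300 µm patch, flagging contralateral
specificity at patch/contralateral ratio ≥ 0.75. Reconstruction links
each point to its nearest neighbour and then repeatedly joins the two
closest clusters via their closest point pair, never exceeding
1000 µm per edge — a Euclidean spanning forest whose components are
exactly the parts of the cell closer than the cap.

## Problem sizes and limitations

The validation experiments run at desk scale by choice: 100 neurons ×
30 rolonies × 17 cycles for end-to-end recovery, 200 neurons for
ET/CT, 1000 cells × 1000 shuffles for the KS calibration, and the
half-cylinder above for the flatmap. Known limitations: the greedy
chaining is order-dependent in pathological equidistant configurations
(resolved deterministically, not globally optimally); consensus
clustering resolves N positions by majority and can in principle fuse
two true barcodes that differ only at positions never co-called, an
event with vanishing probability at realistic coverage; the flatmap
does not correct distortion at the lateral cortical edge or distinguish
folds toward the midline; and the generator's noise model is
independent per cycle, so correlated failure modes (focus loss over a
whole cycle, section tears) are out of scope.
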