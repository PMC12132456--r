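---
title: "Decoding fluorescent-protein identity from hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding fluorescent-protein identity from hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdex)
```

## The problem

Conventional multicolour fluorescence microscopy separates fluorescent
proteins (FPs) with a handful of broad filter channels, which caps how many
FPs can be used together: spectrally adjacent FPs bleed into each other's
channels. Hyperspectral acquisition instead records a fine-grained emission
spectrum for every pixel — here, four sequential excitation blocks whose
~8.9 nm emission channels concatenate into a single 100-dimensional
spectrum per cell:

| block | lasers (nm) | emission (nm) | channels |
|------:|------------:|--------------:|---------:|
| 1     | 405         | 420–695       | 31       |
| 2     | 458, 561    | 455–695       | 27       |
| 3     | 488         | 500–695       | 22       |
| 4     | 514, 594    | 517–695       | 20       |

Because the same emission spectrum is re-weighted by each block's
excitation efficiency, one FP yields a characteristic *block-structured*
100-channel fingerprint. `specdex` decodes these fingerprints: it assigns
each segmented cell the FP whose reference spectrum it most resembles, and
provides the surrounding machinery — spectrum extraction, reference-library
construction, palette design, error modelling, rendering, and a synthetic
scene simulator that makes the whole pipeline testable without a
microscope.

## The decoding model

Spectra are compared by cosine similarity. For two non-negative spectra
$a, b \in \mathbb{R}^{100}$,

$$\mathrm{CS}(a,b) \;=\; \frac{\sum_{ch} a_{ch}\, b_{ch}}
  {\sqrt{\sum_{ch} a_{ch}^2}\,\sqrt{\sum_{ch} b_{ch}^2}},$$

the cosine of the angle between the vectors. The normalisation removes
absolute intensity, so only spectral *shape* is compared: CS = 1 for
spectra that are positive scalar multiples of each other, CS = 0 for
spectra whose non-zero channels do not overlap, and CS ∈ [0, 1] always,
because intensities are non-negative. Classification is
maximum cosine similarity (MCS): a cell is assigned
$\arg\max_r \mathrm{CS}(\text{cell}, \text{reference}_r)$ over a candidate
set of reference spectra. Scale invariance is the key property — cells
differing 100-fold in expression level decode identically as long as their
shape is preserved.

Two accuracy statistics quantify decoding:

* **Error rate** (monoculture, truth known):
  $100 \times \#\text{misclassified} / \#\text{cells}$. Cells whose
  spectrum has zero norm cannot be compared and are labelled
  `unclassified`; they count as misclassified, the conservative choice.
* **% false positive** (FP-minus-one co-culture): one FP is omitted from
  the culture while the decoder still offers it, so its ground-truth count
  is zero and $100 \times \#\text{cells called as the missing FP} /
  \#\text{cells}$ measures spurious calls.

A pairwise CS of about 0.9 acts as the resolvability threshold: pairs
below it decode with low error, pairs at or above it confuse badly.

## Pipeline assumptions and choices

**Channel grid.** Acquisition software reports emission ranges and a
nominal ~8.9 nm bandwidth, not channel centres. `specdex` fixes channel
$k$ of a block at `start + (k − 0.5) × width` — a deterministic convention
the simulator and any spectra sampled onto the grid share. No re-binning
between differing schemes is attempted.

**Extraction.** The 100-channel stack is maximum-intensity projected to a
single image; a label mask (external — e.g. Cellpose — or the built-in
fallback `segment_mip()`: Gaussian smoothing, Otsu threshold, watershed on
the distance transform, minimum area 20 px, smoothing sigma 2 px) is
applied to every channel, and the per-mask mean pixel intensity gives the
cell × channel matrix. No background subtraction or flat-field correction
is applied before averaging. External masks are first-class: the fallback
exists so the pipeline runs end-to-end without any external model, not to
compete with trained segmenters.

**References.** A reference spectrum is the channel-wise mean over all
cells of a monoculture, stored *unnormalised* (CS is scale-invariant, so
normalisation is cosmetic; a normalised export exists for plotting).
Zero-radiance cells are excluded from averaging with a warning. No outlier
rejection is performed.

**Dim-FP detection.** Radiance — the summed mean intensity over all 100
channels — is log10-transformed per cell. Per-FP radiance distributions
are compared by the exact empirical 1-D Wasserstein-1 distance (the
integral of |ΔCDF| over the pooled order statistics, implemented in
`wasserstein1()` since no installed package provides it), clustered by
average-linkage hierarchical clustering, and the cluster with the lowest
mean log10 radiance is flagged dim. Average linkage is a choice — the
distance is prescribed, the linkage is not — made because it is the
standard robust default for non-Euclidean distance matrices. The cut
(`n_groups`, default 2) is exposed rather than hard-coded: real libraries
have shown a distinct dim cluster sitting more than 2.5 orders of
magnitude below the rest, which a 2-group cut recovers.

**Tie-breaking.** Exact MCS ties are resolved to the first candidate in
library order and flagged `ambiguous`; real spectra essentially never tie,
but determinism matters for testing. There is no minimum-MCS rejection by
default (every cell is classified); `min_mcs` enables rejection.

**Intensity strata.** `stratify_by_intensity()` splits cells into
equal-count groups by radiance *rank* (remainder to the lower strata), not
by value thresholds, so duplicated radiances still split deterministically.

## Palette design

Given the library's pairwise CS matrix, `enumerate_feasible_tuples()`
returns every N-subset whose pairwise similarities all fall below the
threshold, sorted by the objective — the sum of pairwise similarities, the
natural "total mutual overlap" of the palette — and
`optimal_ntuple()` returns the minimum. The search walks the
compatibility graph depth-first, pruning any branch containing an
infeasible pair; results are provably identical to brute force over all
$\binom{k}{n}$ subsets (tested against exactly that oracle) while staying
fast for libraries of ~40 FPs.

Feasibility is **strict** `< 0.9` by default. The threshold's strictness is
genuinely ambiguous in practice (exclusion "at or above" vs "above"
describe the same intent), so it is configurable (`strict = FALSE` gives
`<=`), with the stricter reading as default — at the boundary a pair is
treated as unresolvable. A near-duplicate pre-filter
(`dedupe_prefilter()`: connected components of the ≥-threshold graph,
earliest member kept) is provided but **off by default**: combined with
pairwise exclusion it is redundant, and it can silently drop an FP the
user asked to include. Objective ties are broken lexicographically by
member names; enumeration is capped at `max_results` (default 10,000) with
an explicit truncation flag.

`green_panel_matrix()` ships a 7-FP fixture constructed from a reported
green-panel pattern structure (two high-similarity patterns of four and
two FPs, cross-pattern pairs at 0.81–0.87, one large-Stokes-shift outlier
at 0.15–0.58; within-category values set to range midpoints). Its
combinatorics are category-determined: exactly 8 feasible 3-tuples — one
FP per pattern — and none larger, which the tests assert.

## The spatial clone error model

Cells whose neighbours share their label corroborate each other. With
independent per-cell misclassification probability $P$, an entire clone of
$N$ cells is mislabelled with probability $P^N$: at $P = 0.0032$ (a 0.32%
error rate), a 2-cell clone fails at $1.024 \times 10^{-5}$ — order one
cell per hundred thousand — and the probability falls exponentially in
$N$. Clones are modelled on a 3×3 grid with the founder fixed at the
centre and the remaining $N-1$ cells on the 8 surrounding squares, giving
$\binom{8}{N-1}$ distinct placements (these sum to $2^8 = 256$ over
$N = 1..9$). Per-cell errors are taken independent of grid position, so
placement affects visualisation and future spatially correlated
extensions, not the probability; the Monte-Carlo simulator
(`simulate_clone_errors()`, seeded, bit-reproducible) draws placements and
errors and converges to $P^N$.

## Paint-by-number rendering

`render_classification()` produces the decoded overlay: non-cell pixels
show the grayscale MIP; each cell's pixels take its predicted FP's colour,
brightness-scaled by radiance. The transfer function is a convention (the
quantitative content lives in the CSV/JSON outputs, and the tests treat it
as such): per-image min–max scaling of log10 radiance to [0.3, 1],
gamma-adjustable, multiplied into the RGB fill. The 0.3 floor keeps dim
cells visible. Hidden FPs (`visible_fps`) and colour-off mode render
grayscale; highlight outlines use the exact complement
$(255-r, 255-g, 255-b)$ of the fill colour; outlines are the 4-neighbour
boundary pixels of each mask region. Rendering is pure: identical inputs
give bit-identical PNG payloads. `legend_counts()` partitions all cells
(including `unclassified`) and `cell_spectrum()` is the non-interactive
equivalent of clicking a cell: its spectrum, its predicted reference, and
their CS, ready for side-by-side plotting.

## The synthetic generator

`simulate_scene()` and `simulate_experiment()` stand in for microscope
data, with exact ground truth (mask + per-cell labels) emitted alongside
every scene. Design choices:

* **Spectra.** Gaussian excitation and emission bands (FWHM-parameterised)
  per FP, evaluated on the channel grid: per channel, brightness × (sum of
  excitation efficiencies at the block's lasers) × emission density at the
  channel centre. Channels within 10 nm above a block's highest laser are
  zeroed (the detector's laser-notch guard; the default scheme's block 3
  starts 12 nm above its 488 nm laser). Intensities below $10^{-6}$ of the
  brightness scale are clamped to zero so out-of-range FPs give exactly
  all-zero spectra. Real FP spectra are asymmetric with vibronic
  shoulders; Gaussians reproduce the *block structure* and controllable
  pairwise overlap that the decoder's contracts depend on, not true
  shapes. Measured spectra can be supplied via a reference-library CSV
  whenever shape fidelity matters — so passing tests demonstrate the
  pipeline's correctness on block-structured spectra with realistic
  overlap, not decoding accuracy on any particular real FP set.
* **Default panel.** `default_fp_panel(n)` spans 420–695 nm; spacing was
  calibrated once so the first 12 members have all pairwise CS < 0.9
  (maximum 0.858 — deliberately close to the hardest-resolvable regime) and
  members 13–15 crowd the green-yellow region to exercise infeasibility;
  `confusable_fp_pair()` provides a CS ≈ 0.995 pair for negative tests.
* **Cells.** Discs on a jittered grid; expression levels log-normal
  (meanlog = log(500), sdlog = 0.5), emulating transfection variability
  over roughly two orders of magnitude.
* **Noise.** Additive Gaussian read noise (sd 3 by default, against a
  background level of 2) plus optional Poisson shot noise on expected
  counts, clamped at zero. No optical PSF, photobleaching,
  autofluorescence, or chromatic aberration — scenes are "easy" optically;
  what is being stressed is spectral confusability, not segmentation.
* **Clonal growth.** Founders grow into adjacent-disc clones (size
  doubling per day, capped at 9 — the 3×3 neighbourhood of the clone
  model) with expression multiplied by 0.6 per day, emulating plasmid
  dilution across divisions.
* **Determinism.** Every stochastic step runs under a caller-supplied seed
  through a save/restore wrapper, so outputs are pure functions of
  (spec, seed) and the caller's RNG stream is untouched.

## Numerical conventions

* Zero-norm spectra are *errors* in the similarity kernel (silently
  returning 0 would masquerade as orthogonality); only the decoder maps
  them to `unclassified`.
* CS values are clamped to [0, 1] against float overshoot; float
  comparisons in tests use a relative tolerance of 1e-9 unless an exact
  identity is asserted.
* Stack and mask TIFF I/O stores 16-bit integer counts (values rounded;
  above 65535 is an error). Detector counts are integral, so nothing is
  lost on real data; in-memory arrays keep full double precision.
* All CSVs carry a `# specdex-format v1` first line; readers reject
  unknown versions.

## Problem sizes in the test suite

The suite regenerates everything from code: the 12-plex study uses
100-cell monocultures for references and 150-cell scenes for each of the
12 monoculture error rates and 12 FP-minus-one false-positive rates; the
equal-mix recovery uses a single 3,000-cell 1:1:1 scene; Monte-Carlo clone
errors use $10^6$ replicates per clone size. These sizes give the
statistical resolution the assertions need (e.g. a 0.5% false-positive
bound at 150 cells, a ±2.2 percentage-point 99% CI at 3,000 cells) while
keeping the full suite under half a minute.

## Limitations

* No linear unmixing: cells co-expressing several FPs get the single best
  match, not a mixture decomposition.
* No spectral calibration or re-binning across acquisition schemes;
  spectra are only comparable within one scheme.
* The clone model assumes independent errors; spatially correlated noise
  would break $P^N$.
* The simulator's Gaussian spectra understate the heavy red tails of real
  FPs; absolute error rates on real data will differ from simulated ones
  even at matched pairwise CS.
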