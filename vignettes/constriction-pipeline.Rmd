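---
title: "Quantifying constriction-induced cell-state change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying constriction-induced cell-state change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CellSqueeze implements the quantitative analysis stack for experiments in
which circulating tumour cells transit a microcapillary-mimicking device —
a series of constrictive channels (CC) of 30, 20, 10 and 5 µm width, each
150 µm long and followed by a 150 µm relaxation chamber (RC) — and are then
profiled by immunofluorescence, calcium imaging, barrier-permeability
assays, tumorsphere culture and differential-expression screens. Because
raw microscopy from such experiments is large and instrument-specific, the
package pairs every analysis operation with a seeded synthetic-microscopy
generator that produces the same kinds of data with known ground truth, so
each estimator can be validated by parameter recovery.

# The deformation model

The deformation index of a cell at flow-axis location $x$ is
$DI = D_x / D_0$, the ratio of its major axis there to its undeformed major
axis. Percent median deformation of a region is
$100 \cdot \mathrm{median}(DI_\mathrm{region}) /
\mathrm{median}(DI_\mathrm{baseline})$, and "percent increase" is that
value minus 100. Headline summaries expect at least 20 cells per location
(`percentMedianDeformation()` warns below that). Medians of even-length
samples are the mean of the two central order statistics; this convention
is pinned and tested against a sort-based oracle because the percent
values are ratios of medians.

The synthetic squeeze model is deliberately geometric rather than
mechanical: a cell of resting diameter $D_0$ entering a channel of width
$w < D_0$ is rendered as an ellipse with minor axis clamped to $w$ and
major axis $D_0^2 / w$, i.e. 2D projected-area conservation. This is the
simplest model that preserves the inverse relationship between channel
width and deformation without inventing viscoelastic mechanics (explicitly
a non-goal — no stresses, no fluid simulation, no point-spread optics). In
the relaxation chamber the major axis is
$D_0 \,(1 + \rho\,(D_0/w - 1))$ with a retention fraction
$\rho \in [0, 1]$ interpolating linearly between full elastic recovery
($\rho = 0$) and full retention ($\rho = 1$); partial retained deformation
is what the assay observes, and a single dimensionless knob is the
simplest way to inject it. The generator default is $\rho = 0.3$ for every
channel: a moderate retained fraction chosen once as a plausible
mid-range value; it is a generator condition, not a fitted quantity.

Whether $D_0$ should be the same cell's pre-device measurement or a cohort
baseline is genuinely open in this kind of assay; `transitMorphometrics()`
links cells across frames by nearest lane position and uses the per-cell
baseline when linking succeeds, falling back to the cohort baseline median
otherwise, and records which source was used (`d0_source`).

# Synthetic microscopy

All generators share a camera model: Gaussian read noise plus
Poisson-like photon scaling, $\sigma^2(I) = \sigma_r^2 + s \cdot I$,
clamped at zero — the standard fluorescence-camera noise description.
Seeds are explicit arguments; identical seeds give bit-identical output.

Synthetic IF plates render non-overlapping cells (a nucleus disk of 5 µm
radius inside a 9 µm cell body) at uniformly random positions, with
per-cell lognormal brightness variation (CV 0.25) and per-marker
condition effects applied multiplicatively to both compartments. The
observed image is `truth × flatfield + darkfield + noise`, with a radial
quadratic vignette as the default flatfield and a constant darkfield.
Uniform placement matters: the illumination estimator assumes foreground
lands without spatial structure, and cells are kept non-overlapping so
segmentation ground truth is unambiguous (robustness to touching objects
is tested separately with constructed touching-blob fixtures).

What the generator does *not* emulate — out-of-focus light, chromatic
shifts, overlapping and partially adherent cells, autofluorescence,
spectral bleed-through — bounds what passing tests show about real data:
they validate the estimators' conventions and statistical calibration, not
robustness to every optical artefact.

`simulateFeatureTable()` exposes the plate's sampling layer (lognormal
cell variation × condition effect × lognormal measurement noise) without
rendering pixels. The statistical-calibration studies (type-I error over
hundreds of replicate plates, power at a 1.5× effect) run on this layer;
rendering and segmenting hundreds of image plates would only re-test the
segmentation path, which the detection criteria already cover on rendered
plates.

# Illumination correction

The model is `observed = truth × flatfield + darkfield` per channel, the
standard multiplicative/additive decomposition of shading bias. The
estimator works from an ensemble of frames (e.g. one per well):

- **Darkfield**: the per-pixel temporal median, smoothed by a quadratic
  surface. This assumes any pixel is foreground in fewer than half the
  frames; dense coverage biases it slightly upward (the background
  quantile shifts), which is documented behaviour, and any spatially
  uniform true background is absorbed into it.
- **Flatfield**: a retrospective shading fit. Foreground objects are
  detected per frame (threshold at darkfield + 5 estimated noise SDs,
  connected components ≥ 20 px). Each object is reduced to a single
  brightness plateau: objects showing two log-intensity levels — a bright
  nucleus inside a dimmer body — are split at the midpoint of their
  10–90% log-intensity spread and only the dominant level is kept, kept
  *whole*, because truncating a plateau's noise against a window would
  shrink the within-object shading slope (regression dilution). The log
  flatfield is then fit as a degree-4 polynomial surface to all
  within-object shading jointly, with a free per-object intercept
  absorbed by within-object demeaning — a fixed-effects regression that
  integrates local shading gradients into a global field while being
  exactly invariant to object-to-object brightness. The surface is
  exponentiated and normalized to mean 1.

Degree 4 is a bias/variance choice: realistic vignettes are smooth and
radial-ish, and higher degrees inflate the variance of the corner
extrapolation (corners are rarely covered by foreground). At the default
plate design with 48 frames, the estimator recovers an injected 2×
corner vignette to a few percent and a uniform field to under 1% on
uniform-brightness content. At 8 frames the estimate is usable for
correction but noisier; below 8 frames the function warns. Degenerate
inputs degrade explicitly: a single frame yields a smoothed-frame
flatfield with a warning, an all-zero or foreground-free channel yields an
identity model with a warning.

Correction is `(observed − darkfield) / flatfield` clamped at zero, with
the clamped-pixel count recorded in metadata.

# Thresholding and segmentation

Global thresholds use minimum cross-entropy (MCE): for a split of the
histogram at $t$ with below/above intensity sums $S_0, S_1$ and means
$\mu_0, \mu_1$, the objective $-(S_0 \log \mu_0 + S_1 \log \mu_1)$ is
minimized by exhaustive search. Integer images with ≤ 256 levels use
their exact levels; float images are binned to 256 equal-width bins so
the search equals a brute-force oracle on 8-bit data (tested). Constant
images raise an error rather than inventing a threshold.

Nuclei are MCE-thresholded connected components with a minimum area (20
µm² default); touching nuclei are optionally split by a watershed on the
foreground distance transform, whose `tolerance` acts as the minimum seed
separation. A curvature-based split is not provided: distance-transform
maxima are the standard, deterministic choice and the one whose oracle
(counting maxima) is testable. Cell bodies are segmented by
marker-controlled propagation from nucleus seeds (EBImage's `propagate`)
over the MCE foreground of the body channel augmented with all nuclear
pixels; cells keep their seeding nucleus label, foreground components
without a nucleus are discarded, and a nucleus outside the body
foreground becomes its own flagged cell. Cytoplasm is per-label
subtraction, so `area(cell) = area(nucleus) + area(cytoplasm)` holds as
an exact set identity (tested pixelwise). Cells touching the image border
are flagged (`qc_border`) rather than silently dropped, so downstream
filtering is explicit; partial border cells bias axis and area statistics
and are excluded by the profiling stage.

Feature extraction uses 0-based (row, col) pixel indices with the origin
at top-left, physical coordinates `index × pixelSize + origin`. Major and
minor axis lengths come from the ellipse with matching normalized second
central moments ($\mathrm{axis} = 4\sqrt{\lambda}$); the moment ellipse
is deterministic and standard where "major axis" is otherwise not defined
operationally. Features are invariant to translation and 90° rotation
within 1% (tested).

# Single-cell profiling statistics

The pipeline order is fixed: QC flags → IQR outlier filter → robust-Z →
PCA → 2D embedding. Normalization to the control median operates on
unstandardized values and serves plots and fold-change summaries, never
the embedding input.

- **N:C ratio**: $\log_{10}$ of mean nuclear over mean cytoplasmic
  intensity; non-positive denominators yield `NA` with a QC note.
- **Outlier filter**: a cell is removed when *any* feature falls outside
  $[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$, $k = 1.5$, with
  linear-interpolation quantiles (R type 7 — pinned so the worked
  examples are exact), computed per condition × timepoint stratum. The
  union-across-features rule and the strata are the package's reading of
  "removed based on the IQR of each feature"; both are configurable.
- **Robust Z**: $(x - \mathrm{median}) / (1.4826 \cdot \mathrm{MAD})$;
  the 1.4826 constant makes the scale normal-consistent. Zero-MAD
  features cannot be standardized and are dropped from embedding input
  with a warning.
- **PCA**: scores on the smallest leading set of components reaching 97%
  cumulative variance, rank-truncated, with signs fixed
  (largest-magnitude loading positive) for determinism.
- **Embedding**: UMAP to 2D, single-threaded under a fixed seed so runs
  are reproducible. It is a visualization aid; no downstream statistic
  reads embedded coordinates.
- **Group testing**: Mann-Whitney U with midranks. The two-sided p-value
  is exact (null permutation distribution) when $n_A + n_B \le 12$
  without ties — the cutoff keeps full enumeration cheap while covering
  the sizes where the normal approximation is weakest — and otherwise
  uses the normal approximation with tie and continuity correction
  (within 0.01 of exact at $n = 10$ vs 10, tested). BH adjustment is
  applied across timepoints within each feature by default ("across
  timepoints"); a global family is available behind `bhFamily`.
- **Fold change**: mean of per-cell means, treated over control
  (mean-of-means; the median-based alternative is a one-liner on the
  same table but mean-of-means is the default estimator for bar-graph
  style summaries).

Calibration, at the study conditions of the generator defaults: across
hundreds of simulated null plates the fraction of BH-adjusted rejections
at nominal 0.05 stays a few percent at most; at a 1.5× effect with 200
cells per group the fold change is recovered within a few percent and
detected essentially always. The test suite runs 500 null and 200 effect
replicates; the acceptance script reruns 300 and 100.

# Dynamics

Calcium fold change is `max(in-region intensity) / mean(baseline
intensity)` with the baseline window strictly preceding the response —
max-over-baseline, not ΔF/F, because that is the extraction convention
for transit imaging where a single influx peak is the signal. The
statistic is scale-invariant.

Permeability uses the two-compartment first-order exchange model
$dI_t/dt = P\,(S/V)\,(I_v - I_t)$: over an initial window where
$P\,(S/V)\,t \ll 1$ the accumulation is linear and
$P = (V/S)\; \mathrm{slope} / (I_v - I_t(0))$, with the slope from OLS
over the first 10 frames by default (2-min frames over 90 min are the
acquisition defaults). The estimator's bias is known and one-sided: as
the window leaves the linear regime the slope, hence $P$, is
underestimated by roughly $k\,t_\mathrm{window}/2$; at
$k\,t_\mathrm{window} < 0.05$ the error stays under 2% (tested), and the
estimate remains monotone in the true $P$ across a 100-fold sweep. $S/V$
is a user input because compartment geometry is device-specific.

# Tumorspheres and DEG classification

Sphere areas come from dark-blob segmentation (MCE threshold, hole fill)
in µm²; growth rate is the OLS slope of mean area versus day — the
simplest model consistent with linear-looking mean-area curves — and
condition contrasts are rate ratios, with a flagged `NA` on a zero
denominator.

DEG classification labels a gene `up` when $p < 0.01$ and
$\log_2 FC > 0.6$ (a 1.5-fold change), `down` symmetrically, `ns`
otherwise. The p-value comparison direction is configurable because the
two natural readings (`<` vs `≥`) both occur in practice; `<` is the
default. No multiple-testing adjustment is applied by default at this
stage (classification operates on whatever p-values the upstream model
produced; `adjusted = TRUE` switches to an adjusted-p column). Top-gene
selection sorts by p ascending with ties broken by $|\log_2 FC|$
descending then gene id, so selections are deterministic.

# Numerical choices, problem sizes, limitations

- Degenerate inputs fail loudly: zero baselines, constant images,
  empty groups, non-finite cutoffs are errors; empty *foregrounds* are
  empty results, not errors.
- Validation problem sizes (chosen to exercise each estimator's
  assumptions, not to stress throughput): 20-cell transit sequences at
  0.5 µm/px; 8-well, 40-cell plates for detection; 48-frame ensembles
  for illumination recovery (shading estimation is ensemble-hungry by
  nature); traces at the 2-min/90-min acquisition grid; 7-day sphere
  series.
- The moment-ellipse axis of a strongly squeezed cell slightly
  underestimates the rendered axis at coarse pixel sizes; at 0.5 µm/px
  the recovered per-region median DI sits within a couple percent of
  truth.
- The illumination estimator requires objects of locally near-constant
  brightness; strongly textured cells would violate the plateau
  assumption and inflate its variance.
- No cell tracking beyond nearest-lane linking, no mechanical modulus
  estimation, no enrichment analysis, no learning-based segmentation —
  all deliberate non-goals.
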