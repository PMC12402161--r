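# CellSqueeze

Quantitative image analysis for microfluidic constriction cytometry.

When circulating tumour cells transit capillary-scale constrictions they
deform, flux calcium, and — hours later — shift marker expression,
transcription, barrier-crossing behaviour and sphere-forming capacity.
CellSqueeze implements the full measurement stack for such experiments as
one tested R package, for imaging scientists and analysts who need the
conventions pinned down and reproducible:

- **Deformation-index morphometrics** across a device of sequential
  constrictive channels (CC, 30/20/10/5 µm) and relaxation chambers (RC):
  `DI = Dx / D0` (major axis at location *x* over the undeformed major
  axis), per-region **% median deformation**
  `100 · median(DI_region) / median(DI_baseline)` and its increase over
  100, from ≥ 20 cells per location.
- **Illumination correction**: `observed = truth · flatfield + darkfield`,
  with both fields estimated from frame ensembles by a retrospective
  within-object shading fit.
- **Single-cell segmentation**: minimum cross-entropy (MCE) thresholding
  of nuclei, distance-transform watershed splitting, nucleus-seeded
  propagation of cell bodies, cytoplasm by exact per-label subtraction.
- **Profiling statistics**: log10 N:C ratios, IQR outlier removal
  (`k = 1.5`), robust-Z (MAD · 1.4826), PCA retaining 97% variance, seeded
  UMAP, control-median normalization, Mann-Whitney U (exact for
  `n_A + n_B ≤ 12`) with Benjamini-Hochberg correction across timepoints.
- **Dynamics**: calcium fold change (in-region maximum over pre-entry
  baseline) and endothelial permeability
  `P = (V/S) · slope / (I_vessel − I_tissue(0))` from the initial rise of
  a 2-min/90-min dye time-lapse.
- **Tumorsphere growth**: brightfield sphere areas and OLS growth rates
  with condition rate ratios.
- **DEG thresholding**: up/down/ns at `p < 0.01` and `|log2FC| > 0.6`
  (1.5-fold), top-n-by-p selection with deterministic tie-breaks.

Every input has a seeded synthetic generator with known ground truth
(`generateTransitSequence()`, `generateIFPlate()`,
`generateCalciumSeries()`, `generatePermeabilitySeries()`,
`generateTumorsphereSeries()`), so each estimator is validated by
parameter recovery rather than by fixtures.

## Worked example

Generate a 20-cell transit sequence (resting diameter 15 ± 1 µm), segment
each region frame, link cells to their baseline shapes and summarize
deformation per region:

```r
library(CellSqueeze)

geom   <- deviceGeometry(pixelSize = 0.5)           # 30/20/10/5 µm device
params <- squeezeModelParams(baselineDiameterMean = 15, seed = 42)
sim    <- generateTransitSequence(geom, params, 20)
shapes <- transitMorphometrics(sim$stacks, geom)
deformationSummary(shapes)
#>     region  n median_di pct_median_deformation pct_increase
#> 1 BASELINE 20    1.0000                 100.00    0.000e+00
#> 2    CC_30 20    1.0001                 100.01    7.344e-03
#> 3    RC_30 20    1.0000                 100.00   -4.805e-03
#> 4    CC_20 20    0.9998                  99.98   -2.203e-02
#> 5    RC_20 20    1.0000                 100.00   -1.990e-13
#> 6    CC_10 20    1.5186                 151.86    5.186e+01
#> 7    RC_10 20    1.1549                 115.49    1.549e+01
#> 8     CC_5 20    3.0750                 307.50    2.075e+02
#> 9     RC_5 20    1.6006                 160.06    6.006e+01
```

Reading the output: 15 µm cells never touch the 30 and 20 µm channels
(median DI ≈ 1, % increase ≈ 0); in the 10 and 5 µm channels they elongate
(median DI 1.52 and 3.08, i.e. +52% and +208% median deformation), and in
the following relaxation chambers they recover partially (+15% and +60%
retained), reflecting the injected retention fraction of 0.3. The
recovered medians match the generator's ground truth within ~2%.

Classify differential-expression statistics with the standard cutoffs:

```r
genes <- data.frame(gene  = c("THY1", "SUCNR1", "UCHL1", "COL1A2", "ACTB"),
                    logFC = c(2.1, 1.4, 0.9, -0.8, 0.05),
                    pvalue = c(1e-6, 4e-4, 0.003, 0.008, 0.7))
classifyDEG(genes)[, c("gene", "label")]
#>     gene label
#> 1   THY1    up
#> 2 SUCNR1    up
#> 3  UCHL1    up
#> 4 COL1A2  down
#> 5   ACTB    ns
```

End-to-end runs are driven by a serializable config
(`runPipeline(defaultRunConfig(...))` or a YAML file via
`readRunConfig()`); each stage writes CSV outputs plus a JSON manifest
with its parameters and seed.

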