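---
title: "Mapping raised-bog land use and accounting for its CO2 emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping raised-bog land use and accounting for its CO2 emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatluc)
```

## The problem

Degraded raised bogs are a patchwork of land uses -- industrial cutaway,
domestic cutover, drained grassland, afforestation, remnant high bog, open
water and built infrastructure -- and each use carries a very different
annual CO2-C flux. Quantifying national emissions from such landscapes
therefore needs three things chained together: a land-use map from
multispectral satellite imagery, a statistically defensible estimate of the
area of each class (pixel counting is biased once the map contains
classification error), and emission factors applied to those areas.

`peatluc` implements this chain end to end as seeded, testable code:

1. **Synthetic scene generation** -- a seven-class LUCIP ground truth with
   contiguous patches, per-class ten-band reflectance signatures, a
   multi-temporal scene series with contiguous cloud fields encoded in a
   QA bitmask, and labelled training polygons.
2. **Compositing** -- scene-level cloud filtering, QA-based cloud masking,
   per-pixel temporal median compositing, and NDVI/NDWI computation,
   yielding a 12-layer feature stack.
3. **Classification** -- a random-forest pixel classifier (20 trees,
   sqrt-features splits, majority vote) with variable importance.
4. **Validation and area estimation** -- stratified random validation
   sampling, confusion-matrix statistics (OA/UA/PA), and the
   "good-practice" area-based error matrix yielding unbiased class areas
   with standard errors.
5. **Emission accounting** -- tiered (IPCC Tier-1 / country-specific
   Tier-2) emission factors applied to the estimated areas, with
   uncertainty ranges.

Because every stage consumes the synthetic generator's output, the entire
pipeline runs and is tested without any satellite download.

## The statistical core

### Stratified unbiased area estimation

Validation points are drawn by stratified random sampling within the *map*
classes. With $n_{ij}$ the number of points mapped as class $i$ and
reference-labelled as class $j$, $n_{i\cdot}$ the stratum sample sizes and
$W_i = A_i / A_{\mathrm{tot}}$ the mapped-area weights, the area-based error
matrix is

$$\hat p_{ij} = W_i \frac{n_{ij}}{n_{i\cdot}},$$

the unbiased area of reference class $j$ is
$\hat A_j = A_{\mathrm{tot}} \sum_i \hat p_{ij}$, and its standard error is

$$\mathrm{SE}(\hat p_{\cdot j}) = \sqrt{\sum_i W_i^2\,
  \frac{(n_{ij}/n_{i\cdot})\,(1 - n_{ij}/n_{i\cdot})}{n_{i\cdot} - 1}},$$

with the 95% interval $\hat A_j \pm 1.96\, A_{\mathrm{tot}}\,
\mathrm{SE}(\hat p_{\cdot j})$. The normal-approximation multiplier 1.96 is
the package's choice; the protocol this follows does not fix one. When the
confusion matrix is diagonal the estimator collapses to pixel counting with
zero standard error, a limit the tests assert.

Two overall accuracies exist and are deliberately kept apart:
`accuracyReport()` gives the count-based OA $= 100\sum_i n_{ii}/n$, while
`areaWeightedOA()` gives $100\sum_j \hat p_{jj}$, the percent of *area*
correctly mapped. They differ exactly as the stratum weighting dictates.

### Emission accounting

Per class and tier, emission (t CO2-C y$^{-1}$) $=$ area (ha) $\times$ EF
(t CO2-C ha$^{-1}$ y$^{-1}$), with the range obtained from the EF's 95% CI
bounds. Tier totals sum the classwise bounds, which assumes perfect
dependence between classes; the report labels this a "naive" range because
no fully specified alternative is available for the packaged factors.
Remnant peatland, water and built-up areas have no published emission
factor; they are carried as explicitly excluded classes, never as zeros.

The packaged EF table keeps its source's printed labels. For the two peat
extraction classes the published Tier-2 emission values equal the areas
multiplied by each *other's* EF; `computeEmissions()` detects this
arithmetic identity against the packaged published values and flags it in
the report notes rather than silently correcting either number.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixelSizeHa` | 0.01 | ha | a 10 m pixel, the common grid of the band set |
| `proportions` | (.10, .11, .43, .21, .13, .01, .01) | -- | class shares of a degraded raised-bog landscape (grassland dominant, water/built-up marginal) |
| `patchScale` | 20 | pixels | characteristic management-unit edge length; mean patch size is of order `patchScale`^2 |
| `noiseSd` | 0.01 | reflectance | within-class variability; small against the minimum inter-class signature distance (0.065) |
| `nScenes` | 10 | -- | enough acquisitions that every pixel is clear at least once under the cloud range |
| `cloudFractionRange` | (0.05, 0.30) | -- | per-scene cloud cover of a usable mid-latitude series |
| `maxCloudFraction` | 0.35 | -- | scene filter threshold (strict `<`); see below |
| `nTrees` | 20 | -- | ensemble size; `variablesPerSplit = "sqrt"` resolves to 3 of 12 features |
| `totalValidationPoints` | 1460 | -- | assessment sample size |
| `minPerStratum` | 50 | -- | floor so marginal classes (water, built-up) are still estimable |
| `referenceErrorRate` | 0 | -- | optional seeded interpreter-error simulation |

The default scene-filter threshold deserves a note. On a real archive of
thousands of acquisitions one discards everything with $\ge$ 10% cloud and
still has ample clear looks per pixel. The synthetic series is ten scenes;
filtering it at 0.10 against clouds drawn up to 0.30 can leave too few
scenes for gap-free compositing. The default therefore sits above the
generator's cloud range, so the filter passes all synthetic scenes, while
the strict-`<` semantics of the 10% rule are exercised directly by the
compositing tests. Users mirroring real practice set
`maxCloudFraction = 0.10`.

## What the generator emulates -- and what it does not

The spectral signatures are constructed constants, not measurements: they
encode the qualitative structure of the cover types (built-up brightest in
the visible; water darkest in the NIR; grassland and cutaway high-NIR;
cutover and remnant peatland the closest pair; SWIR contrast weaker than
visible/NIR) with additive Gaussian noise. Cloud fields are contiguous
smoothed-noise blobs -- spatially correlated occlusion is the realistic
stressor for a median compositor -- with the most extreme 70% of flagged
pixels set as opaque cloud (bit 10) and the fringe as cirrus (bit 11),
bit-compatible with the QA60 convention. Class maps are nearest-seed
mosaics (seeded region growing with ties to the lowest class code), giving
reproducible contiguous patches.

Deliberately absent: mixed pixels at class boundaries, within-class spectral
gradients and seasonality, cloud shadows and haze, topographic and adjacency
effects, and georeferencing error. Passing tests therefore demonstrate that
the chain of algorithms is correct and internally consistent, not that the
classifier would reach any particular accuracy on real imagery: with clean
class-mean spectra the synthetic recovery (>= 95% pixel agreement on a
300 x 300 scene, checked by the acceptance tests) is an upper bound, the
analogue -- not a reproduction -- of a real-world overall accuracy near 89%.

## Numerical conventions

- **Median**: per pixel and band over non-nodata observations; even counts
  average the two central values. Compositing the composite is the identity
  and scene order never matters.
- **Nodata**: always an explicit NA/mask, never a sentinel reflectance; a
  pixel with zero clear observations is nodata in all 12 layers, and
  index computation returns nodata (not an error) on zero denominators.
- **Ties**: majority-vote ties go to the lowest class code (votes are
  compared unnormalised); equal-distance ties in region growing likewise.
- **Pixel-in-polygon**: pixel-centre containment, even-odd rule; centres
  sit at half-integer coordinates so they never fall on integer-coordinate
  edges.
- **Display truncation**: printed accuracy tables conventionally truncate
  UA/PA/OA to integer percent (e.g. 244/252 = 96.8 prints as 96);
  `formatAccuracy()` truncates while stored values keep full precision.
  Emissions print as integer tonnes, totals as 2-decimal Mt.
- **Resampling**: native 20 m bands join the 10 m grid by nearest-neighbour
  duplication (`upsampleNearest()`), preserving reflectance values exactly.
- **Indices after compositing**: NDVI/NDWI are computed from the median
  composite, not per scene, matching a workflow in which index layers are
  appended to the final mosaic.

## File formats

No georeferenced-raster library is available to the package, so rasters are
stored as multi-page 32-bit-float TIFFs with a JSON sidecar (layer names,
per-layer offset/scale into [0, 1], integer flags, pixel size, metadata)
followed by one nodata-mask page per layer. Integer layers (class codes, QA
bits, provenance) round-trip exactly; reflectance layers to float32
precision (about 1e-7), which is three orders of magnitude below the
default reflectance noise. Polygons travel as GeoJSON FeatureCollections
with a `class_code` property; tables as CSV; the run manifest (config,
derived stage seeds, package version, MD5 checksums of every artifact) as
JSON.

## Determinism and problem sizes

Every source of randomness is seeded; each pipeline stage derives its own
seed from the single master seed, so `runPipeline()` twice with one
configuration yields byte-identical tables and identical class maps. The
test suite works at deliberately modest sizes -- 300 x 300 pixels for the
end-to-end recovery, 150 x 150 with 500 resampled validation draws for the
Monte-Carlo calibration of the area estimator, 500 x 500 for the
class-share checks -- sizes at which the statistical properties under test
are already well resolved while the whole suite runs in well under a
minute.

One calibration subtlety: the Monte-Carlo check compares each class's mean
estimated area to its true area in units of the Monte-Carlo standard error.
For an exactly unbiased estimator each standardised deviation is
approximately standard normal, so a fixed two-standard-error bound applied
to all seven classes simultaneously trips by chance in roughly a quarter of
runs even when everything is correct. The suite therefore also asserts the
properly calibrated joint check (the chi-square statistic of the seven
standardised deviations) alongside per-class CI coverage in [90%, 99%].

## Known limitations

- The forest classifier reports variable importance, but no claim is made
  about which bands rank highest on synthetic data beyond constructed
  cases (a single informative feature ranks first; pure noise ranks last):
  importance rankings are data-dependent.
- The naive range on emission totals overstates uncertainty relative to any
  propagation that treats classes as less than perfectly dependent.
- Mapped areas feeding the packaged emission examples are fixed inputs from
  the packaged tables, not quantities the synthetic pipeline re-derives.
- `run-all` at national raster scale (10^9 pixels) would need tiling, which
  is out of scope.

## A worked run

```{r, eval = FALSE}
library(peatluc)
res <- runPipeline(defaultConfig(seed = 421), outdir = "peatluc_out")
res$assessment$agreementPct          # truth recovery of the predicted map
res$assessment$accuracy$oa           # count-based OA of the assessment
unbiasedAreaEstimates(res$assessment$cm)

# published-table examples, no pipeline required
accuracyReport(confusionMatrixFromCounts(packagedValidationCounts(),
                                         rep(1, 7)))$oa
formatEmissionTable(computeEmissions(defaultClassAreas()))$totals
```
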