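---
title: "Simulating and evaluating CT texture features of mediastinal lymph nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating CT texture features of mediastinal lymph nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodetex)
```

## The problem

Mediastinal lymph-node staging in suspected lung cancer relies on chest CT,
FDG-PET and endobronchial ultrasound (EBUS), none of which is individually
reliable: enlarged or FDG-avid nodes are often benign (reactive hyperplasia,
granulomatous disease), and small metastatic nodes are missed. Quantitative
CT texture analysis (CTTA) asks whether the pixel-intensity histogram and
2D shape of a node's region of interest (ROI), drawn on a single axial
slice, carry diagnostic signal beyond size and uptake.

`nodetex` implements the full desk-scale machinery of such a study:

1. a **synthetic cohort generator** producing benign/malignant node
   phantoms (HU raster + ROI mask) and per-node multimodal records (EBUS
   categoricals, SUVmax/SUVpeak, maximal HU);
2. a **feature extractor** computing the first-order histogram features and
   2D shape descriptors from an image/mask pair after exclusion rules;
3. a **diagnostics layer**: group comparisons, ROC/AUC with Hanley–McNeil
   standard errors, fixed-cutoff sensitivity/specificity, a combined
   PET/CT positivity criterion, and single-split CART (stump) analysis;
4. a **pipeline** tying the three together reproducibly under one seed.

Patient images from such studies are not public, so the generator is the
package's data source; everything downstream treats its output exactly as
it would treat real exported ROIs.

## The feature set

With $X$ the HU values of the $N$ retained ROI pixels, $\mu$ their mean and
$\sigma$ their population SD:

* **mean attenuation** $\mu$ and **SD** $\sigma$ (population divisor by
  default; a sample-divisor flag exists and is recorded in output
  metadata);
* **size-normalized SD** $\mathrm{nSD} = \ln(\sigma)/\ln(N)$, which removes
  the strong size dependence of $\sigma$ in small ROIs. Note that published
  single-slice nSD magnitudes in this literature are not always computed
  with this formula (a plain $\sigma/N$ ratio also circulates, and yields
  values several-fold smaller); only the *direction* of class contrast is
  comparable across conventions, and that is all the package's tests rely
  on;
* **skewness** $m_3/\sigma^3$ and **kurtosis** $m_4/\sigma^4$ (the
  non-excess form matches the magnitudes conventionally tabulated, about 3
  for near-Gaussian texture; the excess form, minus 3, is also emitted);
* **entropy** $-\sum_i p_i \log_2 p_i$ over occupied histogram bins.
  Commercial CTTA software rarely documents its log base or bin width, so
  both are explicit here: base 2 (entropy is then nonnegative, in bits, and
  the simulated magnitudes of ~6.6–6.8 bits at 1-HU bins match tabulated
  single-slice values) and a default 1-HU bin width, configurable via
  `bin_spec()` and recorded in output metadata;
* **percentiles** of HU at 10/25/50/75/90/95%, linear interpolation
  between closest ranks;
* **shape**: area $A$ (pixel count × spacing²), perimeter $P$ (below),
  maximal Feret diameter $d_{\max}$ (caliper, convex hull + one pixel of
  extent), circularity $4\pi A/P^2$, roundness $4A/(\pi d_{\max}^2)$, and
  compactness $\sqrt{4A/\pi}/d_{\max}$. The compactness and roundness
  formulas are stated 2D conventions, not reconstructions of any vendor's
  unpublished definitions — published "compactness ≈ 0.97" values are not
  comparable and not claimed.

**Perimeter estimation.** Circularity is only as good as the perimeter
estimator. Marching squares on the *raw binary* mask locks every contour
vertex to a pixel-edge midpoint and overestimates smooth boundaries by
roughly 7% (a digitized disk then reads circularity ≈ 0.87, not 1). The
package therefore mollifies the indicator with a 3×3 box mean and runs
marching squares with linear interpolation of the 0.5-level crossings:
straight edges then measure their Euclidean length exactly (box-averaging
a half-plane puts the interpolated crossing on the true edge) and smooth
contours lose the staircase inflation. Residual bias comes from the
pixel-count area and the caliper diameter, both $O(1/r)$: a radius-20-px
disk reads circularity 0.983 and roundness 0.952, a side-40 square reads
0.820 against the ideal $\pi/4 \approx 0.785$. Shape extremal tests assert
these identities within a documented tolerance of 0.05 at those sizes.

**Exclusion rules.** Calcified pixels (default threshold 300 HU — the
source protocols exclude calcifications but publish no threshold) and an
optional arbitrary exclusion mask (vessels, beam hardening) are removed
before any statistic; $N$ is the post-exclusion count. An ROI emptied by
exclusions is a distinct error from an empty mask.

**Degenerate input.** A constant ROI has $\sigma = 0$; skewness, kurtosis
and nSD are then reported as a deliberate `NA` sentinel (never silent
NaN), entropy is exactly 0, and mean/percentiles equal the constant.

## The generative model

No generative model for nodal CT texture is published; the package's
phantom is the minimal model that exercises every extractor feature:

* **geometry** — an ellipse with short axis drawn per class, long axis a
  fixed class-specific ratio of it (ratio of the class mean diameters),
  random orientation; pixel spacing defaults to 0.8 mm (typical chest-CT
  in-plane resolution; only slice thickness is usually published) and the
  short axis is floored at 4 mm, the smallest node such studies puncture;
* **base texture** — i.i.d. Gaussian HU field at the class mean/SD inside
  the mask;
* **heterogeneity** — a spatially correlated low-HU blob component
  (Gaussian-smoothed noise field, correlation length 2.5 mm, positive part
  scaled to 60 HU depth) blended at a class weight, emulating
  heterogeneous echotexture/necrosis. The default weights (0.11 benign,
  0.38 malignant) mirror each class's heterogeneous-echogenicity
  prevalence. Because this component deliberately shifts the HU
  distribution, moment-recovery guarantees apply to the base-field
  parameters at weight 0;
* **calcification** — with class probability (defaults 0.10 benign / 0.04
  malignant; package choices, as per-class counts are unpublished), a
  ~3×3-px speck at 600 HU whose coordinates are recorded in the node's
  ground truth, so exclusion tests can check exact coordinate recovery;
* **scalars** — SUVmax from a zero-truncated normal, SUVpeak a fixed 0.82
  ratio of it (the ratio of the class mean SUVs; per-node coupling is
  never published), maximal HU from a floor-shifted gamma, EBUS
  categoricals as independent Bernoulli draws of the published
  prevalences. Size ≥ 1 cm is *derived* from the drawn short axis, not
  drawn — which keeps records internally consistent at the cost of an
  ~8-point shortfall against the separately-measured ultrasound prevalence
  in the malignant class (the published CT-diameter distribution and
  EBUS size calls are not jointly satisfiable; the benign class lands
  within half a point).

**Truncation correction.** Published cohort summaries are moments of the
*observed* — already floored — variables. Sampling
$\mathcal{N}(3.4, 2.4^2)$ and truncating at 0 would inflate the realized
mean to 3.78. `match_tnorm()` therefore solves for latent $(\mu_0,
\sigma_0)$ such that the truncated distribution's mean and SD equal the
configured targets exactly (verified against a numerical-integration
oracle), and all floored draws use the matched parameters. The maximal-HU
row is the one distribution a truncated normal cannot represent (its SD
exceeds its mean minus any sensible floor — the signature of a heavy
calcification tail), so it uses a floor-shifted gamma matched to the same
two moments.

**What the phantoms do not emulate** — and hence what green tests do not
show about patient data: irregular nodal margins (simulated circularity is
high and nearly class-constant, unlike real tracings), spatially
structured enhancement, beam-hardening artifacts, partial-volume effects
at node boundaries, between-node variation in mean HU, and any real
coupling among EBUS findings, SUV and texture beyond size. Diagnostic
AUCs measured on phantoms quantify the machinery, not clinical accuracy;
that is why the package's accuracy tests are direction-only (e.g. AUC of
SUVmax above 0.5, malignant area above benign) and the contingency-table
worked examples operate on the published counts themselves.

## Statistical conventions

* **AUC** is the Mann–Whitney probability with half credit for ties
  (midranks); its SE is Hanley–McNeil; the 95% CI is $\pm 1.96\,$SE
  clipped to [0, 1]. `orientation_policy = "auto_flip"` negates
  benign-coded scores (nSD runs benign-high) and records the flip.
* **Group tests**: pooled-variance Student's t for continuous features
  (Welch by flag), Pearson chi-squared *without* continuity correction
  for 2×2 tables — the uncorrected statistic is what reproduces published
  p-values here (e.g. p = 0.031 for the coagulation-necrosis-sign table);
  Fisher's exact test is available for sparse tables. No multiplicity
  adjustment by default, matching the single-threshold significance
  convention of the source analyses.
* **Combined PET/CT criterion**: positive iff SUVmax ≥ 2.5 **and**
  maximal HU < 70, boundaries exactly `>=` and `<`.
* **CART stump**: exhaustive search over midpoints of sorted unique
  values, maximizing Gini impurity decrease, ties toward the lower
  threshold; the reported relative risk is the malignancy-rate ratio
  between sides, with a 0.5-count (Haldane–Anscombe) guard when a side is
  pure. Full recursive trees are out of scope.
* **Panel rows** for dichotomized rules are scored as 0/1 classifiers, so
  their AUC identically equals (Se + Sp)/2; continuous rows report the
  Youden-optimal operating point.

## Reproducibility and problem sizes

Every stochastic routine consumes the global RNG stream, so `set.seed()`
(or the `seed` arguments of `generate_cohort()` / `run_pipeline()`) makes
any result bit-reproducible; the pipeline fans one seed into fixed
per-stage child seeds so stages can be re-run independently, and its JSON
manifest records the seed, a config hash, and every otherwise-implicit
default (bin width, exclusion threshold, SD divisor).

The shipped analyses and tests use study-sized image cohorts (71 benign /
61 malignant phantoms) where rasters are needed, and 10,000-node
record-only cohorts for moment-recovery checks, where raster synthesis is
skipped because the scalar draws are independent of it; recovery is
asserted within three standard errors of the configured targets. These
sizes were chosen so the whole battery runs comfortably on a laptop while
keeping Monte-Carlo noise far below the asserted tolerances.

## Worked example

```{r example, eval = FALSE}
library(nodetex)

cohort <- generate_cohort(n_benign = 71, n_malignant = 61, seed = 20190522)
features <- extract_all(cohort)
tab <- merge(cohort$records,
             features[setdiff(names(features), "label")], by = "node_id")

summarize_table(tab, c("short_axis_mm", "suv_max", "normalized_sd",
                       "heterogeneous_echo", "cns_present"))
evaluate_panel(tab)
cart_stump(tab, "suv_max")
```

The three scripts under `analysis/` run exactly this, stage by stage, and
write their tables under `results/`.

## Known limitations

* Single-slice 2D only; no 3D shape, no GLCM/GLRLM/wavelet textures.
* The phantom's realism limits are listed above; in particular shape
  features barely separate the classes by construction.
* Published AUC magnitudes from patient cohorts are not reproducible from
  simulation and are nowhere asserted; published count-derived statistics
  are reproduced exactly from the counts.
* Vendor CTTA definitions (entropy base, bin width, compactness) are
  unknowable from the literature; every such choice is a documented,
  configurable default here.
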