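---
title: "Methods: factorial surface morphometry, RFT cluster inference, and expression decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial surface morphometry, RFT cluster inference, and expression decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfgene)
```

# The analysis this package implements

`surfgene` implements a complete imaging-transcriptomics pipeline of the
kind used to study how co-occurring conditions modulate cortical anatomy:
a 2×2 factorial, vertex-wise general linear model of cortical thickness
(CT) or surface area (SA) on a triangulated cortical surface; random field
theory (RFT) cluster-corrected inference on the resulting t-maps; Cohen's
*f* effect-size maps; spatial gene-expression decoding of the statistical
maps against a multi-donor expression atlas; and hypergeometric gene-set
enrichment of the decoded gene lists. Because the clinical imaging data
such analyses are built on are typically access-restricted, the package
ships a synthetic-data generator that reproduces the statistical structure
every stage assumes, so the whole pipeline is testable end to end.

# The vertex-wise factorial model

At every cortical vertex the measurement $Y_i$ of subject $i$ is modelled
as

$$Y_i = \beta_0 + \beta_1\,\mathrm{ASD} + \beta_2\,\mathrm{ADHD}
      + \beta_3\,\mathrm{ASD}\times\mathrm{ADHD} + \beta_4\,\mathrm{Sex}
      + \beta_5\,\mathrm{Age} + \beta_6\,\mathrm{Age}^2
      + \beta_7\,\mathrm{FSIQ} + \beta_8\,\mathrm{Site}
      + \beta_9\,\mathrm{Global} + \varepsilon_i,$$

fit by ordinary least squares independently per vertex
(`build_design()`, `fit_glm()`). Design choices:

* **Treatment (0/1) coding.** ASD, ADHD, and male sex are 0/1 indicators
  and the interaction is their product, so the reference cell is the
  typically developing group and $\beta_3$ is the non-additivity of the
  two diagnoses. Effect coding would change the interpretation of the
  main effects, not the interaction test.
* **Centred continuous covariates.** Age, FSIQ, and the global measure
  are centred at the grand mean ("across groups", read as one grand mean,
  not per-group means). The quadratic age term is the square of *centred*
  age, itself re-centred; this reduces collinearity between the linear and
  quadratic columns and leaves all t-maps invariant (a property the test
  suite checks).
* **Global measure per modality.** Mean CT for CT analyses, total SA (in
  m²) for SA analyses, computed from the subject's own map.
* **Site.** $k-1$ dummy columns against the first site. Alternatively,
  `combat_adjust()` removes site effects from the maps beforehand by
  parametric empirical-Bayes location/scale harmonisation (backed by
  `sva::ComBat`); the two options are not combined in one fit.

The ASD-subset model (`fit_asd_subset()`) restricts the sample to
autistic participants and replaces the factorial block with a single
Group indicator (ADHD status within ASD), keeping all covariates.

Cohen's *f* per term (`cohens_f()`) uses the standard $R^2$-ratio
definition $f = \sqrt{(R^2_{full} - R^2_{reduced}) / (1 - R^2_{full})}$
with the reduced model dropping the term's column(s); no closed form is
trusted — the implementation is checked against a literal two-model refit
oracle. Benchmarks 0.25/0.5/0.75 label small/medium/large effects.

# Smoothing and its calibration

Maps and noise fields are smoothed by iterated neighbour diffusion on the
mesh graph (`smooth_map()`). One iteration applies
$S = I + \lambda A^{-1}(W - D)$ with $A$ the diagonal of barycentric
vertex areas and $W$ the edge adjacency; symmetry of $W$ makes the
area-weighted mean an exact invariant and constants fixed points. The
per-iteration spatial variance is known in closed form from the edge
lengths, so $(n_{iter}, \lambda)$ are solved analytically to hit a target
total variance of $(\mathrm{FWHM}/2.355)^2$ — there is no empirical
tuning loop, and the same smoother serves both the analysis stage and the
noise generator (one implementation, one calibration). A smoothed impulse
on a fine sphere recovers the nominal kernel width within 10% (tested).
The default kernel is 15 mm FWHM, the conventional choice for
population-level CT/SA analyses.

# Smoothness estimation and RFT cluster inference

Cluster-level inference needs the effective smoothness of the *error*
fields. `estimate_smoothness()` normalises the residual vectors to unit
norm per vertex; along each edge of length $h$ the summed squared
difference $v$ of the normalised residuals estimates $2(1-\rho(h))$.
Inverting the Gaussian autocorrelation model
$\rho(h) = \exp(-\lambda h^2/2)$ gives the derivative variance
$\lambda = -2\log(1 - v/2)/h^2$; the small-lag approximation $v/h^2$
systematically overestimates FWHM when edges are an appreciable fraction
of the kernel (about 5% at 6-mm edges under a 15-mm kernel), which
matters because resel counts scale as $\mathrm{FWHM}^{-2}$. Per-triangle
resels are $\mathrm{area}/\mathrm{FWHM}^2$; the global FWHM is the
resel-weighted summary $\sqrt{\mathrm{area}/\mathrm{resels}}$. The resel
vector is completed by the Euler characteristic of the masked submesh
($R_0$; equal to 1 for a sphere minus a cap, an invariant the tests
assert) and the mask boundary length in FWHM units ($R_1$).

Clusters (`find_clusters()`) are edge-connected components of
suprathreshold masked vertices, found per tail at the forming threshold
$u = t_{1-\alpha/2,\nu}$ — the "two-tailed $p<0.05$" policy reads the
threshold as $0.025$ per tail with the per-tail corrected p doubled; a
pooled $|t|$ field would give the same components and the same doubled
count, so the choice is presentational. Extent is measured in resels
(summed per-vertex resel density), which makes extents comparable under
non-stationary smoothness.

The corrected p for a cluster of extent $k$ resels
(`rft_cluster_p()`) is
$1 - \exp(-E[m]\,e^{-\beta k})$ with $\beta = E[m]/E[N]$, where $E[N]$ is
the expected suprathreshold volume in resels ($R_2 P(T>u)$, exact) and
$E[m]$ the expected cluster count. For $E[m]$ two routes are provided:

* `method = "density"` — the classical continuum approximation, resels ×
  t-field Euler-characteristic densities. It is a *high-threshold*
  asymptotic: at a forming threshold as low as $u \approx 2$ it
  overpredicts the cluster count (small excursions merge, and excursions
  smaller than a mesh cell are never observed), which inflates $\beta$
  and makes the corrected p anticonservative.
* `method = "discrete-ec"` (default) — the expected Euler characteristic
  of the excursion set *on the mesh itself*:
  $V p_1 - \sum_e p_2(\rho_e) + \sum_f p_3(\rho_f)$, with the exact t
  marginal $p_1$ and Gaussian-copula joint orthant probabilities at the
  residual-estimated inter-vertex correlations (evaluated by Plackett
  path integrals — one-dimensional quadratures, no Monte Carlo). This
  expectation is exact at any threshold and any mesh resolution and
  converges to the density route for high thresholds on fine meshes.

The default was chosen because the exponential extent-survival form is
validated empirically rather than asserted: on full-null simulated
cohorts the observed extents are exponential with rate equal to the
observed count/area ratio, which the discrete-EC expectation predicts and
the density route does not at these thresholds. The package's acceptance
property — family-wise error within $[0.02, 0.08]$ at nominal 0.05 over
500 null cohorts (subdivision-4 sphere, 60 subjects, 15-mm smoothing) —
is asserted by the test suite with the default method.

A Freedman–Lane permutation oracle (`permutation_cluster_test()`) is
provided for validation: reduced-model residuals are permuted, the full
model refit, and the null distribution of the maximum cluster extent
yields corrected p-values with the add-one rule. On null data the RFT and
permutation p-values agree in rank (tested).

# Gene-expression decoding

`decode_map()` mirrors the decoding of a statistical surface map against
a donor-sampled expression atlas: the map is averaged within spherical
ROIs (default radius 4 mm, Euclidean distance in mesh space — donors are
registered to the template volumetrically, so a geodesic metric is not
implied) at each donor's sampling sites, restricted to the cortex mask;
sites with empty ROIs are dropped and recorded. For each gene and donor a
least-squares slope of expression on map value is computed with both
variables z-scored within donor, so the slope equals the Pearson spatial
correlation (the regression orientation is a switch in principle; the
standardised slope makes the two orientations coincide). The donor slopes
are subjected to a one-sample t test across donors (random-effects;
$df = n_{donors} - 1$, so six donors give $df = 5$), two-sided, and genes
are selected at $p < 0.01$ on either tail — a deliberately liberal
threshold because selection feeds enrichment rather than constituting a
hypothesis test. Genes with fewer than two valid donor slopes are
excluded with a count; identical nonzero slopes (zero variance) are
flagged degenerate and reported at the smallest representable p.

`gls_decode_map()` replaces each donor's OLS slope with a generalised
least-squares slope under an exponential site–site correlation
$\exp(-d/\ell)$ (default length scale 10 mm; the supplementary material
this variant emulates does not fix one). As $\ell \to 0$ the GLS t-values
converge to the OLS ones (tested to $10^{-6}$); under spatially
autocorrelated null expression the GLS selection rate stays at least as
close to nominal as OLS. Singular correlation matrices receive a jitter
with a warning.

`list_overlap()` reports pairwise intersections of decoded lists as a
percentage of the union of all listed genes, the convention used when
quantifying overlap between main-effect and interaction transcriptomic
associations.

# Gene-set enrichment

`hypergeom_enrich()` tests a decoded list against a gene set over a fixed
background universe (default 20,787 genes, the protein-coding background
of the decoding service this emulates): upper-tail hypergeometric p
(equal to full enumeration for every universe ≤ 25, tested), and the
sample contingency odds ratio
$k(N-n-m+k)\,/\,[(n-k)(m-k)]$ with zero cells reported as infinite (an
optional Haldane 0.5 correction is off by default, matching the
GeneOverlap-style convention). `enrich_all()` applies Benjamini–Hochberg
FDR within each decoded list's family of set tests — the per-map-column
family; a global family across all pairs is a switch, since the published
convention is ambiguous — and flags significance at $q < 0.05$.

# The synthetic-data generator

The generator defines the study conditions under which every calibration
claim is made:

* **Cohort** (`simulate_cohort()`): four diagnostic subgroups with the
  reference sample sizes 170 (ASD only), 25 (ADHD only), 142 (ASD+ADHD),
  196 (TD); sex ratios, age and FSIQ means/SDs per group follow
  `default_cohort_summary()`; six acquisition sites assigned round-robin;
  an optional per-site additive shift exercises the harmonisation path.
  One printed value was corrected for physical plausibility: total-SA
  SDs of the order of the group means (0.2–0.3 m²) would imply negative
  areas, so the simulator uses the 0.023–0.029 m² scale consistent with
  the printed F statistic. Subject maps are a baseline (2.7 mm, a typical
  CT) plus treatment-coded planted effects plus smooth Gaussian noise
  (default 15-mm FWHM, 0.25 marginal SD — between-subject vertex-wise
  variability of CT after smoothing). The noise uses the same mesh
  smoother as the analysis.
* **Donor expression** (`simulate_donors()`): per donor, sites are drawn
  from masked vertices (coordinates jittered ≤ 1 mm); each gene is
  $\rho\,z(\mathrm{map}) + \sqrt{1-\rho^2}\,\varepsilon$ at the sites,
  then z-scored within donor by default. The normalisation is a switch,
  not a fixed truth, because the normalisation pipeline of the real atlas
  service is not specified by the analyses this emulates.
* **Gene sets** (`make_gene_sets()`): sets sampled from a synthetic
  universe with planted overlap fractions against a designated list, so
  enrichment has known positives.

All generators are pure functions of (arguments, seed); the pipeline
writes a manifest and reproduces outputs bit-identically under a fixed
config and seed (tested).

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: cortical folding geometry (the
substrate is a sphere with a masked cap as a medial-wall stand-in),
realistic gene–gene co-expression (genes are conditionally independent
given the target map), non-Gaussian noise, site-by-covariate
confounding beyond additive shifts, and the probe-to-gene collapsing of
real microarray atlases.

# Numerical choices and degenerate inputs

* Smoother step size obeys the positivity bound
  $\lambda \le 0.9\,\min_i(a_i/d_i)$; the iteration count is the smallest
  $n$ meeting it, and $\lambda$ is then solved exactly.
* Zero-variance vertices are excluded from smoothness estimation with a
  warning; vertices with perfect fits carry `NA` t-statistics and are
  listed as degenerate; $R^2_{full}=1$ flags Cohen's *f* degenerate.
* Thresholds above the map maximum yield an empty, valid cluster table.
* Corrected p-values are capped into $(0, 1]$ and are never smaller than
  the machine minimum; two-tailed doubling caps at 1.
* Orthant probabilities use 400-point cumulative trapezoid (bivariate)
  and 24-point midpoint path quadrature (trivariate); both are smooth
  one-dimensional integrals where this is accurate to well below the
  Monte Carlo error of any calibration run.
* File indices are 0-based on disk and 1-based in memory; vertex-map
  files carry their vertex count in a header comment and readers check it.

# Problem sizes used by the test and acceptance runs

FWER calibration uses 500 null cohorts of 60 subjects on a
subdivision-4 sphere (2,562 vertices) at 15-mm smoothing; parameter
recovery uses 20 cohorts of 200 subjects on a subdivision-3 sphere with
planted 0.25-unit effects in 30-mm discs; decoding calibration uses
1,050 genes, six donors, and 300 sites per donor. These sizes put the
binomial/simulation error comfortably inside the asserted bands while
keeping a full run in minutes on one core.

# Known limitations

* The discrete-EC cluster count assumes a Gaussian copula between
  vertex values of the t field; at very low df the joint tails of a
  t field are heavier, and the calibration band is asserted at df ≈ 46.
* Smoothness estimation assumes an approximately Gaussian local
  autocorrelation; strongly anisotropic smoothness is handled only
  through per-triangle resels, not per-direction.
* ROI sampling uses Euclidean distance, which can bridge sulcal banks on
  folded cortices; on the spherical test substrate this is immaterial,
  on real surfaces it mirrors the volumetric registration of the
  emulated service rather than a geodesic ideal.
* The GLS length scale is fixed (10 mm) rather than profiled by default.
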