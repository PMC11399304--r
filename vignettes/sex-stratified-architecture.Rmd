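---
title: "Comparing the genetic architecture of quantitative traits between sexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the genetic architecture of quantitative traits between sexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`sexstratgen` implements a sex-stratified screen of the common-variant
architecture of quantitative traits, of the kind applied to biobank-scale
neuroimaging genetics: per-sex SNP-heritability from genomic relationship
matrices (GRMs), the between-sex genetic correlation for the same trait,
per-variant sex-difference tests on stratified GWAS effect sizes, and
spatial enrichment of sex-differentiated cortical maps against functional
networks.  Every stage runs end-to-end on synthetic data with known ground
truth, so the statistical machinery is testable without any cohort access.

The core model is the standard GREML mixed model.  For a trait vector $y$
in one sex,

$$y = X\beta + \textstyle\sum_i g_i + e,\qquad
  g_i \sim N(0,\, V_{G_i}\, \mathbf{A}_i),\qquad e \sim N(0,\, V_E I),$$

with $\mathbf{A}_i$ the GRMs (here: one autosomal, one X-chromosome) and
$h^2_{\mathrm{SNP}} = \sum_i V_{G_i} / V_P$, $V_P = \sum_i V_{G_i} + V_E$.
Variance components are estimated by restricted maximum likelihood (REML)
using average-information (AI) updates with a short EM warm-up, the
combination GCTA popularized.  Fixed covariates (e.g. ten ancestry
principal components) are absorbed through the REML projection matrix
rather than pre-residualized, which keeps the restricted degrees of freedom
correct.

The between-sex genetic correlation treats the male and female measurements
of one trait as two traits observed on disjoint individuals over a
combined-sex autosomal GRM (the two-column-phenotype construction used with
GCTA's `--reml-bivar`).  Components are $V_{Gm}, V_{Gf}, C_G, V_{Em},
V_{Ef}$; the residual cross-covariance is structurally zero because no
individual carries both traits, and
$r_g = C_G / \sqrt{V_{Gm} V_{Gf}}$.  Deviation from $r_g = 1$ is assessed
by refitting under the constraint $C_G = \sqrt{V_{Gm} V_{Gf}}$ and a
1-degree-of-freedom likelihood-ratio test.

Per-sex point estimates (heritabilities or GWAS effect sizes) are compared
with the difference-of-estimates z statistic

$$Z = \frac{X_M - X_F}{\sqrt{SE_M^2 + SE_F^2}},\qquad
  p = 2\,\{1 - \Phi(|Z|)\},$$

with two Bonferroni tiers for variant-level screens: a *relaxed* tier at
the genome-wide $5\times 10^{-8}$ and a *strict* tier dividing that level
by the number of phenotypes in the panel (361 for a cortical class: 360
regions plus the corresponding global measure; 23 for the subcortical
volumes).

# Tunable parameters that matter

* **QC thresholds** (`qc_thresholds()`): minor allele frequency floor
  $3\times10^{-4}$ for heritability work and $10^{-3}$ for GWAS;
  Hardy-Weinberg $p < 10^{-6}$ (1-df chi-square goodness of fit — the exact
  test is a known alternative, but only a p-threshold is specified by the
  protocol we follow, and the chi-square form is directly checkable by
  hand); variant missingness $> 0.05$; sample missingness $> 0.1$;
  relatedness $> 0.05$; image-quality (Euler number) $< -217$; intracranial
  volume beyond 4 within-sex SD; any phenotype beyond 5 SD.  X-chromosome
  variant filters are evaluated per sex and must pass in both; X
  Hardy-Weinberg uses females only (males are hemizygous).
* **Dosage-compensation codings** (`x_grm()`): female X dosages are
  standardized like autosomal ones; male hemizygous values are coded per
  model — FDC (doubled; coded variance 2 under HWE), NDC (raw; variance
  1/2), EV (scaled to variance 1).  The allele frequency counts males as a
  single allele.  `select_dc_model()` picks the coding with the best joint
  autosome+X restricted likelihood, with the deterministic tie order
  FDC > EV > NDC.
* **REML controls** (`fit_reml()`): 4 EM steps, then AI updates with
  step-halving; convergence at $|\Delta \log L| < 10^{-6}$ or 100
  iterations; components constrained non-negative (proposals below a floor
  of $10^{-6}\,\hat V_P$ are pinned there, and the AI system is re-solved
  for the free components — without that active-set step a component stuck
  at zero freezes the whole update).  Standard errors come from the inverse
  AI matrix; heritability and $r_g$ SEs by the delta method.
* **Spin test** (`network_enrichment()`): Haar-uniform rotations, mirrored
  across hemispheres; sample odds ratio with Haldane-Anscombe $+0.5$ only
  when a cell is zero, applied identically to observed and permuted tables;
  add-one permutation p-value, one-sided for enrichment.

# What the generator emulates (and what it does not)

`simulate_genotypes()` draws biallelic variants with per-variant allele
frequencies uniform on a configurable band, genotypes under Hardy-Weinberg
(Binomial(2, p); hemizygous males Binomial(1, p) on the X), and
completely-at-random missingness.  `simulate_phenotypes()` draws causal
effect pairs $(\beta_m, \beta_f)$ from a zero-mean bivariate normal with
correlation $r_g$ — i.i.d. across causal variants, the infinitesimal world
GREML assumes — applies them to column-standardized genotypes, rescales
genetic values so the realized variance fraction hits the $h^2$ targets
exactly, and adds independent Gaussian noise, covariate effects, and a mean
sex gap.  The recorded truth object is sufficient to rebuild the genetic
values bit-for-bit.

Deliberately absent: linkage disequilibrium, imputation uncertainty,
population stratification, rare-variant architectures, indels/CNVs.  A
green test therefore establishes that the estimators are correct and
calibrated under their own assumptions — not that those assumptions hold in
any real cohort, nor anything about the published cohort-specific values
(which require the original individual-level data).

Two generator choices deserve explanation:

* **Per-sex vs pooled scaling.**  The default rescales each sex's genetic
  value to its own $h^2$ target.  That is the right stated world for
  heritability and $r_g$ recovery, but it erases the between-sex
  genetic-variance ratio a dosage-compensation coding implies (and forces
  sex-heteroscedastic noise when targets differ), which makes
  dosage-compensation model selection unidentifiable or biased toward the
  equal-variance coding.  `arch_spec(scale = "pooled")` instead applies one
  common factor to the pooled genetic value, preserving the coding's ratio
  (2:1 male:female X genetic variance under FDC) with homoscedastic noise —
  the world a combined-sex coding comparison actually assumes.  Within a
  single sex the three codings differ only by a scalar the variance
  component absorbs, so selection is only meaningful on mixed-sex samples.
* **Region panels.**  `simulate_region_panel()` needs genotypes to make
  heritable regional traits, so it takes a `genotype_panel` as its first
  argument (a deliberate extension of the minimal interface).  Centroids
  come from a deterministic Fibonacci lattice mirrored across hemispheres;
  network labels from nearest-seed assignment, so labels always partition
  the regions.

# Numerical choices and degenerate inputs

* The reported restricted log-likelihood drops additive constants; only
  differences between fits on the same data are meaningful.
* Monomorphic variants are excluded from GRMs; pairs sharing no usable
  variant get `NA` relatedness with a warning.  Missing genotypes are
  excluded pairwise (GCTA semantics), never mean-imputed, and the per-pair
  counts are kept (and written to `.grm.N.bin`).
* The heritability LRT uses the 50:50 $\chi^2_0{:}\chi^2_1$ boundary
  mixture; the $r_g = 1$ test uses plain $\chi^2_1$, a conservative
  convention for a boundary-of-parameter-space null (its empirical size in
  the acceptance suite is below nominal, as expected).
* GWAS p-values use the t distribution with $n - k - 2$ df; exact fits
  (zero residual variance) and zero-variance dosages are flagged
  (`exact_fit` / `untestable`), never silently dropped.  Male X dosages
  enter GWAS on the 0/2 coding, matching the default additive X model of
  the common GWAS tools.
* Relatedness pruning is greedy by descending number of above-threshold
  partners; among ties the sample occurring last in the GRM id order is
  removed, so results are reproducible.
* Paired Wilcoxon tests are exact for $n \le 25$ and use the
  continuity-corrected normal approximation above that.
* Degenerate inputs raise typed errors: all-zero paired differences,
  all-positive/all-negative binary maps, zero-variance correlation inputs,
  rank-deficient designs (the error names the collinear columns).
* Spin-test calibration is exact for maps that are exchangeable across
  regions (the i.i.d. null used in the acceptance suite).  For spatially
  coherent maps (caps, smooth fields), nearest-centroid reassignment breaks
  exchangeability slightly and the permutation p errs *conservative* —
  the direction the method intends, since its purpose is to suppress the
  false positives that spatial autocorrelation induces in the naive Fisher
  test (asserted directly by the contiguous-cap invariant test).

# Scaling of the acceptance suite

Two acceptance exercises are run below their nominal sizes so the whole
suite fits a single-CPU budget: the bivariate $r_g$ recovery (1000 rather
than 2000 individuals per sex, 2000 markers) and the null calibration of
the variant-level z screen (1000 per sex).  Every assertion involved is
SE-relative (estimates within $2\,SE$ of truth, test size, rank of an
injected variant), so the checks are invariant to this scaling; the
univariate recovery and the injected-SNP screen run at their stated sizes
(n = 2000 and 5000/sex).

# Known limitations

* No LD-aware or MAF/LD-partitioned GRMs; no Haseman-Elston or
  summary-statistic estimators.
* The bivariate fit assumes disjoint male/female samples; it does not
  estimate a residual cross-covariance.
* Spin permutations rotate parcel centroids, not vertex-level maps, and
  assume a spherical parcellation with mirrored hemispheres.
* Imputation INFO scores are accepted as a pass-through column only, never
  computed.
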