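---
title: "Expression-level TWAS with mixed linear models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-level TWAS with mixed linear models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasmlm)
```

## The problem

A transcriptome-wide association study (TWAS) asks, gene by gene, whether
the mRNA expression level of that gene is associated with a quantitative
trait. In livestock cohorts the motivating setting is a modest number of
animals (on the order of a hundred) with bulk RNA-seq of a target tissue
and a handful of carcass or meat-quality traits. Two statistical problems
dominate at this scale: the expression levels of thousands of genes are
mutually correlated, so single-gene regressions are confounded by the
shared transcriptional background; and with ~10^4 tests and ~10^2 samples,
multiple-testing control and calibration diagnostics decide whether any
call is believable.

`twasmlm` addresses both with the mixed-linear-model strategy used by
omic-data association tools: the shared background is absorbed into a
random effect whose covariance is an expression-based similarity matrix,
and each gene is tested as a fixed effect against that background.

## The model

For one trait, the model for the phenotype vector $y$ when testing gene $i$
is

$$y = w_i b_i + C\beta + W u + e,$$

where $w_i$ is the standardized expression of gene $i$, $b_i$ its effect
(per SD of expression), $C$ the incidence matrix of the selected
categorical fixed effects (sex with 2 levels, birth season with 3), $W$ the
matrix of standardized expression of all $m$ retained genes,
$u \sim N(0,\, I\,\sigma^2_o/m)$ the polygenic effects, and
$e \sim N(0, I\sigma^2_e)$. Integrating out $u$ gives
$y \sim N(w_i b_i + C\beta,\; \sigma^2_o O + \sigma^2_e I)$ with the
*omics relationship matrix*

$$O_{jk} = \frac{1}{m} \sum_i \frac{(x_{ij}-\mu_i)(x_{ik}-\mu_i)}{\sigma^2_i},$$

i.e. $O = Z^\top Z/m$ for the gene-standardized expression matrix $Z$. $O$
plays the role a kinship matrix plays in a GWAS mixed model.

**Target exclusion.** Testing gene $i$ as a fixed effect while it also sits
inside $W$ fits it twice — once as fixed and once as random — which biases
$b_i$ toward zero. The scan therefore excludes the target from the
polygenic term: since $O$ is a sum of rank-one gene contributions, the
leave-one-out matrix is exact and cheap,
$O_{(-i)} = (m\,O - z_i z_i^\top)/(m-1)$. `orm_downdate()` implements this
identity and the tests verify it equals full recomputation to 1e-10.

**Estimation.** Variance components are estimated by REML
(`reml_fit()`). By default (`vc_mode = "global"`) they are estimated once
per trait on the full $O$ and reused for every gene with a Woodbury
rank-one update of $V_{(-i)}^{-1}$: one $O(n^3)$ eigendecomposition plus
$O(n p)$ per gene, instead of $m$ separate $O(n^3)$ fits. The rank-one
perturbation from removing 1 gene in $10^3$–$10^4$ has negligible influence
on the variance components; `vc_mode = "per_gene"` re-estimates them on
every leave-one-out ORM (with the target gene as a fixed covariate) and is
kept for verification — the test suite shows the two modes agree closely
(chi-square correlation > 0.95 on a 250-gene instance). Each gene's
$\hat b_i$ and its standard error come from generalized least squares, and
significance from the 1-df Wald statistic $(\hat b_i/\mathrm{se})^2$
referred to $\chi^2_1$.

The full single-component scan with target exclusion corresponds to the
exclusion property that MLM-based omic-association tools guarantee. Some
implementations additionally partition genes into several variance
components by a preliminary scan; that multi-component refinement changes
the background model, not the exclusion principle, and is deliberately not
implemented here — on the simulated architectures the package targets
(one shared polygenic component) it has no effect, and supporting it
would complicate the REML profile from a one-dimensional search to a
multi-dimensional one.

## Preprocessing

* **TMM normalization** (`tmm_normalize()`): weighted trimmed mean of
  M-values with trim fractions 0.30 (M) and 0.05 (A), reference sample
  chosen by the upper-quartile rule, factors rescaled to geometric mean 1.
  This is the reference dialect of the normalization literature, delegated
  to edgeR's implementation and cross-checked in the tests against an
  independently coded brute force of the definition. One caveat the tests
  document: the M-values, A-values and trimming are exactly invariant to
  rescaling a sample's depth, but the *precision weights* are not, so TMM
  factors are only approximately (≈0.1%) depth-invariant.
* **CPM** (`cpm_normalize()`): counts divided by effective library size
  (raw library size × TMM factor) times $10^6$.
* **Expressed-gene filter** (`filter_expressed()`): a gene is kept iff its
  raw count is ≥ 2 in *strictly more than* 30% of samples. The strict
  inequality matters at boundaries (3 of 10 samples fails, 4 passes) and is
  pinned by tests.
* **Phenotype QC** (`mad_filter()`): per trait, values outside
  median ± 3.5 × MAD are removed, where the MAD is the *raw* median
  absolute deviation — no 1.4826 consistency factor. The literal unscaled
  fence is the default because that is what "median absolute deviation"
  denotes; `scaled = TRUE` gives the consistency-scaled variant. QC is per
  trait, so retained-sample sets differ across traits.
* **Standardization** (`standardize_expression()`): per gene,
  $(x-\mu_i)/\sigma_i$ with the population (divide-by-$n$) variance, which
  makes the mean ORM diagonal exactly 1; sample variance is an option.
  Zero-variance genes are dropped with a warning, never propagated as NaN.
  CPM enters the ORM un-logged by default — CPM, not log-CPM, is the
  stated expression measure in the tradition this package follows — and
  `log_cpm = TRUE` standardizes $\log_2(\mathrm{CPM}+1)$ instead.

Fixed effects are chosen per trait by OLS backward elimination on the
phenotype alone (`select_fixed_effects()`): factors are tested as whole
blocks with partial-F tests and the worst factor with $p \ge 0.05$ is
dropped iteratively. The intercept is never dropped. Because each trait's
retained-sample set differs, `run_trait()` rebuilds CPM, standardization
and the ORM *on the retained subset* rather than sub-indexing a
full-sample ORM, keeping the standardization internally consistent.

## Multiplicity and diagnostics

Raw p-values are converted to $\chi^2_1$ statistics and the genomic
inflation factor is $\hat\lambda = \mathrm{median}(\chi^2)/0.4549$, the
denominator being the $\chi^2_1$ median. Its 95% CI is the
distribution-free binomial order-statistic interval for a median (each
endpoint divided by the same constant); a percentile bootstrap is available
via `ci_method = "bootstrap"` since the CI construction is a genuinely open
choice. QQ plots use plotting positions $(i-0.5)/n$ — a cosmetic choice,
stated for reproducibility. FDR control is Benjamini–Hochberg at 0.05
(Benjamini–Yekutieli behind `method = "BY"`), and `pick_candidates()`
additionally reports the $k = 20$ genes with the lowest raw p-values (ties
broken lexicographically by gene id) for downstream functional enrichment,
which itself requires external annotation databases and is out of scope.

## The synthetic data generator

All validation runs on synthetic data with known ground truth
(`sim_config()`, `simulate_twas()`), emulating the target regime: ~115
samples, ~10k genes, negative-binomial counts (gene-shared dispersion 0.1;
0 is the Poisson-limit sentinel) around lognormal per-gene mean expression
(log-SD 1.8) scaled by lognormal library sizes (log-SD 0.5 around 2×10⁶
reads), sex assigned Bernoulli(1/2) and season multinomial(1/3,1/3,1/3),
and additive phenotype outliers of ±6 trait SD at rate 0.02 — large enough
that the 3.5-MAD fence must catch them, at a realistic per-trait frequency.
`polygenic_var_frac` is $\sigma^2_o/(\sigma^2_o+\sigma^2_e)$ and defaults
to 0.3, a moderate expression-explained fraction in line with the moderate
heritabilities reported for growth-type traits in small livestock; causal
genes default to 2 per trait, with effects in phenotype units per SD of
expression.

The polygenic term is generated from the standardized CPM of the simulated
counts themselves, so the analysis model $Wu$ is *exactly* satisfiable
("well-specified" default); `latent_polygenic = TRUE` substitutes a latent
Gaussian gene matrix for robustness studies. Ground truth (causal genes and
effects, polygenic draws, variance components, injected outliers) is
returned separately and, in `run_pipeline()`, written to its own file that
no analysis stage reads.

What the generator does *not* emulate: batch effects beyond library size,
isoform structure, read-level error, count dispersion that varies by gene,
or trait distributions with heavy non-Gaussian tails. Passing tests
therefore demonstrate correctness of the algorithms and calibration under
a well-specified polygenic architecture — not robustness to every artefact
of real tissue RNA-seq.

## Numerical choices

* REML maximizes the restricted likelihood over the variance ratio
  $\gamma = \sigma^2_o/\sigma^2_e$ by bounded scalar search on
  $\log\gamma \in [\log 10^{-6}, \log 10^{6}]$ (tolerance 1e-8), with the
  scale variance profiled out in closed form after a single
  eigendecomposition of $O$. A boundary optimum at the lower end clamps
  $\sigma^2_o = 0$; the upper end raises a warning and sets
  `converged = FALSE` (this genuinely occurs when a single huge effect
  dominates the likelihood). An ORM whose eigenvalues are all equal within
  1e-8 makes the ratio unidentifiable; the fit then reports
  $\sigma^2_o = 0$ with a warning rather than an arbitrary split.
* $O$ is symmetrized against rounding and required to be PSD within
  −1e-8 on the smallest eigenvalue; violations raise an error instead of
  silently bending eigenvalues.
* A gene collinear with the fixed design yields a flagged missing p-value,
  not a crash.
* `run_trait()` refuses fewer than 30 retained samples — below that the
  variance-component model is hopeless.
* Candidate lists break p-value ties lexicographically by gene id so
  outputs are deterministic; two runs of the pipeline on identical inputs
  are byte-identical, which the manifest (input MD5 hashes, parameters,
  version) makes checkable.

## Validation problem sizes

The test suite validates calibration and recovery at sizes chosen to make
Monte-Carlo noise small while keeping the suite fast: null calibration on
20 simulations of 2,000 genes × 200 samples (mean $\lambda$ and pooled
type-I error), variance-fraction recovery at 0.5 on 20 simulations of
1,000 × 300, and planted-gene recovery (1.5 phenotype-SD effect) in the
top-20 list on 20 simulations of 1,000 × 200. Exactness checks (ORM
identities, Woodbury downdates, dense-GLS oracles, BH step-up) run on
instances small enough to verify against explicit brute-force
reimplementations.

## Known limitations

* With $n \approx 100$ the REML estimate of $\sigma^2_o/(\sigma^2_o+\sigma^2_e)$
  has large sampling variance (single-seed estimates at $n = 100$ range
  roughly 0–0.9 around a true 0.5); calibration claims in this package are
  about averages over replicates.
* The order-statistic CI for $\lambda$ reflects only the sampling noise of
  a median of independent $\chi^2$ draws; correlated tests (co-expressed
  genes) make it anti-conservative in principle.
* Backward elimination uses the phenotype alone (OLS), not the mixed
  model; with strong polygenic confounding of a covariate this can select
  differently than a within-MLM selection would.
* The per-gene effect is defined per SD of expression of the *retained
  sample subset*; comparisons of effect sizes across traits with different
  QC masks are therefore not exactly on one scale.
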