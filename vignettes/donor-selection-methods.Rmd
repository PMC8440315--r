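---
title: "Methods: GBLUP-based donor selection with expected improvement"
author: "gsei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBLUP-based donor selection with expected improvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gene banks hold thousands of genotyped accessions, but field phenotyping is
expensive — especially in low-input smallholder conditions where plot
numbers are tightly limited. Genomic selection turns a small phenotyped
training set into predictions for the whole genotyped pool: promising donor
accessions can then be requested and confirmed in the field instead of
screening everything. `gsei` implements that workflow end to end: genotype
QC and kinship, single-kernel GBLUP by REML, two selection criteria (PGV
and expected improvement), multi-cycle selection bookkeeping, and the
standard accuracy-estimation protocols — plus a synthetic-data generator
with known ground truth so that every stage is testable without access to
any particular field dataset.

## Models

### GBLUP

For records $y$ on tested accessions,

$$ y = X\beta + Zu + e, \qquad u \sim N(0, G\sigma_u^2), \qquad
   e \sim N(0, I\sigma_e^2), $$

where $G$ is the VanRaden genomic relationship matrix computed from
centered dosages, $W = D - 2p$, $G = WW^\top / (2\sum_j p_j(1-p_j))$, with
$p$ the observed alternate-allele frequencies of the input matrix itself
(no external reference, no shrinkage). $X$ carries one intercept per
environment block; with a single environment it is a column of ones. No
genotype-by-environment random term is fitted: GxE ends up in the
residual, which is the deliberate simplification the package emulates.

Variance components are estimated by REML with a spectral (EMMA-style)
solver: project out the fixed effects, eigendecompose the projected
$ZGZ^\top + I$ once, and maximize the restricted likelihood over the
single ratio $\delta = \sigma_e^2/\sigma_u^2$ on a log scale in
$[10^{-6}, 10^6]$. A 100-point log-grid brackets the optimum,
`optimize()` refines it, and a root-find on the analytic score polishes
the interior optimum to stationarity — the likelihood is flat near its
maximum, and without the polish a rescaled response can shift the ratio
by ~$10^{-7}$, which is what the scale-equivariance test guards. The
objective uses a sum-normalized spectrum so it is exactly scale-invariant
in $y$.

Genotypic values for *every* accession in $G$ — tested or not — are the
BLUP conditional means
$\hat u = \hat\sigma_u^2\, G Z^\top V^{-1}(y - X\hat\beta)$ with
$V = ZG_{obs}Z^\top\hat\sigma_u^2 + I\hat\sigma_e^2$. An untested
accession unrelated to all tested ones gets exactly 0, the population
mean; a duplicate of a tested accession gets that accession's estimate.
The marker-effect view is equivalent: when $G = WW^\top/c$, $\hat u$
equals $W\hat a$ for the ridge solution with penalty
$c\,\hat\sigma_e^2/\hat\sigma_u^2$ (tested to $10^{-6}$).

### Phenotype scaling across environments

When one trait is modelled jointly across environments, raw observations
can sit on very different ranges while the model carries a single residual
variance, so values are standardized to mean 0, variance 1 within each
environment before fitting. The rule's source phrasing ("more than two
environments") is ambiguous for the exactly-two-environment case; this
package scales whenever more than one environment is jointly modelled
(default), and `model_design(..., scale = FALSE)` restores the raw-scale
behaviour. Single-environment fits are always raw: Pearson correlations —
the accuracy metric everywhere here — are unaffected either way.

### Broad-sense heritability

From a replicated single-environment trial, $y_{ij} = g_i + r_j + e_{ij}$
with independent (identity-covariance, non-genomic) genotype effects and
fixed replicate effects, fitted by the same REML engine, and

$$ H^2 = \frac{V_g}{V_g + V_e / R} $$

with $R$ the replicate count. Identity covariance is deliberate: this is
the trial-design heritability, not a genomic one.

### Expected improvement

Each candidate's genotypic value is summarized by a predictive mean $m_i$
(its PGV) and standard deviation $s_i$; the incumbent $M$ is the maximum
*estimated* genotypic value among tested accessions only — untested
accessions never define the benchmark. Then

$$ EI_i = (m_i - M)\,\Phi(z_i) + s_i\,\phi(z_i), \qquad
   z_i = (m_i - M)/s_i, $$

the closed-form expectation of $\max(U - M, 0)$ under $U \sim N(m_i,
s_i^2)$; at $s_i = 0$ the continuous limit $\max(m_i - M, 0)$ is used. EI
rewards both high predictions and uncertain ones, and collapses to the
PGV ranking when all $s_i$ are equal. Two uncertainty routes are
provided:

* **Mixed-model (frequentist):** $s$ is the square root of the diagonal of
  $(Z^\top Z/\hat\sigma_e^2 + G^{-1}/\hat\sigma_u^2)^{-1}$, the
  conditional covariance of $u$ given $y$ with fixed effects ignored.
  When the smallest eigenvalue of $G$ falls below $10^{-8}$ (duplicated
  accessions), a $10^{-6}$ ridge is added to its diagonal before
  inversion; the same rule applies everywhere $G^{-1}$ is needed.
* **MCMC (Bayesian):** an own Gibbs sampler for the same model with a flat
  prior on $\beta$ and scaled-inverse-$\chi^2$ priors (df 5, scale set so
  the prior mode is half the sample variance of $y$) on both variances;
  the default schedule of 6000 iterations, 1200 burn-in, thinning 5
  retains 960 draws, and $s$ is the per-accession posterior SD. The two
  routes are not mathematically identical but agree closely (correlation
  > 0.9, posterior means vs REML BLUPs > 0.99 on the tested instances).

### Selection bookkeeping

Top-$k$ lists (default $k = 20$) are drawn per criterion, trait and
training site among untested accessions, with deterministic tie-breaking
(descending score, then ascending accession id — the source protocol does
not specify tie handling, so determinism was chosen). `merge_selections`
records the union size and the pairwise overlap matrix. Control sets are
picked at equally spaced ranks of the estimated-genotypic-value
distribution with first and last rank included; note that with 523
candidates and 23 controls endpoint-inclusive spacing gives rank gaps of
23–24 — spacing quoted as "every 22nd–23rd" elsewhere corresponds to
$n/k$ steps without endpoint anchoring, and the endpoint-inclusive
contract was kept because the span property (controls cover the full
value range) depends on it.

## Evaluation protocols

* **Repeated k-fold CV** partitions *accessions* (never records, so
  replicates cannot leak across folds) into 10 folds, 10 repeats by
  default. Per repeat, held-out PGVs are pooled and correlated with
  observed accession means; the mean and SD over repeats are reported.
  Whether the source protocol pooled folds or averaged fold-level
  correlations is unstated; pooling is the default, `aggregate =
  "per_fold"` the alternative.
* **Forward validation** fits on season 1 only and correlates PGVs with
  season 2 accession means, separately for repeated and newly added
  accessions.
* **Phenotypic correlations** between environments are Pearson
  correlations of observed accession means over shared accessions;
  **genetic correlations** refit the single-intercept GBLUP within each
  environment and correlate the estimated genotypic values. Pairs with
  fewer than 3 shared accessions are flagged `NA`, not errors.

### A caution on the genetic-correlation estimator

The Pearson-of-BLUPs genetic correlation is attenuated: with matched
designs in both environments its expectation is roughly $\rho \times
\text{reliability}$, where reliability is that of the within-environment
BLUPs ($\approx$ the accession-mean heritability, plus a small gain from
genomic pooling). At mean-level $H^2 = 0.8$ the estimator returns about
$0.6 \times 0.8 \approx 0.48$ for a true $\rho = 0.6$ — a property of the
estimator, not a bug, and the package's tests verify it recovers $\rho$
within $\pm 0.1$ only in the high-reliability regime ($H^2 = 0.95$,
emulating a heading-date-like trait). Genetic correlations still exceed
phenotypic ones ($\approx \rho H^2$ exactly) because BLUPs shrink the
environment-specific noise.

## The synthetic world

`sim_config()` states the emulated study once:

| parameter | default | why |
|---|---|---|
| `n_pool` | 3000 | a 3K-scale genotyped gene-bank panel |
| `n_train` | 400 | a few hundred phenotyped accessions, the feasible size of low-input trials |
| `n_markers` | 2000 | desk-scale stand-in for a few-hundred-K SNP core set |
| `maf_range` | (0.025, 0.5) | matches the post-filter MAF floor |
| `n_qtl` | 300 | polygenic but not fully dense; tests also use dense (`n_qtl = n_markers`) architectures |
| `h2_per_env` | 0.62 / 0.73 | biomass-trait broad-sense heritabilities; study traits span ~0.3–0.95 |
| `env_intercepts` | 55 / 35 | distinct raw-scale site means (g/plant-scale), so scaling actually matters |
| `genetic_corr` | 0.6 | moderate cross-site genetic correlation |
| `n_reps` | 2 | randomized-complete-block two-replicate trials |
| `missing_rate` | 0.02 | post-QC genotype missingness |

Mechanism: marker allele frequencies uniform on `maf_range`,
Hardy–Weinberg dosages, independent markers (no LD); `n_qtl` markers get
Gaussian effects drawn, across environments, from an equicorrelated
multivariate normal with correlation `genetic_corr` (a symmetric matrix
square root handles the singular $\rho = 1$ limit exactly). True
genotypic values are centered over the pool, and the single-record
residual SD is set from the empirical variance of $u$ over the training
set so that heritability at the accession-mean level equals the
configured value — which makes realized heritability directly checkable.
`phenotype_accessions()` grows out further accessions from the same
frozen truth, which is what the multi-cycle pipeline uses.

What the generator does **not** emulate: population structure and
subpopulations, linkage disequilibrium, dominance/epistasis, GxE beyond
an equicorrelated additive structure, and non-Gaussian trait noise. A
green test therefore establishes estimator correctness under the model's
own assumptions, not robustness to structured real-world panels. All
architecture choices are stand-ins; the emulated study describes none.

## Numerical choices

* REML ratio search bounded in $[10^{-6}, 10^6]$, tolerance $10^{-10}$
  on the log ratio, score-polished; eigenvalues of the projected kernel
  clamped at 0.
* GRM inversion ridge: $10^{-6}$ on the diagonal when the smallest
  eigenvalue is below $10^{-8}$.
* Mean imputation replaces haplotype-based imputation (out of scope by
  design): missing dosages become the marker's mean over non-missing
  calls, which preserves allele frequencies exactly.
* Marker filters: missing fraction strictly greater than 5% removes;
  minor allele frequency strictly below 2.5% removes (a marker at exactly
  0.025 survives). MAF and missingness are computed over all accessions
  in the input matrix, before any training-subset restriction.
* Degenerate inputs error early and specifically: monomorphic markers at
  GRM time, all-missing markers at imputation, zero within-environment
  variance at scaling, single-replicate heritability, folds with fewer
  than 3 test accessions.
* All pipeline randomness derives from one root seed with fixed
  per-stage offsets; reruns are byte-identical and the manifest carries
  MD5 checksums of every artifact.

## Known limitations

Single variance component only (no multi-kernel or explicit GxE
covariance models); no dominance; the Gibbs sampler re-factorizes the
coefficient matrix each sweep, which is fine for a few hundred
accessions but not tuned for thousands; the VCF writer emits synthetic
coordinates and is meant for round-tripping simulated data, not for
annotating real variants.
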