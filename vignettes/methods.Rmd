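---
title: "Block-partitioned estimation of heritability and gene-environment interaction variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-partitioned estimation of heritability and gene-environment interaction variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gxeblock)
```

## The model

For a quantitative outcome $Y$, an environmental exposure $E$, and a
standardized additive genotype matrix $G$ ($n$ individuals $\times$ $m$
SNPs, dosages coded 0/1/2 then scaled to mean 0, sd 1 per SNP), the working
model is

$$Y = \beta_G G + \beta_E E + \beta_{GE}\,(G \circ E) + \varepsilon,$$

where $G \circ E$ is the columnwise genotype-exposure product. The
quantities of interest are genome-wide variance fractions: the additive
genetic variance $R^2_{GW}$ (SNP heritability) and the interaction variance
$R^2_{GWEI}$.

Fitting all $m \sim 10^6$ SNPs jointly is impossible ($m > n$), and
variance-component methods that work around this impose genetic-architecture
assumptions (polygenicity, MAF/LD coupling of effects). The approach here
instead *partitions* the genome into chromosome-bounded blocks of at most
$m_{\max}$ SNPs each (25,000 by default), small enough that $n > 10\,m_i$
per block, and fits ordinary least squares per block:

$$\hat\beta_{U_i} = (U_i^{\top}U_i)^{-1}U_i^{\top}Y, \qquad
  U_i = G_i \text{ or } (G\circ E)_i .$$

Per block, the adjusted coefficient of determination
$\bar R^2_i = 1 - (1 - R^2_i)\frac{n-1}{n-m_i-1}$ (Wherry correction) is
unbiased near zero under the null, so block values can be *summed*
genome-wide:

$$\widehat{R^2}_{GW(EI)} = (1 - R^2_{E,Y}) \sum_{i=1}^{j} \bar R^2_i ,$$

where $R^2_{E,Y}$ is the outcome variance explained by the exposure before
the exposure was residualized out of the outcome; the $(1-R^2_{E,Y})$
factor restores the total-variance scale. LD pruning ($r^2 \le 0.9$) keeps
between-block LD spillage negligible, and the minimal block count (about 60
genome-wide at biobank scale) limits the amplification of residual
stratification.

Separate regressions for $G$ and $G\circ E$ per block are used (rather
than one joint fit): the genome-wide sums are defined over separate block
series for the two matrices, and the interaction columns are orthogonalized
against main effects implicitly by the exposure residualization of $Y$ and
the per-column normalization of the products.

## Sampling variance and confidence intervals

Each block's adjusted $R^2$ carries the asymptotic Kendall–Stuart variance
of a squared multiple correlation. We compute the *exact* first two moments
of $R^2$ under multivariate-normal sampling from the classical mixture
representation

$$R^2 \mid J \sim \mathrm{Beta}\!\left(\tfrac{m}{2}+J,\ \tfrac{n-m-1}{2}\right),
\qquad J \sim \mathrm{NegBin}\!\left(\tfrac{n-1}{2},\ 1-\rho^2\right),$$

truncating the series where the negative-binomial mass drops below
$10^{-14}$. This is numerically equivalent to the hypergeometric-function
form of the classical treatment but avoids cancellation; at $\rho^2 = 0$ it
reduces to the closed-form Beta null variance
$2m(n-m-1)/\{(n-1)^2(n+1)\}$. The variance is mapped to the adjusted scale
by $\left(\frac{n-1}{n-m-1}\right)^2$ and scaled once by $(1-R^2_{E,Y})$.
Genome-wide, block variances add, and 95% confidence intervals are Wald
intervals. The population $\rho^2$ entering the formula is the block's own
adjusted $R^2$, clipped to $[0, 1)$.

Negative genome-wide estimates are legitimate outcomes of summed adjusted
$R^2$ under the null and are never truncated.

For dichotomous outcomes the observed-scale estimate is transformed to the
liability scale with the Robertson-type multiplier
$K^2(1-K)^2 / \{z^2 P(1-P)\}$ ($K$ population prevalence, $P$ sample
prevalence, $z$ the standard-normal density at the $K$-quantile). The
transformation assumes near-normal liability; a warning is emitted when the
observed-scale estimate exceeds 0.2, where that assumption becomes strained.

## Outcome and exposure preparation

For continuous $Y$ and $E$ (the default pipeline): rank-inverse-normal
(quantile) normalization with the Blom offset $(r - 3/8)/(n + 1/4)$ and
average ranks for ties; residualization on user-supplied covariates
(typically age, sex and genetic principal components — a label, not a
hard-coded set); re-normalization; residualization of $E$ out of $Y$
(recording $R^2_{E,Y}$); re-normalization of $Y$; an optional
heteroscedasticity adjustment; and a final linear orthogonalization of $Y$
against the covariates and $E$. The final pass exists because quantile
normalization is nonlinear: without it, $Y$ would retain a small linear
component on $E$ and the covariates. The result is exactly orthogonal and
still normal to numerical precision.

The heteroscedasticity adjustment is deliberately configurable
(`hetero_adjust = "scale-on-e"` or `"none"`): the adjustment is named in
the protocol this package implements but its exact form is not specified
anywhere we could find. The default fits $|Y|$-residual magnitude on $E$ by
OLS, rescales $Y$ by the fitted (floored) scale, and re-normalizes. It is a
reweighting: the rank order of $Y$ within fixed $E$ is unchanged and no
missing values can be introduced.

Dichotomous exposures are left untouched (0/1) and $Y$ is
quantile-normalized within each exposure group separately; interaction
columns are standardized rather than quantile-normalized (a product with a
0/1 exposure is zero-inflated, so rank normalization would be
distortionary). Dichotomous outcomes are standardized, $E$ is
quantile-normalized within each outcome group, and the liability transform
is applied at the end. Stratified normalization requires at least 30
individuals per group — an explicit guard, since rank normalization on tiny
strata is unstable. The tool refuses missing $Y$ or $E$ (no silent
imputation): the simulation module shows that mean imputation attenuates
interaction estimates when missingness is disjoint and *inflates* them when
outcome and exposure are missing in the same individuals.

## Solvers

Per-block least squares offers two routes. The direct solver forms the
Gram matrix and solves by Cholesky — the fastest stable route for tall
($n > 10m$) standardized blocks — and falls back to LAPACK QR automatically
if the factorization fails or the triangular diagonal signals
ill-conditioning (ratio below $10^{-12}$); `method = "qr"` forces QR. The
conjugate-gradient solver never materializes the Gram matrix (products
$U^{\top}(Uv)$ only), uses Jacobi preconditioning (near-trivial here since
standardized columns give an almost constant diagonal), and stops at a
relative normal-equation residual of $10^{-8}$ by default; non-convergence
is an error carrying the residual. The two routes are property-tested to
agree to $10^{-6}$ relative error on random well-conditioned systems.

## The synthetic genotype panel

Tests and the acceptance analyses run on synthetic panels emulating a
post-QC biobank genotype matrix at reduced scale. Each SNP's dosage is the
sum of two independent haplotypes; each haplotype thresholds a latent AR(1)
Gaussian (lag-1 correlation `ld_rho`, default 0.6, independent across
chromosomes) at the SNP's MAF quantile, with target MAFs uniform on
[0.05, 0.5]. This reproduces the features the estimator is sensitive to —
banded LD with realistic decay, a post-QC MAF spectrum, chromosome-bounded
correlation, Binomial(2, MAF) margins — and omits features it is not
designed to exploit: long-range LD, MAF-LD coupling of *causal effects* to
functional annotation, relatedness and population structure. Passing tests
on these panels therefore demonstrate correctness of the estimator under
its stated assumptions, not robustness to structure the real-data QC
(ancestry filtering, relatedness pruning) is supposed to remove upstream.

Default scale for the replicate validation runs: $n = 20{,}000$
individuals, $m = 2{,}000$ SNPs over two chromosomes, block size 1,000
(so $n > 10\,m_i$ holds exactly as at biobank scale), ten replicates per
scenario. These sizes keep each replicate's standard error near 0.005 so
biases of practical size would be detected, while a full scenario sweep
stays desk-sized.

## Simulation scenarios

Twelve scenarios validate the estimator (defaults: heritability 0.20,
interaction variance 0.1 where non-null, 20% of SNPs with marginal effects,
2% with interaction effects, effects standard normal; components are
rescaled so realized sample variance fractions equal the set truths, and a
generation-time audit enforces agreement within 0.01 at $n \ge 20{,}000$):

1. null interaction; 2. non-null base case; 3. causal exposure effect
($R^2_{E\,\text{on}\,Y} = 0.1$); 4. interaction effects confined to the top
LD-score quartile; 5. to top-LD and bottom-MAF; 6–7. interaction effect
sizes from exponential and centered Beta(0.5, 0.5) distributions (the
"positive kurtosis" stress); 8. dichotomous exposure (Bernoulli 0.5);
9–12. collider structures.

In collider scenarios an unobserved standard-normal confounder loads
symmetrically on outcome and exposure ($\sqrt{0.2}$ of each variance) so
that $\mathrm{cor}^2(Y, E) = 0.2$ with no causal path. The exposure carries
20% additive genetic variance; in scenario 12, 20% of that genetic variance
is heterogeneous (effects switched by an unobserved binary variable).
Interaction-causal SNPs are a random set (9), disjoint from (10), or a
strict subset of (11) the marginal-causal set; scenarios 11 and 12 are
interaction-null. In base scenarios the interaction-causal set defaults to
a subset of the marginal-causal set. Exposure heritability with a
heterogeneous component inflates the *genetic* estimate (the residualized
outcome inherits part of the exposure's genetic signal, and only half of a
binary-switched component projects onto the additive span), while
interaction estimates remain unbiased — the asymmetry the collider suite
checks.

Distribution parameters not fixed by the validation design are explicit
defaults: exponential effects use rate 1, the kurtotic choice is
Beta(0.5, 0.5) centered at 0, the heterogeneity-switching binary is
Bernoulli(0.5). Effect rescaling to exact sample-variance targets (rather
than population targets) makes truths exact per replicate, which is what a
finite-replicate bias check needs.

## Power

Power for detecting a genome-wide $R^2$ uses non-central-F sampling: each
block's observed $R^2$ is drawn from the F distribution of an $m_i$-predictor
regression with noncentrality $n\rho_i^2/(1-\rho_i^2)$, where $\rho_i^2$ is
the block's share of the true genome-wide $R^2$ — allocated proportionally
to block size by default (an equal split is available; the choice is
second-order because the Wald test aggregates across blocks). Draws are
converted to adjusted $R^2$, summed with their asymptotic variances
(interpolated over a per-block-size grid of the exact variance, natural
splines on 48 points — the only numerical approximation in the module), and
a two-sided Wald p-value formed; power is the rejection fraction, 10,000
simulations per grid cell by default. The null cell reproduces the test
size within binomial error.

## Downstream analyses

The univariate scan fits, per SNP on a discovery subset (80% by default),
the outcome on the SNP alone and jointly on the SNP and its normalized
product, testing the interaction coefficient — closed-form 1- and
2-predictor solves, two-sided t-tests. Direction-of-effect concordance is
computed on an LD-pruned subset ($r^2 < 0.1$, greedy by ascending
interaction p-value, so the most significant member of a correlated pair
survives) with a pooled two-proportion Z-test against 0.5. Stratified
estimates split SNPs into five MAF bins crossed with LD-score quantile bins
(cuts at the 0.25/0.5/0.75/0.9 quantiles) and report per-SNP $R^2$.
Recovery analysis re-estimates variance in the validation set over SNPs
passing discovery p-value thresholds, re-blocked to the fewest blocks
keeping $n > 10m$. Polygenic scores refit selected SNPs (and interactions
among them) jointly as a single block on the discovery set and evaluate
prediction $R^2$ on the validation set; the improvement test for the
interaction-aware score is a paired bootstrap (1,000 resamples) of the
$R^2$ difference over validation individuals — the protocol names a
significance criterion but no test, so the least parametric choice is used.

## Numerical choices and degenerate inputs

* Raw $R^2$ is clipped to $[0,1]$ before adjustment; the variance formula
  evaluates at adjusted $R^2$ clipped to $[0, 1)$ and capped at 0.99 — the
  mixture series widens without bound as $\rho^2 \to 1$ while the variance
  itself vanishes, so exact fits are evaluated at the cap.
* A zero-predictor block has $R^2 = 0$ by definition.
* Monomorphic SNPs are an error at standardization (the MAF filter should
  remove them); sporadic missing hard calls are mean-imputed per SNP with a
  warning — this applies to genotypes only, never to outcome or exposure.
* LD pruning scans left-to-right within a chromosome against the preceding
  `window` *retained* SNPs and keeps the earlier SNP of a violating pair.
  Defining the window over retained SNPs makes the filter deterministic and
  idempotent (a second pass removes nothing), which a step-wise sliding
  window cannot guarantee.
* Block partitioning balances sizes within a chromosome (differ by at most
  one) after minimizing the count; $n \le 10\,m_i$ is a construction error
  naming the offending chromosome.
* All stochastic operations accept integer seeds; replicate streams derive
  from a master seed via `derive_seed(master, tag, replicate)`.

## Known limitations

* Quantile normalization protects against scale effects and non-normal
  distributions but can bias estimates toward the null; it is the intended
  behavior of the protocol, not a removable artifact.
* The liability transform loses information and assumes normal liability;
  interaction estimates for dichotomous outcomes are the least robust
  output.
* Exposure heritability with heterogeneous architecture inflates the
  genetic (not the interaction) estimate under collider conditions, as the
  collider suite demonstrates.
* The asymptotic variance treats blocks as independent; residual
  between-block LD after pruning slightly underestimates the variance, an
  effect the replicate suite bounds empirically.
* One exposure at a time; no multi-exposure linear combinations, no
  dosage/imputed-probability genotypes, no X chromosome.
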