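---
title: "Modeling products of phenotypes from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling products of phenotypes from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodpcss)
```

## The problem

Biobank repositories increasingly publish *pre-computed summary statistics*
(PCSS) — per-variable means, variances, pairwise covariances, the sample
size, and single-marker association results — instead of individual
participant data (IPD). Many phenotypes of clinical interest, however, are
not in the published tables directly but are *products* of published ones:
ratios of biomarkers (a ratio is a product with a reciprocal), body-size
indices, or logical combinations of binary conditions ("stroke subtype A
**and** B", "coronary disease **or** stroke"). `prodpcss` reconstructs the
covariate-adjusted multiple linear regression of such a product
$w_m = y_1 y_2 \cdots y_m$ (elementwise) on an arbitrary design of SNPs and
covariates, using only PCSS.

## Exact part: OLS from summary statistics

For a design matrix $X$ (with intercept) the normal-equations ingredients
are exact functions of summary statistics:

$$X'X = (n-1)S(X) + n\bar{x}\bar{x}', \qquad
  X'w = (n-1)s_{w,x} + n\bar{w}\bar{x}, \qquad
  w'w = (n-1)s_w^2 + n\bar{w}^2,$$

giving $\hat\beta = (X'X)^{-1}X'w$,
$\hat\sigma^2 = (w'w - \hat\beta'X'w)/(n-p)$, and
$\widehat{\mathrm{Var}}(\hat\beta) = \hat\sigma^2 (X'X)^{-1}$. Fed the exact
moments of a dataset these identities reproduce a direct least-squares fit
to machine precision (the test suite asserts $10^{-8}$ relative agreement on
random toy datasets). Everything non-trivial therefore reduces to
approximating three quantities for the product: its mean $\bar{w}$, its
variance $s^2_w$, and its covariance $s_{x_j,w}$ with each design column.

## Approximated part: product moments

For two phenotypes and a predictor $x_j$ with assumed marginal law $f_j$
(Hardy–Weinberg binomial(2, MAF) for genotypes, Bernoulli for binary
covariates, Gaussian for continuous ones):

* conditional means are the simple-regression lines
  $g(y_k|x) = a_{kj} + b_{kj}x$ with $b_{kj} = s_{x_j,y_k}/s^2_{x_j}$;
* conditional variances are the homoscedastic residual variances
  $h(y_k|x) = (n-1)(s^2_{y_k} - b_{kj}s_{x_j,y_k})/(n-2)$;
* the conditional covariance is the partial correlation (which equals the
  expected conditional correlation under joint linearity) scaled by the
  conditional standard deviations,
  $h(y_1,y_2|x) = r_{y_1,y_2\cdot x_j}\sqrt{h(y_1|x)h(y_2|x)}$;
* the conditional product mean is
  $g(w|x) = g(y_1|x)g(y_2|x) + h(y_1,y_2|x)$;
* the predictor covariance is the expectation
  $s_{x_j,w} \approx \sum_{x \in S_j} f_j(x)(x-\bar{x}_j)\,g(w|x)$,
  with the sum replaced by Gauss–Hermite quadrature (64 nodes by default)
  for Gaussian predictors, and set to 0 for the intercept;
* the product mean is the *exact* identity
  $\bar{w} = \bar{y}_1\bar{y}_2 + s_{y_1,y_2}(n-1)/n$;
* the variance combines within- and between-group pieces over $f_j$ and
  takes the median across eligible predictors (see below).

### Numerical choices

**Conditional product variance.** The within-group variance of a product
of two jointly Gaussian variables with means $g_1,g_2$, variances
$h_1,h_2$, and covariance $h_{12}$ is

$$h(w|x) = g_1^2 h_2 + g_2^2 h_1 + h_1 h_2 + 2 g_1 g_2 h_{12} + h_{12}^2 .$$

An alternative grouping in circulation enters the conditional means
*linearly* ($h_1h_2 + g_1h_2 + g_2h_1 + g_w h_{12}$), which is
dimensionally inconsistent (rescaling a phenotype by a constant does not
rescale the formula's terms coherently). We use the normal-theory form,
validated against $10^6$-draw Monte-Carlo oracles in the acceptance suite,
and keep the linear grouping behind
`conditional_product_variance(..., strict_printed = TRUE)` purely for
comparison.

**Total-variance grouping.** For a discrete predictor the product variance
estimate is the between/within decomposition with group sizes $nf_j(x)$:

$$s^2_w \approx \frac{\sum_x \left[(nf_j(x) - 1)\,h(w|x)
  + nf_j(x)\,(g(w|x)-\bar{w})^2\right]}{n-1},$$

which reduces to the exact sample-variance decomposition when $f_j$ matches
the empirical group frequencies. For a Gaussian predictor the
sum-to-integral swap is taken as
$E[h(w|x)] + \tfrac{n}{n-1}E[(g(w|x)-\bar{w})^2]$ — the "$-1$ per support
point" correction becomes $-E[h]$, since a continuous law has no finite
support to enumerate. Each eligible (non-intercept, non-degenerate)
predictor yields one estimate; the **median** across predictors is used.
With no eligible predictor the unconditional normal-theory product variance
$\bar y_1^2 s_2^2 + \bar y_2^2 s_1^2 + s_1^2 s_2^2 + 2\bar y_1\bar y_2
s_{12} + s_{12}^2$ is the fallback. Variances are floored at 0.

**Matching the assumed law to the sample mean.** The expectation
$\sum_x f_j(x)(x-\bar{x}_j)g(w|x)$ annihilates the (large) constant part of
$g(w|x)$ only when the mean of $f_j$ equals the sample mean $\bar{x}_j$.
If a genotype's *true* population MAF were attached while $\bar{x}_j$ is
the sample mean, the mismatch (of order $n^{-1/2}$) would multiply the
constant part of $g(w|x)$ and roughly double the covariance estimator's
sampling noise — we measured Type I error inflation to ~0.11 at
$\alpha = 0.05$ in exactly this setup. Repositories publish the *sample*
allele frequency, and `exact_pcss_from_ipd()` attaches the empirical
frequency accordingly; `dist_genotype()` therefore accepts frequencies in
$(0,1)$, not just $(0, 0.5]$.

**Other settings.** Binary-phenotype means are clamped to
$(\epsilon, 1-\epsilon)$ with $\epsilon = 10^{-6}$ (configurable; the
method only requires "some small $\epsilon$"). $X'X$ condition numbers
above $10^{10}$ fail loudly naming the collinear columns — a silent
near-singular solve corrupts standard errors. A numerically non-positive
$\hat\sigma^2$ (possible because the product moments are approximate) is
floored at $10^{-12}$ with a warning and p-values then report 1; this keeps
genome-wide scans running and errs conservative. Two-sided p-values use the
$t$ distribution with $n-p$ degrees of freedom — the natural OLS choice; at
GWAS sample sizes it is indistinguishable from the normal reference.
Zero-variance predictors are treated as intercept-like (zero covariance,
no variance vote) with a warning.

## Binary phenotypes and logical combinations

Binary phenotypes violate homoscedasticity and linearity, so two estimators
change: conditional variances become Bernoulli variances
$h(y_k|x) = g(y_k|x)(1-g(y_k|x))$ of the clamped conditional means
(`conditional_variance()`), and the product's overall variance becomes the
exact Bernoulli form $s^2_w = \bar{w}(1-\bar{w})\,n/(n-1)$
(`binary_product_variance()`), since a product of 0/1 phenotypes is itself
0/1.

A conjunction is simply the product: `and_model()`. A disjunction uses
complements: $y_1 \lor y_2 = 1 - (1-y_1)(1-y_2)$. `complement_stats()`
maps summary statistics of $y$ to those of $1-y$ (mean $\mapsto 1 -$ mean,
covariances with non-complemented variables negated, covariances among
complemented phenotypes and all variances preserved), and `or_model()`
computes the complement-product's moments and transforms back
($\bar{w} = 1-\bar{w}'$, $s_{x_j,w} = -s_{x_j,w'}$, $s^2_w = s^2_{w'}$).
The De Morgan relation between the two models holds *exactly* at the
moment level, and the coefficient identity
$\hat\beta_{\lor} = e_{\text{intercept}} - \hat\beta_{\land'}$ is asserted
to $10^{-10}$ in the tests.

## Products of three or more phenotypes

The pair method extends recursively: write $w_l = w_{l-1} y_l$, reuse the
machinery with $y_1 \to w_{l-1}$, $y_2 \to y_l$, and obtain the two
non-PCSS inputs by recursion — $s_{x_j,w_{l-1}}$ from the previous level,
and $s_{w_{l-1},y_l}$ by re-expressing it as the covariance of the
*conditioning phenotype* $y_l$ with the lower-order product, treating
$y_l$ as a predictor with an assumed marginal law (Gaussian at its own
mean/SD for continuous phenotypes, Bernoulli at its mean for binary ones).
Because the result depends on multiplication order, all $m!/2$ orderings
unique up to the first two factors are evaluated and the **median of each
scalar term** (mean, variance, each predictor covariance) is taken across
orderings — the aggregation targets the moments, not the final
coefficients, because the downstream fit is a shared deterministic function
of those moments; the test suite confirms on a three-phenotype example that
median-of-coefficients aggregation lands in the same place. Intermediate
partial products are treated as continuous even when factors are binary;
the Bernoulli estimators apply to the two-binary base case and to the final
mean/variance of an all-binary product, whose scope is the fully binary
product itself. Approximation error compounds with $m$: `m_cap = 6`
refuses larger products unless forced, and five-plus-phenotype
combinations deserve caution regardless.

## What the synthetic world is — and is not

`sim_config("null_type1")` draws, per replicate, $n \sim U\{500..2000\}$,
MAF $\sim U(0.1, 0.5)$, continuous phenotype means $\sim U(0.5, 3)$, SDs
$\sim U(0.5, 2)$ and correlations $\sim U(0.1, 0.7)$ (binary: means
$\sim U(0.2, 0.8)$, correlations $\sim U(0, 0.5)$ subject to Fréchet
feasibility), simulates a genotype *independent* of the phenotypes, and
fits the product model on SNP + intercept. The published validation of
this method used $10^7$–$10^8$ replicates from parameter distributions in
an unavailable supplement; the ranges above are this package's own
declared stand-ins — positive means and moderate positive correlations,
mirroring the documented caution that negative phenotype values and strong
negative correlations degrade the approximation. Green Type-I-error tests
here therefore establish conservativeness *in this regime at desk scale*
($5\times10^4$ replicates, with Wilson confidence intervals reported), not
a reproduction of the published error rates to their printed precision.

Correlated Bernoulli phenotypes are generated through a Gaussian copula;
the latent correlation is calibrated by root-finding on the bivariate
normal orthant probability, itself computed by 64-node Gauss–Legendre
quadrature of the probit representation (no bivariate-CDF dependency).
Infeasible target correlations are resampled.

`sim_config("factorial")` generates the comparison study's structure:
genotype at HWE, binary covariate $x_2 \sim
\mathrm{Bern}(\mathrm{logit}^{-1}(\alpha_2 x_1))$, optional continuous
covariate with $\bar{x}_3 = 0$, $s^2_{x_3} = 1$, $r_{x_1,x_3} = \alpha_3$,
and phenotypes $u(y_{ik}) = \beta_{k0} + \sum_j x_{ij}\beta_{kj} +
\epsilon_{ik}$ with multivariate-normal errors ($u$ = identity or logit
link). `run_comparison_experiment()` lays a $2^k$ factorial over any named
two-level factors; the default is a $2^3$ design over $n$, MAF, and the
SNP effect at 1,000 replicates per cell — the published studies crossed
$2^{12}$–$2^{14}$ cells, far beyond a desk-scale budget, so per-cell and
aggregate summaries (bias/MSE of slope, SE, $|t|$; decision disagreement
rates across $\alpha = 10^{-1}..10^{-8}$; a logistic oracle for binary
products) are reported with the reduced design declared here.

The generator emulates independent subjects with exactly linear (or
logit-linear) phenotype models and exact HWE; it does not emulate family
structure, missingness, linkage disequilibrium between markers, or
phenotype distributions with heavy tails — conclusions about those regimes
are out of scope.

## Deriving missing summary statistics

`hwe_moments()` (mean $2p$, variance $2p(1-p)$), `cov_from_marginal_slope()`
($s_{x,y} = b \cdot s^2_x$, the algebraic inverse of the slope definition),
and `pheno_corr_from_z()` (Pearson correlation of association Z statistics
over markers with both $|z| < 2$; at least 30 must survive) fill PCSS gaps
from repository-standard quantities. The Z-based estimator is mildly
attenuated by the tail truncation (a few percent at threshold 2) — its
test band is wider than pure sampling noise for that reason. No
finite-sample correction is applied to derived genotype moments.
`assemble_marker_pcss()` combines a phenotype-block PCSS set with one
marker's summary row, recording the provenance of every derived cell;
user-supplied statistics always take precedence over derived ones.

## Known limitations

* Accuracy degrades for phenotypes taking negative values, strongly
  negatively correlated binary phenotypes, and large $m$.
* Linear (not logistic) modeling of binary products; the logistic oracle
  in the comparison study quantifies the cost.
* Score-test-based summary statistics (null model refit per marker) are
  not supported; neither are weighted least squares, mixed models, or
  family/cluster adjustment.
* PCSS computed on differing subsets of subjects (missingness) are assumed
  away; all statistics must refer to one sample of size $n$.

## A worked example

```{r example}
set.seed(1)
n <- 1000
g  <- rbinom(n, 2, 0.3)                        # SNP at HWE
z  <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, .4, .4, 1), 2))
y1 <- 1.5 + 0.20 * g + 0.8 * z[, 1]            # two continuous phenotypes
y2 <- 2.0 + 0.10 * g + 1.1 * z[, 2]

# summary statistics are all the model ever sees
dat <- cbind(g = g, y1 = y1, y2 = y2)
pcss <- pcss_set(n, colMeans(dat), cov(dat),
                 list(pcss_variable("g", "predictor", "genotype",
                                    dist_genotype(mean(g) / 2)),
                      pcss_variable("y1", "phenotype"),
                      pcss_variable("y2", "phenotype")))

fit <- product_model(pcss, c("y1", "y2"), design = "g")
fit

# against the IPD fit it approximates
coef(lm(I(y1 * y2) ~ g))
```
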