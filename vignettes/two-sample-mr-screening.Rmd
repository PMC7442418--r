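---
title: "Two-sample Mendelian randomization screening: models, estimators and design choices"
author: "mrscreen"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The problem

Observational associations between modifiable exposures (lipids, glycemic
traits, anthropometry, circulating micronutrients, inflammation markers)
and disease risk are vulnerable to confounding and reverse causation.
Mendelian randomization (MR) sidesteps both by using germline variants as
instrumental variables: alleles are assigned at conception, so a variant
robustly associated with an exposure provides a randomized proxy for it.
In the *two-sample* design the SNP–exposure and SNP–outcome associations
come from separate, non-overlapping GWAS, and only summary statistics are
needed.

`mrscreen` implements the complete screening workflow for many continuous
exposures against one or more binary disease outcomes: instrument
selection, allele harmonization, five causal estimators, MR-Egger
pleiotropy assessment, leave-one-out driver-SNP detection, Bonferroni
multiplicity classification, a priori power — plus a synthetic
summary-statistic generator with known causal structure, so that every
stage is testable without external data.

# Model and estimators

For SNP $j$, let $\hat\beta_{Xj}$ (SD units of the exposure per allele)
and $\hat\beta_{Yj}$ (log-odds of disease per allele) be the observed
effects with standard errors $\sigma_{Xj}, \sigma_{Yj}$. All estimators
target $\theta$, the log odds ratio of disease per SD increase in the
genetically predicted exposure; results are reported as
$\mathrm{OR}_{SD} = e^{\theta}$ with normal-theory confidence intervals.

* **Wald ratio** (single instrument):
  $\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$. The default
  first-order standard error is $\sigma_{Yj}/|\hat\beta_{Xj}|$; a
  second-order option adds the exposure-uncertainty term
  $\sqrt{\sigma_{Yj}^2/\hat\beta_{Xj}^2 +
  \hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4}$. First order is the
  default because it is the dominant convention for two-sample summary
  data (strong instruments make the second term negligible).
* **IVW-FE**: the fixed-effects inverse-variance-weighted mean of the
  per-SNP ratios, $w_j = 1/se(\hat\theta_j)^2$,
  $se = (\sum_j w_j)^{-1/2}$, with no overdispersion scaling. With
  first-order SEs this is identical to weighted least squares of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin with weights
  $1/\sigma_{Yj}^2$ — an identity the test suite checks to $10^{-10}$.
* **Profile maximum likelihood**: observed effects are modelled as
  independent normals around $(\gamma_j, \theta\gamma_j)$ with known SEs
  and zero cross-trait error correlation (non-overlapping samples). The
  $\gamma_j$ profile out in closed form, leaving
  $\ell(\theta) = -\tfrac12 \sum_j
  (\hat\beta_{Yj}-\theta\hat\beta_{Xj})^2 /
  (\sigma_{Yj}^2+\theta^2\sigma_{Xj}^2)$, maximized by a safeguarded
  Newton iteration (analytic gradient, numerical curvature, step
  halving) started at the IVW estimate; tolerance $10^{-8}$, at most 200
  iterations, non-convergence is an error carrying the iterate trace.
  The SE comes from the curvature of the profile log-likelihood at the
  maximum.
* **Weighted median**: per-SNP ratios ordered, inverse-variance weights
  standardized to $p_j = (S_j - w_j/2)/S_{tot}$, and the estimate
  interpolates linearly to $p = 0.5$. Consistent when valid instruments
  carry at least half the weight.
* **Weighted mode**: the maximizer of an inverse-variance-weighted
  Gaussian kernel density over the ratios. The bandwidth is
  $\varphi \times 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,n^{-1/5}$ with
  $\varphi = 1$ by default; the maximizer is located by a 512-point
  grid bracket refined with golden-section search, which the tests
  compare against a dense-grid argmax of the same density. Consistent
  when the largest cluster of instruments is valid.
* **MR-Egger**: weighted linear regression of outcome on exposure
  effects *with* an intercept (weights $1/\sigma_{Yj}^2$), after
  orienting every SNP to a positive exposure effect. Under the InSIDE
  assumption the slope estimates $\theta$ and an intercept deviating
  from zero measures directional horizontal pleiotropy. SEs are scaled
  by the residual standard deviation of the weighted fit.

Two-sided p-values use the standard normal for every estimator (not a
t-distribution), matching the summary-data MR convention; for very small
instrument counts this is mildly anti-conservative, which is documented
rather than patched.

Bootstrap SEs for the median and mode estimators resample
$\hat\beta_{Xj}, \hat\beta_{Yj}$ from normals with their reported SEs
(1000 resamples by default, seed mandatory). The resampling operates on
a sign-oriented copy of the outcome effects (multiplied by the sign of
the point estimate, with the sign carried back afterwards), so negating
every outcome effect negates the estimate and leaves the SE exactly
unchanged under the same seed — making sign equivariance an exact,
testable property rather than a distributional one.

# Instrument selection and harmonization

Instruments are variants associated with the exposure at genome-wide
significance ($P \le 5\times10^{-8}$, boundary inclusive). Correlated
variants are pruned by greedy clumping on a caller-supplied $r^2$
matrix: rank by $|\beta|$ (ties by smaller p, then SNP id — a total
order, so the output is independent of input order), accept the top
remaining variant, discard everything with $r^2 \ge 0.01$ against it.
A variant without LD information is an error, never assumed
independent: the matrix is explicit precisely so the step is testable
offline rather than tied to a remote reference panel. Instrument
strength is screened by $F = (\beta/se)^2$ per SNP, with the weak
instrument flag raised when the mean is at or below the conventional 10.

Harmonization puts outcome effects on the exposure's effect-allele
orientation: equal allele pairs pass unchanged; swapped pairs negate the
outcome beta and complement its frequency; strand flips (complementary
pairs) are attempted before declaring a pair incompatible, because
summary files mix strand conventions. Palindromic variants (A/T, C/G)
are dropped by default — the conservative two-sample choice. The
permissive policy keeps them only when both allele frequencies fall on
the same side of 0.5 and outside $0.5 \pm 0.08$ *after label
alignment*; a missing frequency drops the variant, since orientation
cannot be adjudicated. Every intersected SNP leaves the step with a
recorded action (`unchanged`, `flipped`, `dropped_palindromic`,
`dropped_incompatible`); exposure SNPs absent from the outcome are
reported separately. Upstream options of the original analyses this
package re-implements were not published, so these defaults are the
package's own and are not claimed to match any particular historical
run.

# Sensitivity analyses

**Leave-one-out.** The estimator (IVW-FE by default, to contain
bootstrap cost) is re-run with each instrument excluded. When the
full-set association is significant at $\alpha$ (0.05 default) and one
exclusion moves the p-value to $\alpha + 0.01$ or beyond, that SNP is a
**driver**: the association rested on a single variant and is
dismissed. Exclusions landing in $[\alpha, \alpha + 0.01)$ are
**near-drivers** — the borderline pattern reported but not treated as
an outright dismissal. The 0.01 window is configurable.

**Concordance.** An association is stable when IVW-FE, MLE, weighted
median and weighted mode agree in direction and all reach $p < \alpha$.

# Multiplicity and power

Screening $m$ exposures applies a Bonferroni threshold $\alpha/m$
(0.05/37 $= 1.35\times10^{-3}$ in the motivating screen); p-values in
$[\alpha/m, 0.05)$ are *suggestive*, and boundaries are strict on the
significant side (a p-value equal to a threshold falls in the weaker
class). The test denominator is a config value decoupled from the
number of exposures actually run, so partial runs keep the full
correction.

A priori power uses the normal approximation for a binary outcome: the
Wald statistic has approximate mean
$\mu = |\theta|\sqrt{nR^2\phi(1-\phi)}$ ($R^2$ = exposure variance
explained by the instruments, $n$ = outcome study size, $\phi$ = case
fraction) and power is the two-sided tail mass
$\Phi(-z_{1-\alpha/2}+\mu) + \Phi(-z_{1-\alpha/2}-\mu)$. The two-sided
form is used deliberately: it equals $\alpha$ exactly under the null
and is monotone in all drivers, which the one-tailed shortcut is not.
`detectableOR()` inverts it by monotone root finding. Outputs are
approximate and labelled as such in run manifests.

# The synthetic-data generator

`simulatePair()` draws, per SNP: MAF $\sim U(0.1, 0.5)$; true exposure
effect $\gamma_j \sim N(0.07, 0.045^2)$ SD/allele; pleiotropic effect
$\alpha_j = 0$ for valid instruments, $N(0, s^2)$ (balanced) or
$N(s, (s/4)^2)$ (directional — a concentrated same-direction cluster,
as when invalid instruments act through one shared pathway) for the
invalid fraction; true outcome effect $\theta\gamma_j + \alpha_j$.
Observed effects are normal around the truths with the standard GWAS
standard errors $se_X = (2f(1-f)n_X)^{-1/2}$ and
$se_Y = (2f(1-f)n_Y\phi(1-\phi))^{-1/2}$, and an optional outlier adds
a fixed log-odds shift to one SNP — the driver scenario. Defaults
mirror a well-powered screen: exposure GWAS of 100,000; outcome study
of 30,657 with case fraction 0.407 (12,488 cases, 18,169 controls).
The wide effect-size spread is deliberate: real instrument sets mix a
few strong variants with many moderate ones, and MR-Egger's intercept
is unidentifiable when exposure effects cluster tightly.

Summary statistics are simulated directly rather than via
individual-level genotypes: two-sample MR consumes only summary data,
and direct simulation keeps the whole suite in seconds. Exposure and
outcome noise are independent (non-overlapping samples), and
pleiotropic effects are drawn independently of $\gamma_j$, so InSIDE
holds by construction; correlating them is future work, not a config
switch. The generator does **not** emulate LD between instruments,
winner's-curse inflation of discovery effects, allele-frequency
differences between studies, or binary exposures — so passing tests
certify the estimators' statistical behaviour under the stated model,
not robustness to those real-data complications.

Scenario presets (`scenarioPresets()`) freeze the documented study
conditions: `all_valid` (30 instruments, $\theta = 0.2$) for parameter
recovery and CI coverage; `null_screen_37` ($\theta = 0$) for type-I
error and the 37-exposure multiplicity simulation; `balanced_40` /
`directional_40` (150 instruments, 40% invalid, $s = 0.1$) for
robustness separation — the large instrument count reflects the
many-instrument regime the Egger intercept test needs for useful
power; and `driver_snp` (11 instruments, null effect, one 0.7 log-odds
outlier, ten times the mean SNP-exposure effect) for the dismissal
pattern, where the full-set IVW association is significant by
construction and rests entirely on the injected variant.

# Numerical and design notes

* Clump ranking, classification boundaries and the driver rule are all
  deterministic and strict, so re-runs are byte-identical given config
  seeds; `runStudy()` writes a manifest with an FNV-1a checksum of the
  config alongside seeds, thresholds and package version.
* Tables round-trip bit-exactly: numerics are written with 17
  significant digits (TSV) or `digits = I(17)` (truth-record JSON).
* An exact Egger fit (zero residuals) would give zero SEs; they are
  floored at $10^{-12}$ so result objects remain well-formed.
* Degenerate inputs fail loudly: zero exposure effect (undefined Wald
  ratio), empty instrument sets, singular Egger designs, variants
  missing from the LD matrix. In a multi-exposure run these become
  recorded skips, not aborts.
* Verification problem sizes: 500 replicates for parameter recovery and
  coverage, 2000 for type-I error, 200 for robustness separation and
  concordance, 100 runs of the 37-exposure null screen — large enough
  for three-sigma Monte-Carlo bands, small enough that the whole suite
  runs in about a minute.

# Limitations

Random-effects IVW, MR-PRESSO, contamination mixture, multivariable MR
and correlated-instrument IVW are out of scope, as are VCF-encoded
inputs, genome-build liftover and proxy-SNP lookup. Power calculations
are normal approximations. The normal (rather than t) reference for
p-values is mildly liberal below ~10 instruments. Published odds
ratios from any specific screen can only be reproduced given that
screen's per-SNP instrument tables; the package reproduces the
*method*, and certifies it on synthetic data with known truth.
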