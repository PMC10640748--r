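---
title: "Methods: phenome-wide two-sample Mendelian randomization with mrphewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide two-sample Mendelian randomization with mrphewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrphewas` implements a complete phenome-wide Mendelian randomization (MR)
screening study against a binary disease outcome, together with the
follow-up analyses such a screen requires: reverse-direction MR,
multiple-testing correction by spectral decomposition, two-step mediation
through intermediate traits, Bayesian colocalization, and a conditional
scan for secondary association signals. This vignette describes the models
and procedures, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the package's known limitations.

## The two-sample MR model

A genetic variant $G_j$ is a valid instrument for an exposure $X$ when it
is (i) associated with $X$, (ii) associated with the outcome $Y$ only
through $X$, and (iii) independent of confounders of the $X$–$Y$
relationship. In the two-sample design the per-variant association
estimates $\hat\beta_{Xj}$ (SD units for continuous traits) and
$\hat\beta_{Yj}$ (log-odds for a binary outcome) come from separate,
non-overlapping cohorts. Under a linear structural model with causal
effect $\theta$, each instrument supplies a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
delta-method standard error
$\mathrm{se}_j = \sigma_{Yj}/|\hat\beta_{Xj}|$.

The multi-instrument estimators all operate on the harmonised vectors:

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $1/\sigma_{Yj}^2$; algebraically the
  $1/\mathrm{se}_j^2$-weighted mean of Wald ratios. The standard error is
  the fixed-effect SE multiplied by $\max(\hat\sigma, 1)$, where
  $\hat\sigma$ is the residual scale: between-instrument dispersion can
  widen the interval but never narrow it below the fixed-effect width.
* **MR-Egger** — the same regression with a free intercept. A non-zero
  intercept estimates the average directional pleiotropic effect; its
  two-sided normal p-value is the pleiotropy test. Standard errors carry
  the same $\max(\hat\sigma, 1)$ dispersion floor. At least three
  instruments are required; with fewer, the screen records the test as
  missing.
* **Maximum likelihood** — maximises
  $\prod_j \phi(\hat\beta_{Xj};\xi_j,\sigma_{Xj})\,
  \phi(\hat\beta_{Yj};\theta\xi_j,\sigma_{Yj})$ over the true effects
  $\xi_j$ and $\theta$. The $\xi_j$ profile out analytically, leaving the
  one-dimensional objective
  $\tfrac12\sum_j (\hat\beta_{Yj}-\theta\hat\beta_{Xj})^2 /
  (\sigma_{Yj}^2+\theta^2\sigma_{Xj}^2)$, minimised by Brent's method with
  the IVW estimate as the start; the SE comes from the observed
  information of the profile. Unlike IVW, this estimator propagates the
  exposure-side sampling error. The heterogeneity statistic is the
  likelihood ratio against the saturated model (which fits every
  instrument exactly), $\chi^2$ with $n_{\mathrm{snp}}-1$ degrees of
  freedom.
* **Cochran's Q** — $\sum_j w_j(\hat\theta_j-\hat\theta_{\mathrm{IVW}})^2$
  with $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$, against the fixed-effect
  IVW mean; the classical IVW heterogeneity test.

All confidence intervals use the fixed multiplier
$\Phi^{-1}(0.975)=1.959964$, and every p-value downstream of file input is
recomputed as two-sided normal from the estimate and its SE, so the
pipeline is internally consistent regardless of how the input files
rounded their p-values (the file's p-value column is used only for
instrument selection). For a rare binary outcome the log-odds estimate is
reported as a log risk ratio (`to_risk_ratio()` exponentiates estimate and
bounds); no rare-disease attenuation correction is applied.

## Harmonisation

Exposure and outcome files may report the same variant on different
strands or with the allele roles swapped. `harmonise_pair()` aligns the
outcome record to the exposure's effect allele: label-swapped records are
flipped (beta negated, effect-allele frequency complemented),
strand-complemented records are complemented first, and incompatible
allele sets are dropped. Palindromic variants (A/T, C/G) cannot be
oriented from labels; both studies' effect-allele frequencies decide,
provided both lie outside the ambiguity window $0.5 \pm 0.08$ (i.e.
[0.42, 0.58]); otherwise the variant is dropped as ambiguous. The window
half-width is a declared convention: common MR practice uses windows in
this range, and the value is configurable
(`palindrome_eaf_window`). A palindromic variant with a missing frequency
on either side is dropped — the conservative choice. Harmonisation is
idempotent, and dropped records are retained with their reason so the
pipeline can report exclusion tallies.

## Instrument selection, clumping and proxies

Instruments are selected at genome-wide significance ($p <$ 5e-8,
strict), then pruned to LD independence by greedy clumping against a
reference dosage panel: repeatedly retain the smallest-p record (ties by
variant id) and remove in-window records ($\pm$10,000 kb) whose squared
dosage correlation exceeds 0.001. These stringent defaults match standard
practice for MR instrument selection. Instruments absent from the outcome
dataset are replaced by the candidate with maximal $r^2 > 0.8$ in the
panel (ties by proximity, then id); the signed correlation orients the
proxy's alleles onto the target's. Variants that cannot be mapped to the
panel pass through clumping untested, with a message — retaining them is
the less destructive default, and the log records the count. LD is the
Pearson correlation of unphased dosages.

## The phenome-wide screen and multiple testing

`run_screen()` applies the full chain per exposure — select, clump,
harmonise (with proxies), estimate (Wald ratio for one instrument, IVW
otherwise), sensitivity tests — and never lets one exposure's failure
abort the batch; failures and harmonisation losses are recorded per row.
Because screened traits are correlated, the family-wise threshold uses the
effective number of independent tests: the trait-trait correlation matrix
is estimated as the Pearson correlation of per-trait z-scores over the
variants shared by all traits, and its eigenvalues $\lambda_i$ give either
Nyholt's $M_{\mathrm{eff}} = 1 + (M-1)(1 - \mathrm{Var}(\lambda)/M)$ (the
default) or the Li–Ji count
$\sum_i [\,\mathbb{I}(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i
\rfloor)\,]$. The corrected threshold $\alpha/M_{\mathrm{eff}}$ can never
be stricter than plain Bonferroni since $M_{\mathrm{eff}} \le M$.
Estimating trait correlation from shared-variant z-scores is a declared
simplification of the full phenotypic-correlation machinery behind
spectral-decomposition corrections; it is adequate for synthetic data
where the shared variant grid is dense, and the `bonferroni` method is
available when no shared variants exist.

Reverse-direction MR reruns the identical machinery with the roles
swapped: the disease trait supplies instruments and each forward hit is
analysed as an outcome. A forward hit whose reverse estimate also passes
the (by default, forward) threshold is flagged as possible reverse
causation. No Steiger filtering is applied; the flag is advisory, as in
practice such hits need case-by-case judgement.

## Mediation

`two_step_mediation()` uses the product of coefficients: with total
effect $\tau$ (exposure$\to$outcome MR), step-1 effect $\alpha$
(exposure$\to$mediator) and step-2 effect $\beta$ (mediator$\to$outcome
MR), the indirect effect is $\alpha\beta$ and the proportion mediated
$100\,\alpha\beta/\tau$, on the log-risk scale throughout. When
$\alpha\beta$ and $\tau$ disagree in sign the decomposition is
meaningless and the row is labelled "Effect not consistent" instead of
reporting a proportion. Proportions outside [0, 100]% — the signature of
a weak or unstable total effect — are reported verbatim with a warning
rather than truncated, so the pathology stays visible. The SE of the
indirect effect uses the product delta method
$\sqrt{\alpha^2\mathrm{se}_\beta^2 + \beta^2\mathrm{se}_\alpha^2}$.

## Colocalization and the conditional scan

Single-instrument hits cannot support pleiotropy or heterogeneity tests,
and a Wald ratio can be confounded by LD: the instrument may merely be
correlated with a distinct causal variant for the outcome. Two regional
analyses address this.

**Colocalization.** For each variant shared by the two regional profiles,
Wakefield's approximate Bayes factor
$\log\mathrm{ABF} = \tfrac12[\log(1-\lambda) + z^2\lambda]$, with
$\lambda = w/(V+w)$, $V$ the squared SE and $w$ the prior effect
variance, summarises the evidence for a nonzero effect. Under the
at-most-one-causal-variant-per-trait model with per-variant priors
$p_1 = p_2 =$ 1e-4 and $p_{12} =$ 1e-5, the posterior mass of the five
hypotheses (H0 none, H1/H2 one trait only, H3 two distinct variants, H4
one shared variant) follows from the sums $S_1$, $S_2$ and
$S_{12} = \sum_i e^{\mathrm{lbf}_{1i}+\mathrm{lbf}_{2i}}$ via the
unnormalised masses $[1,\; p_1 S_1,\; p_2 S_2,\; p_1 p_2 (S_1 S_2 -
S_{12}),\; p_{12} S_{12}]$. All sums are evaluated in log space
(log-sum-exp); the H3 mass, a difference of exponentials, is guarded to
zero with a warning if cancellation drives it negative. The prior effect
variance is $0.2^2$ for both traits — the conventional binary-trait
default, applied to both scales for symmetry. The analysis window is
$\pm$250 kb around the index variant (a 500 kb region) and the priors and
window are configurable.

**Conditional scan.** Given an index variant (by default the smallest
marginal p in the window), each regional variant's conditional z-score is
$(z_j - r\,z_{\mathrm{index}})/\sqrt{1-r^2}$, with $r$ the panel dosage
correlation. This is the standardized-effect approximation to a full
joint conditional model: it assumes the panel matches the GWAS population
and ignores allele-frequency weighting, which is accurate for the
simulated data the package targets and conventionally acceptable for
flagging, not fine-mapping, secondary signals. Variants effectively
collinear with the index ($|r| \ge 0.99$) are skipped rather than
errored; unmappable variants keep their marginal z. A secondary signal is
declared when any non-index variant in the $\pm$500 kb window (a 1 Mb
region) stays below 5e-8 after conditioning. `regional_scatter()` exports
the position / $-\log_{10}p$ / $r^2$ triplet for a plain regional
association plot.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
truth without external downloads. Its defaults describe the study
conditions the package targets:

* two disjoint cohorts of 20,000 (plus a held-out panel of 2,000);
* a unit-variance continuous exposure with 30 causal variants explaining
  20% of its variance, plus a shared standard-normal confounder (effects
  0.3 on the exposure, 0.2 on the outcome);
* a binary outcome at 2% prevalence — the case fraction of a deep-vein
  thrombosis cohort — generated from a logistic model whose intercept is
  solved numerically for the target prevalence, with the causal effect
  $\theta = 0.4$ per SD on the log-odds scale;
* per-variant summary statistics produced by the same regressions a GWAS
  would run: simple linear regression for quantitative traits and
  per-variant logistic regression (a vectorised Newton–Raphson scan over
  all variants simultaneously) for the binary outcome.

Causal effect magnitudes are drawn as $0.7 + |N(0,1)|$ with random sign
before rescaling to the target heritability. The lower bound reflects
that published instrument sets contain only discoverable,
genome-wide-significant hits, not near-null effects; without it a
simulated "instrument" can be arbitrarily weak, which no real instrument
list would include. Variants are placed 11 Mb apart round-robin across
autosomes so that independent instruments are outside each other's
clumping window, as real clumped instruments are. Optional pleiotropy
adds direct variant-outcome effects, balanced (mean zero) or directional
(mean equal to the magnitude parameter).

The mediation triplet simulates three disjoint cohorts (exposure,
mediator, outcome GWAS). The mediator receives `step1` times the
exposure's genetic component plus its own instrument set
(`m_mediator_snps`, `h2_mediator`); the outcome receives `step2` times
the mediator plus an optional direct path. The mediator-specific
instruments mirror cis-acting protein QTLs and are what make the step-2
MR identified when a direct path exists — instruments acting only through
the exposure would be invalid for the mediator. The triplet's outcome
defaults to continuous: the proportion mediated is scale-free, and the
continuous path isolates the mediation arithmetic from binary-trait
noncollapsibility, which the two-sample generator already exercises.

The regional generator builds one LD block from two latent AR(1)
Gaussian haplotypes per individual ($\rho = 0.9$, thresholded at the
allele frequency), giving LD that decays with distance, and injects at
most one causal variant per trait (shared, distinct, or none) at an
effect size targeting $z \approx 8$.

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, sample overlap between cohorts and winner's-curse
bias, population stratification, allele-frequency mismatch between panel
and cohorts, and indel/multi-allelic variation. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to those real-data complications.

## Numerical choices and problem sizes

Tie-breaks are fixed everywhere (p-value then variant id for clumping and
index choice; $r^2$, proximity, then id for proxies), so every analysis
is deterministic given inputs and seed; the generator is fully
deterministic given its config (Mersenne–Twister, R's default RNG).
Bayes-factor arithmetic never exponentiates without a log-sum-exp guard.
The ML optimiser brackets the causal effect around the IVW start and
fails loudly on non-convergence or a non-positive observed information.
Degenerate inputs (all-zero exposure effects, zero-variance dosages,
empty variant intersections) raise typed errors rather than propagating
NaNs; within a batch screen those errors are caught per exposure.

The test suite validates calibration with 500-replicate null studies
(cohorts of 5,000, 50 instruments) and recovery with 50-replicate
mediation and 25-replicate regional studies at the default sizes above —
sizes chosen so the whole suite completes in a few minutes while leaving
Monte-Carlo error well inside the asserted bounds.

## Limitations

The estimator set is deliberately the screening core: no weighted
median/mode, MR-PRESSO, Steiger filtering, or correlated-instrument IVW.
Colocalization assumes at most one causal variant per trait per region
(no SuSiE-style multi-signal decomposition), and the conditional scan is
a one-step approximation, not stepwise joint model selection. Panel
population matching is the caller's responsibility. Input parsing covers
tab-separated summary statistics with header aliases — not GWAS-VCF, nor
genome-build liftover.
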