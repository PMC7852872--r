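---
title: "Methods: phenome-wide two-sample Mendelian randomisation"
author: "mrphewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide two-sample Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrphewas)
```

## The model

Two-sample Mendelian randomisation (MR) estimates the causal effect of a
continuous exposure $X$ on a binary outcome $Y$ from two independent GWAS.
For each instrument SNP $j$ we observe the exposure association
$\hat\beta_{Xj}$ (trait-SD per allele, SE $\sigma_{Xj}$) and the outcome
association $\hat\beta_{Yj}$ (log-odds per allele, SE $\sigma_{Yj}$).  Under
the instrumental-variable assumptions (association with the exposure,
no confounder association, no direct path to the outcome), each SNP's Wald
ratio $\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ estimates the causal
log-odds ratio $\theta$ per exposure SD.

The package implements the estimator family used in phenome-wide MR scans of
case-control outcomes:

* **IVW** — the inverse-variance-weighted mean of the Wald ratios with
  first-order weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, equivalent to
  weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
  origin.  *Fixed effects* uses $\mathrm{SE} = (\sum_j w_j)^{-1/2}$;
  *multiplicative random effects* inflates that SE by
  $\max\{1, \sqrt{Q/(L-1)}\}$, where $Q$ is Cochran's statistic, so that
  heterogeneous per-SNP effects widen the interval while the point estimate
  is unchanged.  Under balanced pleiotropy the heterogeneous effects average
  to the causal one, which is the rationale for using random effects as the
  primary model with many SNPs.
* **The 10-SNP rule** — the primary estimate uses the Wald ratio for a
  single instrument, fixed-effects IVW for 2–9 instruments, and
  random-effects IVW for 10 or more (`select_primary_method()`).  Exactly 10
  remaining SNPs in a leave-one-out refit therefore use random effects; the
  rule is applied to the reduced count, deterministically.
* **MR-Egger** — weighted regression with an intercept after orienting all
  pairs so $\hat\beta_{Xj}\ge 0$.  The intercept estimates the mean direct
  (pleiotropic) effect under InSIDE; the slope is the pleiotropy-adjusted
  causal effect.  Inference uses $t_{L-2}$ with multiplicative
  overdispersion $\max\{1, \sqrt{Q'/(L-2)}\}$.
* **Weighted median** — interpolation of the inverse-variance-weighted
  cumulative distribution of ordered ratios at 50%; consistent when valid
  instruments carry a majority of the weight.
* **Weighted mode** — the argmax of a Gaussian-kernel, weight-smoothed
  density over the ratios with bandwidth $\varphi \cdot 0.9\min(\mathrm{sd},
  \mathrm{mad})L^{-1/5}$ ($\varphi = 1$ by default); consistent when the
  largest cluster of agreeing instruments is valid.
* **RAPS** — the root of the profile score
  $\sum_j (\hat\beta_{Yj} - \theta\hat\beta_{Xj})\hat\beta_{Xj} /
  (\sigma_{Yj}^2 + \theta^2\sigma_{Xj}^2 + \tau^2) = 0$, which accounts for
  exposure-side noise; squared-error loss, with optional multiplicative
  overdispersion $\tau^2$ (floored at zero) solved jointly so standardized
  residuals have unit dispersion.  The SE comes from the observed
  information of the profile log-likelihood.  With $\sigma_{Xj}=0$ and
  $\tau^2=0$ the score reduces exactly to the IVW-FE normal equation, a
  property the tests assert.

Median and mode standard errors use a parametric bootstrap (both betas
resampled from normals at their reported SEs; 1000 replicates by default,
seed mandatory), so repeated runs with one seed are bit-identical.

## Instrument processing

Harmonisation aligns outcome to exposure effect alleles, negating the
outcome beta (and complementing its frequency) when the alleles are swapped,
and trying the complementary strand before declaring a mismatch.
Palindromic A/T and G/C pairs cannot be resolved from allele codes; the
default policy drops them (conservative), and `infer_by_eaf` aligns them by
allele frequency when both frequencies are at least `eaf_tol = 0.08` from
0.5.  No LD-proxy substitution is attempted for SNPs absent from the
outcome.  Duplicate rsids within a file keep the smallest-p record.

Instrument QC applies, in order: genome-wide significance ($P <
5\times10^{-8}$, strict), minor allele frequency ($>0.01$; records without a
frequency are kept with a warning), and greedy LD pruning at $r^2 \ge 0.01$
— candidates ranked by p-value (ties: larger $|\beta|$, then rsid), the best
accepted, and everything correlated with an accepted SNP discarded.  Pairs
absent from the (sparse) LD table count as $r^2 = 0$.  Trait-level strength
uses the per-SNP proportion of variance explained in the t-statistic form
$\mathrm{PVE}_j = t_j^2/(t_j^2 + n)$ — chosen because it requires no
trait-variance assumption and is exact for standardized traits — summed over
the pruned set, with
$F = \frac{n-k-1}{k}\,\frac{\mathrm{PVE}}{1-\mathrm{PVE}}$.  Traits enter
the scan only when $\mathrm{PVE} > 0.1\%$ and $F > 10$ (both strict).

## The scan

`run_phewas()` crosses every exposure with every outcome stratum:
harmonise, QC-gate, estimate (primary by the 10-SNP rule plus all
applicable sensitivity estimators), diagnose (Cochran's $Q$, $I^2 =
\max(0,(Q-\mathrm{df})/Q)$, radial Rucker's $Q'$, Egger intercept), classify
and attach power.  Multiplicity follows the two-band scheme: the primary
p-value is *significant* below the Bonferroni threshold $\alpha/m$,
*suggestive* below 0.05, otherwise null — strict inequalities on both
boundaries, and only the primary estimator is classified (sensitivity
estimators are reported unadjusted).  "Consistent evidence" is
operationalised as: primary $p<0.05$ and all three of weighted median,
weighted mode and RAPS agreeing in sign with $p<0.05$ — the definition is a
package choice, recorded here because scan reports use the flag.  Per-trait
estimator failures are logged to stderr and the trait emitted without
estimates; a failure never aborts the scan.

A-priori power for a binary outcome uses the asymptotic non-centrality
$\nu = N\,\mathrm{PVE}\,K(1-K)\log(\mathrm{OR})^2$ with case fraction
$K$, giving $\Phi(\sqrt{\nu}-z_{1-\alpha/2}) +
\Phi(-\sqrt{\nu}-z_{1-\alpha/2})$; at OR = 1 this equals $\alpha$ exactly,
which the tests assert.  Rucker's $Q'$ is computed as the residual sum of
squares of the radial (Galbraith) Egger fit — regress
$\hat\theta_j\sqrt{w_j}$ on $\sqrt{w_j}$ with an intercept — so $Q' \le Q$
holds by model nesting.

## The synthetic-data generator

`simulate_trait()` draws, per SNP: frequency $f_j \sim U(0.05, 0.95)$; true
exposure effect $\gamma_j = |N(0, \texttt{gamma\_sd}^2)|$; direct outcome
effect $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ with correlation
`inside_violation` to the standardized effect size.  Observed betas add
sampling noise at GWAS-realistic SEs: $1/\sqrt{2f(1-f)n}$ for the
standardized exposure and the same form with the effective sample size
$n_{\mathrm{eff}} = n_1 n_0/(n_1+n_0)$ for the case-control log-OR — making
the generator self-consistent with the power formula above.

Effect alleles are coded as the *exposure-increasing* alleles (the
convention for curated instruments).  This makes "directional" pleiotropy
well-defined: MR-Egger reorients pairs so exposure betas are non-negative,
and under a sign-symmetric effect distribution that reorientation would
cancel any injected pleiotropy mean, leaving nothing for the intercept to
recover.  With increasing-allele coding the Egger intercept recovers
$\mu_\alpha$ under InSIDE, which the acceptance suite verifies by
simulation.  That check gates instruments at genome-wide significance, as
the scan itself does: sub-threshold SNPs violate the NO-Measurement-Error
assumption, and sign-orienting them flips part of the injected pleiotropy,
attenuating the intercept (the same weak-instrument attenuation that
motivates SIMEX-corrected Egger in practice).

Default conditions (chosen once, as a realistic curated-panel scenario):
27 SNPs per trait (a ~8400-variant panel over ~316 traits), exposure GWAS
of 50,000, outcome of 12,488 cases / 18,169 controls with subtype strata of
6183 and 5820 cases against the shared controls, and `gamma_sd = 0.047`,
which puts the expected trait PVE near 2% — the typical strength of
continuous-trait instrument panels.  `simulate_phewas()` derives one seed
per trait from the master seed (counter-based), relabels rsids to be
panel-unique, and concatenates per-stratum outcome tables into scan-ready
files; identical seeds give byte-identical panels.

What the generator does *not* emulate: LD between instruments (SNPs are
post-pruning by construction), individual-level genotypes, binary
exposures, sample overlap between the two GWAS, and winner's-curse
selection of instruments.  Passing calibration tests therefore demonstrate
correctness of the estimators under the stated sampling model, not
robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Wald-ratio SE is first-order delta ($\sigma_{Yj}/|\hat\beta_{Xj}|$),
  ignoring exposure noise, matching common practice; a second-order form is
  available via `wald_ratio(second_order = TRUE)`.  A zero exposure beta is
  an error (undefined ratio).
* p-values are two-sided normal throughout, except MR-Egger which uses
  $t_{L-2}$; extreme statistics are floored at $10^{-300}$ so p-values stay
  in $(0, 1]$.
* The RAPS root is bracketed by a sign change over a 401-point grid on
  $[-10, 10]$ then polished by `uniroot` (tolerance $10^{-12}$); no sign
  change raises a non-convergence error.  The overdispersion loop
  alternates $\theta$ and $\tau^2$ solves to $10^{-10}$.
* The weighted-mode argmax is located on a 1024-point grid spanning the
  ratios $\pm 3$ bandwidths and refined by `optimize`; the bootstrap uses a
  128-point grid per replicate, vectorised across replicates.  A degenerate
  instrument set (all ratios equal) returns the shared ratio for any
  bandwidth; a zero median absolute deviation falls back to a floor of
  $10^{-8}$ on the bandwidth.
* Weighted-median interpolation pins to the first (last) ratio when half
  the weight is reached before (never past) it.
* $I^2$ clamps at 0 when $Q < \mathrm{df}$; the trait PVE sum caps at 1 and
  an $F$ statistic at PVE = 1 is reported as infinite.
* All bootstraps and simulations restore the caller's RNG state, so library
  calls never perturb a user's random stream.

## Problem sizes used in the checks

The calibration suite uses a 316-trait × 3-stratum all-null scan (type-I
error of the primary estimator, Bonferroni hit count, byte-identical
reruns), 2000 replicates at $L=30$ for IVW-FE coverage, 200 replicates for
Egger intercept recovery, and smaller fixed-seed fixtures for the solver
oracles (bisection for RAPS, dense grid for the mode, closed-form WLS for
IVW/Egger).  These sizes give Monte-Carlo error comfortably inside the
asserted bands while keeping a full run in minutes on one core.

## Known limitations

* No LD-proxy lookup, Steiger filtering, MR-PRESSO, multivariable MR or
  contamination-mixture estimators; the estimator set is deliberately the
  classic scan family above.
* Binary exposures are out of scope (two-sample MR with binary exposure and
  outcome is prone to badly biased Wald ORs).
* The per-trait PVE depends on the reported sample size; exposure GWAS that
  misreport effective n will propagate into the F gate and power column.
* RAPS here uses squared-error loss; the robust (Huber/Tukey) variants are
  not implemented.
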