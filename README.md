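# mrphewas

Phenome-wide two-sample Mendelian randomisation (MR-PheWAS) from GWAS
summary statistics, for epidemiologists scanning many genetically proxied
exposures (continuous traits, effects in trait-SD per allele) against one
or more case-control outcomes (effects in log-odds per allele), such as
glioma and its subtypes.

For each exposure the pipeline harmonises exposure/outcome associations,
applies instrument QC (P < 5×10⁻⁸, MAF > 0.01, greedy LD pruning at
r² ≥ 0.01, trait gates PVE > 0.1% and F > 10), and estimates the causal
odds ratio per exposure SD (OR_SD). The per-SNP Wald ratios
θ̂ⱼ = β̂_Yj / β̂_Xj are combined by inverse-variance weighting
(w_j = β̂²_Xj / σ²_Yj):

- **IVW-FE / IVW-RE** — β̂ = Σwθ̂ / Σw with SE (Σw)^(−1/2); random effects
  multiplies the SE by max{1, √(Q/(L−1))} from Cochran's Q. One SNP falls
  back to the Wald ratio; 2–9 SNPs use FE; ≥ 10 use RE (the primary model).
- **MR-Egger** — weighted regression with an intercept (the directional
  pleiotropy test), t inference on L−2 df.
- **Weighted median / weighted mode / RAPS** — sensitivity estimators with
  parametric-bootstrap or profile-likelihood SEs.

Diagnostics cover Cochran's Q and I², radial Rucker's Q′, leave-one-out,
named-SNP exclusion and forest-ready single-SNP tables. Scan-level results
are classified as significant (p < α/m, Bonferroni), suggestive (p < 0.05)
or null, with a-priori power for OR 1.5 per trait, and volcano-plot tables.
A summary-statistics simulator with known ground truth (configurable causal
effect, balanced/directional pleiotropy, InSIDE violation, case-control
scaled SEs) makes every stage testable end to end.

## Worked example

Simulate a 5-trait panel (3 null, 2 causal) against one outcome of 12,488
cases / 18,169 controls, and scan it:

```r
library(mrphewas)
panel <- simulate_phewas(5, frac_null = 0.6, seed = 7,
                         template = sim_config(L = 15),
                         strata = list(all = list(n_case = 12488,
                                                  n_control = 18169)))
rec <- run_phewas(panel$exposures, panel$outcomes, phewas_config(seed = 7))
rec[, c("trait_id", "n_snps", "method", "primary_or_sd", "primary_pval",
        "classification", "power")]
#>   trait_id n_snps method primary_or_sd primary_pval classification     power
#> 1 trait001      7 ivw_fe     1.0127240 0.9029393556           null 0.9742007
#> 2 trait002      8 ivw_fe     1.1133010 0.2853019026           null 0.9808727
#> 3 trait003      6 ivw_fe     0.9442369 0.5894422951           null 0.9677145
#> 4 trait004      4 ivw_fe     1.3588683 0.0330383273     suggestive 0.8037922
#> 5 trait005      8 ivw_fe     0.7236630 0.0003523061    significant 0.9940252
```

The two causal traits (true θ = 0.18 and −0.40 in `panel$truth`) surface as
suggestive and significant; the three null traits stay null. `power` is the
a-priori probability of detecting OR_SD = 1.5 at α = 0.05 given each
trait's instrument PVE and the outcome's case/control split.

Single-trait analysis on the harmonised instruments:

```r
d <- panel$traits[["trait005"]]
insts <- build_instrument_set(d$exposure, d$outcomes$all)$instruments
mr_ivw(insts, "re")
#> MR estimate [ivw_re], 15 SNP(s)
#>   log-OR per SD: -0.3145 (SE 0.0898), 95% CI [-0.4905, -0.1385], p = 0.000461
#>   OR per SD: 0.730 (95% CI 0.612-0.871)
#>   aux: Q=14.8, df=14, inflation=1.028, se_fe=0.08733
```

(The scan row above shows 8 SNPs because the P < 5×10⁻⁸ gate trims the 15
simulated instruments; here all 15 are used directly.) An OR_SD of 0.73
means each SD increase in the exposure multiplies the odds of disease by
0.73. `mr_egger()`, `mr_weighted_median()`, `mr_weighted_mode()`,
`mr_raps()`, `heterogeneity()`, `leave_one_out()` and
`single_snp_table(insts, exclude_rsid = ...)` take the same instrument
table; `volcano_table(rec)` emits plot-ready coordinates with the
−log₁₀ threshold lines.

A thin CLI wraps the same functions:

```sh
exec/mrphewas simulate --traits 10 --seed 1 --out panel/
exec/mrphewas power --n-case 12488 --n-control 18169 --pve 0.022
```

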