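# snpmeta

Meta-analysis of case-control SNP association studies, for
epidemiologists and statistical geneticists who pool published
genotype counts.  The package takes a table with one row per
(study, SNP) — case and control genotype counts XX/XY/YY, or allele
tallies, plus metadata — and produces pooled odds ratios under six
genetic models, with heterogeneity-driven model selection,
Hardy–Weinberg screening, subgroup analyses, publication-bias tests and
leave-one-out sensitivity analysis.  A transcribed data set of 16
published IL-10 promoter polymorphism studies (−1082 A/G, −819 T/C,
−592 A/C) in atopic dermatitis ships with the package and anchors the
test suite: the pipeline reproduces the published pooled tables from
the raw counts.

## The statistics

Per-study effects are crude log odds ratios, `y_i = log(a_i d_i / (b_i
c_i))`, `v_i = 1/a_i + 1/b_i + 1/c_i + 1/d_i`, with the
Haldane–Anscombe 0.5 correction for studies containing a zero cell.
Pooling is either

* **fixed effect (Mantel–Haenszel)**:
  `OR_MH = Σ(a_i d_i / n_i) / Σ(b_i c_i / n_i)` with the
  Robins–Breslow–Greenland variance of `log OR_MH`, or
* **random effects (DerSimonian–Laird)**: `τ² = max(0, (Q − (k−1)) /
  (Σw − Σw²/Σw))` with `w_i = 1/v_i`, pooled with weights
  `1/(v_i + τ²)`,

chosen by heterogeneity: random effects when `I² > 50%` or Cochran's
`P(Q) < 0.05`.  Control-arm Hardy–Weinberg equilibrium is tested by
Pearson chi-square (1 df) against `n p², 2npq, n q²`.  Publication bias
uses Egger's regression of `y_i/se_i` on `1/se_i` (intercept t, k−2 df)
and the Begg–Mazumdar rank correlation between standardized deviates
and variances.  The methods vignette
(`vignettes/snp-meta-analysis.Rmd`) documents every convention and why
it was chosen.

## Worked example

```r
library(snpmeta)
tab <- il10_ad_studies()          # 33 records: 15 x -1082, 9 x -819, 9 x -592

fit <- snp_meta(tab, "-1082A/G", "allele")
fit
#> Case-control meta-analysis: -1082A/G, allele model (allele Y vs X)
#> Group: Overall   Studies: 14   Cases/Controls: 1593/2095
#> Pooled OR (fixed effect, Mantel-Haenszel): 0.96 (95% CI 0.86-1.07), z = -0.74, P = 0.459
#> Heterogeneity: Q = 17.90 on 13 df (P = 0.161), I2 = 27.4%, tau2 = 0.0000
```

Fourteen studies supply allele counts (one reports only a collapsed
genotype class and is ineligible); the pooled odds ratio of 0.96 with a
confidence interval spanning 1 means no detectable association of the
G allele with atopic dermatitis.  Low heterogeneity (I² = 27%) keeps
the analysis on the fixed-effect path.  The one positive subgroup
signal in this data set:

```r
snp_meta(tab, "-1082A/G", "recessive", ethnicity = "Asian")
#> Case-control meta-analysis: -1082A/G, recessive model (YY vs XX+XY)
#> Group: Asian   Studies: 3   Cases/Controls: 469/491
#> Pooled OR (fixed effect, Mantel-Haenszel): 2.22 (95% CI 1.32-3.74), z = 3.01, P = 0.003
#> Heterogeneity: Q = 3.53 on 2 df (P = 0.172), I2 = 43.3%, tau2 = 0.0000
```

Publication bias and the full pipeline:

```r
egger_test(snp_meta(tab, "-819T/C", "allele"))
#> Egger test: intercept = -4.839, t = -2.767 (7 df), P = 0.028

rep <- run_analysis(tab, analysis_spec("-592A/C"))   # all models x subgroups
write_report(rep, "out", "markdown")
```

`simulate_study_table(sim_config(k_studies = 10, true_or = 1.5))`
generates corpora with known truth for calibration;
`simulate_biased_corpus()` adds small-study suppression to exercise the
bias tests.

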