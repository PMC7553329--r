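# sumprs

Polygenic risk scores (PRS) from GWAS summary statistics, with model
selection that needs no individual-level validation data.

Most published GWAS results are summary statistics — per-SNP marginal
effects $\hat\beta_j$, standard errors, sample sizes — not genotypes.
`sumprs` fits joint PRS weights from those statistics plus a genotype
reference panel, and then answers the two questions that usually require
held-out individual-level data: *which candidate model should I pick?* and
*how well will it predict out of sample?*

It is aimed at statistical geneticists building PRS from public GWAS
results, and at methodologists who want a self-contained, simulation-backed
implementation of the summary-statistic penalized-regression stack.

## What it implements

**Penalized regression on summary statistics.** With standardized data the
least-squares objective depends on the data only through the SNP–phenotype
correlations $r$ (from the summary statistics) and the LD matrix $R$ (from
the reference panel). Because the two come from different samples, $R$ is
shrunk toward the identity, $R_s = (1-s)R + sI$, and the objective

$$f(\beta) = \beta' R_s \beta - 2\beta' r + J(\beta)$$

is minimized per LD block by coordinate descent (compiled core). Penalties:
LASSO ($2\lambda\|\beta\|_1$), elastic net, and the truncated LASSO penalty
(TLP) $2\lambda\sum_j\min(|\beta_j|,\tau)$, which stops penalizing effects
above $\tau$ — less bias on large effects and sparser fits when the truth
is sparse, especially under allelic heterogeneity (several causal variants
per LD region). SNPs absent from the panel are modeled as independent and
solved in closed form.

**Pseudo-AIC / pseudo-BIC.** The training SSE and residual variance are
reconstructed from three moment estimates —
$\tfrac1N X'X \approx \tfrac1n X_r'X_r + 0.2I$,
$\tfrac1N X'Y \approx \hat s_j^2\hat\beta_j$, and
$\tfrac1N Y'Y \approx \mathrm{med}_j\{N\hat s_j^2\widehat{var}(\hat\beta_j)
+ \hat s_j^2\hat\beta_j^2\}$ — giving $AIC = 2k - 2l$, $BIC = \ln(N)k - 2l$
with $l = -\widehat{SSE}/(2\tilde\sigma^2)$. The reference panel must be
split: one half fits the models, the disjoint half scores them (reuse is a
hard error).

**Quasi-correlation.** An estimate of the Pearson correlation between a PRS
and a testing phenotype observed only through summary statistics:

$$\mathrm{quasiCor} = \frac{\sum_j \hat s_j^2\hat\beta^*_j\hat\beta^P_j}
{\sqrt{\widehat{var}(Y^*)\,(\beta^P)'\hat\Sigma_r\beta^P}}.$$

**Binary traits.** Marginal logistic estimates are converted to the linear
scale by Taylor matching: $\beta_1 = \kappa b_1$,
$SE(\beta_1)=\kappa\,se(b_1)$, $\kappa = e^{-b_0}/(1+e^{-b_0})^2$, with
$e^{-b_0}$ the control:case ratio.

**Simulator.** Block-LD genotypes (latent AR(1) haplotypes, HWE by
construction), point-normal or clustered ("allelic heterogeneity") causal
effects, quantitative or liability-threshold binary phenotypes, and marginal
GWAS statistics — so the whole stack is testable end to end without any
downloads.

**Formats.** PLINK 1 bed/bim/fam (native reader/writer), LDetect-style
3-column BED LD blocks, delimited summary statistics with configurable
column names, JSON harmonization logs and manifests. A thin CLI
(`inst/cli/sumprs`) exposes `simulate`, `fit`, `select`, `qcor`,
`convert-binary`, and an end-to-end `demo`.

## Worked example

Simulate a study (M = 1000 SNPs, h² = 0.5, 1% causal), fit LASSO and TLP
grids on the tuning-1 LD panel, select by pseudo-BIC on the disjoint
tuning-2 panel, and check the pick with the quasi-correlation against
testing-cohort summary statistics:

```r
library(sumprs)

cfg   <- sim_config(n_snps = 1000, scale = 0.5, h2 = 0.5,
                    p_causal = 0.01, seed = 42)
study <- simulate_study(cfg)

panel_fit <- ref_panel(study$tune1$X, study$map)   # fitting LD panel
panel_sel <- ref_panel(study$tune2$X, study$map)   # disjoint selection panel
problem   <- harmonize(study$sumstats, panel_fit, study$blocks)
problem
#> <harmonized_problem: 1000 SNPs (1000 in reference, 40 blocks), n_eff = 3120>

lam  <- exp(seq(log(0.01), log(0.12), length.out = 6))
grid <- c(lapply(lam, function(l) penalty_spec("lasso", l, s = 0.1)),
          lapply(lam, function(l) penalty_spec("tlp", l, s = 0.1, tau = 0.05)))
models  <- fit_path(problem, panel_fit, grid)

moments <- estimate_moments(problem, panel_sel)
report  <- pseudo_criteria(models, moments)
report
#> <selection_report: 12 candidates, sigma2 = 0.6575, AIC-> model 5, BIC-> model 5>

best <- models[[report$selected$bic]]
best
#> <prs_model lasso: lambda = 0.0730037, s = 0.1, 8/1000 nonzero, objective = -0.3034>

test_ss <- compute_gwas(study$test$X, study$test$y, study$map)
quasi_correlation(best, problem, test_ss, panel_sel)^2
#> [1] 0.457

scores <- predict_prs(best$beta_std[problem$snps$snp_id],
                      ref_panel(study$test$X, study$map))
cor(scores, study$test$y)^2
#> [1] 0.460
```

The truth here has 10 causal SNPs; the pseudo-BIC pick keeps 8 nonzero
weights, and its squared quasi-correlation (0.457) — computed from testing
*summary statistics only* — agrees with the true out-of-sample r²
(0.460) computed from the held genotypes. `rescale_to_per_allele()`
converts the standardized weights for scoring raw dosages, and
`run_demo()` packages this whole workflow (including quasi-correlation
model selection) behind one call.

## References

The methods implemented here follow the summary-statistic penalized
regression literature: LASSO-on-summary-statistics with a shrunk LD matrix
and LD-block estimation, the truncated LASSO penalty, and
information-criterion model selection adapted to summary data. See the
methods vignette (`vignettes/summary-statistic-prs.Rmd`) for the full
derivations, conventions, and design decisions.
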