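---
title: "Penalized polygenic risk scores from summary statistics: models, selection criteria, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized polygenic risk scores from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumprs)
```

## The problem

A polygenic risk score (PRS) predicts the genetic component of a trait as a
weighted sum of allele dosages, $\hat y_i = \sum_j x_{ij}\beta_j$. Jointly
estimating the weights ordinarily requires individual-level genotypes and
phenotypes, which are rarely shareable. What *is* public are GWAS summary
statistics — per-SNP marginal effects $\hat\beta_j$, standard errors, sample
sizes — and reference genotype panels from which linkage disequilibrium (LD)
between SNPs can be estimated. `sumprs` estimates penalized-regression PRS
weights, selects among candidate models, and evaluates out-of-sample fit
using only those two ingredients.

## The fitting objective

With a standardized design matrix and phenotype, the least-squares objective
expands to $y'y + \beta' R \beta - 2\beta' r + J(\beta)$, where
$r_j$ is the SNP–phenotype correlation and $R$ the SNP–SNP correlation
matrix. Neither is observed directly: $r$ is recovered from the summary
statistics and $R$ from the reference panel. Because the two come from
different samples, the plain objective can be unbounded; the LD matrix is
therefore shrunk toward the identity,

$$R_s = (1-s)R + sI, \qquad 0 \le s \le 1,$$

which restores convexity of the quadratic part and doubles as an implicit
ridge penalty ($s\,\beta'\beta$). In practice $s \approx 0.1$ gives reliable
convergence for sparse traits; denser genetic signals may need larger $s$.
Estimation is blockwise over approximately independent LD blocks
(LDetect-style intervals), so $R$ is block diagonal and blocks can be
solved independently.

Three penalties $J(\beta)$ are supported:

* **LASSO**: $2\lambda\sum_j |\beta_j|$;
* **elastic net**: $2\alpha\lambda \sum_j|\beta_j| +
  (1-\alpha)\lambda\sum_j \beta_j^2$;
* **truncated LASSO penalty (TLP)**:
  $2\lambda\sum_j \min(|\beta_j|, \tau)$, which stops penalizing
  coefficients above $\tau$. Large effects escape shrinkage entirely, which
  reduces bias and, when the truth is sparse, yields sparser fits: the
  effective behavior is a hard threshold at roughly $\sqrt{2\lambda\tau}$
  with no shrinkage beyond it.

**Lambda parametrization.** The quadratic part of the objective is left
unhalved, and the penalty carries a factor 2, so that the identity-LD
($s=1$) LASSO solution is *exactly* the soft threshold of $r$ at $\lambda$.
This makes $\lambda$ directly interpretable on the correlation scale
(a marginal SNP–phenotype correlation below $\lambda$ cannot enter the
model on its own). Grids from other conventions (where the implied
threshold is $\lambda/2$) should be rescaled accordingly.

### Computing r from published statistics

Published effects are per-allele, not standardized, so $r$ must be
reconstructed. The default uses the marginal t-statistic,
$r_j = t_j/\sqrt{n_j - 2 + t_j^2}$ with $t_j = \hat\beta_j/se_j$, which is
an exact identity for simple linear regression and requires no phenotype-SD
estimate. The alternative $r_j = \hat\beta_j \hat s_j/\widehat{sd}(y)$
(`r_method = "beta"`) uses the panel SNP SD $\hat s_j$ and the
summary-level phenotype SD; it is provided because per-allele effects from
meta-analyses do not always satisfy the t identity. Both are clipped to
$[-1, 1]$.

### SNPs absent from the reference panel

SNPs present in the summary statistics but missing from the panel carry no
LD information. Rather than discarding them, they are treated as mutually
independent: their rows of $R$ are zero, the $s$ and $(1-s)$ diagonal
contributions sum to one, and each solves the univariate objective
$\beta^2 - 2\beta r + J(\beta)$ in closed form (`fit_missing_snps()`).

### Harmonization

Before fitting, `harmonize()` aligns the inputs: palindromic (A/T, C/G)
SNPs are removed unconditionally (strand cannot be resolved from summary
data); alleles are matched to the panel coding with a sign flip for
swapped coding and a drop for irreconcilable alleles; SNPs below the panel
MAF threshold (default 0.01) are removed; and SNPs are greedily clumped
within blocks so that no retained pair exceeds $r^2 = 0.9$ (priority:
smaller p-value, ties by position). The clumping bound exists to guarantee
solver convergence, not to sparsify — informative SNPs are rarely lost at
0.9. `.bim` positions are treated as 1-based and block intervals as 0-based
half-open, so a SNP maps to a block iff $start \le pos - 1 < end$; SNPs
outside every interval form singleton pseudo-blocks. Missing panel
genotypes are mean-imputed per SNP before any variance or LD computation,
which keeps $R$ a valid correlation matrix.

## The solver

Each block is solved by cyclic coordinate descent. For the LASSO and
elastic net the coordinate update is the usual soft threshold
($z_j = r_j - (1-s)\sum_{k\ne j} R_{jk}\beta_k$;
$\beta_j \leftarrow S(z_j, \lambda)$, elastic net divides by
$1 + (1-\alpha)\lambda$), and the objective is convex, so the solution is
exact. Convergence is declared when the largest coordinate change in a
sweep falls below `tol` ($10^{-6}$ by default), with a cap of 10,000
sweeps; non-convergence sets a `converged = FALSE` flag on the model and is
never silent. Along a descending-$\lambda$ path within one
$(s, \tau, \alpha)$ slice, fits are warm-started from the previous
solution.

The TLP objective is nonconvex, and this deserves care. A
difference-of-convex scheme (inner weighted LASSO with weights
$1\{|\beta_j| \le \tau\}$) was evaluated first and found to stall in
coordinate-separable local minima — even one-dimensional problems can stay
on the soft-threshold branch when the unpenalized branch is strictly
better. The shipped solver instead uses the *exact univariate TLP update*
at each coordinate: the penalized branch (soft threshold clamped to
$[-\tau, \tau]$) is compared with the unpenalized branch
($\beta_j = z_j$, penalty cost $2\lambda\tau$) by objective value, so
every accepted move decreases the true objective. Because coordinate-wise
minimality still does not imply global minimality, the solver runs from a
deterministic set of starts and keeps the best: the LASSO solution at the
same $(\lambda, s)$, zero, the ridge-relaxed solution
$R_s^{-1} r$, and — on blocks of up to 50 SNPs — single-coordinate and
leave-one-out variants of the relaxed solution, which reach branch
patterns outside the LASSO basin. Larger blocks substitute a
$\tau$-continuation run (geometrically decreasing $\tau$ with warm
starts). On random problems of up to four SNPs this start set reproduces
brute-force global minima to $10^{-6}$, which the test suite verifies
against an independent grid-refinement search.

### Per-allele rescaling and scoring

Fitted weights live on the correlation scale. For scoring raw dosages they
are rescaled per SNP as
$\beta_j^{\text{per-allele}} = \beta_j\,\widehat{sd}(y)/\hat s_j$. When no
phenotype SD is supplied, it is estimated from the summary statistics (see
the next section): for a centered phenotype,
$\widehat{sd}(y) = \sqrt{\widehat{(1/N)Y'Y}}$.

## Pseudo-AIC and pseudo-BIC

Classical AIC/BIC need the training log-likelihood, which for a Gaussian
linear model reduces to the SSE and the residual variance. Both can be
approximated from summary data via three moment estimates (all
sample-size-normalized so quantities from different cohorts are
comparable; panel variances use the population $1/n$ denominator so the
identities below are exact in the no-split limit):

$$\widehat{\tfrac1N X'X} = \tfrac1n X_r'X_r, \qquad
  \widehat{\tfrac1N X'Y}_j = \hat s_j^2 \hat\beta_j, \qquad
  \widehat{\tfrac1N Y'Y} = \mathrm{med}_j\left\{N \hat s_j^2
  \widehat{var}(\hat\beta_j) + \hat s_j^2\hat\beta_j^2\right\}.$$

The first is the covariance of the (centered) panel; the second and third
follow from the simple-regression identities
$\hat\beta_j = x_j'y/(N s_j^2)$ and the residual-variance expansion — every
SNP yields the *same* $Y'Y$ estimate in exact arithmetic, and the median
across SNPs makes the estimate robust to SNPs that violate the identities
(meta-analyzed or filtered statistics). From these,

$$\widehat{SSE}(\beta) = N\left[\widehat{\tfrac1N Y'Y}
  - 2\beta'\widehat{\tfrac1N X'Y}
  + \beta'\widehat{\tfrac1N X'X}\beta\right], \qquad
  \tilde\sigma^2 = \frac{N}{N-q}\left[\widehat{\tfrac1N Y'Y} -
  \widehat{\tfrac1N X'Y}'\,\widehat{\tfrac1N X'X}^{-1}\,
  \widehat{\tfrac1N X'Y}\right],$$

the latter restricted to a pruned-and-thresholded SNP subset playing the
role of the OLS fit (defaults: clump at $r^2 < 0.2$, keep $p < 10^{-3}$,
cap at $\min(500, N/4)$ SNPs; $q$ = subset size; all configurable — the
estimate is fairly insensitive to reasonable choices). The criteria are
then $AIC = 2k - 2l$ and $BIC = \ln(N)k - 2l$ with
$l = -\widehat{SSE}/(2\tilde\sigma^2)$; $\tilde\sigma^2$ is computed once
and shared across candidates so the criteria differences are driven by SSE
and $k$. Ties select the smaller $k$. The identity
$BIC - AIC = (\ln N - 2)k$ holds by construction and is asserted in the
tests.

Two practical safeguards from the method's own validation:

* **Covariance regularization.** The selection-side covariance is
  regularized as $\tfrac1n X_r'X_r + 0.2I$ (constant configurable). This
  is distinct from the fitting-side $R_s$ shrinkage.
* **Reference-panel splitting.** Reusing one panel both to fit the models
  and to score them with pseudo-AIC/BIC overfits the criteria badly.
  `split_reference_panel()` produces disjoint halves and tags them;
  passing the fitting half into `estimate_moments()` is a hard error, not
  a warning.

**Degrees of freedom.** Since the $s$-shrunk objective behaves like an
elastic net, $k$ can be taken as the ridge trace
$tr[(R + \lambda s I)^{-1} R]$, computed blockwise on the selection-panel
correlation matrix restricted to SNPs with nonzero fitted weights (without
the restriction the trace would not depend on the model at all). The
$\lambda s$ scalar is used directly against unit-diagonal correlation
blocks, which makes it dimensionless; this normalization is a convention
of this package and is stated here because other resolutions of the
$n$-scaling ambiguity exist. The cheap alternative `mode = "nonzero"`
(count of nonzero weights, the LASSO df) is the default; a singular block
at $\lambda s = 0$ falls back to the count with a warning.

**Binary traits.** The Gaussian machinery does not apply to log-odds.
Marginal logistic estimates $(\hat b_0, \hat b_1)$ are converted by
first-order Taylor matching of the two mean functions:
$\beta_1 = \kappa\,b_1$, $SE(\beta_1) = \kappa\,se(b_1)$,
$\beta_0 = 1/(1+e^{-b_0})$ with
$\kappa = e^{-b_0}/(1+e^{-b_0})^2$ and $e^{-b_0}$ = the control:case
ratio. $\kappa \in (0, \tfrac14]$, maximal at balance. The approximation
is first-order in $b_1$ and is accurate for the small per-SNP effects
typical of GWAS; it degrades for large log-odds. When both an intercept
column and case/control counts are available the counts win — they are
robust to covariate-adjusted intercepts — and a message is emitted.
`estimate_moments()` refuses unconverted logistic statistics outright.

## Quasi-correlation

To evaluate a PRS on a testing cohort known only through its summary
statistics, note that for centered data
$\tfrac1{n_t}\sum_i Y^*_i \hat Y^*_i = \sum_j \hat s_j^2 \hat\beta^*_j
\hat\beta^P_j$ — the cross-moment needs only the testing-data marginal
effects and panel variances — while
$var(\hat Y^*) = (\beta^P)'\,\tfrac1n X_r'X_r\,\beta^P$ and $var(Y^*)$
comes from the same second-moment identity as above (median across SNPs).
Hence

$$\mathrm{quasiCor} = \frac{\sum_j \hat s_j^2\hat\beta^*_j\hat\beta^P_j}
 {\sqrt{\widehat{var}(Y^*)\;(\beta^P)'\hat\Sigma_r\,\beta^P}}.$$

The denominator uses the *unregularized* panel covariance: the derivation
has no ridge term, unlike the pseudo-AIC/BIC covariance — the two choices
are intentionally different. Finite-panel noise can push the ratio
slightly outside $[-1,1]$; it is clipped with a warning rather than an
error. The statistic is scale-invariant up to sign
($\mathrm{quasiCor}(c\beta) = \mathrm{sign}(c)\,\mathrm{quasiCor}(\beta)$),
equals the true Pearson correlation exactly when the testing cohort itself
serves as the panel, and an all-zero model is an error (correlation
undefined). `select_by_quasicor()` picks the arg-max over candidates, ties
toward the sparser model. Squared quasi-correlation mildly overestimates
the true testing $r^2$ on average in this package's simulations, matching
the behavior expected of the estimator.

## The simulator

All validation runs on synthetic data, generated by `simulate_study()`
under one seed:

* **Genotypes.** Per LD block, two independent latent AR(1) standard
  normal vectors per individual (one per haplotype) are thresholded at the
  MAF quantile and summed, giving dosages in $\{0,1,2\}$ with
  Hardy–Weinberg equilibrium by construction and geometrically decaying
  within-block LD. Thresholding attenuates the latent correlation
  (a latent $\rho = 0.9$ yields dosage correlation near 0.75 at
  MAF 0.3); the tests pin this against a large-$n$ Monte-Carlo oracle
  rather than a closed form.
* **Effects.** Point-normal: an exact-count causal set of
  $\mathrm{round}(p_{causal} M)$ SNPs drawn without replacement (exact
  count rather than per-SNP Bernoulli, so sparse settings are stable
  across seeds when comparisons against the true number of nonzero
  effects are made), each effect
  $N(0, h^2/(M p_{causal}))$ on the standardized scale. Clustered
  (allelic-heterogeneity) mode: anchors are drawn uniformly among SNPs
  with at least one within-block neighbor at $r^2 \ge 0.25$, extended to
  groups of 2–8 LD-sharing SNPs until the causal quota is met, with
  per-causal variance $h^2/\#causal$. This clustered procedure is the
  package's own emulation of the allelic-heterogeneity regime, not a
  reproduction of any external algorithm.
* **Phenotypes.** $y = X_{std}\beta + \varepsilon$ with noise variance
  $var(g)(1-h^2)/h^2$ calibrated to the realized genetic variance, so the
  sample variance ratio targets $h^2$ up to noise sampling alone. Binary
  traits threshold the liability at the empirical case-fraction quantile.
* **Summary statistics.** Vectorized per-SNP OLS (quantitative) or
  per-SNP logistic fits (binary) on the training cohort.

Cohort sizes default to a 6240/3119/1560/1560 training/tuning-1/tuning-2/
testing split — training statistics feed the fit, tuning-1 serves as the
fitting LD panel, tuning-2 as the disjoint selection panel, testing for
evaluation — and `scale` shrinks all four proportionally.

**What the simulator does not emulate:** real LD (long-range, variable
block structure, allele-frequency–dependent), population structure and
relatedness, genotyping error and imputation noise, strand ambiguity in
the panel, per-SNP sample-size heterogeneity from meta-analysis, and
binary-trait ascertainment. Passing tests therefore demonstrate internal
correctness of the estimators under block-LD Gaussian-liability
conditions, not performance on real cohorts.

## Problem sizes used in the validation suite

The test suite runs reduced but non-trivial designs chosen to keep each
statistical check to a few minutes on a single core: heritability
calibration at the full training size ($n = 6240$, $M = 2000$); solver
oracle equivalence on 100 random blocks of up to 4 SNPs; quasi-correlation
fidelity over 20 seeds at $M = 2000$, $n_{train} = 4000$,
$n_{test} = 3000$; sparsity orderings at $p_{causal} = 0.001$, $s = 0$
over 20 seeds; and the clustered-effects TLP-vs-LASSO comparison at
$M = 1000$ with latent $\rho = 0.85$ (clusters need genuinely high LD to
exist) over 20 seeds. Tuning in these comparisons selects by
individual-level tuning-cohort $r^2$, mirroring how the candidate grids
would be tuned with validation data; λ grids are log-spaced on
$[0.01, 0.12]$ with TLP $\tau \in \{0.01, 0.05, 0.1\}$, inside the
package's default grid ranges.

## Known limitations

* Only the main-text standard-error conversion for binary traits is
  implemented; covariate-adjusted GWAS (multiple-regression summary
  statistics) are accepted but their SEs are treated as marginal.
* No strand flipping beyond allele-swap detection; palindromic SNPs are
  always dropped rather than frequency-resolved.
* No summary-statistic imputation, liftover, or multi-ancestry panel
  mixing; the pseudovalidation criterion of the LassoSum family is not
  reimplemented (the selection report leaves room to carry externally
  computed values).
* Pseudo-AIC/BIC assume sparse candidate models; for dense (ridge-like)
  models the df penalty degenerates and the criteria reduce to estimated
  training SSE, which is not useful for selection.
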