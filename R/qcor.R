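#' Quasi-correlation between a PRS and an out-of-sample phenotype
#'
#' Estimates the Pearson correlation between the PRS predictions
#' \eqn{X_* \beta^P} and an unobserved testing phenotype \eqn{Y_*} from the
#' testing cohort's marginal summary statistics alone:
#' \deqn{\mathrm{quasiCor} = \frac{\sum_j \hat s_j^2 \hat\beta^*_j
#'   \hat\beta^P_j}{\sqrt{\widehat{var}(Y_*) \; (\beta^P)' \hat\Sigma_r
#'   \beta^P}},}
#' where \eqn{\hat\beta^*} are the testing-data marginal (per-allele)
#' effects, \eqn{\hat s_j^2} the reference-panel SNP variances,
#' \eqn{\hat\Sigma_r = (1/n) X_r'X_r} the unregularized panel covariance
#' (blockwise), and \eqn{\widehat{var}(Y_*)} the summary-level phenotype
#' variance (median across SNPs of
#' \eqn{n_t \hat s_j^2 \widehat{var}(\hat\beta^*_j) + \hat s_j^2
#' (\hat\beta^*_j)^2}). The result is clipped to `[-1, 1]` with a warning,
#' since finite-panel noise can push the ratio slightly out of range.
#'
#' @param model A `prs_model` (standardized weights; converted internally),
#'   or a named numeric vector of per-allele weights.
#' @param problem The `harmonized_problem` the model was fitted on
#'   (supplies SNP ids, alleles, blocks, and the training-phenotype SD used
#'   for the per-allele conversion).
#' @param test_ss Testing-cohort `sumstats` (quantitative scale; alleles
#'   are aligned to the problem's coding, swaps flip the sign, conflicts
#'   drop the SNP).
#' @param panel_half Reference panel (a `ref_panel`) for SNP variances and
#'   the covariance quadratic form.
#' @param var_y_star Optional known variance of the testing phenotype;
#'   default is the summary-level estimate.
#' @return Scalar quasi-correlation in `[-1, 1]`.
#' @export
quasi_correlation <- function(model, problem, test_ss, panel_half,
                              var_y_star = NULL) {
  stopifnot(inherits(problem, "harmonized_problem"),
            inherits(panel_half, "ref_panel"))
  if (isTRUE(attr(test_ss, "is_binary_trait")))
    stop("convert binary testing summary statistics first", call. = FALSE)
  snps <- problem$snps[problem$snps$in_reference, , drop = FALSE]

  # Align testing stats to the problem's allele coding.
  ts <- match(snps$snp_id, test_ss$snp_id)
  ok <- !is.na(ts)
  same <- ok
  flip <- rep(FALSE, nrow(snps))
  same[ok] <- test_ss$a1[ts[ok]] == snps$a1[ok] &
    test_ss$a2[ts[ok]] == snps$a2[ok]
  flip[ok] <- test_ss$a1[ts[ok]] == snps$a2[ok] &
    test_ss$a2[ts[ok]] == snps$a1[ok]
  usable <- ok & (same | flip)
  if (!any(usable))
    stop("no testing-data SNPs align with the model", call. = FALSE)
  beta_star <- rep(0, nrow(snps))
  beta_star[usable] <- test_ss$beta[ts[usable]] *
    ifelse(flip[usable], -1, 1)
  se_star <- rep(NA_real_, nrow(snps))
  se_star[usable] <- test_ss$se[ts[usable]]
  n_star <- rep(NA_real_, nrow(snps))
  n_star[usable] <- test_ss$n[ts[usable]]

  cols <- match(snps$snp_id, panel_half$map$snp_id)
  if (anyNA(cols))
    stop("panel half is missing model SNPs", call. = FALSE)
  G <- impute_mean(panel_half$genotypes[, cols, drop = FALSE])
  Gc <- sweep(G, 2, colMeans(G))
  n <- nrow(G)
  s2 <- colSums(Gc^2) / n
  if (any(s2 == 0))
    stop("zero-variance SNP in quasi-correlation panel", call. = FALSE)

  beta_p <- if (inherits(model, "prs_model")) {
    model$beta_std[snps$snp_id] * problem$sd_y_hat / sqrt(s2)
  } else {
    b <- model[snps$snp_id]
    if (anyNA(b)) stop("weights do not cover the problem's SNPs",
                       call. = FALSE)
    unname(b)
  }
  if (all(beta_p == 0))
    stop("quasi-correlation undefined for an all-zero model",
         call. = FALSE)

  if (is.null(var_y_star)) {
    u <- usable
    var_y_star <- median(n_star[u] * s2[u] * se_star[u]^2 +
                           s2[u] * beta_star[u]^2)
  }
  if (!is.finite(var_y_star) || var_y_star <= 0)
    stop("nonpositive testing-phenotype variance estimate", call. = FALSE)

  numerator <- sum(s2 * beta_star * beta_p)
  quad <- 0
  for (bk in unique(snps$block)) {
    jj <- which(snps$block == bk)
    bb <- beta_p[jj]
    if (all(bb == 0)) next
    Cb <- crossprod(Gc[, jj, drop = FALSE]) / n
    quad <- quad + drop(crossprod(bb, Cb %*% bb))
  }
  if (quad <= 0) stop("zero predicted-score variance", call. = FALSE)
  out <- numerator / sqrt(var_y_star * quad)
  if (abs(out) > 1) {
    warning(sprintf("quasi-correlation %.4f clipped to [-1, 1]", out),
            call. = FALSE)
    out <- sign(out)
  }
  out
}

#' Select the candidate model maximizing the quasi-correlation
#'
#' @param models List of `prs_model` objects (NULL or degenerate all-zero
#'   candidates are skipped with `NA` entries).
#' @param problem,test_ss,panel_half As in [quasi_correlation()].
#' @return List with `index` (selected model; ties break toward the
#'   smaller nonzero count, then the earlier candidate) and `qcor`
#'   (per-model values).
#' @export
select_by_quasicor <- function(models, problem, test_ss, panel_half) {
  if (inherits(models, "prs_model")) models <- list(models)
  if (!length(models)) stop("no candidate models", call. = FALSE)
  qc <- vapply(models, function(m) {
    if (is.null(m)) return(NA_real_)
    tryCatch(quasi_correlation(m, problem, test_ss, panel_half),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(qc)))
    stop("all candidate models are degenerate", call. = FALSE)
  nz <- vapply(models, function(m)
    if (is.null(m)) Inf else sum(m$beta_std != 0), numeric(1))
  ord <- order(-qc, nz, seq_along(qc), na.last = TRUE)
  list(index = ord[1], qcor = qc)
}
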