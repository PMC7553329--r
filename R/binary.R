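#' Convert univariate logistic-regression estimates to the linear scale
#'
#' Equating the first-order Taylor expansions of the linear and logistic
#' mean functions for a marginal SNP regression gives
#' \deqn{\beta_1 = \kappa \, b_1, \quad
#'       SE(\beta_1) = \kappa \, se(b_1), \quad
#'       \beta_0 = 1 / (1 + e^{-b_0}),}
#' with \eqn{\kappa = e^{-b_0} / (1 + e^{-b_0})^2} and
#' \eqn{e^{-b_0}} equal to the control:case ratio. The approximation is
#' accurate when the log-odds `b1` are small, which holds for typical
#' per-SNP GWAS effects. When both an intercept and case/control counts
#' are supplied, the counts win (they are robust to covariate-adjusted
#' intercepts) and a message is emitted.
#'
#' @param b1 Log-odds estimate(s).
#' @param se_b1 Standard error(s) of `b1`.
#' @param n_cases,n_controls Case and control counts (both > 0).
#' @param b0 Marginal logistic intercept, used only when counts are
#'   absent.
#' @return List with `beta0`, `beta1`, `se_beta1`, and the conversion
#'   factor `kappa`.
#' @examples
#' logistic_to_linear(0.2, 0.05, n_cases = 500, n_controls = 500)
#' @export
logistic_to_linear <- function(b1, se_b1, n_cases = NULL, n_controls = NULL,
                               b0 = NULL) {
  if (!is.null(n_cases) || !is.null(n_controls)) {
    if (is.null(n_cases) || is.null(n_controls) || n_cases <= 0 ||
        n_controls <= 0)
      stop("n_cases and n_controls must both be positive", call. = FALSE)
    if (!is.null(b0))
      message("both b0 and case/control counts supplied; using the counts")
    e_nb0 <- n_controls / n_cases
  } else if (!is.null(b0)) {
    e_nb0 <- exp(-b0)
  } else {
    stop("supply either n_cases/n_controls or b0", call. = FALSE)
  }
  kappa <- e_nb0 / (1 + e_nb0)^2
  list(beta0 = 1 / (1 + e_nb0), beta1 = kappa * b1,
       se_beta1 = kappa * se_b1, kappa = kappa)
}

#' Convert binary-trait summary statistics to the linear scale
#'
#' Applies [logistic_to_linear()] to every SNP of a logistic-scale
#' `sumstats` object, producing quantitative-scale statistics usable by
#' [estimate_moments()] and [quasi_correlation()]. The per-SNP sample size
#' becomes `n_cases + n_controls` where no `n` column exists.
#'
#' @param ss A `sumstats` object with `is_binary_trait = TRUE`.
#' @param n_cases,n_controls Case/control counts; default to the
#'   attributes recorded by [compute_gwas()].
#' @return A quantitative-scale `sumstats` object flagged with attribute
#'   `converted_from_logistic = TRUE`.
#' @export
convert_binary_sumstats <- function(ss, n_cases = NULL, n_controls = NULL) {
  if (!isTRUE(attr(ss, "is_binary_trait")))
    stop("summary statistics are not flagged as a binary trait",
         call. = FALSE)
  if (is.null(n_cases)) n_cases <- attr(ss, "n_cases")
  if (is.null(n_controls)) n_controls <- attr(ss, "n_controls")
  conv <- logistic_to_linear(ss$beta, ss$se, n_cases = n_cases,
                             n_controls = n_controls)
  out <- sumstats(snp_id = ss$snp_id, chrom = ss$chrom, pos = ss$pos,
                  a1 = ss$a1, a2 = ss$a2, beta = conv$beta1,
                  se = conv$se_beta1, n = ss$n, pvalue = ss$pvalue,
                  is_binary_trait = FALSE)
  attr(out, "converted_from_logistic") <- TRUE
  attr(out, "kappa") <- conv$kappa
  out
}
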