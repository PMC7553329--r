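#' Specify a penalty for summary-statistic penalized regression
#'
#' Constructs the penalty used in the blockwise objective
#' \deqn{f(\beta) = \beta' R_s \beta - 2 \beta' r + J(\beta),}
#' where \eqn{R_s = (1 - s) R + s I} is the LD matrix shrunk towards the
#' identity. Three penalties are supported:
#' \describe{
#'   \item{lasso}{\eqn{J(\beta) = 2\lambda \sum_j |\beta_j|}}
#'   \item{elastic_net}{\eqn{J(\beta) = 2\alpha\lambda \sum_j |\beta_j| +
#'     (1-\alpha)\lambda \sum_j \beta_j^2}}
#'   \item{tlp}{the truncated LASSO penalty
#'     \eqn{J(\beta) = 2\lambda \sum_j \min(|\beta_j|, \tau)}, which stops
#'     penalizing coefficients above \eqn{\tau} and so reduces shrinkage bias
#'     on large effects}
#' }
#' The factor 2 is a parametrization choice: with the quadratic part of the
#' objective left unhalved, it makes the identity-LD (\eqn{s = 1}) LASSO
#' solution exactly the soft threshold of \eqn{r} at \eqn{\lambda}, so
#' \eqn{\lambda} is directly interpretable on the correlation scale.
#'
#' @param kind One of `"lasso"`, `"elastic_net"`, `"tlp"`.
#' @param lambda Non-negative penalty strength.
#' @param s LD shrinkage in `[0, 1]`; `s = 1` treats SNPs as independent.
#' @param tau Truncation threshold (> 0) for `"tlp"`. `Inf` recovers the
#'   LASSO.
#' @param alpha Elastic-net mixing parameter in (0, 1]; `alpha = 1` recovers
#'   the LASSO.
#' @return An object of class `penalty_spec`.
#' @examples
#' penalty_spec("lasso", lambda = 0.01, s = 0.1)
#' penalty_spec("tlp", lambda = 0.01, s = 0, tau = 0.005)
#' @export
penalty_spec <- function(kind = c("lasso", "elastic_net", "tlp"),
                         lambda, s = 0.1, tau = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
            is.numeric(s), length(s) == 1L, s >= 0, s <= 1)
  if (kind == "tlp") {
    if (is.null(tau) || !is.numeric(tau) || length(tau) != 1L || tau <= 0)
      stop("tlp penalty requires a single tau > 0", call. = FALSE)
  } else {
    tau <- NULL
  }
  if (kind == "elastic_net") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L ||
        alpha <= 0 || alpha > 1)
      stop("elastic_net penalty requires alpha in (0, 1]", call. = FALSE)
  } else {
    alpha <- NULL
  }
  structure(list(kind = kind, lambda = lambda, s = s, tau = tau,
                 alpha = alpha),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  extra <- switch(x$kind,
                  tlp = sprintf(", tau = %g", x$tau),
                  elastic_net = sprintf(", alpha = %g", x$alpha),
                  "")
  cat(sprintf("<penalty_spec %s: lambda = %g, s = %g%s>\n",
              x$kind, x$lambda, x$s, extra))
  invisible(x)
}

soft_threshold <- function(z, thr) sign(z) * pmax(abs(z) - thr, 0)

# J(beta) under the package's 2*lambda parametrization.
penalty_value <- function(beta, penalty) {
  switch(penalty$kind,
    lasso = 2 * penalty$lambda * sum(abs(beta)),
    elastic_net = 2 * penalty$alpha * penalty$lambda * sum(abs(beta)) +
      (1 - penalty$alpha) * penalty$lambda * sum(beta^2),
    tlp = 2 * penalty$lambda * sum(pmin(abs(beta), penalty$tau))
  )
}

#' Value of the blockwise summary-statistic objective
#'
#' Evaluates \eqn{(1-s)\beta'R\beta + s\beta'\beta - 2\beta'r + J(\beta)}
#' (the constant \eqn{y'y} is omitted). Used for diagnostics and for
#' verifying descent of the coordinate-wise solver.
#'
#' @param beta Coefficient vector.
#' @param r Vector of SNP-phenotype correlations for the block.
#' @param R Unit-diagonal LD correlation matrix for the block.
#' @param penalty A [penalty_spec()].
#' @return Scalar objective value.
#' @export
objective_value <- function(beta, r, R, penalty) {
  s <- penalty$s
  q <- if (all(beta == 0)) 0 else drop(crossprod(beta, R %*% beta))
  (1 - s) * q + s * sum(beta^2) - 2 * sum(beta * r) +
    penalty_value(beta, penalty)
}

# Univariate objective for SNPs absent from the reference panel: the s*I and
# (1-s)*I diagonal contributions sum to 1, so the quadratic part is
# beta^2 - 2*beta*r regardless of s.
univariate_objective <- function(beta, r, penalty) {
  beta^2 - 2 * beta * r + penalty_value_elementwise(beta, penalty)
}

penalty_value_elementwise <- function(beta, penalty) {
  switch(penalty$kind,
    lasso = 2 * penalty$lambda * abs(beta),
    elastic_net = 2 * penalty$alpha * penalty$lambda * abs(beta) +
      (1 - penalty$alpha) * penalty$lambda * beta^2,
    tlp = 2 * penalty$lambda * pmin(abs(beta), penalty$tau)
  )
}

#' Closed-form solutions for SNPs missing from the reference panel
#'
#' SNPs present in the summary statistics but absent from the reference
#' panel are treated as mutually independent: each solves the univariate
#' objective \eqn{\beta^2 - 2\beta r + J(\beta)} in closed form.
#'
#' @param r Vector of SNP-phenotype correlations for the missing SNPs.
#' @param penalty A [penalty_spec()].
#' @return Numeric vector of coefficients, same length as `r`.
#' @examples
#' fit_missing_snps(0.3, penalty_spec("lasso", lambda = 0.1))  # 0.2
#' @export
fit_missing_snps <- function(r, penalty) {
  stopifnot(inherits(penalty, "penalty_spec"))
  if (length(r) == 0L) return(numeric(0))
  if (anyNA(r) || any(!is.finite(r)))
    stop("non-finite r passed to fit_missing_snps", call. = FALSE)
  lam <- penalty$lambda
  switch(penalty$kind,
    lasso = soft_threshold(r, lam),
    elastic_net = soft_threshold(r, penalty$alpha * lam) /
      (1 + (1 - penalty$alpha) * lam),
    tlp = {
      tau <- penalty$tau
      # Penalized branch: minimize over |beta| <= tau (soft threshold,
      # clamped to the boundary); unpenalized branch: beta = r (flat penalty
      # 2*lambda*tau beyond tau). Exact minimizer is the better of the two.
      b1 <- soft_threshold(r, lam)
      b1 <- sign(b1) * pmin(abs(b1), tau)
      b2 <- r
      o1 <- univariate_objective(b1, r, penalty)
      o2 <- univariate_objective(b2, r, penalty)
      ifelse(o2 < o1, b2, b1)
    }
  )
}
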