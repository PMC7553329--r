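#' Compute marginal GWAS summary statistics
#'
#' Quantitative traits: per-SNP simple linear regression of the centered
#' phenotype on the centered (mean-imputed) dosage, vectorized across SNPs;
#' two-sided p-values from the t distribution with `n - 2` df. Binary
#' traits: per-SNP univariate logistic regression (Wald statistics).
#' Monomorphic SNPs have an undefined standard error and are excluded with
#' a message.
#'
#' @param X Dosage matrix (individuals x SNPs).
#' @param y Phenotype vector (0/1 for binary).
#' @param map Data frame with `chrom`, `snp_id`, `pos`, `a1`, `a2` for the
#'   columns of `X`.
#' @param binary Fit logistic instead of linear marginal models.
#' @return A `sumstats` object. For binary traits the effects are log-odds,
#'   `is_binary_trait` is set, and attributes `n_cases` / `n_controls`
#'   record the phenotype split.
#' @export
compute_gwas <- function(X, y, map, binary = FALSE) {
  X <- impute_mean(as.matrix(X))
  n <- nrow(X)
  stopifnot(length(y) == n, nrow(map) == ncol(X))
  mono <- matrixStats_colVars(X) == 0
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s) excluded from GWAS")
  keep <- which(!mono)
  if (!length(keep)) stop("all SNPs monomorphic", call. = FALSE)
  Xk <- X[, keep, drop = FALSE]
  if (binary) {
    yb <- as.integer(y)
    if (!all(yb %in% 0:1)) stop("binary trait must be 0/1", call. = FALSE)
    est <- vapply(seq_len(ncol(Xk)), function(j) {
      fit <- glm(yb ~ Xk[, j], family = binomial())
      cf <- summary(fit)$coefficients
      c(cf[2, 1], cf[2, 2], cf[2, 4])
    }, numeric(3))
    beta <- est[1, ]
    se <- est[2, ]
    pv <- est[3, ]
  } else {
    yc <- y - mean(y)
    Xc <- sweep(Xk, 2, colMeans(Xk))
    sxx <- colSums(Xc^2)
    beta <- drop(crossprod(Xc, yc)) / sxx
    # floor the residual SS at a tiny positive value so a perfectly
    # collinear phenotype yields a near-zero (not zero) standard error
    rss <- pmax(sum(yc^2) - beta^2 * sxx,
                .Machine$double.eps * sum(yc^2))
    sigma2 <- rss / (n - 2)
    se <- sqrt(sigma2 / sxx)
    tt <- beta / se
    pv <- 2 * pt(-abs(tt), df = n - 2)
  }
  ss <- sumstats(snp_id = map$snp_id[keep], chrom = map$chrom[keep],
                 pos = map$pos[keep], a1 = map$a1[keep], a2 = map$a2[keep],
                 beta = beta, se = se, n = n, pvalue = pv,
                 is_binary_trait = binary)
  if (binary) {
    attr(ss, "n_cases") <- sum(y == 1)
    attr(ss, "n_controls") <- sum(y == 0)
  }
  attr(ss, "n_excluded_monomorphic") <- sum(mono)
  ss
}
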