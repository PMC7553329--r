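#' Convert standardized PRS weights to the per-allele scale
#'
#' Penalized regression on summary statistics yields weights on the
#' correlation (standardized-genotype, standardized-phenotype) scale. For
#' scoring raw dosages they are rescaled as
#' \eqn{\beta_j^{per-allele} = \beta_j \, \widehat{sd}(y) / \hat s_j},
#' with \eqn{\hat s_j} the reference-panel dosage SD. SNPs without a panel
#' SD (not in the reference, or zero variance) are excluded from the
#' per-allele output.
#'
#' @param model A `prs_model` from [fit_path()] or [fit_block()] output
#'   assembled by the caller.
#' @param problem The `harmonized_problem` the model was fitted on.
#' @param sd_y Phenotype SD; defaults to the problem's summary-level
#'   estimate `sd_y_hat`.
#' @return Data frame with `snp_id`, `a1`, `beta_std`, `beta_per_allele`
#'   (rows with no panel SD dropped).
#' @export
rescale_to_per_allele <- function(model, problem, sd_y = NULL) {
  stopifnot(inherits(model, "prs_model"),
            inherits(problem, "harmonized_problem"))
  if (is.null(sd_y)) sd_y <- problem$sd_y_hat
  if (is.null(sd_y) || !is.finite(sd_y))
    stop("no phenotype SD available; supply sd_y or use standardized weights",
         call. = FALSE)
  snps <- problem$snps
  ok <- snps$in_reference & !is.na(snps$s_hat) & snps$s_hat > 0
  data.frame(snp_id = snps$snp_id[ok], a1 = snps$a1[ok],
             beta_std = model$beta_std[ok],
             beta_per_allele = model$beta_std[ok] * sd_y / snps$s_hat[ok],
             stringsAsFactors = FALSE)
}

#' Score individuals with PRS weights
#'
#' Computes `score_i = sum_j x_ij beta_j`, matching weights to genotype
#' columns by SNP id and mean-imputing missing dosages.
#'
#' @param weights Data frame with `snp_id` and a weight column
#'   (`beta_per_allele` by default, else `beta_std`, else `beta`), or a
#'   named numeric vector.
#' @param genotypes A `ref_panel` or a dosage matrix with SNP-id column
#'   names.
#' @return Numeric score vector, one entry per individual.
#' @export
predict_prs <- function(weights, genotypes) {
  if (inherits(genotypes, "ref_panel")) genotypes <- genotypes$genotypes
  genotypes <- as.matrix(genotypes)
  if (is.data.frame(weights)) {
    wcol <- intersect(c("beta_per_allele", "beta_std", "beta"),
                      names(weights))[1]
    if (is.na(wcol)) stop("no weight column found", call. = FALSE)
    w <- setNames(weights[[wcol]], weights$snp_id)
  } else {
    w <- weights
    if (is.null(names(w))) stop("weights must be named by snp_id",
                                call. = FALSE)
  }
  idx <- match(names(w), colnames(genotypes))
  if (anyNA(idx))
    stop("SNP id(s) absent from genotypes: ",
         paste(head(names(w)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  X <- impute_mean(genotypes[, idx, drop = FALSE])
  drop(X %*% w)
}
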