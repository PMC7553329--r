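#' Split a reference panel into disjoint fitting and selection halves
#'
#' Reusing one reference panel both to fit penalized models and to estimate
#' pseudo-AIC/BIC overfits the criteria; the panel must be split and the
#' halves used for the two purposes. The halves are tagged so that passing
#' the fitting half into [estimate_moments()] is a hard error.
#'
#' @param panel A `ref_panel` with at least 4 individuals.
#' @param seed Seed for the shuffle.
#' @return List with elements `fit` and `select`, two disjoint `ref_panel`
#'   halves (sizes differing by at most 1).
#' @export
split_reference_panel <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "ref_panel"))
  n <- panel$n_ref
  if (n < 4) stop("need at least 4 individuals to split", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  h1 <- sort(idx[seq_len(n %/% 2)])
  h2 <- sort(idx[(n %/% 2 + 1):n])
  tag <- sprintf("split_seed%d_n%d", seed, n)
  mk <- function(rows, role) {
    half <- ref_panel(panel$genotypes[rows, , drop = FALSE], panel$map)
    attr(half, "panel_role") <- role
    attr(half, "split_tag") <- tag
    half
  }
  list(fit = mk(h1, "fit"), select = mk(h2, "select"))
}

#' Estimate summary-level moments for pseudo-AIC/BIC
#'
#' Builds the moment approximations
#' \deqn{(1/N) X'X \approx (1/n) X_r'X_r, \quad
#'       (1/N) Y'Y \approx \mathrm{med}_j\{N \hat s_j^2
#'         \widehat{var}(\hat\beta_j) + \hat s_j^2 \hat\beta_j^2\}, \quad
#'       (1/N) X'Y \approx (\hat s_1^2 \hat\beta_1, \ldots)'}
#' from the harmonized summary statistics and a reference-panel half
#' disjoint from the one used for fitting. The blockwise covariance is
#' regularized as \eqn{(1/n) X_r'X_r + c I} with \eqn{c = 0.2} by default.
#'
#' @param problem A `harmonized_problem` (quantitative scale; convert
#'   binary-trait statistics first with [convert_binary_sumstats()]).
#' @param panel_half The selection half from [split_reference_panel()] (or
#'   any panel disjoint from the fitting panel).
#' @param ridge Covariance regularization constant added to the diagonal.
#' @param center `"median"` (recommended) or `"mean"` across SNPs for the
#'   \eqn{(1/N) Y'Y} estimate.
#' @return An object of class `summary_moments`.
#' @export
estimate_moments <- function(problem, panel_half, ridge = 0.2,
                             center = c("median", "mean")) {
  stopifnot(inherits(problem, "harmonized_problem"),
            inherits(panel_half, "ref_panel"))
  center <- match.arg(center)
  if (isTRUE(problem$is_binary_trait))
    stop(paste("summary statistics are on the logistic scale;",
               "convert them with convert_binary_sumstats() first"),
         call. = FALSE)
  if (identical(attr(panel_half, "panel_role"), "fit"))
    stop(paste("this panel half is tagged as the fitting half;",
               "reusing it for pseudo-AIC/BIC invalidates the criteria"),
         call. = FALSE)
  snps <- problem$snps[problem$snps$in_reference, , drop = FALSE]
  cols <- match(snps$snp_id, panel_half$map$snp_id)
  if (anyNA(cols))
    stop("panel half is missing harmonized SNPs", call. = FALSE)
  G <- impute_mean(panel_half$genotypes[, cols, drop = FALSE])
  Gc <- sweep(G, 2, colMeans(G))
  n <- nrow(G)
  s2 <- colSums(Gc^2) / n
  if (any(s2 == 0))
    stop("zero-variance SNP in selection panel half", call. = FALSE)
  ctr <- if (center == "median") median else mean
  yty <- ctr(snps$n * s2 * snps$se^2 + s2 * snps$beta^2)
  xty <- s2 * snps$beta
  block_index <- split(seq_len(nrow(snps)), snps$block)
  cov_blocks <- lapply(block_index, function(jj)
    crossprod(Gc[, jj, drop = FALSE]) / n)
  structure(list(snp_id = snps$snp_id, block = snps$block,
                 pvalue = snps$pvalue, pos = snps$pos, s2 = s2,
                 xty_per_n = setNames(xty, snps$snp_id), yty_per_n = yty,
                 cov_blocks = cov_blocks, block_index = block_index,
                 ridge = ridge, N = problem$n_eff, n_panel = n),
            class = "summary_moments")
}

#' @export
print.summary_moments <- function(x, ...) {
  cat(sprintf("<summary_moments: %d SNPs, %d blocks, N = %g, n_panel = %d, ridge = %g>\n",
              length(x$snp_id), length(x$cov_blocks), x$N, x$n_panel,
              x$ridge))
  invisible(x)
}

#' Default SNP subset for the residual-variance estimate
#'
#' Greedily clumps SNPs (within block, priority ascending p-value) so no
#' retained pair exceeds `r2_max`, keeps those with p-value below `p_max`,
#' and caps the subset at `min(cap, N / 4)` by smallest p-value.
#'
#' @param moments A `summary_moments` object.
#' @param r2_max Clumping threshold.
#' @param p_max Marginal p-value threshold.
#' @param cap Maximum subset size.
#' @return Integer indices into the moments' SNP order (possibly empty).
#' @export
sigma2_snp_subset <- function(moments, r2_max = 0.2, p_max = 1e-3,
                              cap = 500L) {
  stopifnot(inherits(moments, "summary_moments"))
  keep <- logical(length(moments$snp_id))
  for (b in names(moments$block_index)) {
    jj <- moments$block_index[[b]]
    if (length(jj) == 1L) { keep[jj] <- TRUE; next }
    C <- moments$cov_blocks[[b]]
    R <- C / tcrossprod(sqrt(diag(C)))
    prio <- order(moments$pvalue[jj], moments$pos[jj])
    rank <- integer(length(jj))
    rank[prio] <- seq_along(jj)
    keep[jj] <- greedy_clump(R, rank, r2_max)
  }
  idx <- which(keep & moments$pvalue < p_max)
  cap <- min(cap, floor(moments$N / 4))
  if (length(idx) > cap)
    idx <- idx[order(moments$pvalue[idx])][seq_len(cap)]
  sort(idx)
}

#' Residual-variance estimate from summary moments
#'
#' Implements
#' \deqn{\tilde\sigma^2 = \frac{N}{N - q}\left[\widehat{(1/N) Y'Y} -
#'   \widehat{(1/N)X'Y}' \, \widehat{(1/N)X'X}^{-1} \,
#'   \widehat{(1/N)X'Y}\right]}
#' restricted to a pruned-and-thresholded SNP subset (the OLS basis of the
#' pseudo log-likelihood), blockwise with the regularized covariance.
#'
#' @param moments A `summary_moments` object.
#' @param subset Integer indices (into the moments SNP order) or SNP ids;
#'   default [sigma2_snp_subset()]. An empty subset gives
#'   `yty_per_n` (no regression reduction).
#' @param q Degrees of freedom; defaults to the subset size.
#' @return Positive scalar estimate of the residual variance.
#' @export
estimate_sigma2 <- function(moments, subset = NULL, q = NULL) {
  stopifnot(inherits(moments, "summary_moments"))
  if (is.null(subset)) subset <- sigma2_snp_subset(moments)
  if (is.character(subset)) subset <- match(subset, moments$snp_id)
  if (anyNA(subset)) stop("subset SNPs not found", call. = FALSE)
  if (is.null(q)) q <- length(subset)
  if (q >= moments$N)
    stop("subset degrees of freedom q must be < N", call. = FALSE)
  reduction <- 0
  if (length(subset)) {
    inset <- logical(length(moments$snp_id))
    inset[subset] <- TRUE
    for (b in names(moments$block_index)) {
      jj <- moments$block_index[[b]]
      sel <- jj[inset[jj]]
      if (!length(sel)) next
      pos_in_block <- match(sel, jj)
      C <- moments$cov_blocks[[b]][pos_in_block, pos_in_block, drop = FALSE]
      diag(C) <- diag(C) + moments$ridge
      v <- moments$xty_per_n[sel]
      reduction <- reduction + drop(crossprod(v, solve(C, v)))
    }
  }
  out <- moments$N / (moments$N - q) * (moments$yty_per_n - reduction)
  if (!is.finite(out) || out <= 0)
    stop(paste("nonpositive residual-variance estimate; increase the",
               "covariance regularization or shrink the SNP subset"),
         call. = FALSE)
  out
}

# Per-allele weights for the moments' SNPs from a prs_model (or pass-through
# for a named numeric vector already on the per-allele scale).
per_allele_for_moments <- function(model, moments, sd_y = NULL) {
  if (is.null(sd_y)) sd_y <- sqrt(moments$yty_per_n)
  if (inherits(model, "prs_model")) {
    b <- model$beta_std[moments$snp_id]
    if (anyNA(b)) stop("model does not cover the moments' SNPs",
                       call. = FALSE)
    b * sd_y / sqrt(moments$s2)
  } else {
    b <- model[moments$snp_id]
    if (anyNA(b)) stop("weights do not cover the moments' SNPs",
                       call. = FALSE)
    unname(b)
  }
}

#' Sum of squared errors of a PRS model from summary moments
#'
#' Implements
#' \deqn{\widehat{SSE} = N\left[\widehat{(1/N)Y'Y} -
#'   2\beta'\widehat{(1/N)X'Y} + \beta'\widehat{(1/N)X'X}\beta\right]}
#' blockwise, with `beta` the model on the per-allele scale (standardized
#' weights are converted internally using the summary-level phenotype SD
#' and the selection-panel SNP SDs).
#'
#' @param model A `prs_model`, or a named numeric vector of per-allele
#'   weights covering the moments' SNPs.
#' @param moments A `summary_moments` object.
#' @param sd_y Phenotype SD for the standardized-to-per-allele conversion;
#'   defaults to `sqrt(yty_per_n)`.
#' @return Non-negative SSE estimate.
#' @export
estimate_sse <- function(model, moments, sd_y = NULL) {
  stopifnot(inherits(moments, "summary_moments"))
  b <- per_allele_for_moments(model, moments, sd_y)
  quad <- 0
  for (bk in names(moments$block_index)) {
    jj <- moments$block_index[[bk]]
    bb <- b[jj]
    if (all(bb == 0)) next
    C <- moments$cov_blocks[[bk]]
    quad <- quad + drop(crossprod(bb, C %*% bb)) +
      moments$ridge * sum(bb^2)
  }
  sse <- moments$N *
    (moments$yty_per_n - 2 * sum(b * moments$xty_per_n) + quad)
  if (sse < 0 && sse > -1e-8 * moments$N) sse <- 0
  if (sse < 0) stop("negative SSE estimate", call. = FALSE)
  sse
}

#' Degrees of freedom of a fitted PRS model
#'
#' `mode = "nonzero"` counts nonzero weights (the LASSO df). `mode =
#' "ridge"` uses the ridge-regression trace
#' \eqn{tr[(R + \lambda s I)^{-1} R]} computed blockwise on the
#' selection-panel correlation matrix restricted to SNPs with nonzero
#' fitted weights (otherwise the trace would not depend on the model), with
#' \eqn{\lambda s} taken from the model's tuning parameters. A singular
#' block at \eqn{\lambda s = 0} falls back to the nonzero count with a
#' warning.
#'
#' @param model A `prs_model`.
#' @param moments A `summary_moments` object (supplies the panel
#'   correlation blocks).
#' @param mode `"nonzero"` or `"ridge"`.
#' @return Scalar degrees of freedom `k >= 0`.
#' @export
degrees_of_freedom <- function(model, moments, mode = c("nonzero", "ridge")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "prs_model"), inherits(moments, "summary_moments"))
  b <- model$beta_std[moments$snp_id]
  nz <- which(!is.na(b) & b != 0)
  if (mode == "nonzero" || !length(nz)) return(length(nz))
  lam_s <- model$penalty$lambda * model$penalty$s
  k <- 0
  active <- logical(length(b))
  active[nz] <- TRUE
  for (bk in names(moments$block_index)) {
    jj <- moments$block_index[[bk]]
    sel <- jj[active[jj]]
    if (!length(sel)) next
    pos_in_block <- match(sel, jj)
    C <- moments$cov_blocks[[bk]][pos_in_block, pos_in_block, drop = FALSE]
    R <- C / tcrossprod(sqrt(diag(C)))
    tr <- tryCatch(
      sum(diag(solve(R + diag(lam_s, nrow(R)), R))),
      error = function(e) NA_real_)
    if (is.na(tr)) {
      warning("singular block with lambda*s = 0; using nonzero count",
              call. = FALSE)
      tr <- length(sel)
    }
    k <- k + tr
  }
  k
}

#' Pseudo-AIC and pseudo-BIC for a set of candidate PRS models
#'
#' For each candidate, estimates the SSE from summary moments, forms the
#' pseudo log-likelihood \eqn{l = -\widehat{SSE} / (2 \tilde\sigma^2)} with
#' a residual variance \eqn{\tilde\sigma^2} estimated once and shared
#' across candidates, and reports
#' \deqn{AIC = 2k - 2l, \qquad BIC = \ln(N) k - 2l.}
#' The minimizer of each criterion is selected; ties break toward the
#' smaller degrees of freedom.
#'
#' @param models List of `prs_model` objects (NULL entries from failed grid
#'   points are skipped).
#' @param moments A `summary_moments` object from the selection half of the
#'   reference panel.
#' @param df_mode Degrees-of-freedom mode, see [degrees_of_freedom()].
#' @param sigma2 Optional precomputed residual variance.
#' @param sigma2_subset Optional SNP subset for [estimate_sigma2()].
#' @return An object of class `selection_report`: a per-model table
#'   (`sse`, `k`, `loglik`, `aic`, `bic`, `nonzero`), the shared `sigma2`,
#'   and the selected indices per criterion.
#' @export
pseudo_criteria <- function(models, moments,
                            df_mode = c("nonzero", "ridge"),
                            sigma2 = NULL, sigma2_subset = NULL) {
  df_mode <- match.arg(df_mode)
  stopifnot(inherits(moments, "summary_moments"))
  if (inherits(models, "prs_model")) models <- list(models)
  if (!length(models)) stop("no candidate models", call. = FALSE)
  if (is.null(sigma2))
    sigma2 <- estimate_sigma2(moments, subset = sigma2_subset)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (is.null(m)) return(NULL)
    sse <- estimate_sse(m, moments)
    k <- degrees_of_freedom(m, moments, mode = df_mode)
    l <- -sse / (2 * sigma2)
    data.frame(model = i, sse = sse, k = k, loglik = l,
               aic = 2 * k - 2 * l, bic = log(moments$N) * k - 2 * l,
               nonzero = sum(m$beta_std != 0))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("all candidate models failed", call. = FALSE)
  pick <- function(crit) tab$model[order(tab[[crit]], tab$k)][1]
  structure(list(table = tab, sigma2 = sigma2, df_mode = df_mode,
                 N = moments$N,
                 selected = list(aic = pick("aic"), bic = pick("bic"))),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report: %d candidates, sigma2 = %.4g, AIC-> model %d, BIC-> model %d>\n",
              nrow(x$table), x$sigma2, x$selected$aic, x$selected$bic))
  invisible(x)
}
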