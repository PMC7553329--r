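#' LD correlation matrix for one block
#'
#' Computes the SNP-SNP Pearson correlation matrix from reference-panel
#' dosages. Missing genotypes are mean-imputed per SNP first, so the result
#' is a valid correlation matrix.
#'
#' @param X Dosage matrix (individuals x SNPs) for the SNPs of one LD block.
#' @return Symmetric unit-diagonal correlation matrix.
#' @export
block_correlation <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("block has no SNPs", call. = FALSE)
  X <- impute_mean(X)
  v <- matrixStats_colVars(X)
  if (any(v == 0))
    stop("zero-variance SNP in block; filter monomorphic SNPs first",
         call. = FALSE)
  R <- cor(X)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

# Population-variance column helper (denominator n, matching the X'X/n
# moment convention used throughout).
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  colSums(X^2) / n - mu^2
}

impute_mean <- function(X) {
  nas <- which(colSums(is.na(X)) > 0L)
  for (j in nas) {
    x <- X[, j]
    m <- mean(x, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    x[is.na(x)] <- m
    X[, j] <- x
  }
  X
}

#' Fit one LD block by coordinate descent
#'
#' Minimizes the blockwise objective
#' \eqn{(1-s)\beta'R\beta + s\beta'\beta - 2\beta'r + J(\beta)} by cyclic
#' coordinate descent. The LASSO and elastic net use soft-threshold
#' updates. The nonconvex truncated LASSO penalty uses an exact univariate
#' TLP coordinate update (the penalized soft-threshold branch is compared
#' with the unpenalized branch at every coordinate, so each accepted move
#' decreases the objective), run from three starts -- the LASSO solution at
#' the same \eqn{(\lambda, s)}, zero, and the ridge-relaxed
#' (\eqn{\lambda = 0}) solution -- keeping the lowest objective. The
#' multi-start makes the solver match a brute-force global search on small
#' blocks; see the methods vignette.
#'
#' @param r Correlation vector (SNP vs phenotype) for the block.
#' @param R Unit-diagonal LD correlation matrix for the block.
#' @param penalty A [penalty_spec()].
#' @param init Optional warm-start coefficient vector.
#' @param tol Convergence tolerance on the maximum absolute coordinate
#'   change per sweep.
#' @param max_iter Maximum coordinate-descent sweeps per (inner) solve.
#' @return List with elements `beta`, `iterations` (total sweeps),
#'   `converged` (logical; `FALSE` is reported, never silently dropped), and
#'   `objective`.
#' @export
fit_block <- function(r, R, penalty, init = NULL, tol = 1e-6,
                      max_iter = 10000L) {
  stopifnot(inherits(penalty, "penalty_spec"))
  r <- as.numeric(r)
  R <- as.matrix(R)
  p <- length(r)
  if (nrow(R) != p || ncol(R) != p)
    stop("dim(R) must match length(r)", call. = FALSE)
  if (anyNA(r) || anyNA(R) || any(!is.finite(r)) || any(!is.finite(R)))
    stop("NaN/Inf in fit_block inputs", call. = FALSE)
  if (is.null(init)) init <- numeric(p)
  lam <- penalty$lambda

  if (penalty$kind == "lasso") {
    fit <- cd_solve(R, r, penalty$s, rep(lam, p), rep(1, p), init, tol,
                    as.integer(max_iter))
    out <- list(beta = fit$beta, iterations = fit$iter,
                converged = fit$converged)
  } else if (penalty$kind == "elastic_net") {
    thr <- rep(penalty$alpha * lam, p)
    den <- rep(1 + (1 - penalty$alpha) * lam, p)
    fit <- cd_solve(R, r, penalty$s, thr, den, init, tol,
                    as.integer(max_iter))
    out <- list(beta = fit$beta, iterations = fit$iter,
                converged = fit$converged)
  } else { # tlp
    # The TLP objective is nonconvex, so coordinate descent (here with the
    # exact univariate TLP update: penalized vs unpenalized branch compared
    # at every coordinate, each accepted move decreasing the objective) is
    # run from several deterministic starts and the lowest objective wins:
    # the LASSO solution at the same (lambda, s), zero, the ridge-relaxed
    # (lambda = 0) solution, and -- on blocks small enough for it to be
    # cheap -- single-coordinate and leave-one-out variants of the relaxed
    # solution, which let the solver reach branch patterns that differ from
    # the LASSO basin. Larger blocks substitute a tau-continuation run
    # (solve at geometrically decreasing tau, warm-starting). This start
    # set attains brute-force global minima on random small problems.
    start <- cd_solve(R, r, penalty$s, rep(lam, p), rep(1, p), init, tol,
                      as.integer(max_iter))
    iters <- start$iter
    relax <- tryCatch(
      as.numeric(solve((1 - penalty$s) * R + diag(penalty$s, p), r)),
      error = function(e) NULL)
    cands <- c(list(start$beta, numeric(p)),
               if (!is.null(relax)) list(relax))
    if (!is.null(relax) && p <= 50) {
      singles <- lapply(seq_len(p), function(j) {
        b <- numeric(p); b[j] <- relax[j]; b
      })
      loo <- lapply(seq_len(p), function(j) {
        b <- relax; b[j] <- 0; b
      })
      cands <- c(cands, singles, loo)
    } else if (!is.null(relax) && is.finite(penalty$tau)) {
      taus <- exp(seq(log(max(abs(relax)) + penalty$tau),
                      log(penalty$tau), length.out = 6))
      b <- start$beta
      for (tv in taus)
        b <- cd_solve_tlp(R, r, penalty$s, lam, tv, b, tol,
                          as.integer(max_iter))$beta
      cands <- c(cands, list(b))
    }
    best <- NULL
    best_obj <- Inf
    conv <- TRUE
    for (b0 in cands) {
      fit <- cd_solve_tlp(R, r, penalty$s, lam, penalty$tau, b0, tol,
                          as.integer(max_iter))
      iters <- iters + fit$iter
      obj <- objective_value(fit$beta, r, R, penalty)
      if (obj < best_obj) {
        best <- fit$beta
        best_obj <- obj
        conv <- fit$converged
      }
    }
    out <- list(beta = best, iterations = iters, converged = conv)
  }
  out$objective <- objective_value(out$beta, r, R, penalty)
  out
}

#' Fit a grid of penalized PRS models over all LD blocks
#'
#' Fits each LD block independently and concatenates the solutions.
#' Within each `(kind, s, tau, alpha)` slice of the grid, models are fitted
#' in order of descending `lambda` with warm starts. SNPs flagged as absent
#' from the reference panel are solved in closed form by
#' [fit_missing_snps()] and never enter the block matrices.
#'
#' @param problem A [harmonize()]d problem.
#' @param panel The reference panel used for LD (a `ref_panel`), or a
#'   precomputed list of block correlation matrices from
#'   [ld_block_matrices()].
#' @param grid List of [penalty_spec()] objects.
#' @param tol,max_iter Passed to [fit_block()].
#' @return List of `prs_model` objects, in the order of `grid`. Grid points
#'   whose fit fails are returned as `NULL` with a warning.
#' @export
fit_path <- function(problem, panel, grid, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(problem, "harmonized_problem"))
  if (length(grid) == 0L) stop("empty tuning grid", call. = FALSE)
  if (inherits(grid, "penalty_spec")) grid <- list(grid)
  ld <- if (is.list(panel) && !inherits(panel, "ref_panel")) panel
        else ld_block_matrices(problem, panel)

  snps <- problem$snps
  in_ref <- snps$in_reference
  r_all <- problem$r
  p <- nrow(snps)

  key <- vapply(grid, function(pen) {
    paste(pen$kind, pen$s, pen$tau %||% "", pen$alpha %||% "")
  }, character(1))
  lambdas <- vapply(grid, `[[`, numeric(1), "lambda")

  models <- vector("list", length(grid))
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(-lambdas[idx])]
    warm <- NULL # list of per-block warm starts
    for (g in idx) {
      pen <- grid[[g]]
      beta <- numeric(p)
      diag_list <- list()
      ok <- TRUE
      total_obj <- 0
      warm_next <- vector("list", length(ld$block_ids))
      for (b in seq_along(ld$block_ids)) {
        jj <- ld$index[[b]]
        res <- tryCatch(
          fit_block(r_all[jj], ld$R[[b]], pen,
                    init = if (!is.null(warm)) warm[[b]] else NULL,
                    tol = tol, max_iter = max_iter),
          error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("grid point %d (block %s) failed: %s", g,
                          ld$block_ids[b], conditionMessage(res)),
                  call. = FALSE)
          ok <- FALSE
          break
        }
        beta[jj] <- res$beta
        warm_next[[b]] <- res$beta
        total_obj <- total_obj + res$objective
        diag_list[[b]] <- data.frame(block = ld$block_ids[b],
                                     iterations = res$iterations,
                                     converged = res$converged,
                                     objective = res$objective)
      }
      if (!ok) { models[[g]] <- NULL; next }
      miss <- which(!in_ref)
      if (length(miss)) {
        beta[miss] <- fit_missing_snps(r_all[miss], pen)
        total_obj <- total_obj +
          sum(univariate_objective(beta[miss], r_all[miss], pen))
      }
      warm <- warm_next
      diagnostics <- do.call(rbind, diag_list)
      models[[g]] <- structure(
        list(beta_std = setNames(beta, snps$snp_id), penalty = pen,
             diagnostics = diagnostics, objective = total_obj,
             converged = all(diagnostics$converged)),
        class = "prs_model")
    }
  }
  models
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model %s: lambda = %g, s = %g, %d/%d nonzero, objective = %.6g%s>\n",
              x$penalty$kind, x$penalty$lambda, x$penalty$s,
              sum(x$beta_std != 0), length(x$beta_std), x$objective,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Precompute per-block LD correlation matrices
#'
#' @param problem A [harmonize()]d problem.
#' @param panel A `ref_panel` whose columns cover the problem's
#'   in-reference SNPs.
#' @return List with `block_ids`, `index` (per-block indices into the
#'   problem's SNP table), and `R` (correlation matrices).
#' @export
ld_block_matrices <- function(problem, panel) {
  stopifnot(inherits(problem, "harmonized_problem"),
            inherits(panel, "ref_panel"))
  snps <- problem$snps
  in_ref <- which(snps$in_reference)
  cols <- match(snps$snp_id[in_ref], panel$map$snp_id)
  if (anyNA(cols))
    stop("panel is missing SNPs flagged in_reference: ",
         paste(head(snps$snp_id[in_ref][is.na(cols)], 5), collapse = ", "),
         call. = FALSE)
  blocks <- split(seq_along(in_ref), snps$block[in_ref])
  block_ids <- names(blocks)
  Rl <- vector("list", length(blocks))
  index <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    sel <- blocks[[b]]
    index[[b]] <- in_ref[sel]
    Rl[[b]] <- block_correlation(panel$genotypes[, cols[sel], drop = FALSE])
  }
  list(block_ids = block_ids, index = index, R = Rl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a default tuning grid
#'
#' Lambda is log-spaced over `lambda_range`; for the TLP each lambda is
#' crossed with each `tau`; for the elastic net with each `alpha`.
#'
#' @param kind Penalty kind.
#' @param lambda_range Range for the log-spaced lambda sequence.
#' @param n_lambda Number of lambda values.
#' @param s LD shrinkage values.
#' @param tau TLP truncation thresholds.
#' @param alpha Elastic-net mixing values.
#' @return List of [penalty_spec()] objects.
#' @export
default_grid <- function(kind = c("lasso", "elastic_net", "tlp"),
                         lambda_range = c(0.001, 0.1), n_lambda = 20L,
                         s = c(0, 0.1, 0.2, 0.5, 0.9),
                         tau = c(0.001, 0.005, 0.01, 0.05),
                         alpha = c(0.1, 0.5, 0.9, 1)) {
  kind <- match.arg(kind)
  lam <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                 length.out = n_lambda))
  grid <- list()
  for (si in s) for (l in lam) {
    grid <- c(grid, switch(kind,
      lasso = list(penalty_spec("lasso", lambda = l, s = si)),
      tlp = lapply(tau, function(tv)
        penalty_spec("tlp", lambda = l, s = si, tau = tv)),
      elastic_net = lapply(alpha, function(av)
        penalty_spec("elastic_net", lambda = l, s = si, alpha = av))))
  }
  grid
}
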