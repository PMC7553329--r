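#' End-to-end demonstration workflow
#'
#' Runs the full summary-statistic PRS workflow on simulated data: a
#' four-cohort study is generated, marginal summary statistics are computed
#' from the training cohort, LASSO and TLP grids are fitted with the
#' tuning-1 cohort as the LD reference, candidate models are selected by
#' tuning-cohort r-squared, pseudo-AIC, pseudo-BIC (tuning-2 cohort as the
#' selection panel), and quasi-correlation (tuning-2 summary statistics),
#' and every selected model is evaluated by its true predictive r-squared
#' on the held-out testing cohort.
#'
#' @param seed Integer seed; the entire run is deterministic given it.
#' @param cfg A [sim_config()]; the default is a reduced-size study
#'   (M = 500 SNPs, cohort sizes scaled to one quarter) that runs in
#'   seconds.
#' @param grids Optional named list of penalty grids (default: small LASSO
#'   and TLP grids).
#' @param outdir Optional directory; when given, the comparison table
#'   (CSV), the selected weights (TSV), and a JSON manifest are written.
#' @param dry_run Print the plan and return without computing.
#' @return Invisibly, a list with the comparison `table` (one row per
#'   selection criterion: selected model index, nonzero count, test
#'   r-squared, quasi-correlation on testing summary statistics) and the
#'   fitted `models`.
#' @export
run_demo <- function(seed = 1L, cfg = NULL, grids = NULL, outdir = NULL,
                     dry_run = FALSE) {
  if (is.null(cfg))
    cfg <- sim_config(n_snps = 500, scale = 0.25, p_causal = 0.01,
                      h2 = 0.5, seed = seed)
  if (is.null(grids)) {
    lam <- exp(seq(log(0.002), log(0.08), length.out = 8))
    grids <- list(
      lasso = lapply(lam, function(l) penalty_spec("lasso", l, s = 0.1)),
      tlp = unlist(lapply(lam, function(l)
        lapply(c(0.005, 0.02), function(tv)
          penalty_spec("tlp", l, s = 0.1, tau = tv))), recursive = FALSE))
  }
  if (dry_run) {
    cat(sprintf(paste0(
      "plan: simulate M=%d SNPs, cohorts %d/%d/%d/%d (seed %d);\n",
      "      fit %d lasso + %d tlp grid points on tuning-1 LD;\n",
      "      select by tuning r2, pseudo-AIC, pseudo-BIC, quasi-correlation;\n",
      "      evaluate test r2. No files written.\n"),
      cfg$n_snps, cfg$n_train, cfg$n_tune1, cfg$n_tune2, cfg$n_test,
      cfg$seed, length(grids$lasso), length(grids$tlp)))
    return(invisible(NULL))
  }
  study <- simulate_study(cfg)
  panel_fit <- ref_panel(study$tune1$X, study$map)
  panel_sel <- ref_panel(study$tune2$X, study$map)
  problem <- harmonize(study$sumstats, panel_fit, study$blocks)
  models <- c(fit_path(problem, panel_fit, grids$lasso),
              fit_path(problem, panel_fit, grids$tlp))

  tune_r2 <- vapply(models, function(m) {
    if (is.null(m) || all(m$beta_std == 0)) return(0)
    scores <- predict_prs(m$beta_std[problem$snps$snp_id],
                          ref_panel(study$tune1$X, study$map))
    if (sd(scores) == 0) 0 else cor(scores, study$tune1$y)^2
  }, numeric(1))

  moments <- estimate_moments(problem, panel_sel)
  report <- pseudo_criteria(models, moments)
  tune2_ss <- compute_gwas(study$tune2$X, study$tune2$y, study$map)
  qsel <- select_by_quasicor(models, problem, tune2_ss, panel_sel)

  test_ss <- compute_gwas(study$test$X, study$test$y, study$map)
  panel_test <- ref_panel(study$test$X, study$map)
  eval_model <- function(i) {
    m <- models[[i]]
    scores <- predict_prs(m$beta_std[problem$snps$snp_id],
                          ref_panel(study$test$X, study$map))
    r2 <- if (sd(scores) == 0) 0 else cor(scores, study$test$y)^2
    qc <- tryCatch(quasi_correlation(m, problem, test_ss, panel_test),
                   error = function(e) NA_real_)
    c(test_r2 = r2, test_qcor = qc)
  }
  chosen <- c(tune_r2 = which.max(tune_r2), pseudo_aic = report$selected$aic,
              pseudo_bic = report$selected$bic, quasi_cor = qsel$index)
  perf <- t(vapply(chosen, eval_model, numeric(2)))
  tab <- data.frame(criterion = names(chosen), model = unname(chosen),
                    nonzero = vapply(chosen, function(i)
                      sum(models[[i]]$beta_std != 0), numeric(1)),
                    test_r2 = perf[, "test_r2"],
                    test_qcor = perf[, "test_qcor"],
                    row.names = NULL)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(tab, file.path(outdir, "selection_comparison.csv"))
    best <- rescale_to_per_allele(models[[chosen[["quasi_cor"]]]], problem)
    data.table::fwrite(best, file.path(outdir, "selected_weights.tsv"),
                       sep = "\t")
    manifest <- list(seed = seed,
                     config = unclass(cfg),
                     n_models = length(models),
                     sigma2 = report$sigma2,
                     selected = as.list(chosen),
                     package_version =
                       as.character(utils::packageVersion("sumprs")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(table = tab, models = models, report = report,
                 problem = problem))
}
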