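# Small random reference panel with a metadata map.
tiny_panel <- function(n = 50, p = 6, seed = 1, chrom = "1",
                       pos = 100L * seq_len(p)) {
  set.seed(seed)
  maf <- runif(p, 0.1, 0.5)
  X <- sapply(maf, function(f) rbinom(n, 2, f))
  map <- data.frame(chrom = chrom, snp_id = sprintf("rs%03d", seq_len(p)),
                    pos = pos, a1 = rep_len(c("A", "C"), p),
                    a2 = rep_len(c("G", "T"), p), stringsAsFactors = FALSE)
  ref_panel(X, map)
}

# Marginal summary statistics computed with the population (1/n) variance
# conventions of the moment identities: beta_j = x_j'y / (n s_j^2) and
# var(beta_j) = sum((y - x_j beta_j)^2) / (n^2 s_j^2), both on centered
# data. Under these conventions the summary-level moment estimates recover
# Y'Y, X'Y exactly, which the exact-recovery tests rely on.
exact_sumstats <- function(X, y, map) {
  X <- as.matrix(X)
  n <- nrow(X)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  s2 <- colSums(Xc^2) / n
  beta <- drop(crossprod(Xc, yc)) / (n * s2)
  rss <- colSums((matrix(yc, n, ncol(X)) - sweep(Xc, 2, beta, "*"))^2)
  se <- sqrt(rss / (n^2 * s2))
  sumstats(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
           a1 = map$a1, a2 = map$a2, beta = beta, se = se, n = n)
}

# Hand-assembled PRS model (standardized weights) for selection tests.
fake_model <- function(beta_std, snp_ids,
                       penalty = penalty_spec("lasso", 0.05, 0.2)) {
  structure(list(beta_std = setNames(beta_std, snp_ids), penalty = penalty,
                 diagnostics = NULL, objective = NA_real_,
                 converged = TRUE),
            class = "prs_model")
}

# Quick harmonized problem from a simulated study cohort.
quick_problem <- function(study, panel = NULL) {
  if (is.null(panel)) panel <- ref_panel(study$tune1$X, study$map)
  harmonize(study$sumstats, panel, study$blocks)
}
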