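# Individual-level fixture in a single LD block, with summary statistics on
# the population-variance convention so the moment identities are exact.
exact_fixture <- function(n = 300, p = 8, seed = 101, h2 = 0.4) {
  cfg <- sim_config(n_snps = p, block_sizes = as.integer(p),
                    within_block_rho = 0.4, seed = seed)
  set.seed(seed)
  mafs <- runif(p, 0.15, 0.45)
  X <- simulate_genotypes(cfg, n, mafs = mafs)
  beta <- numeric(p)
  beta[1] <- 0.5
  if (p >= 4) beta[4] <- -0.4
  ph <- simulate_phenotype(X, beta, h2 = h2)
  map <- data.frame(chrom = "1", snp_id = sprintf("s%02d", 1:p),
                    pos = 100L * (1:p), a1 = "A", a2 = "G")
  ss <- exact_sumstats(X, ph$y, map)
  panel <- ref_panel(X, map)
  problem <- harmonize(ss, panel, maf_min = 0.01, ld_clump_r2 = 1)
  list(X = X, y = ph$y, map = map, ss = ss, panel = panel,
       problem = problem)
}

test_that("split halves are disjoint, seeded, and guard against reuse", {
  panel <- tiny_panel(n = 100, p = 4, seed = 7)
  rownames(panel$genotypes) <- paste0("ind", 1:100)
  sp <- split_reference_panel(panel, seed = 3)
  expect_equal(sp$fit$n_ref, 50)
  expect_equal(sp$select$n_ref, 50)
  ids <- c(rownames(sp$fit$genotypes), rownames(sp$select$genotypes))
  expect_setequal(ids, rownames(panel$genotypes))
  expect_equal(anyDuplicated(ids), 0)
  sp2 <- split_reference_panel(panel, seed = 3)
  expect_identical(sp$fit$genotypes, sp2$fit$genotypes)

  fx <- exact_fixture()
  expect_error(estimate_moments(fx$problem, sp$fit), "fitting half")
  expect_error(split_reference_panel(tiny_panel(n = 3, p = 2), 1),
               "at least 4")
})

test_that("null-SNP algebra: a zero-effect SNP recovers the phenotype variance", {
  # single SNP with beta = 0, var(beta) = 1/N, s^2 = 1 -> yty_per_n = 1
  map <- data.frame(chrom = "1", snp_id = "s1", pos = 100L, a1 = "A",
                    a2 = "G")
  N <- 400
  ss <- sumstats(snp_id = "s1", chrom = "1", pos = 100L, a1 = "A",
                 a2 = "G", beta = 0, se = sqrt(1 / N), n = N)
  set.seed(8)
  x <- rbinom(200, 2, 0.5)
  panel <- ref_panel(matrix(x, ncol = 1), map)
  prob <- harmonize(ss, panel, maf_min = 0.0001, ld_clump_r2 = 1)
  mom <- estimate_moments(prob, panel, ridge = 0)
  # yty = N s^2 (1/N) + s^2 * 0 = s^2 (equals 1 when the SNP has unit SD)
  expect_equal(mom$yty_per_n, mom$s2[[1]], tolerance = 1e-12)
  expect_equal(unname(mom$xty_per_n), 0)
})

test_that("yty estimate tracks the empirical phenotype variance", {
  study <- simulate_study(sim_config(n_snps = 200, scale = 0.5,
                                     p_causal = 0.05, seed = 33))
  panel <- ref_panel(study$tune1$X, study$map)
  prob <- harmonize(study$sumstats, panel, study$blocks)
  mom <- estimate_moments(prob, ref_panel(study$tune2$X, study$map))
  expect_equal(mom$yty_per_n, var(study$train$y), tolerance = 0.05 * var(study$train$y))
})

test_that("xty estimate matches the individual-level cross-moment", {
  fx <- exact_fixture(n = 4000, seed = 37)
  mom <- estimate_moments(fx$problem, fx$panel, ridge = 0)
  Xc <- sweep(fx$X, 2, colMeans(fx$X))
  yc <- fx$y - mean(fx$y)
  truth <- drop(crossprod(Xc, yc)) / nrow(fx$X)
  expect_equal(unname(mom$xty_per_n), truth, tolerance = 0.02)
})

test_that("exact-recovery limit: SSE and sigma2 match individual-level values", {
  fx <- exact_fixture(n = 500, p = 8, seed = 41)
  mom <- estimate_moments(fx$problem, fx$panel, ridge = 0)
  Xc <- sweep(fx$X, 2, colMeans(fx$X))
  yc <- fx$y - mean(fx$y)

  # arbitrary per-allele weights
  set.seed(42)
  w <- setNames(rnorm(8, 0, 0.1), fx$map$snp_id)
  sse_hat <- estimate_sse(w, mom)
  sse_true <- sum((yc - drop(Xc %*% w))^2)
  expect_equal(sse_hat, sse_true, tolerance = 1e-6)

  # zero model: SSE = N * yty
  w0 <- setNames(numeric(8), fx$map$snp_id)
  expect_equal(estimate_sse(w0, mom), mom$N * mom$yty_per_n)

  # sigma2 on a subset equals the OLS mean squared error with df = q
  sub <- c(1L, 4L, 6L)
  s2_hat <- estimate_sigma2(mom, subset = sub)
  ols <- lm(yc ~ Xc[, sub] - 1)
  mse <- sum(ols$residuals^2) / (length(yc) - 3)
  expect_equal(s2_hat, mse, tolerance = 1e-6)
})

test_that("sigma2 limits: empty subset and null trait", {
  fx <- exact_fixture(n = 500, seed = 43)
  mom <- estimate_moments(fx$problem, fx$panel, ridge = 0)
  expect_equal(estimate_sigma2(mom, subset = integer(0)), mom$yty_per_n)

  # null trait: sigma2 ~= var(y)
  set.seed(44)
  cfg <- sim_config(n_snps = 20, block_sizes = 20L, seed = 44)
  X <- simulate_genotypes(cfg, 800, mafs = runif(20, 0.2, 0.5))
  y <- rnorm(800)
  map <- data.frame(chrom = "1", snp_id = sprintf("n%02d", 1:20),
                    pos = 100L * (1:20), a1 = "A", a2 = "G")
  ss <- exact_sumstats(X, y, map)
  panel <- ref_panel(X, map)
  prob <- harmonize(ss, panel, maf_min = 0.01, ld_clump_r2 = 1)
  mom2 <- estimate_moments(prob, panel, ridge = 0)
  s2 <- estimate_sigma2(mom2)
  vy <- mean(y^2) - mean(y)^2
  expect_lt(abs(s2 - vy) / vy, 0.1)
  expect_error(estimate_sigma2(mom2, subset = 1:20, q = mom2$N), "q")
})

test_that("sigma2 brackets the residual variance on heritable traits", {
  hits <- 0
  for (seed in 1:8) {
    study <- simulate_study(sim_config(n_snps = 150, scale = 0.4,
                                       p_causal = 0.05, h2 = 0.5,
                                       seed = seed))
    panel <- ref_panel(study$tune1$X, study$map)
    prob <- harmonize(study$sumstats, panel, study$blocks)
    mom <- estimate_moments(prob, ref_panel(study$tune2$X, study$map))
    s2 <- estimate_sigma2(mom)
    vy <- var(study$train$y)
    if (s2 > 0.4 * vy && s2 < 0.8 * vy) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("ridge degrees of freedom match the eigenvalue oracle and limits", {
  fx <- exact_fixture(n = 400, p = 3, seed = 47)
  mom <- estimate_moments(fx$problem, fx$panel, ridge = 0)
  ids <- fx$map$snp_id
  m_all <- fake_model(c(0.1, 0.2, -0.1), ids,
                      penalty_spec("lasso", lambda = 1, s = 0.5))
  C <- mom$cov_blocks[[1]]
  R <- C / tcrossprod(sqrt(diag(C)))
  d <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(degrees_of_freedom(m_all, mom, mode = "ridge"),
               sum(d / (d + 0.5)), tolerance = 1e-10)
  # lambda*s = 0 on a full-rank block: df equals the number of SNPs
  m0 <- fake_model(c(0.1, 0.2, -0.1), ids, penalty_spec("lasso", 0, 0))
  expect_equal(degrees_of_freedom(m0, mom, mode = "ridge"), 3,
               tolerance = 1e-8)
  # huge lambda*s: df -> 0
  mb <- fake_model(c(0.1, 0.2, -0.1), ids,
                   penalty_spec("lasso", 1e8, s = 1))
  expect_lt(degrees_of_freedom(mb, mom, mode = "ridge"), 1e-4)
  # nonzero mode counts, restricted to nonzero weights
  m_sparse <- fake_model(c(0.1, 0, 0), ids, penalty_spec("lasso", 1, 0.5))
  expect_equal(degrees_of_freedom(m_sparse, mom, mode = "nonzero"), 1)
  expect_equal(degrees_of_freedom(m_sparse, mom, mode = "ridge"), 1 / 1.5,
               tolerance = 1e-10)
})

test_that("criteria identity and tie-breaking toward smaller k", {
  fx <- exact_fixture(n = 500, seed = 53)
  mom <- estimate_moments(fx$problem, fx$panel)
  ids <- fx$map$snp_id
  b5 <- c(rep(0.05, 5), numeric(3))
  b10 <- b5 + c(numeric(5), rep(1e-10, 3)) # same SSE to numerical noise
  models <- list(fake_model(b10, ids), fake_model(b5, ids))
  rep_ <- pseudo_criteria(models, mom)
  expect_equal(rep_$table$bic - rep_$table$aic,
               (log(mom$N) - 2) * rep_$table$k, tolerance = 1e-10)
  expect_equal(rep_$selected$aic, 2)
  expect_equal(rep_$selected$bic, 2)
  # single candidate is selected trivially
  rep1 <- pseudo_criteria(models[2], mom)
  expect_equal(rep1$selected$aic, 1)
})

test_that("adding pure-noise SNPs does not decrease pseudo-BIC on average", {
  deltas <- numeric(10)
  for (seed in 1:10) {
    fx <- exact_fixture(n = 400, p = 8, seed = 200 + seed)
    mom <- estimate_moments(fx$problem, fx$panel)
    ids <- fx$map$snp_id
    base <- fake_model(c(0.2, 0, 0, -0.15, numeric(4)), ids)
    set.seed(300 + seed)
    noise <- c(numeric(4), rnorm(4, 0, 0.01))
    aug <- fake_model(base$beta_std + noise, ids)
    r <- pseudo_criteria(list(base, aug), mom)
    deltas[seed] <- r$table$bic[2] - r$table$bic[1]
  }
  expect_gt(mean(deltas), 0)
})

test_that("binary-trait summary statistics are refused before conversion", {
  fx <- exact_fixture()
  prob <- fx$problem
  prob$is_binary_trait <- TRUE
  expect_error(estimate_moments(prob, fx$panel), "convert")
})
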