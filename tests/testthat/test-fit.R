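test_that("identity-LD (s = 1) lasso is the exact soft threshold of r", {
  R <- diag(2)
  fit <- fit_block(c(0.5, -0.1), R, penalty_spec("lasso", 0.2, s = 1))
  expect_equal(fit$beta, c(0.3, 0), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("penalty degeneracies: tlp(tau=Inf) and enet(alpha=1) equal lasso", {
  set.seed(11)
  for (i in 1:5) {
    p <- sample(2:5, 1)
    R <- random_correlation(p)
    r <- runif(p, -0.5, 0.5)
    lam <- runif(1, 0.02, 0.2)
    s <- runif(1, 0.1, 0.9)
    b_lasso <- fit_block(r, R, penalty_spec("lasso", lam, s))$beta
    b_tlp <- fit_block(r, R, penalty_spec("tlp", lam, s, tau = Inf))$beta
    b_en <- fit_block(r, R, penalty_spec("elastic_net", lam, s,
                                         alpha = 1))$beta
    expect_equal(b_tlp, b_lasso, tolerance = 1e-5)
    expect_equal(b_en, b_lasso, tolerance = 1e-5)
  }
})

test_that("lambda = 0 with s > 0 matches the ridge closed form", {
  set.seed(12)
  for (s in c(0.1, 0.5)) {
    p <- 4
    R <- random_correlation(p)
    r <- runif(p, -0.5, 0.5)
    closed <- solve((1 - s) * R + diag(s, p), r)
    for (kind in c("lasso", "elastic_net", "tlp")) {
      pen <- switch(kind,
        lasso = penalty_spec("lasso", 0, s),
        elastic_net = penalty_spec("elastic_net", 0, s, alpha = 0.5),
        tlp = penalty_spec("tlp", 0, s, tau = 0.1))
      fit <- fit_block(r, R, pen, tol = 1e-10)
      expect_equal(fit$beta, as.numeric(closed), tolerance = 1e-8)
    }
  }
})

test_that("coordinate descent attains brute-force minima on small blocks", {
  set.seed(21)
  for (i in 1:12) {
    p <- sample(1:4, 1)
    R <- random_correlation(p)
    r <- runif(p, -0.5, 0.5)
    lam <- runif(1, 0.02, 0.3)
    s <- runif(1, 0.05, 0.9)
    pens <- list(penalty_spec("lasso", lam, s),
                 penalty_spec("elastic_net", lam, s,
                              alpha = runif(1, 0.2, 1)),
                 penalty_spec("tlp", lam, s, tau = runif(1, 0.02, 0.4)))
    for (pen in pens) {
      fit <- fit_block(r, R, pen)
      bf <- brute_force_min(r, R, pen)
      expect_lte(fit$objective, bf$objective + 1e-6)
    }
  }
})

test_that("solutions never increase the objective relative to simpler points", {
  set.seed(31)
  p <- 6
  R <- random_correlation(p)
  r <- runif(p, -0.5, 0.5)
  for (pen in list(penalty_spec("lasso", 0.05, 0.2),
                   penalty_spec("tlp", 0.05, 0.2, tau = 0.08))) {
    fit <- fit_block(r, R, pen)
    expect_lte(fit$objective, objective_value(numeric(p), r, R, pen))
    expect_lte(fit$objective,
               objective_value(fit_missing_snps(r, pen), r, R, pen) + 1e-9)
  }
})

test_that("fit_block rejects malformed inputs", {
  expect_error(fit_block(c(0.1, NA), diag(2), penalty_spec("lasso", 0.1)),
               "NaN")
  expect_error(fit_block(c(0.1, 0.2), diag(3), penalty_spec("lasso", 0.1)),
               "dim")
})

test_that("block_correlation matches the library correlation", {
  set.seed(5)
  X <- matrix(rbinom(200 * 4, 2, 0.3), 200, 4)
  expect_equal(block_correlation(X), cor(X), tolerance = 1e-12)
  expect_equal(block_correlation(matrix(c(0, 1, 2, 1), 4, 1)),
               matrix(1, 1, 1))
  X2 <- cbind(X[, 1], X[, 1])
  expect_equal(block_correlation(X2)[1, 2], 1)
  expect_error(block_correlation(matrix(1, 5, 1)), "variance")
})

test_that("fit_path: null condition, separability, and missing SNPs", {
  study <- simulate_study(sim_config(n_snps = 60, scale = 0.05, p_causal = 0.1,
                                     block_sizes = rep(15L, 4), seed = 9))
  panel <- ref_panel(study$tune1$X, study$map)
  problem <- harmonize(study$sumstats, panel, study$blocks)

  # grid of one -> list of one
  m1 <- fit_path(problem, panel, list(penalty_spec("lasso", 0.05, 0.2)))
  expect_length(m1, 1)
  expect_s3_class(m1[[1]], "prs_model")

  # lambda above max |r| -> all-zero model (KKT null condition)
  lam_big <- max(abs(problem$r)) * 1.01
  m0 <- fit_path(problem, panel,
                 list(penalty_spec("lasso", lam_big, 0.3)))[[1]]
  expect_true(all(m0$beta_std == 0))

  # block separability: whole-problem fit equals per-block fits
  pen <- penalty_spec("lasso", 0.02, 0.1)
  mfull <- fit_path(problem, panel, list(pen))[[1]]
  ld <- ld_block_matrices(problem, panel)
  for (b in seq_along(ld$block_ids)) {
    jj <- ld$index[[b]]
    sep <- fit_block(problem$r[jj], ld$R[[b]], pen)
    expect_equal(unname(mfull$beta_std[jj]), sep$beta, tolerance = 1e-8)
  }

  # SNPs absent from the panel get the univariate closed form
  ss2 <- study$sumstats
  extra <- sumstats(snp_id = "rs_extra", chrom = "2", pos = 50L, a1 = "A",
                    a2 = "G", beta = 0.4, se = 0.05, n = 300)
  ss_aug <- rbind(as.data.frame(ss2), as.data.frame(extra))
  class(ss_aug) <- class(ss2)
  attr(ss_aug, "is_binary_trait") <- FALSE
  prob2 <- harmonize(ss_aug, panel, study$blocks)
  expect_false(all(prob2$snps$in_reference))
  m2 <- fit_path(prob2, panel, list(pen))[[1]]
  miss <- which(!prob2$snps$in_reference)
  expect_equal(unname(m2$beta_std[miss]),
               unname(fit_missing_snps(prob2$r[miss], pen)))
})

test_that("warm starts along the lambda path do not change the solutions", {
  study <- simulate_study(sim_config(n_snps = 50, scale = 0.05, p_causal = 0.1,
                                     block_sizes = rep(25L, 2), seed = 13))
  panel <- ref_panel(study$tune1$X, study$map)
  problem <- harmonize(study$sumstats, panel, study$blocks)
  lams <- c(0.1, 0.05, 0.02, 0.01)
  grid <- lapply(lams, function(l) penalty_spec("lasso", l, 0.2))
  path <- fit_path(problem, panel, grid)
  for (i in seq_along(lams)) {
    solo <- fit_path(problem, panel, grid[i])[[1]]
    expect_equal(path[[i]]$beta_std, solo$beta_std, tolerance = 1e-5)
  }
})
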