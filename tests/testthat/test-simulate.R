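test_that("seeded simulation is deterministic", {
  cfg <- sim_config(n_snps = 40, scale = 0.02, p_causal = 0.1, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$train$X, s2$train$X)
  expect_identical(s1$train$y, s2$train$y)
  expect_identical(s1$truth$beta, s2$truth$beta)
})

test_that("rho = 0 gives essentially independent SNPs", {
  cfg <- sim_config(n_snps = 30, within_block_rho = 0, seed = 5)
  set.seed(5)
  X <- simulate_genotypes(cfg, 2000)
  R <- cor(X)
  offdiag <- abs(R[upper.tri(R)])
  expect_lt(mean(offdiag), 3 / sqrt(2000))
})

test_that("adjacent-SNP dosage correlation matches a large-n Monte-Carlo oracle", {
  cfg <- sim_config(n_snps = 2, block_sizes = 2L, within_block_rho = 0.9,
                    maf_range = c(0.3, 0.3), seed = 8)
  # Monte-Carlo oracle at n = 200000: the dosage correlation induced by
  # thresholding latent AR(1) normals, computed from an independent draw.
  set.seed(1008)
  Xbig <- simulate_genotypes(cfg, 200000, mafs = c(0.3, 0.3))
  rho_oracle <- cor(Xbig[, 1], Xbig[, 2])
  set.seed(9)
  X <- simulate_genotypes(cfg, 5000, mafs = c(0.3, 0.3))
  expect_equal(cor(X[, 1], X[, 2]), rho_oracle, tolerance = 0.05)
  # thresholding attenuates the latent correlation
  expect_lt(rho_oracle, 0.9)
  expect_gt(rho_oracle, 0.6)
})

test_that("dosages respect Hardy-Weinberg frequencies at the target MAF", {
  cfg <- sim_config(n_snps = 1, block_sizes = 1L, seed = 10)
  set.seed(10)
  X <- simulate_genotypes(cfg, 50000, mafs = 0.2)
  expect_lt(abs(mean(X) / 2 - 0.2), 0.005)
  expect_lt(abs(mean(X == 2) - 0.04), 0.005)
})

test_that("point-normal effects have the exact causal count and variance", {
  cfg <- sim_config(n_snps = 30000, p_causal = 0.01, h2 = 0.5, seed = 3)
  set.seed(3)
  eff <- simulate_effects(cfg)
  expect_equal(length(eff$causal), 300)
  # full-causal limit: sum of squared effects concentrates at h2
  cfg2 <- sim_config(n_snps = 100, p_causal = 1, h2 = 0.5, seed = 4)
  set.seed(4)
  eff2 <- simulate_effects(cfg2)
  expect_equal(length(eff2$causal), 100)
  # sum beta^2 ~ (h2/M) * chi^2_M; 3 SD band
  expect_lt(abs(sum(eff2$beta^2) - 0.5), 3 * sqrt(2 * 100) * 0.5 / 100)
})

test_that("clustered effects form within-block groups of size 2 to 8", {
  cfg <- sim_config(n_snps = 400, block_sizes = rep(20L, 20),
                    within_block_rho = 0.85, p_causal = 0.05,
                    effect_model = "clustered", seed = 12, scale = 0.1)
  study <- simulate_study(cfg)
  causal <- study$truth$causal
  expect_gt(length(causal), 0)
  block_of <- rep(seq_len(20), each = 20)
  counts <- table(block_of[causal])
  # every causal SNP shares its block with at least one other causal SNP
  expect_true(all(counts >= 2))
  # and causal SNPs sit in high-LD company within their block
  R2s <- vapply(causal, function(j) {
    b <- block_of[j]
    others <- setdiff(causal[block_of[causal] == b], j)
    max(cor(study$train$X[, j], study$train$X[, others])^2)
  }, numeric(1))
  expect_gt(mean(R2s >= 0.25), 0.8)
})

test_that("clustered model is rejected when LD is too weak", {
  cfg <- sim_config(n_snps = 40, block_sizes = rep(4L, 10),
                    within_block_rho = 0, p_causal = 0.2,
                    effect_model = "clustered", seed = 2, scale = 0.05)
  expect_error(simulate_study(cfg), "infeasible")
})

test_that("phenotype heritability is calibrated and the null is pure noise", {
  cfg <- sim_config(n_snps = 200, scale = 0.5, h2 = 0.5, p_causal = 0.05,
                    seed = 21)
  study <- simulate_study(cfg)
  expect_equal(study$truth$h2_realized, 0.5, tolerance = 0.03)
  # null effects -> phenotype is pure noise
  set.seed(22)
  X <- simulate_genotypes(cfg, 500)
  ph <- simulate_phenotype(X, numeric(200), h2 = 0)
  expect_equal(ph$h2_realized, 0)
  r2 <- cor(X[, 1], ph$y)^2
  expect_lt(r2, 0.02)
  expect_error(simulate_phenotype(X, c(1, numeric(199)), h2 = 0),
               "inconsistent")
})

test_that("binary phenotypes hit the requested case fraction", {
  cfg <- sim_config(n_snps = 50, scale = 0.1, binary = TRUE,
                    case_fraction = 0.3, p_causal = 0.1, seed = 31)
  study <- simulate_study(cfg)
  expect_equal(mean(study$train$y), 0.3, tolerance = 0.01)
  expect_true(all(study$train$y %in% 0:1))
})

test_that("marginal effects converge to R beta on a correlated block", {
  cfg <- sim_config(n_snps = 5, block_sizes = 5L, within_block_rho = 0.7,
                    h2 = 0.4, p_causal = 1, seed = 41)
  set.seed(41)
  mafs <- runif(5, 0.1, 0.5)
  beta <- c(0.3, 0, -0.2, 0, 0.1)
  X <- simulate_genotypes(cfg, 50000, mafs = mafs)
  ph <- simulate_phenotype(X, beta, h2 = 0.4)
  map <- data.frame(chrom = "1", snp_id = paste0("s", 1:5),
                    pos = 1:5 * 100L, a1 = "A", a2 = "G")
  ss <- compute_gwas(X, ph$y, map)
  # standardized marginal effect = t-based r times sd(y)... compare on the
  # correlation scale against the matrix-product oracle R %*% beta
  Xs <- scale(X)
  r_marg <- drop(cor(X, ph$y))
  R <- cor(X)
  sd_y <- sd(ph$y)
  expect_equal(r_marg * sd_y, drop(R %*% beta), tolerance = 0.02)
})

test_that("a written study round-trips through the standard formats", {
  study <- simulate_study(sim_config(n_snps = 30, scale = 0.02,
                                     p_causal = 0.1, seed = 51))
  dir <- file.path(tempdir(), "studyout")
  write_study(study, dir)
  panel <- read_reference_panel(file.path(dir, "train"))
  expect_equal(unname(panel$genotypes), unname(study$train$X))
  ss <- read_sumstats(file.path(dir, "train_sumstats.tsv"))
  expect_equal(ss$beta, study$sumstats$beta, tolerance = 1e-10)
  blocks <- load_ld_blocks(file.path(dir, "ld_blocks.bed"))
  expect_equal(nrow(blocks), nrow(study$blocks))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beta, study$truth$beta)
})
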