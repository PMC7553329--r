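#' Configure a GWAS simulation
#'
#' Defines the study conditions for the block-LD genotype / phenotype
#' simulator: four independent cohorts (training, two tuning sets, testing)
#' drawn from the same LD process, point-normal or clustered causal
#' effects, and quantitative or liability-threshold binary phenotypes.
#' Default split sizes are 6240 / 3119 / 1560 / 1560, the training /
#' tuning-1 / tuning-2 / testing layout used throughout the validation
#' studies; `scale` shrinks all four proportionally.
#'
#' @param n_train,n_tune1,n_tune2,n_test Cohort sizes.
#' @param n_snps Number of SNPs M.
#' @param block_sizes Integer vector of LD block sizes summing to
#'   `n_snps`; default blocks of 25 SNPs.
#' @param within_block_rho AR(1) correlation of the latent haplotype
#'   Gaussian within a block, in `[0, 1)`.
#' @param maf_range Range of minor-allele frequencies, within (0, 0.5].
#' @param h2 SNP heritability in `[0, 1)`.
#' @param p_causal Fraction of causal SNPs in (0, 1].
#' @param effect_model `"point_normal"` (each causal effect
#'   `N(0, h2 / (M * p_causal))` on the standardized scale) or
#'   `"clustered"` (causal SNPs placed in LD-sharing groups of 2-8,
#'   emulating allelic heterogeneity; per-causal variance
#'   `h2 / n_causal`).
#' @param cluster_size_range Group-size range for clustered effects.
#' @param cluster_r2_min Minimum within-block r-squared for a SNP to join a
#'   cluster.
#' @param binary Generate a binary phenotype by liability thresholding.
#' @param case_fraction Case fraction for binary traits.
#' @param scale Multiplier applied to all four cohort sizes.
#' @param seed Integer seed; every draw is reproducible given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_train = 6240, n_tune1 = 3119, n_tune2 = 1560,
                       n_test = 1560, n_snps = 2000, block_sizes = NULL,
                       within_block_rho = 0.5, maf_range = c(0.05, 0.5),
                       h2 = 0.5, p_causal = 0.01,
                       effect_model = c("point_normal", "clustered"),
                       cluster_size_range = c(2L, 8L),
                       cluster_r2_min = 0.25, binary = FALSE,
                       case_fraction = 0.5, scale = 1, seed = 1L) {
  effect_model <- match.arg(effect_model)
  if (is.null(block_sizes)) {
    size <- min(25L, n_snps)
    block_sizes <- rep(size, n_snps %/% size)
    rem <- n_snps - sum(block_sizes)
    if (rem > 0) block_sizes <- c(block_sizes, rem)
  }
  cfg <- list(n_train = as.integer(round(n_train * scale)),
              n_tune1 = as.integer(round(n_tune1 * scale)),
              n_tune2 = as.integer(round(n_tune2 * scale)),
              n_test = as.integer(round(n_test * scale)),
              n_snps = as.integer(n_snps),
              block_sizes = as.integer(block_sizes),
              within_block_rho = within_block_rho,
              maf_range = maf_range, h2 = h2, p_causal = p_causal,
              effect_model = effect_model,
              cluster_size_range = as.integer(cluster_size_range),
              cluster_r2_min = cluster_r2_min, binary = binary,
              case_fraction = case_fraction, seed = as.integer(seed))
  if (sum(cfg$block_sizes) != cfg$n_snps)
    stop("block sizes must sum to n_snps", call. = FALSE)
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1)
    stop("within_block_rho must lie in [0, 1)", call. = FALSE)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (cfg$h2 < 0 || cfg$h2 >= 1) stop("h2 must lie in [0, 1)", call. = FALSE)
  if (cfg$p_causal <= 0 || cfg$p_causal > 1)
    stop("p_causal must lie in (0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate block-LD genotype dosages
#'
#' For each block, two independent latent AR(1) standard-normal haplotype
#' draws per individual are thresholded at the MAF quantile and summed, so
#' dosages lie in `{0, 1, 2}` and Hardy-Weinberg equilibrium holds by
#' construction. Adjacent SNPs within a block share the latent AR(1)
#' correlation; blocks are independent.
#'
#' @param cfg A [sim_config()].
#' @param n Number of individuals.
#' @param mafs Per-SNP minor-allele frequencies (drawn from
#'   `cfg$maf_range` when `NULL`).
#' @return Integer dosage matrix (`n` x `n_snps`).
#' @export
simulate_genotypes <- function(cfg, n, mafs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(mafs))
    mafs <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  rho <- cfg$within_block_rho
  X <- matrix(0L, n, cfg$n_snps)
  thr <- qnorm(mafs)
  offset <- 0L
  for (m in cfg$block_sizes) {
    cols <- offset + seq_len(m)
    for (hap in 1:2) {
      Z <- matrix(rnorm(n * m), n, m)
      if (rho > 0 && m > 1) {
        w <- sqrt(1 - rho^2)
        for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + w * Z[, j]
      }
      X[, cols] <- X[, cols] +
        (Z < rep(thr[cols], each = n)) * 1L
    }
    offset <- offset + m
  }
  X
}

#' Draw causal effects on the standardized-genotype scale
#'
#' Point-normal model: an exact-count causal set of size
#' `round(p_causal * M)` is sampled without replacement and each causal
#' effect is drawn `N(0, h2 / (M * p_causal))`. Clustered model: anchor
#' SNPs are chosen uniformly among SNPs with at least one within-block
#' neighbor at r-squared `>= cluster_r2_min`, and each anchor is extended
#' to a group (size uniform on `cluster_size_range`, truncated by
#' availability and the remaining causal quota) of LD-sharing SNPs in its
#' block; per-causal variance is `h2 / n_causal`.
#'
#' @param cfg A [sim_config()].
#' @param R_blocks For the clustered model only: list of per-block LD
#'   correlation matrices (e.g. estimated from a simulated cohort).
#' @return List with `beta` (length-M standardized effects) and `causal`
#'   (integer index set).
#' @export
simulate_effects <- function(cfg, R_blocks = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  M <- cfg$n_snps
  m_causal <- round(cfg$p_causal * M)
  if (m_causal < 1)
    stop("p_causal * n_snps rounds to zero causal SNPs", call. = FALSE)
  beta <- numeric(M)
  if (cfg$effect_model == "point_normal") {
    causal <- sort(sample.int(M, m_causal))
    beta[causal] <- rnorm(m_causal, 0, sqrt(cfg$h2 / (M * cfg$p_causal)))
  } else {
    if (is.null(R_blocks))
      stop("clustered effects need per-block LD matrices (R_blocks)",
           call. = FALSE)
    block_of <- rep(seq_along(cfg$block_sizes), cfg$block_sizes)
    block_start <- cumsum(c(0L, cfg$block_sizes))
    # within-block neighbor lists at r2 >= cluster_r2_min
    neighbors <- vector("list", M)
    eligible <- logical(M)
    for (b in seq_along(R_blocks)) {
      R2 <- R_blocks[[b]]^2
      diag(R2) <- 0
      m <- nrow(R2)
      for (j in seq_len(m)) {
        nb <- which(R2[j, ] >= cfg$cluster_r2_min)
        g <- block_start[b] + j
        neighbors[[g]] <- block_start[b] + nb
        eligible[g] <- length(nb) > 0
      }
    }
    if (!any(eligible))
      stop(paste("clustered model infeasible: no SNP has a within-block",
                 "neighbor at r2 >=", cfg$cluster_r2_min,
                 "- increase within_block_rho or block sizes"),
           call. = FALSE)
    if (m_causal < cfg$cluster_size_range[1])
      stop("clustered model infeasible: causal quota below minimum cluster size",
           call. = FALSE)
    causal <- integer(0)
    used <- logical(M)
    remaining <- m_causal
    while (remaining >= cfg$cluster_size_range[1]) {
      pool <- which(eligible & !used)
      if (!length(pool)) break
      anchor <- pool[sample.int(length(pool), 1L)]
      avail <- setdiff(neighbors[[anchor]], which(used))
      gmax <- min(cfg$cluster_size_range[2], length(avail) + 1L, remaining)
      gmin <- min(cfg$cluster_size_range[1], gmax)
      gsize <- if (gmax > gmin) sample(gmin:gmax, 1L) else gmax
      grp <- c(anchor,
               if (gsize > 1L) avail[sample.int(length(avail), gsize - 1L)])
      used[grp] <- TRUE
      causal <- c(causal, grp)
      remaining <- remaining - length(grp)
    }
    if (!length(causal))
      stop("clustered model infeasible: could not place any cluster",
           call. = FALSE)
    causal <- sort(causal)
    beta[causal] <- rnorm(length(causal), 0, sqrt(cfg$h2 / length(causal)))
  }
  list(beta = beta, causal = which(beta != 0))
}

#' Generate a phenotype from standardized genotype effects
#'
#' Standardizes the genotype columns, forms the genetic component
#' `g = X_std beta`, and adds Gaussian noise with variance
#' `var(g) (1 - h2) / h2`, so the realized variance ratio
#' `var(g) / var(y)` targets `h2` exactly up to noise sampling. Binary
#' phenotypes threshold the liability at the empirical
#' `1 - case_fraction` quantile.
#'
#' @param X Dosage matrix.
#' @param beta Standardized-scale effect vector.
#' @param h2 Target heritability.
#' @param binary Liability-threshold binary trait?
#' @param case_fraction Case fraction for binary traits.
#' @return List with `y` (phenotype), `g` (genetic component), and
#'   `h2_realized`.
#' @export
simulate_phenotype <- function(X, beta, h2, binary = FALSE,
                               case_fraction = 0.5) {
  n <- nrow(X)
  if (h2 == 0 && any(beta != 0))
    stop("h2 = 0 is inconsistent with nonzero effects", call. = FALSE)
  if (all(beta == 0)) {
    y <- rnorm(n)
    g <- numeric(n)
  } else {
    Xs <- standardize_columns(X)
    g <- drop(Xs %*% beta)
    vg <- mean(g^2) - mean(g)^2
    sigma2 <- vg * (1 - h2) / h2
    y <- g + rnorm(n, 0, sqrt(sigma2))
  }
  vy <- mean(y^2) - mean(y)^2
  h2_realized <- if (vy > 0) (mean(g^2) - mean(g)^2) / vy else 0
  if (binary) {
    thr <- quantile(y, 1 - case_fraction, names = FALSE)
    y <- as.integer(y > thr)
  }
  list(y = y, g = g, h2_realized = h2_realized)
}

standardize_columns <- function(X) {
  X <- impute_mean(X)
  mu <- colMeans(X)
  sdv <- sqrt(matrixStats_colVars(X))
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Simulate a complete four-cohort GWAS study
#'
#' Runs the whole generator under one seed: MAFs, causal effects,
#' independent genotype draws for the training / tuning-1 / tuning-2 /
#' testing cohorts, phenotypes for every cohort, and marginal GWAS summary
#' statistics from the training cohort.
#'
#' @param cfg A [sim_config()].
#' @return List with per-cohort `X` and `y` (`train`, `tune1`, `tune2`,
#'   `test`), the `truth` (standardized `beta`, `causal` set,
#'   `h2_realized` in the training cohort), SNP `map`, LD `blocks`, `mafs`,
#'   and training `sumstats`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_snps
  mafs <- runif(M, cfg$maf_range[1], cfg$maf_range[2])
  map <- data.frame(chrom = "1", snp_id = sprintf("rs%05d", seq_len(M)),
                    pos = 100L * seq_len(M),
                    a1 = rep_len(c("A", "C"), M),
                    a2 = rep_len(c("G", "T"), M),
                    stringsAsFactors = FALSE)
  ends <- cumsum(cfg$block_sizes)
  starts <- c(0L, head(ends, -1)) # SNP index offsets
  blocks <- ld_blocks(data.frame(chrom = "1", start = 100L * starts,
                                 end = 100L * ends))

  X_train <- simulate_genotypes(cfg, cfg$n_train, mafs)
  if (cfg$effect_model == "clustered") {
    Rb <- lapply(seq_along(cfg$block_sizes), function(b) {
      cols <- (starts[b] + 1L):ends[b]
      block_correlation(X_train[, cols, drop = FALSE])
    })
    eff <- simulate_effects(cfg, R_blocks = Rb)
  } else {
    eff <- simulate_effects(cfg)
  }

  cohorts <- list(train = X_train,
                  tune1 = simulate_genotypes(cfg, cfg$n_tune1, mafs),
                  tune2 = simulate_genotypes(cfg, cfg$n_tune2, mafs),
                  test = simulate_genotypes(cfg, cfg$n_test, mafs))
  phen <- lapply(cohorts, simulate_phenotype, beta = eff$beta, h2 = cfg$h2,
                 binary = cfg$binary, case_fraction = cfg$case_fraction)
  ss <- compute_gwas(cohorts$train, phen$train$y, map = map,
                     binary = cfg$binary)
  out <- list(config = cfg, map = map, blocks = blocks, mafs = mafs,
              truth = list(beta = eff$beta, causal = eff$causal,
                           h2_realized = phen$train$h2_realized),
              sumstats = ss)
  for (nm in names(cohorts))
    out[[nm]] <- list(X = cohorts[[nm]], y = phen[[nm]]$y,
                      g = phen[[nm]]$g,
                      h2_realized = phen[[nm]]$h2_realized)
  class(out) <- "sim_study"
  out
}

#' Write a simulated study to disk in standard formats
#'
#' Emits the training cohort as PLINK bed/bim/fam plus phenotype text, the
#' summary statistics as TSV, the LD blocks as 3-column BED, and the truth
#' (effects, causal set, realized heritability) as JSON.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("train", "tune1", "tune2", "test")) {
    panel <- ref_panel(study[[nm]]$X, study$map)
    write_plink(panel, file.path(dir, nm), phenotype = study[[nm]]$y)
  }
  write_sumstats(study$sumstats, file.path(dir, "train_sumstats.tsv"))
  data.table::fwrite(as.data.frame(study$blocks)[, c("chrom", "start", "end")],
                     file.path(dir, "ld_blocks.bed"), sep = "\t",
                     col.names = FALSE)
  jsonlite::write_json(
    list(beta = study$truth$beta, causal = study$truth$causal,
         h2_realized = study$truth$h2_realized,
         seed = study$config$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
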