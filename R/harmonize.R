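ambiguous_alleles <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Greedy clumping: SNPs visited by `priority` order are kept unless their
# squared correlation with an already-kept SNP exceeds r2_max.
greedy_clump <- function(R, priority, r2_max) {
  p <- nrow(R)
  keep <- logical(p)
  for (j in order(priority)) {
    ok <- TRUE
    if (any(keep) && p > 1) {
      if (max(R[j, keep]^2) > r2_max) ok <- FALSE
    }
    keep[j] <- ok
  }
  keep
}

#' Harmonize summary statistics with a reference panel and LD blocks
#'
#' Aligns a [sumstats()] table to a reference panel: palindromic (A/T, C/G)
#' SNPs are removed, effect alleles are matched to the panel coding (beta's
#' sign is flipped when a1/a2 are swapped; irreconcilable alleles are
#' dropped), SNPs with panel minor-allele frequency below `maf_min` are
#' removed, and SNPs are greedily clumped so no retained pair within an LD
#' block has squared correlation above `ld_clump_r2` (smaller p-value wins,
#' ties broken by position). SNPs present in the summary statistics but not
#' the panel are retained with `in_reference = FALSE`; they are later
#' modeled as mutually independent.
#'
#' The SNP-phenotype correlation vector `r` is computed, by default, from
#' the marginal t-statistic as \eqn{r_j = t_j / \sqrt{n_j - 2 + t_j^2}}
#' (exact for simple linear regression), or alternatively as
#' \eqn{r_j = \hat\beta_j \hat s_j / \widehat{sd}(y)} with
#' `r_method = "beta"`.
#'
#' @param ss A `sumstats` object.
#' @param panel A `ref_panel`.
#' @param blocks An `ld_blocks` set, or `NULL` for one block per
#'   chromosome.
#' @param maf_min Minimum panel minor-allele frequency (default
#'   0.01).
#' @param ld_clump_r2 Maximum squared correlation between retained SNPs in
#'   a block (default 0.9, enough to guarantee solver convergence).
#' @param r_method `"t"` (default) or `"beta"`; see Details.
#' @return An object of class `harmonized_problem`: a SNP table with panel
#'   SDs, block labels and `in_reference` flags; the correlation vector
#'   `r`; `sd_y_hat`; effective sample size `n_eff`; and a `log` of per-
#'   reason drop counts.
#' @export
harmonize <- function(ss, panel, blocks = NULL, maf_min = 0.01,
                      ld_clump_r2 = 0.9, r_method = c("t", "beta")) {
  stopifnot(inherits(panel, "ref_panel"))
  r_method <- match.arg(r_method)
  validate_sumstats(ss)
  is_binary <- isTRUE(attr(ss, "is_binary_trait"))
  log <- list(input = nrow(ss))

  amb <- ambiguous_alleles(ss$a1, ss$a2)
  log$ambiguous_removed <- sum(amb)
  ss <- ss[!amb, , drop = FALSE]

  pcol <- match(ss$snp_id, panel$map$snp_id)
  in_ref <- !is.na(pcol)
  if (!any(in_ref))
    stop("no overlap between summary statistics and reference panel",
         call. = FALSE)

  # Allele alignment against the panel coding for matched SNPs.
  flip <- rep(FALSE, nrow(ss))
  drop_conflict <- rep(FALSE, nrow(ss))
  m <- which(in_ref)
  pa1 <- toupper(panel$map$a1[pcol[m]])
  pa2 <- toupper(panel$map$a2[pcol[m]])
  same <- ss$a1[m] == pa1 & ss$a2[m] == pa2
  swap <- ss$a1[m] == pa2 & ss$a2[m] == pa1
  flip[m[swap]] <- TRUE
  drop_conflict[m[!same & !swap]] <- TRUE
  log$allele_conflict_removed <- sum(drop_conflict)

  ss$beta[flip] <- -ss$beta[flip]
  tmp <- ss$a1[flip]
  ss$a1[flip] <- ss$a2[flip]
  ss$a2[flip] <- tmp
  log$allele_flipped <- sum(flip)

  keep <- !drop_conflict
  ss <- ss[keep, , drop = FALSE]
  pcol <- pcol[keep]
  in_ref <- in_ref[keep]

  # Panel per-SNP statistics (mean imputation; population 1/n variances).
  s_hat <- rep(NA_real_, nrow(ss))
  maf <- rep(NA_real_, nrow(ss))
  if (any(in_ref)) {
    G <- impute_mean(panel$genotypes[, pcol[in_ref], drop = FALSE])
    v <- matrixStats_colVars(G)
    af <- colMeans(G) / 2
    s_hat[in_ref] <- sqrt(v)
    maf[in_ref] <- pmin(af, 1 - af)
  }
  low_maf <- in_ref & (maf < maf_min | s_hat == 0)
  log$maf_removed <- sum(low_maf)
  ss <- ss[!low_maf, , drop = FALSE]
  pcol <- pcol[!low_maf]
  in_ref <- in_ref[!low_maf]
  s_hat <- s_hat[!low_maf]
  maf <- maf[!low_maf]
  if (!any(in_ref))
    stop("no SNPs left in the panel intersection after filtering",
         call. = FALSE)

  # Prefer panel coordinates for block assignment of matched SNPs.
  chrom <- ifelse(in_ref, panel$map$chrom[pcol], ss$chrom)
  pos <- ifelse(in_ref, panel$map$pos[pcol], ss$pos)
  block <- rep(NA_character_, nrow(ss))
  block[in_ref] <- assign_blocks(chrom[in_ref], pos[in_ref], blocks)
  block[!in_ref] <- paste0("noref_", ss$snp_id[!in_ref])

  # Greedy clumping within blocks (priority: ascending p, then position).
  clump_keep <- rep(TRUE, nrow(ss))
  for (b in unique(block[in_ref])) {
    jj <- which(block == b & in_ref)
    if (length(jj) < 2) next
    R <- block_correlation(panel$genotypes[, pcol[jj], drop = FALSE])
    prio <- order(ss$pvalue[jj], pos[jj])
    rank <- integer(length(jj))
    rank[prio] <- seq_along(jj)
    clump_keep[jj] <- greedy_clump(R, rank, ld_clump_r2)
  }
  log$clump_removed <- sum(!clump_keep)
  ss <- ss[clump_keep, , drop = FALSE]
  pcol <- pcol[clump_keep]
  in_ref <- in_ref[clump_keep]
  s_hat <- s_hat[clump_keep]
  maf <- maf[clump_keep]
  chrom <- chrom[clump_keep]
  pos <- pos[clump_keep]
  block <- block[clump_keep]
  log$retained <- nrow(ss)

  # Phenotype SD from the summary-level second-moment identity
  # (1/N) Y'Y ~= N s_j^2 var(beta_j) + s_j^2 beta_j^2, median across SNPs.
  yty <- median(ss$n[in_ref] * s_hat[in_ref]^2 * ss$se[in_ref]^2 +
                  s_hat[in_ref]^2 * ss$beta[in_ref]^2)
  sd_y_hat <- sqrt(yty)

  t_stat <- ss$beta / ss$se
  r <- if (r_method == "t") {
    t_stat / sqrt(ss$n - 2 + t_stat^2)
  } else {
    out <- ss$beta * s_hat / sd_y_hat
    # t-based fallback where no panel SD exists
    out[!in_ref] <- (t_stat / sqrt(ss$n - 2 + t_stat^2))[!in_ref]
    out
  }
  r <- pmin(pmax(r, -1), 1)

  snps <- data.frame(snp_id = ss$snp_id, chrom = chrom, pos = pos,
                     a1 = ss$a1, a2 = ss$a2, beta = ss$beta, se = ss$se,
                     n = ss$n, pvalue = ss$pvalue, in_reference = in_ref,
                     block = block, s_hat = s_hat, maf = maf,
                     panel_col = pcol, stringsAsFactors = FALSE)
  structure(list(snps = snps, r = setNames(r, snps$snp_id),
                 sd_y_hat = sd_y_hat, n_eff = median(ss$n),
                 is_binary_trait = is_binary, maf_min = maf_min,
                 ld_clump_r2 = ld_clump_r2, r_method = r_method,
                 log = log),
            class = "harmonized_problem")
}

#' @export
print.harmonized_problem <- function(x, ...) {
  cat(sprintf("<harmonized_problem: %d SNPs (%d in reference, %d blocks), n_eff = %g>\n",
              nrow(x$snps), sum(x$snps$in_reference),
              length(unique(x$snps$block[x$snps$in_reference])), x$n_eff))
  invisible(x)
}

#' Write the harmonization log as JSON
#'
#' @param problem A `harmonized_problem`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(problem, path) {
  jsonlite::write_json(problem$log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
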