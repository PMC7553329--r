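#' Default column names for summary-statistic files
#' @noRd
.sumstats_default_map <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                           a1 = "A1", a2 = "A2", beta = "BETA", se = "SE",
                           n = "N", pvalue = "P")

#' Construct a summary-statistics object in memory
#'
#' @param snp_id,chrom,pos,a1,a2,beta,se,n,pvalue Per-SNP GWAS results:
#'   marginal (per-allele) effect `beta` of allele `a1`, its standard error
#'   `se`, per-SNP sample size `n`, and two-sided p-value.
#' @param is_binary_trait Logical flag: `TRUE` when `beta` is on the
#'   log-odds scale (see [convert_binary_sumstats()]).
#' @return A data frame of class `sumstats`.
#' @export
sumstats <- function(snp_id, chrom = NA_character_, pos = NA_integer_,
                     a1, a2, beta, se, n, pvalue = NULL,
                     is_binary_trait = FALSE) {
  if (is.null(pvalue))
    pvalue <- 2 * pt(-abs(beta / se), df = pmax(n - 2, 1))
  ss <- data.frame(snp_id = as.character(snp_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   a1 = toupper(as.character(a1)),
                   a2 = toupper(as.character(a2)),
                   beta = as.numeric(beta), se = as.numeric(se),
                   n = as.numeric(n), pvalue = as.numeric(pvalue),
                   stringsAsFactors = FALSE)
  validate_sumstats(ss)
  attr(ss, "is_binary_trait") <- isTRUE(is_binary_trait)
  class(ss) <- c("sumstats", "data.frame")
  ss
}

validate_sumstats <- function(ss) {
  if (nrow(ss) == 0L) stop("empty summary statistics", call. = FALSE)
  if (anyDuplicated(ss$snp_id))
    stop("duplicate snp_id in summary statistics", call. = FALSE)
  if (any(ss$se <= 0)) stop("se must be > 0 for every SNP", call. = FALSE)
  if (any(ss$n < 2)) stop("n must be >= 2 for every SNP", call. = FALSE)
  if (any(ss$a1 == ss$a2)) stop("a1 == a2 for some SNPs", call. = FALSE)
  invisible(ss)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads whitespace- or tab-delimited summary statistics with a header.
#' Rows with non-numeric or non-positive `se`, or non-numeric `beta`, are
#' dropped with a message reporting the count.
#'
#' @param path File path.
#' @param column_map Named character vector mapping internal names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `n`, `pvalue`) to
#'   the file's column names. Defaults to
#'   `SNP, CHR, BP, A1, A2, BETA, SE, N, P`.
#' @param n Global sample size used when the file has no sample-size
#'   column.
#' @param is_binary_trait Flag the effects as log-odds from logistic
#'   regression.
#' @return A `sumstats` data frame; the number of dropped rows is recorded
#'   in attribute `n_dropped`.
#' @export
read_sumstats <- function(path, column_map = NULL, n = NULL,
                          is_binary_trait = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cmap <- .sumstats_default_map
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path,
                            call. = FALSE)
  mandatory <- c("snp_id", "a1", "a2", "beta", "se")
  missing_cols <- mandatory[!cmap[mandatory] %in% names(raw)]
  if (length(missing_cols))
    stop("summary-statistics file lacks mapped column(s): ",
         paste(cmap[missing_cols], collapse = ", "), call. = FALSE)
  get <- function(field, default = NULL) {
    col <- cmap[[field]]
    if (col %in% names(raw)) raw[[col]] else default
  }
  beta <- suppressWarnings(as.numeric(get("beta")))
  se <- suppressWarnings(as.numeric(get("se")))
  nn <- get("n")
  if (is.null(nn)) {
    if (is.null(n))
      stop("no sample-size column '", cmap[["n"]],
           "' in file; supply n explicitly", call. = FALSE)
    nn <- rep(n, nrow(raw))
  } else {
    nn <- suppressWarnings(as.numeric(nn))
  }
  keep <- is.finite(beta) & is.finite(se) & se > 0 & is.finite(nn)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped (non-numeric or invalid beta/se/n)")
  if (!any(keep))
    stop("no usable rows in summary-statistics file", call. = FALSE)
  pv <- get("pvalue")
  if (!is.null(pv)) pv <- suppressWarnings(as.numeric(pv))
  ss <- sumstats(snp_id = get("snp_id")[keep],
                 chrom = (get("chrom", NA_character_))[keep],
                 pos = suppressWarnings(as.integer(get("pos", NA)))[keep],
                 a1 = get("a1")[keep], a2 = get("a2")[keep],
                 beta = beta[keep], se = se[keep], n = nn[keep],
                 pvalue = if (is.null(pv)) NULL else pv[keep],
                 is_binary_trait = is_binary_trait)
  attr(ss, "n_dropped") <- n_dropped
  ss
}

#' Write summary statistics to a TSV file
#'
#' @param ss A `sumstats` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp_id, CHR = ss$chrom, BP = ss$pos,
                    A1 = ss$a1, A2 = ss$a2, BETA = ss$beta, SE = ss$se,
                    N = ss$n, P = ss$pvalue)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
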