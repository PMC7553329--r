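#' Construct a reference panel from in-memory dosages
#'
#' @param genotypes Individuals x SNPs matrix of allele dosages in
#'   `{0, 1, 2}` (NA allowed) counting the a1 allele.
#' @param map Data frame with columns `chrom`, `snp_id`, `pos`, `a1`, `a2`,
#'   one row per genotype column.
#' @return An object of class `ref_panel` with elements `genotypes`, `map`,
#'   `n_ref`.
#' @export
ref_panel <- function(genotypes, map) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(map), nrow(map) == ncol(genotypes),
            all(c("chrom", "snp_id", "pos", "a1", "a2") %in% names(map)))
  if (any(colMeans(is.na(genotypes)) >= 1))
    stop("panel contains SNPs with 100% missingness", call. = FALSE)
  rng <- range(genotypes, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]", call. = FALSE)
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in panel map", call. = FALSE)
  colnames(genotypes) <- map$snp_id
  map$chrom <- as.character(map$chrom)
  structure(list(genotypes = genotypes, map = map, n_ref = nrow(genotypes)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel: %d individuals x %d SNPs>\n", x$n_ref,
              ncol(x$genotypes)))
  invisible(x)
}

# PLINK 1 .bed 2-bit codes (SNP-major): 00 = hom a1 (dosage 2),
# 01 = missing, 10 = het, 11 = hom a2 (dosage 0).
.bed_code_from_dosage <- c(`2` = 0L, `1` = 2L, `0` = 3L)
.bed_dosage_from_code <- c(2, NA, 1, 0)

#' Write a reference panel as a PLINK 1 bed/bim/fam triplet
#'
#' Writes the SNP-major binary format understood by PLINK 1.x. Dosages
#' count the a1 (`.bim` column 5) allele.
#'
#' @param panel A `ref_panel`.
#' @param prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @param phenotype Optional numeric phenotype written to the `.fam` file
#'   (default `-9`, i.e. missing).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix, phenotype = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  X <- panel$genotypes
  n <- nrow(X)
  p <- ncol(X)
  map <- panel$map
  bim <- data.frame(chrom = map$chrom, snp_id = map$snp_id, cm = 0,
                    pos = map$pos, a1 = map$a1, a2 = map$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  ph <- if (is.null(phenotype)) rep(-9, n) else phenotype
  fam <- data.frame(fid = paste0("F", seq_len(n)),
                    iid = paste0("I", seq_len(n)),
                    pat = 0, mat = 0, sex = 0, pheno = ph)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  nbytes <- ceiling(n / 4)
  pad <- 4 * nbytes - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(p)) {
    d <- X[, j]
    code <- integer(n)
    code[is.na(d)] <- 1L
    ok <- !is.na(d)
    code[ok] <- .bed_code_from_dosage[as.character(round(d[ok]))]
    if (pad > 0) code <- c(code, integer(pad)) # zero padding bits
    bytes <- colSums(matrix(code * mult, nrow = 4L))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK 1 bed/bim/fam reference panel
#'
#' Reads the SNP-major binary genotype format. Missing genotypes are
#' returned as `NA`, distinct from dosage 0; padding bits in the final byte
#' of each SNP record are ignored.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A `ref_panel` with dosages counting the `.bim` a1 allele.
#' @export
read_reference_panel <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bim <- data.table::fread(paths[2], header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = list(character = c(1, 2, 5, 6)),
                           data.table = FALSE)
  fam <- data.table::fread(paths[3], header = FALSE, data.table = FALSE)
  n <- nrow(fam)
  p <- nrow(bim)
  nbytes <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes): ", paths[1],
         call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported", call. = FALSE)
  expected <- 3 + nbytes * p
  if (length(raw) != expected)
    stop(sprintf(".bed truncated or oversized: expected %d bytes (3 + %d x %d), found %d",
                 expected, nbytes, p, length(raw)), call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  # Unpack 2-bit codes, sample index advancing within each byte.
  codes <- rbind(bitwAnd(body, 3L),
                 bitwAnd(bitwShiftR(body, 2L), 3L),
                 bitwAnd(bitwShiftR(body, 4L), 3L),
                 bitwAnd(bitwShiftR(body, 6L), 3L))
  dim(codes) <- c(4L * nbytes, p)
  X <- matrix(.bed_dosage_from_code[codes[seq_len(n), , drop = FALSE] + 1L],
              nrow = n, ncol = p)
  map <- bim[, c("chrom", "snp_id", "pos", "a1", "a2")]
  ref_panel(X, map)
}
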