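#' Load LD block definitions from a BED-like file
#'
#' Reads a three-column (chrom, start, end) text file of approximately
#' independent LD blocks (LDetect dialect). Coordinates are 0-based
#' half-open. Blocks are validated and sorted; overlapping intervals on the
#' same chromosome are an error.
#'
#' @param path File path (whitespace- or tab-delimited; a header line is
#'   detected and skipped).
#' @return A data frame of class `ld_blocks` with columns `chrom`, `start`,
#'   `end`.
#' @export
load_ld_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\S+\\s+[0-9]+\\s+[0-9]+", first)
  b <- data.table::fread(path, header = has_header, data.table = FALSE)
  if (ncol(b) < 3) stop("LD block file needs 3 columns (chrom, start, end)",
                        call. = FALSE)
  b <- b[, 1:3]
  names(b) <- c("chrom", "start", "end")
  ld_blocks(b)
}

#' Construct an LD block set from a data frame
#'
#' @param b Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A validated, sorted `ld_blocks` data frame.
#' @export
ld_blocks <- function(b) {
  stopifnot(all(c("chrom", "start", "end") %in% names(b)))
  b$chrom <- sub("^chr", "", as.character(b$chrom))
  b$start <- as.numeric(b$start)
  b$end <- as.numeric(b$end)
  if (any(b$end <= b$start))
    stop("LD block with end <= start", call. = FALSE)
  b <- b[order(b$chrom, b$start), ]
  for (ch in unique(b$chrom)) {
    sub <- b[b$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping LD blocks on chromosome ", ch, call. = FALSE)
  }
  rownames(b) <- NULL
  class(b) <- c("ld_blocks", "data.frame")
  b
}

#' Assign SNPs to LD blocks
#'
#' `.bim`-style positions are 1-based; block intervals are 0-based
#' half-open, so a SNP maps to a block iff `start <= pos - 1 < end`. SNPs
#' outside every interval are placed in singleton pseudo-blocks.
#'
#' @param chrom,pos Character/integer vectors of SNP coordinates.
#' @param blocks An `ld_blocks` data frame, or `NULL` to place each
#'   chromosome in a single block.
#' @return Character vector of block labels, one per SNP.
#' @export
assign_blocks <- function(chrom, pos, blocks = NULL) {
  chrom <- sub("^chr", "", as.character(chrom))
  if (is.null(blocks)) return(paste0("chrom_", chrom))
  stopifnot(inherits(blocks, "ld_blocks"))
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sub <- blocks[blocks$chrom == ch, ]
    if (nrow(sub) == 0L) {
      out[sel] <- paste0("singleton_", ch, ":", pos[sel])
      next
    }
    p0 <- pos[sel] - 1 # 0-based
    i <- findInterval(p0, sub$start)
    hit <- i >= 1 & ifelse(i >= 1, p0 < sub$end[pmax(i, 1)], FALSE)
    out[sel[hit]] <- paste0(ch, ":", sub$start[i[hit]], "-", sub$end[i[hit]])
    out[sel[!hit]] <- paste0("singleton_", ch, ":", pos[sel[!hit]])
  }
  out
}
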