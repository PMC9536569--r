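#' Delineate donor-strain (D2) haplotype blocks for one line
#'
#' A block is a maximal run of at least 2 consecutive markers (in
#' chromosome + position order) whose allele for the line is `D`. Runs are
#' terminated by any `B`, `H` or `U` marker and by chromosome boundaries:
#' heterozygous calls flag uncertainty and missing genotypes are not
#' imputed across. The block interval is the closed span from the first to
#' the last `D` marker of the run — boundaries are the marker positions
#' themselves, not extended toward flanking non-D markers, so variants in
#' the inter-marker uncertainty zone are not imputed.
#'
#' @param table A [genotype_table()].
#' @param line Line identifier (must be a column of the table).
#' @return `data.frame` with columns `chrom`, `start`, `end` (1-based,
#'   inclusive), `n_markers`. Zero rows when the line has no qualifying run.
#' @export
delineate_d2_blocks <- function(table, line) {
  stopifnot(inherits(table, "genotype_table"))
  if (!line %in% table$lines) stop("unknown line: ", line)
  al <- table$alleles[, line]
  out <- list()
  for (ch in unique(table$markers$chrom)) {
    idx <- which(table$markers$chrom == ch)
    isd <- al[idx] == "D"
    r <- rle(isd)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 2L
    if (!any(keep)) next
    pos <- table$markers$pos[idx]
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch,
                 start = pos[starts[keep]],
                 end = pos[ends[keep]],
                 n_markers = r$lengths[keep],
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_markers = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the variants overlapping a line's haplotype blocks
#'
#' A variant's genomic footprint is `[pos, pos + nchar(ref) - 1]`; it is
#' imputed into the line when the footprint intersects any block on the
#' same chromosome by at least 1 bp (the bedtools-intersect default).
#' Zygosity labels are carried through unchanged — HET-labelled variants
#' survive imputation and are filtered only at genome-editing time.
#'
#' @param blocks Blocks `data.frame` from [delineate_d2_blocks()].
#' @param v Variants `data.frame`, sorted by `(chrom, pos)`.
#' @return The overlapping subset of `v`, sorted.
#' @export
impute_line_variants <- function(blocks, v) {
  validate_variants(v)
  if (nrow(v) == 0L || nrow(blocks) == 0L)
    return(v[integer(0), , drop = FALSE])
  keep <- logical(nrow(v))
  for (ch in unique(blocks$chrom)) {
    bi <- blocks$chrom == ch
    vi <- which(v$chrom == ch)
    if (length(vi) == 0L) next
    ir_v <- IRanges::IRanges(start = v$pos[vi],
                             end = v$pos[vi] + nchar(v$ref[vi]) - 1L)
    ir_b <- IRanges::IRanges(start = blocks$start[bi], end = blocks$end[bi])
    keep[vi] <- IRanges::overlapsAny(ir_v, ir_b)
  }
  res <- v[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Impute dense strain variants into every line of a panel
#'
#' Applies [delineate_d2_blocks()] and [impute_line_variants()] to each
#' line and reports a per-line summary (number of blocks, total block bp,
#' number of variants imputed) via `message()`.
#'
#' @param table A [genotype_table()].
#' @param v Variants `data.frame`.
#' @param quiet Suppress the per-line summary messages.
#' @return Named list (one element per line) with `blocks` and `variants`.
#' @export
impute_panel <- function(table, v, quiet = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  res <- lapply(table$lines, function(ln) {
    blocks <- delineate_d2_blocks(table, ln)
    vv <- impute_line_variants(blocks, v)
    if (!quiet)
      message(sprintf("impute_panel: %s: %d block(s), %d bp, %d variant(s)",
                      ln, nrow(blocks),
                      sum(blocks$end - blocks$start + 1L), nrow(vv)))
    list(blocks = blocks, variants = vv)
  })
  names(res) <- table$lines
  res
}
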