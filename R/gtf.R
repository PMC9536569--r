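#' Read / write GTF annotation
#'
#' Features are held as a `data.frame` with the nine GTF columns
#' (`seqname`, `source`, `feature`, `start`, `end`, `score`, `strand`,
#' `frame`, `attributes`; coordinates 1-based inclusive) plus a `gene_id`
#' column extracted from the attribute string. The raw attribute string is
#' kept verbatim so that `write_gtf(read_gtf(p))` is byte-lossless,
#' including attribute order — a property GRanges-based importers do not
#' guarantee.
#'
#' @param path File path.
#' @return `read_gtf` returns the feature `data.frame`; `write_gtf`
#'   invisibly returns `path`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep))
    return(empty_features())
  ln <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L))
    stop("malformed GTF record (", nf[nf != 9L][1L], " fields) at line ",
         ln[which(nf != 9L)[1L]])
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at line ", ln[which(is.na(start) | is.na(end))[1L]])
  bad <- which(end < start | start < 1L)
  if (length(bad))
    stop("invalid coordinates (end < start or start < 1) at line ", ln[bad[1L]])
  bad_strand <- which(!m[, 7L] %in% c("+", "-"))
  if (length(bad_strand))
    stop("strand must be + or - at line ", ln[bad_strand[1L]])
  f <- data.frame(seqname = m[, 1L], source = m[, 2L], feature = m[, 3L],
                  start = start, end = end, score = m[, 6L],
                  strand = m[, 7L], frame = m[, 8L], attributes = m[, 9L],
                  stringsAsFactors = FALSE)
  f$gene_id <- extract_attribute(f$attributes, "gene_id")
  f
}

empty_features <- function() {
  data.frame(seqname = character(), source = character(), feature = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), frame = character(), attributes = character(),
             gene_id = character(), stringsAsFactors = FALSE)
}

# pull a single quoted attribute value out of a GTF attribute string
extract_attribute <- function(attributes, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regexec(pat, attributes)
  vapply(regmatches(attributes, m), function(g) {
    if (length(g) >= 3L) g[3L] else NA_character_
  }, character(1L))
}

#' @param features Feature `data.frame` as returned by [read_gtf()].
#' @rdname read_gtf
#' @export
write_gtf <- function(features, path) {
  stopifnot(is.data.frame(features))
  if (nrow(features) && any(features$end < features$start))
    stop("invalid feature: end < start")
  lines <- with(features, paste(seqname, source, feature, start, end, score,
                                strand, frame, attributes, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Resolve one transcription start site per gene
#'
#' The TSS is the 5' end of the gene on its strand: `start` on `+`, `end`
#' on `-`. When a gene has several features/transcripts the 5'-most TSS per
#' strand is used (minimum `start` on `+`, maximum `end` on `-`).
#'
#' @param features Feature `data.frame` (typically the `gene` rows of a GTF,
#'   but any rows carrying `gene_id` work).
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
gene_tss <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  f <- features[!is.na(features$gene_id), , drop = FALSE]
  sp <- split(f, f$gene_id)
  out <- lapply(sp, function(g) {
    strand <- g$strand[1L]
    tss <- if (strand == "+") min(g$start) else max(g$end)
    data.frame(gene_id = g$gene_id[1L], chrom = g$seqname[1L],
               tss = as.integer(tss), strand = strand,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
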