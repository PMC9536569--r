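#' Panel genotype tables
#'
#' A genotype table holds the marker map of a recombinant inbred panel
#' (markers ordered by chromosome and position) together with the allele call
#' of every line at every marker. Alleles use the four GeneNetwork-style
#' codes:
#'
#' * `B` — the reference-strain (B6) allele,
#' * `D` — the donor-strain (D2) allele,
#' * `H` — heterozygous, used by panel providers to flag uncertain calls,
#' * `U` — unknown / missing.
#'
#' @param markers `data.frame` with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp), strictly increasing within each chromosome.
#' @param alleles Character matrix, markers x lines, entries in
#'   `c("B","D","H","U")`; column names are the line identifiers.
#' @return An object of class `genotype_table`: a list with elements
#'   `markers`, `lines` and `alleles`.
#' @seealso [read_genotype_table()], [delineate_d2_blocks()]
#' @export
genotype_table <- function(markers, alleles) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chrom", "pos") %in% names(markers)),
            is.matrix(alleles), is.character(alleles))
  markers <- data.frame(marker_id = as.character(markers$marker_id),
                        chrom = as.character(markers$chrom),
                        pos = as.integer(markers$pos),
                        stringsAsFactors = FALSE)
  if (nrow(markers) != nrow(alleles))
    stop("alleles must have one row per marker")
  if (is.null(colnames(alleles)))
    stop("alleles must carry line identifiers as column names")
  if (anyDuplicated(colnames(alleles)))
    stop("duplicated line identifiers")
  if (anyDuplicated(markers$marker_id))
    stop("duplicated marker_id")
  if (any(markers$pos < 1L)) stop("marker positions must be >= 1")
  bad <- !(alleles %in% c("B", "D", "H", "U"))
  if (any(bad))
    stop("allele codes must be one of B, D, H, U (got e.g. '",
         alleles[which(bad)[1L]], "')")
  key <- paste(markers$chrom, markers$pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicated marker coordinates: ", d)
  }
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      i <- which(diff(p) <= 0)[1L] + 1L
      bad_id <- markers$marker_id[markers$chrom == ch][i]
      stop("marker positions not strictly increasing on chrom ", ch,
           " at marker ", bad_id)
    }
  }
  rownames(alleles) <- markers$marker_id
  structure(list(markers = markers,
                 lines = colnames(alleles),
                 alleles = alleles),
            class = "genotype_table")
}

#' @exportS3Method base::print
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$markers), "markers x", length(x$lines),
      "lines on", length(unique(x$markers$chrom)), "chromosome(s)\n")
  tab <- table(factor(x$alleles, levels = c("B", "D", "H", "U")))
  cat("allele calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# map raw panel tokens onto the four allele codes; anything unrecognized is U
normalize_allele_tokens <- function(x) {
  up <- toupper(trimws(x))
  out <- rep("U", length(up))
  out[up %in% c("B", "B6")] <- "B"
  out[up %in% c("D", "D2")] <- "D"
  out[up == "H"] <- "H"
  n_unknown <- sum(out == "U" & !(up %in% c("U", "")) & !is.na(x))
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Read a delimited panel genotype table
#'
#' Reads a GeneNetwork-style genotype sheet re-expressed as delimited text:
#' a header row naming the lines and one row per marker with marker id,
#' chromosome and position followed by one allele column per line. Allele
#' tokens are mapped case-insensitively (`B`/`B6` -> B, `D`/`D2` -> D,
#' `H` -> H); unrecognized tokens become `U` and their count is reported via
#' a message (panel sheets contain assorted tokens).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default, sniffed by delimiter), `"tsv"` or
#'   `"csv"`.
#' @return A [genotype_table()].
#' @details The first three columns are taken as marker id, chromosome and
#'   position; columns named (case-insensitively) `marker`/`marker_id`/
#'   `locus`, `chr`/`chrom`/`chromosome` and `pos`/`position` are recognized
#'   in any order. Duplicate `(chrom, pos)` pairs and non-monotone positions
#'   are hard errors.
#' @export
read_genotype_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(dialect, auto = "auto", tsv = "\t", csv = ",")
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = FALSE)
  nm <- tolower(names(dt))
  id_col <- which(nm %in% c("marker", "marker_id", "locus", "id"))[1L]
  chrom_col <- which(nm %in% c("chr", "chrom", "chromosome"))[1L]
  pos_col <- which(nm %in% c("pos", "position", "bp"))[1L]
  if (is.na(id_col) || is.na(chrom_col) || is.na(pos_col)) {
    id_col <- 1L; chrom_col <- 2L; pos_col <- 3L
  }
  line_cols <- setdiff(seq_along(dt), c(id_col, chrom_col, pos_col))
  if (length(line_cols) == 0L) stop("no line columns found in ", path)
  markers <- data.frame(marker_id = dt[[id_col]],
                        chrom = dt[[chrom_col]],
                        pos = suppressWarnings(as.integer(dt[[pos_col]])),
                        stringsAsFactors = FALSE)
  if (anyNA(markers$pos)) stop("non-numeric marker position in ", path)
  raw <- as.matrix(dt[line_cols])
  mapped <- normalize_allele_tokens(raw)
  n_unknown <- attr(mapped, "n_unknown")
  alleles <- matrix(mapped, nrow = nrow(raw),
                    dimnames = list(NULL, names(dt)[line_cols]))
  if (n_unknown > 0)
    message("read_genotype_table: ", n_unknown,
            " unrecognized allele token(s) mapped to U")
  gt <- genotype_table(markers, alleles)
  attr(gt, "n_unknown_tokens") <- n_unknown
  gt
}

#' Write a genotype table as tab-separated text
#'
#' @param table A [genotype_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  out <- data.frame(marker_id = table$markers$marker_id,
                    chrom = table$markers$chrom,
                    pos = table$markers$pos,
                    table$alleles, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
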