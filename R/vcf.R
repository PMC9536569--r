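#' Variant tables
#'
#' Variants are held as a plain `data.frame` with one row per ALT allele and
#' columns `chrom`, `pos` (1-based position of the first REF base, VCF
#' convention), `id`, `ref`, `alt` and `zygosity` (`"HOM"` or `"HET"`).
#' Sequences are normalized-VCF style: non-empty, no symbolic alleles.
#' Heterozygous labels in strain variant files are often quality flags
#' rather than genuine heterozygosity; they are carried through here and
#' only acted upon at genome-editing time (HET variants are never written
#' into a custom reference).
#'
#' @param chrom,pos,ref,alt,zygosity,id Column vectors (recycled where
#'   length 1). `id` defaults to `NA`.
#' @return A validated `data.frame` of variants, sorted by `(chrom, pos)`.
#' @export
variants <- function(chrom, pos, ref, alt, zygosity = "HOM", id = NA_character_) {
  n <- length(chrom)
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  id = rep_len(as.character(id), n),
                  ref = as.character(ref), alt = as.character(alt),
                  zygosity = rep_len(as.character(zygosity), n),
                  stringsAsFactors = FALSE)
  validate_variants(v)
  v[order(v$chrom, v$pos), , drop = FALSE]
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("chrom", "pos", "ref", "alt", "zygosity") %in% names(v)))
  if (any(v$pos < 1L)) stop("variant pos must be >= 1")
  if (any(nchar(v$ref) == 0L | nchar(v$alt) == 0L))
    stop("ref and alt must be non-empty")
  if (any(v$ref == v$alt)) stop("ref must differ from alt")
  if (any(!grepl("^[ACGTNacgtn]+$", v$ref)) ||
      any(!grepl("^[ACGTNacgtn]+$", v$alt)))
    stop("ref/alt must be sequences over A,C,G,T,N")
  if (any(!v$zygosity %in% c("HOM", "HET")))
    stop("zygosity must be HOM or HET")
  invisible(v)
}

#' Classify variants as SNV, insertion or deletion
#'
#' @param v A variants `data.frame`.
#' @return Character vector: `"snv"` (1 bp vs 1 bp), `"insertion"`
#'   (`nchar(alt) > nchar(ref)`), `"deletion"` (`nchar(ref) > nchar(alt)`),
#'   or `"mnv"` for equal-length multi-base substitutions.
#' @export
variant_type <- function(v) {
  lr <- nchar(v$ref); la <- nchar(v$alt)
  ifelse(lr == 1L & la == 1L, "snv",
         ifelse(la > lr, "insertion", ifelse(lr > la, "deletion", "mnv")))
}

#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file (site-only or single-sample) into a variants
#' `data.frame`, one row per ALT allele. Multi-allelic records are split.
#' Zygosity is `HET` when the first sample's `GT` carries two distinct
#' alleles, or when the record's `FILTER` column matches `het_filter`
#' (strain variant archives flag low-quality calls this way); otherwise
#' `HOM`. Symbolic or breakend ALT alleles (structural variants) are skipped
#' and counted; the count is attached as attribute `n_skipped_symbolic`.
#'
#' @param path Path to a `.vcf` (optionally gzipped) file.
#' @param het_filter Optional character vector of FILTER values that mark a
#'   record heterozygous / low quality regardless of GT.
#' @return Variants `data.frame` sorted by `(chrom, pos)`.
#' @export
read_vcf <- function(path, het_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vc)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  gt <- NULL
  if (ncol(vc@gt) >= 2L) {
    fmt <- vc@gt[, 1L]
    smp <- vc@gt[, 2L]
    gt <- vapply(seq_len(n), function(i) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1L]]
      vals <- strsplit(smp[i], ":", fixed = TRUE)[[1L]]
      j <- match("GT", keys)
      if (is.na(j) || j > length(vals)) NA_character_ else vals[j]
    }, character(1L))
  }
  out <- vector("list", n)
  n_symbolic <- 0L
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    # "]" first inside the class: POSIX bracket expressions take \ literally
    symbolic <- grepl("[][<>]", alts) | alts == "*"
    n_symbolic <- n_symbolic + sum(symbolic)
    alts <- alts[!symbolic]
    if (length(alts) == 0L) next
    het <- FALSE
    if (!is.null(gt) && !is.na(gt[i])) {
      al <- strsplit(gt[i], "[/|]")[[1L]]
      het <- length(unique(al[al != "."])) > 1L
    }
    if (!is.null(het_filter) && !is.na(fix[i, "FILTER"]) &&
        fix[i, "FILTER"] %in% het_filter) het <- TRUE
    k <- length(alts)
    out[[i]] <- data.frame(chrom = rep(unname(fix[i, "CHROM"]), k),
                           pos = rep(as.integer(fix[i, "POS"]), k),
                           id = rep(unname(fix[i, "ID"]), k),
                           ref = rep(unname(fix[i, "REF"]), k),
                           alt = unname(alts),
                           zygosity = rep(if (het) "HET" else "HOM", k),
                           stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, out)
  if (is.null(v))
    v <- data.frame(chrom = character(), pos = integer(), id = character(),
                    ref = character(), alt = character(),
                    zygosity = character(), stringsAsFactors = FALSE)
  if (nrow(v)) {
    validate_variants(v)
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    rownames(v) <- NULL
  }
  if (n_symbolic > 0)
    message("read_vcf: skipped ", n_symbolic,
            " symbolic/breakend ALT allele(s) (structural variants)")
  attr(v, "n_skipped_symbolic") <- n_symbolic
  v
}

#' Write variants as a single-sample VCF 4.2 file
#'
#' Zygosity is encoded in the sample GT field (`1/1` for HOM, `0/1` for
#' HET), so `read_vcf(write_vcf(v))` preserves `chrom`, `pos`, `ref`, `alt`
#' and `zygosity`.
#'
#' @param v Variants `data.frame`.
#' @param path Output path (plain text).
#' @param sample_name Sample column name.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(v, path, sample_name = "SAMPLE") {
  validate_variants(v)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  id <- ifelse(is.na(v$id) | v$id == "", ".", v$id)
  gt <- ifelse(v$zygosity == "HET", "0/1", "1/1")
  body <- paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "GT", gt,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
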