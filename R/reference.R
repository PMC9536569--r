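#' Build a custom (strain-specific) genome from a base genome and variants
#'
#' Splices homozygous variants into the base genome left-to-right,
#' reproducing the haploid "paternal"-style output of variant-aware
#' reference editors: unphased heterozygous variants are ignored (strain
#' archives use HET labels as low-quality flags), REF alleles that do not
#' match the base genome are skipped and counted rather than erroring
#' (variant-archive/assembly discordance is routine), and variants whose
#' footprint overlaps an already-applied variant are skipped (first wins in
#' coordinate order, ties by input order). Soft-mask case of unedited bases
#' is preserved; spliced-in bases take the ALT string's case verbatim.
#'
#' A liftover chain between the two coordinate systems is built alongside:
#' chain blocks are broken only at applied indels (SNVs are mismatches
#' inside blocks); the shared REF/ALT prefix of a normalized indel stays
#' inside the preceding block.
#'
#' @param genome A [genome()].
#' @param v Variants `data.frame`, sorted by `(chrom, pos)`.
#' @return List with elements `custom` (the edited [genome()]), `chain`
#'   (a [liftover_chain()], base -> custom) and `report` (an `edit_report`:
#'   counts of applied SNVs/insertions/deletions and of variants skipped as
#'   heterozygous, REF-mismatching or overlapping).
#' @examples
#' g <- genome(c(chr1 = "ACGT"))
#' r <- apply_variants(g, variants("chr1", 2, "C", "G"))
#' as.character(r$custom)  # "AGGT"
#' @export
apply_variants <- function(genome, v) {
  if (!inherits(genome, "genome")) genome <- genome(genome)
  validate_variants(v)
  if (nrow(v)) {
    unknown <- setdiff(unique(v$chrom), names(genome))
    if (length(unknown)) stop("variant chrom not in genome: ", unknown[1L])
    o <- order(match(v$chrom, unique(v$chrom)))
    for (ch in unique(v$chrom)) {
      p <- v$pos[v$chrom == ch]
      if (is.unsorted(p)) stop("variants not sorted by (chrom, pos)")
    }
  }
  report <- list(n_applied_snv = 0L, n_applied_ins = 0L, n_applied_del = 0L,
                 n_skipped_het = 0L, n_skipped_ref_mismatch = 0L,
                 n_skipped_overlap = 0L, n_input = nrow(v))
  custom <- character(length(genome))
  names(custom) <- names(genome)
  entries <- vector("list", length(genome))
  applied_idx <- logical(nrow(v))

  for (si in seq_along(genome)) {
    nm <- names(genome)[si]
    seq <- genome[[si]]
    L <- nchar(seq)
    vs <- which(v$chrom == nm)
    pieces <- character(0)
    cur <- 0L            # ref bases consumed (0-based)
    applied_end <- 0L    # end (exclusive, 0-based) of last applied footprint
    r0 <- 0L; c0 <- 0L   # current chain block starts (ref / custom)
    custom_at_r0 <- 0L   # custom length corresponding to ref position r0
    blocks <- list()
    for (i in vs) {
      lr <- nchar(v$ref[i]); la <- nchar(v$alt[i])
      p0 <- v$pos[i] - 1L
      if (v$zygosity[i] == "HET") {
        report$n_skipped_het <- report$n_skipped_het + 1L
        next
      }
      if (p0 < applied_end && applied_end > 0L) {
        report$n_skipped_overlap <- report$n_skipped_overlap + 1L
        next
      }
      if (p0 + lr > L ||
          toupper(substr(seq, p0 + 1L, p0 + lr)) != toupper(v$ref[i])) {
        report$n_skipped_ref_mismatch <- report$n_skipped_ref_mismatch + 1L
        next
      }
      # apply
      ty <- if (lr == la) "snv" else if (la > lr) "ins" else "del"
      report[[paste0("n_applied_", ty)]] <- report[[paste0("n_applied_", ty)]] + 1L
      applied_idx[i] <- TRUE
      pieces <- c(pieces, substr(seq, cur + 1L, p0), v$alt[i])
      cur <- p0 + lr
      applied_end <- p0 + lr
      if (lr != la) {
        k <- common_prefix_len(toupper(v$ref[i]), toupper(v$alt[i]))
        blk_len <- (p0 + k) - r0
        if (blk_len > 0L)
          blocks[[length(blocks) + 1L]] <-
            c(ref_start = r0, custom_start = c0, length = blk_len)
        # custom coordinate after splicing the full ALT
        c0 <- c0 + (p0 - r0) + la
        r0 <- p0 + lr
      }
    }
    pieces <- c(pieces, substr(seq, cur + 1L, L))
    cust_seq <- paste(pieces, collapse = "")
    custom[[si]] <- cust_seq
    Lc <- nchar(cust_seq)
    if (L - r0 > 0L)
      blocks[[length(blocks) + 1L]] <-
        c(ref_start = r0, custom_start = c0, length = L - r0)
    bdf <- if (length(blocks)) {
      as.data.frame(do.call(rbind, blocks))
    } else {
      data.frame(ref_start = integer(), custom_start = integer(),
                 length = integer())
    }
    entries[[si]] <- list(ref_name = nm, ref_len = L, custom_name = nm,
                          custom_len = Lc, blocks = bdf)
  }
  out_genome <- genome(custom)
  res <- list(custom = out_genome, chain = liftover_chain(entries),
              report = structure(report, class = "edit_report"))
  attr(res, "applied") <- applied_idx
  res
}

#' @exportS3Method base::print
print.edit_report <- function(x, ...) {
  cat("edit_report:", x$n_input, "input variant(s)\n")
  cat("  applied: snv", x$n_applied_snv, "| ins", x$n_applied_ins,
      "| del", x$n_applied_del, "\n")
  cat("  skipped: het", x$n_skipped_het, "| ref mismatch",
      x$n_skipped_ref_mismatch, "| overlap", x$n_skipped_overlap, "\n")
  invisible(x)
}

#' Lift annotation features through a chain
#'
#' Start and end of each feature are lifted independently (forward
#' direction); a feature either of whose endpoints falls in a deleted
#' region is dropped and returned separately. Strand, attributes and all
#' other columns are unchanged.
#'
#' @param chain A [liftover_chain()].
#' @param features Feature `data.frame` (see [read_gtf()]).
#' @return List with `lifted` and `dropped` feature `data.frame`s.
#' @export
lift_annotation <- function(chain, features) {
  stopifnot(inherits(chain, "liftover_chain"), is.data.frame(features))
  if (nrow(features) == 0L)
    return(list(lifted = features, dropped = features))
  new_start <- rep(NA_integer_, nrow(features))
  new_end <- rep(NA_integer_, nrow(features))
  for (ch in unique(features$seqname)) {
    idx <- which(features$seqname == ch)
    new_start[idx] <- lift_positions(chain, ch, features$start[idx], "forward")
    new_end[idx] <- lift_positions(chain, ch, features$end[idx], "forward")
  }
  ok <- !is.na(new_start) & !is.na(new_end)
  lifted <- features[ok, , drop = FALSE]
  lifted$start <- new_start[ok]
  lifted$end <- new_end[ok]
  stopifnot(all(lifted$start <= lifted$end))
  dropped <- features[!ok, , drop = FALSE]
  rownames(lifted) <- rownames(dropped) <- NULL
  list(lifted = lifted, dropped = dropped)
}

#' Build and write the reference files for one line
#'
#' Composes [apply_variants()] and [lift_annotation()] and writes the three
#' deliverables of a per-line custom reference: FASTA genome, lifted GTF and
#' UCSC chain file.
#'
#' @param genome Base [genome()].
#' @param features Annotation `data.frame` (see [read_gtf()]).
#' @param v Variants to splice in.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix (e.g. the line id).
#' @return List with `fasta`, `gtf`, `chain` paths, the `report`, and the
#'   `dropped` features.
#' @export
build_line_reference <- function(genome, features, v, out_dir,
                                 prefix = "custom") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ed <- apply_variants(genome, v)
  ann <- lift_annotation(ed$chain, features)
  fasta <- file.path(out_dir, paste0(prefix, ".fa"))
  gtf <- file.path(out_dir, paste0(prefix, ".gtf"))
  chain <- file.path(out_dir, paste0(prefix, ".chain"))
  write_fasta(ed$custom, fasta)
  write_gtf(ann$lifted, gtf)
  write_chain(ed$chain, chain)
  list(fasta = fasta, gtf = gtf, chain = chain,
       report = ed$report, dropped = ann$dropped)
}
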