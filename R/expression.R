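#' Counts per million on raw library sizes
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Matrix of cpm values (no prior, no normalization factors).
#' @export
cpm_raw <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Keeps genes whose cpm (computed on raw library sizes, before
#' normalization) is strictly above `min_cpm` in at least `min_samples`
#' samples. The strictness follows the "cpm above 0.5" wording: a gene at
#' exactly the threshold everywhere is removed.
#'
#' @param counts Genes x samples count matrix.
#' @param min_cpm Threshold (default 0.5).
#' @param min_samples Minimum number of samples above threshold
#'   (default 20, the panel-scale convention for 66-sample tissues).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 0.5, min_samples = 20) {
  counts <- as.matrix(counts)
  if (min_samples > ncol(counts))
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(counts), ")")
  keep <- rowSums(cpm_raw(counts) > min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values between-sample normalization
#' (Robinson & Oshlack 2010), computed via edgeR. The reference sample is
#' the one whose 75th-percentile cpm is closest to the mean 75th
#' percentile; per sample, over genes nonzero in both sample and reference,
#' the 30% most extreme M values (15% per tail) and 5% most extreme A
#' values (2.5% per tail) are trimmed and the surviving M are averaged with
#' inverse asymptotic-binomial-variance weights. Factors are rescaled to
#' geometric mean 1.
#'
#' A sample sharing no nonzero gene with the reference gets factor 1 with a
#' warning.
#'
#' @param counts Genes x samples count matrix (>= 2 samples, each with at
#'   least one nonzero gene).
#' @return Numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("each sample needs at least one nonzero gene")
  f75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  shared <- colSums(counts > 0 & counts[, ref] > 0)
  bad <- which(shared == 0L)
  f <- rep(1, ncol(counts))
  ok <- setdiff(seq_len(ncol(counts)), bad)
  if (length(bad)) {
    warning("sample(s) share no nonzero gene with the TMM reference; ",
            "factor set to 1: ", paste(colnames(counts)[bad], collapse = ", "))
    ref_ok <- match(ref, ok)
    f[ok] <- edgeR::calcNormFactors(counts[, ok, drop = FALSE],
                                    method = "TMM", refColumn = ref_ok)
  } else {
    f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalized log2-cpm expression
#'
#' `log2((count + 0.5) / (libsize * factor + 1) * 1e6)` — the damped
#' log-cpm transform with a 0.5 count prior and effective (TMM-scaled)
#' library sizes.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample normalization factors (default
#'   [tmm_factors()]).
#' @return Object of class `normalized_matrix`: list with `E` (log2-cpm
#'   matrix), `factors`, `lib_sizes`.
#' @export
log_cpm <- function(counts, factors = tmm_factors(counts)) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  eff <- lib * factors
  E <- log2(sweep(counts + 0.5, 2L, eff + 1, "/") * 1e6)
  structure(list(E = E, factors = factors, lib_sizes = lib),
            class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$E), "genes x", ncol(x$E), "samples",
      "(log2-cpm, TMM factors geometric mean",
      format(exp(mean(log(x$factors)))), ")\n")
  invisible(x)
}

#' Restrict two count matrices to a shared, unambiguous gene set
#'
#' Genes duplicated within either matrix are dropped entirely (an
#' ambiguous name cannot be matched across annotations), then the
#' intersection is taken; both outputs share the identical gene order.
#'
#' @param a,b Genes x samples matrices with gene rownames.
#' @return List with the two reduced matrices `a` and `b`.
#' @export
harmonize_gene_sets <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ga <- rownames(a); gb <- rownames(b)
  if (is.null(ga) || is.null(gb)) stop("matrices must have gene rownames")
  ga_keep <- setdiff(ga, ga[duplicated(ga)])
  gb_keep <- setdiff(gb, gb[duplicated(gb)])
  common <- intersect(ga_keep, gb_keep)
  if (length(common) == 0L) stop("no genes in common after deduplication")
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}
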