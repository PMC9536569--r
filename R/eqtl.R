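#' Local (cis) eQTL scan with permutation adjustment
#'
#' For every gene, markers within `window` bp of the transcription start
#' site on the gene's chromosome are tested by simple linear regression of
#' expression on allele dose, coded 0 for the reference-strain (B) allele
#' and 1 for the donor-strain (D) allele; `H`/`U` genotypes are excluded
#' per marker (heterozygous panel calls flag uncertainty, and imputing them
#' would dilute the dose). With this coding a negative slope means the B
#' allele increases expression. The best marker per gene is the one with
#' the smallest nominal p, ties broken by distance to the TSS and then by
#' marker id.
#'
#' Multiple-marker testing is adjusted by phenotype permutation: expression
#' values are permuted across lines `n_perm` times (seeded, so runs are
#' bit-reproducible) and the adjusted p-value is
#' `(1 + #\{permuted best p <= observed best p\}) / (1 + n_perm)`. The same
#' seeded permutations are reused for every gene. Gene-level FDR control
#' uses Storey q-values ([storey_qvalues()]); a gene is significant at
#' `qvalue < fdr`.
#'
#' Genes with no candidate marker are reported with `NA` results and
#' `significant = FALSE`; they stay in the expressed-gene denominator of
#' [percent_significant()] and [eqtl_skewness()].
#'
#' @param expr Genes x lines matrix of normalized expression (e.g. the `E`
#'   component of [log_cpm()] averaged or subset to one sample per line);
#'   column names must be line ids of `geno`.
#' @param geno A [genotype_table()].
#' @param tss `data.frame` with `gene_id`, `chrom`, `tss` (see
#'   [gene_tss()]).
#' @param window Half-width of the cis window in bp (default 2 Mb).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Permutation seed (default 1).
#' @param min_lines Minimum number of lines with a usable (B/D) genotype
#'   for a marker to enter the scan (default 8).
#' @param d_allele Allele coded as dose 1 (`"D"`, the default; set `"B"` to
#'   swap the coding, which negates every slope).
#' @param fdr Gene-level FDR threshold (default 0.05).
#' @return `data.frame` with one row per gene: `gene`, `chrom`, `tss`,
#'   `marker`, `dist`, `slope`, `n_lines`, `n_markers`, `p_nominal`,
#'   `p_perm`, `qvalue`, `significant`.
#' @export
eqtl_scan <- function(expr, geno, tss, window = 2e6, n_perm = 1000,
                      seed = 1, min_lines = 8, d_allele = c("D", "B"),
                      fdr = 0.05) {
  d_allele <- match.arg(d_allele)
  stopifnot(inherits(geno, "genotype_table"), is.matrix(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr needs gene rownames and line colnames")
  lines <- intersect(colnames(expr), geno$lines)
  if (length(lines) < 3L) stop("fewer than 3 lines shared with genotypes")
  genes <- intersect(rownames(expr), tss$gene_id)
  if (length(genes) == 0L) stop("no expressed gene has a TSS entry")
  genes <- rownames(expr)[rownames(expr) %in% genes]  # keep expr order
  tssm <- tss[match(genes, tss$gene_id), , drop = FALSE]
  Y <- expr[genes, lines, drop = FALSE]
  n <- length(lines)

  # allele dose per marker x line
  al <- geno$alleles[, lines, drop = FALSE]
  dose <- matrix(NA_real_, nrow(al), ncol(al), dimnames = dimnames(al))
  dose[al == "B"] <- if (d_allele == "D") 0 else 1
  dose[al == "D"] <- if (d_allele == "D") 1 else 0

  perms <- NULL
  if (n_perm > 0L)
    perms <- with_seed(seed, replicate(n_perm, sample.int(n)))

  res <- data.frame(gene = genes, chrom = tssm$chrom, tss = tssm$tss,
                    marker = NA_character_, dist = NA_integer_,
                    slope = NA_real_, n_lines = NA_integer_,
                    n_markers = 0L, p_nominal = NA_real_, p_perm = NA_real_,
                    stringsAsFactors = FALSE)

  for (ch in unique(tssm$chrom)) {
    g_idx <- which(tssm$chrom == ch)
    m_idx <- which(geno$markers$chrom == ch)
    if (length(m_idx) == 0L) next
    D <- dose[m_idx, , drop = FALSE]
    Msk <- (!is.na(D)) * 1
    D0 <- D; D0[is.na(D0)] <- 0
    nm <- rowSums(Msk)
    usable <- nm >= max(min_lines, 3L)
    pos <- geno$markers$pos[m_idx]
    ids <- geno$markers$marker_id[m_idx]
    # per-gene candidate rows (usable markers inside the window)
    cand <- lapply(g_idx, function(gi) {
      which(usable & abs(pos - tssm$tss[gi]) <= window)
    })
    res$n_markers[g_idx] <- lengths(cand)
    has <- lengths(cand) > 0L
    if (!any(has)) next
    g_use <- g_idx[has]
    cand <- cand[has]
    Yg <- Y[g_use, , drop = FALSE]

    Sx <- as.numeric(D0 %*% rep(1, n))        # dose is 0/1 so Sxx == Sx
    denx <- nm * Sx - Sx^2
    dfm <- matrix(nm - 2, nrow = length(m_idx), ncol = length(g_use))

    marker_p <- function(Yt) {
      # Yt: lines x genes; center each gene for numerical stability (the
      # per-marker intercept absorbs any global shift, so results are
      # unchanged in exact arithmetic)
      Yt <- sweep(Yt, 2L, colMeans(Yt), "-")
      Sy <- Msk %*% Yt
      Syy <- Msk %*% (Yt * Yt)
      Sxy <- D0 %*% Yt
      num <- nm * Sxy - Sx * Sy
      deny <- nm * Syy - Sy^2
      den <- denx * deny
      r2 <- matrix(0, nrow(num), ncol(num))
      okd <- den > 0
      r2[okd] <- num[okd]^2 / den[okd]
      p <- matrix(1, nrow(num), ncol(num))
      lt1 <- okd & r2 < 1
      p[lt1] <- 2 * stats::pt(sqrt(r2[lt1] * dfm[lt1] / (1 - r2[lt1])),
                              df = dfm[lt1], lower.tail = FALSE)
      p[okd & r2 >= 1] <- 0
      p[dfm < 1] <- 1
      slope <- matrix(0, nrow(num), ncol(num))
      okx <- denx > 0
      slope[okx, ] <- num[okx, , drop = FALSE] / denx[okx]
      list(p = p, slope = slope)
    }

    obs <- marker_p(t(Yg))
    best_row <- integer(length(g_use))
    for (j in seq_along(g_use)) {
      rows <- cand[[j]]
      pj <- obs$p[rows, j]
      dj <- abs(pos[rows] - tssm$tss[g_use[j]])
      o <- order(pj, dj, ids[rows])[1L]
      best_row[j] <- rows[o]
      res$marker[g_use[j]] <- ids[rows[o]]
      res$dist[g_use[j]] <- dj[o]
      res$slope[g_use[j]] <- obs$slope[rows[o], j]
      res$n_lines[g_use[j]] <- nm[rows[o]]
      res$p_nominal[g_use[j]] <- pj[o]
    }
    best_obs <- res$p_nominal[g_use]

    if (n_perm > 0L) {
      exceed <- integer(length(g_use))
      Xg <- t(Yg)  # lines x genes
      for (k in seq_len(n_perm)) {
        pk <- marker_p(Xg[perms[, k], , drop = FALSE])$p
        for (j in seq_along(g_use)) {
          if (min(pk[cand[[j]], j]) <= best_obs[j])
            exceed[j] <- exceed[j] + 1L
        }
      }
      res$p_perm[g_use] <- (1 + exceed) / (1 + n_perm)
    }
  }

  if (n_perm > 0L) {
    res$qvalue <- NA_real_
    okq <- !is.na(res$p_perm)
    if (any(okq)) res$qvalue[okq] <- storey_qvalues(res$p_perm[okq])
    res$significant <- !is.na(res$qvalue) & res$qvalue < fdr
  }
  res
}

#' Single-gene local association scan
#'
#' Convenience wrapper around [eqtl_scan()] for one gene without
#' permutations.
#'
#' @param expr Named numeric vector of expression per line.
#' @param geno A [genotype_table()].
#' @param chrom,tss TSS coordinates of the gene.
#' @inheritParams eqtl_scan
#' @return List with `marker`, `slope`, `p`, `n_markers`, `n_lines`
#'   (`marker = NA` when no candidate marker exists).
#' @export
local_scan <- function(expr, geno, chrom, tss, window = 2e6, min_lines = 8,
                       d_allele = "D") {
  stopifnot(!is.null(names(expr)))
  m <- matrix(expr, nrow = 1L, dimnames = list("gene", names(expr)))
  r <- eqtl_scan(m, geno, data.frame(gene_id = "gene", chrom = chrom,
                                     tss = tss, stringsAsFactors = FALSE),
                 window = window, n_perm = 0L, min_lines = min_lines,
                 d_allele = d_allele)
  list(marker = r$marker, slope = r$slope, p = r$p_nominal,
       n_markers = r$n_markers, n_lines = r$n_lines)
}

#' Permutation-adjusted p-value for one gene
#'
#' @inheritParams local_scan
#' @inheritParams eqtl_scan
#' @return List with `marker`, `slope`, `p_nominal`, `p_perm`.
#' @export
permutation_adjust <- function(expr, geno, chrom, tss, window = 2e6,
                               n_perm = 1000, seed = 1, min_lines = 8,
                               d_allele = "D") {
  stopifnot(!is.null(names(expr)))
  m <- matrix(expr, nrow = 1L, dimnames = list("gene", names(expr)))
  r <- eqtl_scan(m, geno, data.frame(gene_id = "gene", chrom = chrom,
                                     tss = tss, stringsAsFactors = FALSE),
                 window = window, n_perm = n_perm, seed = seed,
                 min_lines = min_lines, d_allele = d_allele)
  list(marker = r$marker, slope = r$slope, p_nominal = r$p_nominal,
       p_perm = r$p_perm)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the lambda grid 0.05, 0.10, ...,
#' 0.95 via `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smooths the
#' estimates with a natural cubic spline (3 df) evaluated at lambda = 0.95
#' and clamps to (0, 1]; q-values are the step-up
#' `q_i = pi0 * min_\{p_j >= p_i\} (m p_j / rank_j)`. With fewer than
#' `min_genes` p-values, or a non-positive pi0 estimate, falls back to
#' Benjamini-Hochberg (`pi0 = 1`).
#'
#' @param p Numeric vector of p-values.
#' @param lambda Grid for pi0 estimation.
#' @param min_genes Minimum number of p-values for the spline estimate.
#' @return Vector of q-values, monotone non-decreasing in `p`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           min_genes = 100L) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- 1
  if (m >= min_genes) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    est <- stats::predict(sp, x = max(lambda))$y
    if (is.finite(est) && est > 0) pi0 <- min(est, 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- rank(p, ties.method = "max")
  q <- pi0 * m * p / ro
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

#' Percentage of expressed genes with a significant local eQTL
#'
#' `100 * #significant / n_expressed`. The denominator is all genes that
#' survived expression filtering, including genes without any local marker
#' (which can never be significant).
#'
#' @param results Result `data.frame` from [eqtl_scan()].
#' @param n_expressed Denominator (defaults to `nrow(results)`).
#' @return Percentage (numeric scalar).
#' @export
percent_significant <- function(results, n_expressed = nrow(results)) {
  if (NROW(results) == 0L || n_expressed <= 0) stop("empty eQTL results")
  100 * sum(results$significant, na.rm = TRUE) / n_expressed
}

#' Reference-bias skewness of local eQTL slopes
#'
#' `100 * (#significant with negative slope - #significant with positive
#' slope) / n_expressed`. Zero indicates no reference bias; positive values
#' indicate a reference-strain (B6) bias — more eQTLs where the B allele
#' increases expression — under the dose coding of [eqtl_scan()].
#' Significant results with slope exactly zero count in neither term.
#'
#' @inheritParams percent_significant
#' @return Percentage (numeric scalar).
#' @export
eqtl_skewness <- function(results, n_expressed = nrow(results)) {
  if (NROW(results) == 0L || n_expressed <= 0) stop("empty eQTL results")
  sig <- !is.na(results$significant) & results$significant
  neg <- sum(sig & results$slope < 0, na.rm = TRUE)
  pos <- sum(sig & results$slope > 0, na.rm = TRUE)
  100 * (neg - pos) / n_expressed
}

#' Compare local eQTL results obtained under two references
#'
#' Per gene (on the intersection of the two gene sets) three criteria are
#' evaluated: same best marker id; slope similar; q-value similar.
#' "Similar" means a relative difference below `tol` (default 5%):
#' `|a - b| / |mean(a, b)| < tol`. When the mean is zero the formula is
#' undefined; the convention here is similar only if `a == b == 0`
#' (opposite-sign equal-magnitude values are maximally dissimilar). A gene
#' is `unaffected` when all three criteria hold.
#'
#' @param a,b Result `data.frame`s from [eqtl_scan()] under the two
#'   references.
#' @param tol Relative-difference threshold (default 0.05).
#' @return List with `genes` (per-gene flags), `venn` (named counts over
#'   the 8 combinations of the three criteria) and `pct_unaffected`.
#' @export
compare_eqtls <- function(a, b, tol = 0.05) {
  common <- intersect(a$gene, b$gene)
  if (length(common) == 0L) stop("no genes in common")
  a <- a[match(common, a$gene), , drop = FALSE]
  b <- b[match(common, b$gene), , drop = FALSE]
  rel_similar <- function(x, y) {
    m <- (x + y) / 2
    ifelse(is.na(x) | is.na(y), FALSE,
           ifelse(m == 0, x == 0 & y == 0, abs(x - y) / abs(m) < tol))
  }
  same_marker <- !is.na(a$marker) & !is.na(b$marker) & a$marker == b$marker
  slope_similar <- rel_similar(a$slope, b$slope)
  qvalue_similar <- rel_similar(a$qvalue, b$qvalue)
  unaffected <- same_marker & slope_similar & qvalue_similar
  genes <- data.frame(gene = common, same_marker = same_marker,
                      slope_similar = slope_similar,
                      qvalue_similar = qvalue_similar,
                      unaffected = unaffected, stringsAsFactors = FALSE)
  combo <- paste0(ifelse(same_marker, "marker", ""),
                  ifelse(slope_similar, "+slope", ""),
                  ifelse(qvalue_similar, "+qvalue", ""))
  combo <- sub("^\\+", "", combo)
  combo[combo == ""] <- "none"
  lv <- c("marker+slope+qvalue", "marker+slope", "marker+qvalue",
          "slope+qvalue", "marker", "slope", "qvalue", "none")
  venn <- table(factor(combo, levels = lv))
  list(genes = genes, venn = c(venn),
       pct_unaffected = 100 * mean(unaffected))
}
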