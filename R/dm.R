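#' Differential-mapping test between two references
#'
#' Tests, gene by gene, whether the same samples quantified against two
#' different references yield different expression. Because the two groups
#' contain exactly the same samples (only the mapping reference differs),
#' the test is a paired moderated-t on the per-sample log2-cpm differences
#' `d_i = b_i - a_i`: the gene-wise variances are shrunk toward a common
#' prior fitted by closed-form moment matching of `log s^2` to a scaled
#' chi-square model (Smyth 2004), giving moderated variance
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` with `d = n - 1` residual degrees
#' of freedom, `t = mean * sqrt(n) / s~` on `d0 + d` degrees of freedom.
#' P-values are BH-adjusted across genes; a gene is flagged DM at adjusted
#' p < 0.05.
#'
#' @param a,b `normalized_matrix` objects (see [log_cpm()]) or log2-cpm
#'   matrices with identical genes and samples in identical order; pairing
#'   is by column.
#' @param prior_df Optional fixed prior degrees of freedom `d0`; `NULL`
#'   (default) estimates `d0` and `s0^2` from the data. `prior_df = 0`
#'   recovers the ordinary paired t-test.
#' @param fdr DM flag threshold on the BH-adjusted p-value.
#' @return `data.frame` with per-gene `gene`, `logFC` (mean of b - a),
#'   `t`, `df`, `p`, `p_adj`, `dm`; the fitted `d0` and `s0_sq` are
#'   attached as attributes.
#' @export
differential_mapping <- function(a, b, prior_df = NULL, fdr = 0.05) {
  A <- if (inherits(a, "normalized_matrix")) a$E else as.matrix(a)
  B <- if (inherits(b, "normalized_matrix")) b$E else as.matrix(b)
  if (!identical(dim(A), dim(B)))
    stop("matrices must have identical dimensions")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("gene sets/order differ; harmonize first")
  if (!is.null(colnames(A)) && !is.null(colnames(B)) &&
      !identical(colnames(A), colnames(B)))
    stop("sample sets/order differ")
  n <- ncol(A)
  if (n < 3L) stop("need at least 3 sample pairs")
  d <- B - A
  mean_d <- rowMeans(d)
  s2 <- rowSums((d - mean_d)^2) / (n - 1L)
  df_resid <- n - 1L
  if (is.null(prior_df)) {
    fit <- fit_scaled_chisq(s2, df_resid)
  } else {
    fit <- list(d0 = prior_df,
                s0_sq = if (prior_df > 0) mean(s2) else 0)
  }
  d0 <- fit$d0; s0_sq <- fit$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  tt <- mean_d * sqrt(n) / sqrt(s2_post)
  tt[s2_post == 0 & mean_d == 0] <- 0
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(abs(tt), df = df_total, lower.tail = FALSE)
  p[is.nan(tt)] <- 1        # degenerate: zero variance, zero mean
  p[is.infinite(tt)] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(A) %||% as.character(seq_len(nrow(A))),
                    logFC = mean_d, t = tt, df = df_total, p = p,
                    p_adj = p_adj, dm = p_adj < fdr,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Moment-matching fit of gene-wise variances to a scaled chi-square prior
#'
#' Closed-form estimators of the prior degrees of freedom `d0` and prior
#' variance `s0^2` from the first two moments of `log(s^2)` (Smyth 2004):
#' with `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`, solve
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` (via a Newton trigamma
#' inverse) and `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
#' Non-positive variances are excluded from the fit; if the corrected
#' variance of `e` is non-positive, `d0 = Inf` (complete shrinkage).
#'
#' @param s2 Gene-wise sample variances.
#' @param df Residual degrees of freedom of each `s2`.
#' @return List with `d0` and `s0_sq`.
#' @export
fit_scaled_chisq <- function(s2, df) {
  pos <- s2[s2 > 0 & is.finite(s2)]
  if (length(pos) < 2L)
    return(list(d0 = Inf, s0_sq = if (length(pos)) mean(pos) else 0))
  e <- log(pos) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x  (x > 0)
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
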