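#' End-to-end local eQTL analysis from raw counts
#'
#' Composes the standard downstream chain: low-expression filtering
#' ([filter_low_expression()]), TMM normalization ([tmm_factors()],
#' [log_cpm()]) and the permutation-based local eQTL scan ([eqtl_scan()]),
#' then summarizes with [percent_significant()] and [eqtl_skewness()].
#'
#' @param counts Genes x lines count matrix (one sample per line).
#' @param geno A [genotype_table()].
#' @param tss TSS table ([gene_tss()]).
#' @param min_cpm,min_samples Filtering parameters.
#' @inheritParams eqtl_scan
#' @return List with `results` (the [eqtl_scan()] table), `n_expressed`,
#'   `pct_significant`, `skewness` and the `normalized` expression.
#' @export
eqtl_pipeline <- function(counts, geno, tss, min_cpm = 0.5,
                          min_samples = 20, window = 2e6, n_perm = 1000,
                          seed = 1, min_lines = 8, fdr = 0.05) {
  f <- filter_low_expression(counts, min_cpm = min_cpm,
                             min_samples = min_samples)
  norm <- log_cpm(f)
  res <- eqtl_scan(norm$E, geno, tss, window = window, n_perm = n_perm,
                   seed = seed, min_lines = min_lines, fdr = fdr)
  list(results = res, n_expressed = nrow(f),
       pct_significant = percent_significant(res, nrow(f)),
       skewness = eqtl_skewness(res, nrow(f)),
       normalized = norm)
}
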