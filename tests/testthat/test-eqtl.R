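# shared toy panel: 1 chromosome, deterministic-ish mosaic genotypes
toy_panel <- function(n_markers = 20, n_lines = 33, seed = 1) {
  g <- simulate_genome(seed, n_chrom = 1, chrom_len = 1e6)
  simulate_panel_genotypes(g, n_markers_per_chrom = n_markers,
                           n_lines = n_lines, seed = seed + 1)
}

test_that("a perfect dose-expression relation gives slope 1 at the marker", {
  geno <- toy_panel(seed = 501)
  mid <- 10L
  dose <- as.numeric(geno$alleles[mid, ] == "D")
  names(dose) <- geno$lines
  r <- local_scan(dose, geno, chrom = "chr1",
                  tss = geno$markers$pos[mid])
  expect_equal(r$marker, geno$markers$marker_id[mid])
  expect_equal(r$slope, 1)
  expect_lt(r$p, 1e-12)
})

test_that("constant expression yields the degenerate slope 0 / p 1", {
  geno <- toy_panel(seed = 502)
  expr <- rep(3.7, length(geno$lines))
  names(expr) <- geno$lines
  r <- local_scan(expr, geno, chrom = "chr1", tss = 5e5)
  expect_equal(r$slope, 0)
  expect_equal(r$p, 1)
})

test_that("a gene with no local marker returns an empty result", {
  geno <- toy_panel(seed = 503)
  expr <- rnorm(length(geno$lines))
  names(expr) <- geno$lines
  r <- local_scan(expr, geno, chrom = "chrZ", tss = 100)
  expect_true(is.na(r$marker))
  expect_equal(r$n_markers, 0L)
})

test_that("the scan is invariant to affine rescaling of expression", {
  geno <- toy_panel(seed = 504)
  set.seed(504)
  expr <- rnorm(length(geno$lines))
  names(expr) <- geno$lines
  r1 <- local_scan(expr, geno, "chr1", 5e5)
  r2 <- local_scan(3 * expr + 10, geno, "chr1", 5e5)
  expect_equal(r2$marker, r1$marker)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  expect_equal(r2$slope, 3 * r1$slope, tolerance = 1e-12)
})

test_that("planted effects are recovered at or in tight LD with the causal marker", {
  # Markers on a recombination mosaic are in strong LD (adjacent markers
  # share their genotype with prob 1 - switch_prob), so the best marker can
  # land on a near-perfect proxy of the causal one; recovery is therefore
  # scored both as an exact hit and as dose correlation with the truth.
  set.seed(505)
  n_sim <- 40L
  exact <- 0L; proxy <- 0L
  for (i in seq_len(n_sim)) {
    geno <- toy_panel(seed = 5050 + i)
    m <- sample.int(nrow(geno$markers), 1)
    dose <- as.numeric(geno$alleles[m, ] == "D")
    expr <- 1.5 * dose + rnorm(length(dose))  # beta/sigma = 1.5
    names(expr) <- geno$lines
    r <- local_scan(expr, geno, "chr1", geno$markers$pos[m])
    if (identical(r$marker, geno$markers$marker_id[m])) exact <- exact + 1L
    best_dose <- as.numeric(geno$alleles[r$marker, ] == "D")
    if (abs(cor(best_dose, dose)) > 0.7) proxy <- proxy + 1L
  }
  expect_gt(exact / n_sim, 0.5)
  expect_gt(proxy / n_sim, 0.9)
})

test_that("permutation adjustment floors at 1/(n_perm+1) and is reproducible", {
  geno <- toy_panel(seed = 506)
  mid <- 7L
  dose <- as.numeric(geno$alleles[mid, ] == "D")
  names(dose) <- geno$lines
  r <- permutation_adjust(dose, geno, "chr1", geno$markers$pos[mid],
                          n_perm = 200, seed = 9)
  expect_equal(r$p_perm, 1 / 201)
  r2 <- permutation_adjust(dose, geno, "chr1", geno$markers$pos[mid],
                           n_perm = 200, seed = 9)
  expect_identical(r, r2)  # bit-reproducible under a fixed seed
})

test_that("with a single local marker the adjusted p tracks the nominal p", {
  set.seed(507)
  geno <- toy_panel(n_markers = 1, seed = 507)
  diffs <- vapply(1:30, function(i) {
    expr <- rnorm(length(geno$lines))
    names(expr) <- geno$lines
    r <- permutation_adjust(expr, geno, "chr1", geno$markers$pos[1],
                            n_perm = 400, seed = i)
    r$p_perm - r$p_nominal
  }, numeric(1))
  # Monte-Carlo error of a binomial proportion at n_perm = 400
  expect_lt(mean(abs(diffs)), 3 / sqrt(400))
})

test_that("q-values: degenerate cases, BH fallback, monotonicity", {
  expect_equal(storey_qvalues(rep(1, 200)), rep(1, 200))
  set.seed(508)
  p <- runif(500)
  # forcing the fallback (min_genes above m) gives exactly BH
  expect_equal(storey_qvalues(p, min_genes = 1000),
               p.adjust(p, "BH"), tolerance = 1e-12)
  q <- storey_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))  # pi0 <= 1
})

test_that("q-value FDR is controlled on a signal/null mixture", {
  set.seed(509)
  fdp <- vapply(1:5, function(i) {
    m <- 5000
    null <- runif(0.8 * m)
    sig <- rbeta(0.2 * m, 0.1, 1)
    p <- c(null, sig)
    truth <- rep(c(TRUE, FALSE), c(length(null), length(sig)))
    q <- storey_qvalues(p)
    called <- q < 0.05
    if (!any(called)) return(0)
    sum(called & truth) / sum(called)
  }, numeric(1))
  expect_lte(mean(fdp), 0.08)
})

test_that("summary percentages follow their defining arithmetic", {
  res <- data.frame(gene = paste0("g", 1:10),
                    slope = c(-2, -1, -0.5, 0.5, 1, 2, -3, 3, 0, 1),
                    significant = c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(percent_significant(res, 1000), 0.6)
  expect_equal(percent_significant(res), 60)
  # 3 negative vs 3 positive significant slopes: symmetric, skewness 0
  expect_equal(eqtl_skewness(res), 0)
  res$significant[4:6] <- FALSE  # now 3 negative, 0 positive of 10 expressed
  expect_equal(eqtl_skewness(res), 30)
  expect_equal(eqtl_skewness(res, 100), 3)
  expect_error(percent_significant(res[0, ]), "empty")
})

test_that("swapping the allele coding negates slopes and skewness exactly", {
  st <- simulate_bxd_study(510, "unbiased", n_genes = 60)
  f <- filter_low_expression(st$counts_custom, min_samples = 20)
  E <- log_cpm(f)$E
  rd <- eqtl_scan(E, st$geno, st$tss, n_perm = 100, seed = 2)
  rb <- eqtl_scan(E, st$geno, st$tss, n_perm = 100, seed = 2, d_allele = "B")
  expect_equal(rb$slope, -rd$slope, tolerance = 1e-12)
  expect_equal(rb$p_nominal, rd$p_nominal, tolerance = 1e-12)
  expect_identical(rb$marker, rd$marker)
  expect_identical(rb$significant, rd$significant)
  expect_equal(eqtl_skewness(rb), -eqtl_skewness(rd), tolerance = 1e-12)
})

test_that("eQTL comparison flags follow the 5% relative-difference rule", {
  base <- data.frame(gene = c("g1", "g2", "g3"),
                     marker = c("m1", "m2", "m3"),
                     slope = c(1.00, 1.00, -1.00),
                     qvalue = c(0.01, 0.02, 0.03),
                     stringsAsFactors = FALSE)
  # identical inputs: everything unaffected, all mass in the triple overlap
  cmp <- compare_eqtls(base, base)
  expect_equal(cmp$pct_unaffected, 100)
  expect_equal(unname(cmp$venn["marker+slope+qvalue"]), 3L)
  expect_equal(sum(cmp$venn), 3L)
  # 1.00 vs 1.04 -> 0.0392 < 0.05 similar; 1.00 vs 1.06 -> 0.0583 dissimilar
  other <- base
  other$slope <- c(1.04, 1.06, -1.00)
  cmp2 <- compare_eqtls(base, other)
  expect_equal(cmp2$genes$slope_similar, c(TRUE, FALSE, TRUE))
  # zero-mean convention: opposite-sign equal-magnitude slopes dissimilar
  flip <- base; flip$slope <- c(-1.00, 1.00, 1.00)
  cmp3 <- compare_eqtls(base, flip)
  expect_equal(cmp3$genes$slope_similar, c(FALSE, TRUE, FALSE))
  both0 <- base; both0$slope <- 0
  expect_equal(compare_eqtls(both0, both0)$genes$slope_similar,
               rep(TRUE, 3))
})
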