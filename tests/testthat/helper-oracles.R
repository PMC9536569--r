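# Independent oracles and random-fixture builders shared across tests.
# These deliberately avoid the package's internal helpers: each oracle is a
# separate straight-line code path against which the implementation is
# checked.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force imputation oracle: enumerate D runs by linear scan, then test
# every variant against every block with explicit interval arithmetic.
oracle_impute_line <- function(table, line, v) {
  blocks <- list()
  for (ch in unique(table$markers$chrom)) {
    idx <- which(table$markers$chrom == ch)
    al <- table$alleles[idx, line]
    pos <- table$markers$pos[idx]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= 2)
        blocks[[length(blocks) + 1]] <<- c(ch = ch, s = pos[run[1]],
                                           e = pos[run[length(run)]])
    }
    for (i in seq_along(al)) {
      if (al[i] == "D") run <- c(run, i)
      else { flush(run); run <- integer(0) }
    }
    flush(run)
  }
  if (nrow(v) == 0) return(v)
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    vs <- v$pos[i]; ve <- v$pos[i] + nchar(v$ref[i]) - 1
    for (b in blocks) {
      if (b[["ch"]] == v$chrom[i] &&
          vs <= as.integer(b[["e"]]) && ve >= as.integer(b[["s"]])) {
        keep[i] <- TRUE; break
      }
    }
  }
  out <- v[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Straight-line reimplementation of the published weighted trimmed mean of
# M-values recipe (reference by 75th-percentile cpm, 30%/5% two-sided trims
# on M and A, inverse asymptotic binomial variance weights, geometric-mean
# rescaling).
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  nR <- lib[ref]; r <- counts[, ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]; nO <- lib[j]
    logR <- log2((x / nO) / (r / nR))
    absE <- (log2(x / nO) + log2(r / nR)) / 2
    v <- (nO - x) / (nO * x) + (nR - r) / (nR * r)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    fj <- sum(logR[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
    if (is.na(fj)) fj <- 0
    2^fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Random fixtures --------------------------------------------------------

rand_genotype_table <- function(n_markers, n_lines, n_chrom = 2,
                                probs = c(B = .4, D = .4, H = .1, U = .1)) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_markers,
                       replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    sort(sample.int(1e6, sum(chrom == ch)))
  }))
  markers <- data.frame(marker_id = sprintf("m%04d", seq_len(n_markers)),
                        chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  alleles <- matrix(sample(names(probs), n_markers * n_lines, replace = TRUE,
                           prob = probs),
                    n_markers, n_lines,
                    dimnames = list(NULL, sprintf("L%02d", seq_len(n_lines))))
  genotype_table(markers, alleles)
}

rand_variants <- function(n, n_chrom = 2, max_pos = 1e6) {
  if (n == 0)
    return(variants(character(0), integer(0), character(0), character(0)))
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  pos <- sample.int(max_pos - 20L, n)
  type <- sample(c("snv", "ins", "del"), n, replace = TRUE)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    b <- sample(c("A", "C", "G", "T"), 1)
    if (type[i] == "snv") {
      ref[i] <- b; alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    } else if (type[i] == "ins") {
      ref[i] <- b
      alt[i] <- paste0(b, paste(sample(c("A", "C", "G", "T"),
                                       sample.int(6, 1), replace = TRUE),
                                collapse = ""))
    } else {
      ref[i] <- paste0(b, paste(sample(c("A", "C", "G", "T"),
                                       sample.int(6, 1), replace = TRUE),
                                collapse = ""))
      alt[i] <- b
    }
  }
  v <- data.frame(chrom = chrom, pos = pos, id = sprintf("rv%04d", seq_len(n)),
                  ref = ref, alt = alt,
                  zygosity = sample(c("HOM", "HET"), n, TRUE, c(.9, .1)),
                  stringsAsFactors = FALSE)
  v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# small random genome + non-overlapping HOM variants for chain tests
rand_edit_case <- function(len = 300, n_var = 12) {
  seq <- paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t"),
                      len, replace = TRUE), collapse = "")
  g <- genome(stats::setNames(seq, "chr1"))
  vr <- simulate_variants(g, snv_rate = n_var / (2 * len),
                          indel_rate = n_var / (2 * len),
                          het_fraction = 0, max_indel = 5,
                          seed = sample.int(1e6, 1))
  list(genome = g, variants = vr$variants, d2 = vr$d2_genome)
}
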