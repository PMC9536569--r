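#' Simulate a toy soft-masked base genome
#'
#' Sequences are i.i.d. uniform over A/C/G/T with a configurable fraction
#' covered by lowercase (soft-masked) runs, mimicking the `dna_sm` builds
#' the pipeline consumes.
#'
#' @param seed RNG seed (all generator randomness derives from it).
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp (recycled).
#' @param masked_fraction Approximate fraction of soft-masked sequence.
#' @return A [genome()] with sequences `chr1`, `chr2`, ...
#' @export
simulate_genome <- function(seed, n_chrom = 2, chrom_len = 1e6,
                            masked_fraction = 0.1) {
  chrom_len <- as.integer(rep_len(chrom_len, n_chrom))
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      L <- chrom_len[i]
      x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (masked_fraction > 0) {
        covered <- 0L
        target <- masked_fraction * L
        while (covered < target) {
          s <- sample.int(L, 1L)
          w <- min(stats::rgeom(1L, 1 / 200) + 1L, L - s + 1L)
          x[s:(s + w - 1L)] <- tolower(x[s:(s + w - 1L)])
          covered <- covered + w
        }
      }
      paste(x, collapse = "")
    }, character(1L))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    genome(seqs)
  })
}

#' Plant strain-specific variants and build the donor-strain genome
#'
#' Plants non-overlapping SNVs and short indels at the given per-bp rates
#' and labels a fraction of them heterozygous (strain variant archives use
#' HET as a low-quality flag at about 7-8% of records). The donor ("D2")
#' genome is assembled by direct sequence surgery from the HOM subset — an
#' independent construction that [apply_variants()] must reproduce exactly,
#' which the test suite uses as a cross-module oracle.
#'
#' @param genome Base [genome()].
#' @param snv_rate,indel_rate Per-bp planting rates.
#' @param het_fraction Fraction of variants labelled HET.
#' @param max_indel Maximum inserted/deleted length in bp.
#' @param seed RNG seed.
#' @return List with `variants` (sorted variants `data.frame`) and
#'   `d2_genome` (the [genome()] carrying every HOM variant).
#' @export
simulate_variants <- function(genome, snv_rate = 5e-3, indel_rate = 1e-3,
                              het_fraction = 0.08, max_indel = 8, seed = 1) {
  stopifnot(inherits(genome, "genome"))
  with_seed(seed, {
    vlist <- list()
    d2 <- character(length(genome))
    names(d2) <- names(genome)
    vid <- 0L
    for (nm in names(genome)) {
      seq <- genome[[nm]]
      L <- nchar(seq)
      n_snv <- stats::rbinom(1L, L, snv_rate)
      n_ind <- stats::rbinom(1L, L, indel_rate)
      cand_pos <- sample.int(L, min(n_snv + n_ind, L))
      is_indel <- rep(c(FALSE, TRUE), c(n_snv, length(cand_pos) - n_snv))
      o <- order(cand_pos)
      cand_pos <- cand_pos[o]; is_indel <- is_indel[o]
      rows <- list()
      last_end <- 0L
      for (i in seq_along(cand_pos)) {
        p <- cand_pos[i]
        if (p <= last_end) next
        refb <- substr(seq, p, p)
        if (!is_indel[i]) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), toupper(refb)), 1L)
          ref <- refb
        } else if (stats::runif(1L) < 0.5) {  # insertion
          w <- sample.int(max_indel, 1L)
          ins <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                       collapse = "")
          ref <- refb
          alt <- paste0(refb, ins)
        } else {                              # deletion
          w <- sample.int(max_indel, 1L)
          if (p + w > L) next
          ref <- substr(seq, p, p + w)
          alt <- refb
        }
        vid <- vid + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = nm, pos = p, id = sprintf("v%06d", vid),
                     ref = ref, alt = alt,
                     zygosity = if (stats::runif(1L) < het_fraction)
                       "HET" else "HOM",
                     stringsAsFactors = FALSE)
        last_end <- p + nchar(ref) - 1L
      }
      v <- do.call(rbind, rows)
      vlist[[nm]] <- v
      # independent surgery: splice HOM alternates directly
      pieces <- character(0)
      cur <- 0L
      if (!is.null(v)) {
        for (i in seq_len(nrow(v))) {
          if (v$zygosity[i] != "HOM") next
          p0 <- v$pos[i] - 1L
          pieces <- c(pieces, substr(seq, cur + 1L, p0), v$alt[i])
          cur <- p0 + nchar(v$ref[i])
        }
      }
      d2[[nm]] <- paste(c(pieces, substr(seq, cur + 1L, L)), collapse = "")
    }
    v <- do.call(rbind, vlist)
    rownames(v) <- NULL
    validate_variants(v)
    list(variants = v, d2_genome = genome(d2))
  })
}

#' Simulate recombination-mosaic panel genotypes
#'
#' Marker positions are sorted uniform draws per chromosome; each
#' line x chromosome is a two-state Markov chain over `\{B, D\}` with a
#' per-interval switch probability (the block mosaic of a recombinant
#' inbred line), and individual calls are flipped to `H` at a small rate to
#' mimic uncertain panel calls.
#'
#' @param genome A [genome()] (provides chromosome names and lengths).
#' @param n_markers_per_chrom Markers per chromosome.
#' @param n_lines Number of lines (default 33, a typical panel subset).
#' @param switch_prob Per-interval probability of switching parental state.
#' @param h_rate Per-call probability of an `H` (uncertain) flag.
#' @param seed RNG seed.
#' @return A [genotype_table()] with lines `BXD01`, `BXD02`, ...
#' @export
simulate_panel_genotypes <- function(genome, n_markers_per_chrom = 50,
                                     n_lines = 33, switch_prob = 0.1,
                                     h_rate = 0.01, seed = 1) {
  stopifnot(inherits(genome, "genome"))
  with_seed(seed, {
    mk <- list()
    for (nm in names(genome)) {
      pos <- sort(sample.int(nchar(genome[[nm]]), n_markers_per_chrom))
      mk[[nm]] <- data.frame(
        marker_id = sprintf("%s_m%03d", nm, seq_along(pos)),
        chrom = nm, pos = pos, stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, mk)
    rownames(markers) <- NULL
    lines <- sprintf("BXD%02d", seq_len(n_lines))
    alleles <- matrix("B", nrow(markers), n_lines,
                      dimnames = list(markers$marker_id, lines))
    for (l in seq_len(n_lines)) {
      for (nm in names(genome)) {
        idx <- which(markers$chrom == nm)
        k <- length(idx)
        state <- character(k)
        state[1L] <- if (stats::runif(1L) < 0.5) "B" else "D"
        if (k > 1L) {
          sw <- stats::runif(k - 1L) < switch_prob
          for (i in 2L:k)
            state[i] <- if (sw[i - 1L])
              setdiff(c("B", "D"), state[i - 1L]) else state[i - 1L]
        }
        h <- stats::runif(k) < h_rate
        state[h] <- "H"
        alleles[idx, l] <- state
      }
    }
    genotype_table(markers, alleles)
  })
}

#' Simulate a toy transcriptome annotation
#'
#' Non-overlapping single-transcript genes with 1-5 exons and random
#' strand, emitted as `gene` and `exon` feature rows with `gene_id` /
#' `transcript_id` attributes. Genes are laid out on an even grid of slots
#' so they never overlap.
#'
#' @param genome A [genome()].
#' @param n_genes Total number of genes (split across chromosomes in
#'   proportion to length).
#' @param span_range Gene span range in bp.
#' @param seed RNG seed.
#' @return Feature `data.frame` in the layout of [read_gtf()].
#' @export
simulate_annotation <- function(genome, n_genes = 500,
                                span_range = c(500, 3000), seed = 1) {
  stopifnot(inherits(genome, "genome"))
  lens <- nchar(genome)
  n_per <- pmax(1L, round(n_genes * lens / sum(lens)))
  n_per[1L] <- n_per[1L] + (n_genes - sum(n_per))
  with_seed(seed, {
    rows <- list()
    gnum <- 0L
    for (ci in seq_along(genome)) {
      nm <- names(genome)[ci]
      slot <- floor(lens[ci] / n_per[ci])
      stopifnot(slot > span_range[1L] + 2L)
      for (g in seq_len(n_per[ci])) {
        gnum <- gnum + 1L
        gid <- sprintf("gene%04d", gnum)
        span <- sample(span_range[1L]:min(span_range[2L], slot - 2L), 1L)
        start <- (g - 1L) * slot + sample.int(slot - span - 1L, 1L)
        end <- start + span - 1L
        strand <- if (stats::runif(1L) < 0.5) "+" else "-"
        n_ex <- sample.int(5L, 1L)
        seg <- floor(span / n_ex)
        ex_start <- integer(n_ex); ex_end <- integer(n_ex)
        for (e in seq_len(n_ex)) {
          s0 <- start + (e - 1L) * seg
          e0 <- if (e == n_ex) end else s0 + seg - 1L
          w <- sample.int(e0 - s0 + 1L, 1L)
          if (e == 1L) { ex_start[e] <- s0; ex_end[e] <- s0 + w - 1L }
          else if (e == n_ex) { ex_start[e] <- e0 - w + 1L; ex_end[e] <- e0 }
          else {
            off <- sample.int(e0 - s0 - w + 2L, 1L) - 1L
            ex_start[e] <- s0 + off; ex_end[e] <- s0 + off + w - 1L
          }
        }
        ex_end[n_ex] <- end  # gene span = exon envelope
        attrs <- sprintf('gene_id "%s"; transcript_id "%s.1";', gid, gid)
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, source = "strainref_sim",
          feature = c("gene", rep("exon", n_ex)),
          start = c(start, ex_start), end = c(end, ex_end),
          score = ".", strand = strand, frame = ".",
          attributes = attrs, gene_id = gid, stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    ann
  })
}

#' Simulate negative-binomial counts with planted cis effects
#'
#' Each gene receives a baseline log2 abundance; with probability
#' `causal_fraction` a causal marker is drawn uniformly from the markers
#' within the cis window of the gene's TSS and the gene's log2 abundance
#' shifts by `beta` per donor-allele dose (`B` = 0, `D` = 1, `H` = 0.5).
#' Per-line relative abundances are scaled to a uniform random library size
#' and counts drawn from a negative binomial, one sample per line (the
#' pooled-by-line design of panel studies).
#'
#' @param geno A [genotype_table()].
#' @param annotation Feature `data.frame` (for TSSs).
#' @param causal_fraction Probability a gene has a causal local marker.
#' @param beta_sd SD of the causal effect (log2 units per D dose).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param libsize_range Library size range (uniform).
#' @param window Cis window for the causal marker draw (bp).
#' @param baseline_range Range of baseline log2 abundance.
#' @param seed RNG seed.
#' @return List with `counts` (genes x lines integer matrix), `samples`
#'   (`data.frame` of line/condition/reference), `tss`, and `ledger` — the
#'   ground-truth record (`genes`: gene, causal marker or `NA`, true beta;
#'   `params`; `seed`).
#' @export
simulate_counts <- function(geno, annotation, causal_fraction = 0.3,
                            beta_sd = 1.0, nb_dispersion = 0.1,
                            libsize_range = c(8e5, 1.2e6), window = 2e6,
                            baseline_range = c(3, 9), seed = 1) {
  stopifnot(inherits(geno, "genotype_table"))
  tss <- gene_tss(annotation[annotation$feature == "gene", , drop = FALSE])
  n_g <- nrow(tss)
  lines <- geno$lines
  n_l <- length(lines)
  with_seed(seed, {
    causal <- rep(NA_character_, n_g)
    beta <- numeric(n_g)
    is_causal <- stats::runif(n_g) < causal_fraction
    for (g in which(is_causal)) {
      cand <- which(geno$markers$chrom == tss$chrom[g] &
                    abs(geno$markers$pos - tss$tss[g]) <= window)
      if (length(cand) == 0L) { is_causal[g] <- FALSE; next }
      causal[g] <- geno$markers$marker_id[cand[sample.int(length(cand), 1L)]]
      beta[g] <- stats::rnorm(1L, 0, beta_sd)
    }
    baseline <- stats::runif(n_g, baseline_range[1L], baseline_range[2L])
    dose <- matrix(0, n_g, n_l)
    has <- !is.na(causal)
    if (any(has)) {
      al <- geno$alleles[causal[has], lines, drop = FALSE]
      dose[has, ] <- (al == "D") + 0.5 * (al == "H") + 0.5 * (al == "U")
    }
    logmu <- baseline + beta * dose
    rel <- 2^logmu
    lib <- stats::runif(n_l, libsize_range[1L], libsize_range[2L])
    mu <- sweep(rel, 2L, lib / colSums(rel), "*")
    counts <- matrix(stats::rnbinom(n_g * n_l, mu = mu,
                                    size = 1 / nb_dispersion),
                     n_g, n_l, dimnames = list(tss$gene_id, lines))
    ledger <- list(
      genes = data.frame(gene = tss$gene_id, causal_marker = causal,
                         beta = beta, stringsAsFactors = FALSE),
      params = list(causal_fraction = causal_fraction, beta_sd = beta_sd,
                    nb_dispersion = nb_dispersion,
                    libsize_range = libsize_range, window = window,
                    baseline_range = baseline_range),
      seed = seed)
    list(counts = counts,
         samples = data.frame(sample = lines, line = lines,
                              condition = "NSD", reference = "custom",
                              stringsAsFactors = FALSE),
         tss = tss, ledger = ledger)
  })
}

#' Inject a reference-bias (allele-loss) mechanism into counts
#'
#' Emulates reads lost when a donor-allele sample is mapped to the
#' reference-strain genome: a variant inside a gene disrupts mapping
#' precisely for the samples carrying the alternative allele. For each
#' gene the burden is the number of HOM variants overlapping its exons;
#' for lines carrying the `D` allele at the marker nearest the gene's TSS
#' (the TSS-containing haplotype block), counts are thinned binomially by
#' `1 - min(cap, burden * loss_per_variant)`. Binomial thinning keeps
#' counts integer and NB-like. The unthinned matrix plays the role of the
#' custom-reference quantification; the thinned one of the
#' reference-strain quantification.
#'
#' @param counts Genes x lines count matrix (from [simulate_counts()]).
#' @param geno A [genotype_table()].
#' @param annotation Feature `data.frame` (exon rows are used).
#' @param v Variants `data.frame` (the HOM subset defines the burden).
#' @param tss TSS table as from [gene_tss()] (defaults to one computed
#'   from `annotation`).
#' @param loss_per_variant Fractional read loss per exonic variant.
#' @param cap Maximum total loss fraction.
#' @param seed RNG seed for the binomial thinning.
#' @return List with `counts` (thinned matrix), `burden` (named per-gene
#'   variant burden), `loss_factor` (named per-gene thinning factor) and
#'   `d_lines` (per-gene list is omitted; the thinned columns are those of
#'   D-allele lines at the gene's TSS marker).
#' @export
inject_reference_bias <- function(counts, geno, annotation, v,
                                  tss = NULL, loss_per_variant = 0.02,
                                  cap = 0.5, seed = 1) {
  stopifnot(is.matrix(counts), inherits(geno, "genotype_table"))
  if (is.null(tss))
    tss <- gene_tss(annotation[annotation$feature == "gene", , drop = FALSE])
  tss <- tss[match(rownames(counts), tss$gene_id), , drop = FALSE]
  if (anyNA(tss$gene_id)) stop("counts contain genes absent from annotation")
  ex <- annotation[annotation$feature == "exon", , drop = FALSE]
  hom <- v[v$zygosity == "HOM", , drop = FALSE]
  burden <- integer(nrow(counts))
  names(burden) <- rownames(counts)
  for (ch in unique(ex$seqname)) {
    exc <- ex[ex$seqname == ch, , drop = FALSE]
    vc <- hom[hom$chrom == ch, , drop = FALSE]
    if (nrow(vc) == 0L || nrow(exc) == 0L) next
    ir_v <- IRanges::IRanges(vc$pos, vc$pos + nchar(vc$ref) - 1L)
    ir_e <- IRanges::IRanges(exc$start, exc$end)
    hits <- IRanges::countOverlaps(ir_e, ir_v)
    per_gene <- tapply(hits, exc$gene_id, sum)
    idx <- match(names(per_gene), names(burden))
    ok <- !is.na(idx)
    burden[idx[ok]] <- burden[idx[ok]] + as.integer(per_gene[ok])
  }
  loss <- pmin(cap, burden * loss_per_variant)
  out <- counts
  lines <- colnames(counts)
  with_seed(seed, {
    for (g in seq_len(nrow(counts))) {
      if (loss[g] <= 0) next
      mi <- which(geno$markers$chrom == tss$chrom[g])
      if (length(mi) == 0L) next
      nearest <- mi[which.min(abs(geno$markers$pos[mi] - tss$tss[g]))]
      dl <- lines[geno$alleles[nearest, lines] == "D"]
      if (length(dl) == 0L) next
      out[g, dl] <- stats::rbinom(length(dl), counts[g, dl], 1 - loss[g])
    }
    list(counts = out, burden = burden, loss_factor = 1 - loss)
  })
}

#' Simulate a complete strain-aware expression study
#'
#' Convenience wrapper composing the generator: base genome, planted
#' variants and donor genome, panel genotypes, annotation, counts with
#' planted cis effects, and (for the biased preset) a thinned
#' reference-strain count matrix.
#'
#' @param seed Master seed; sub-generators derive their seeds from it.
#' @param preset `"unbiased"` (no allele loss), `"biased"` (allele loss
#'   injected into the reference-strain counts) or `"null"` (no causal
#'   effects, no loss).
#' @param n_genes,n_lines Study size.
#' @param loss_per_variant Allele-loss rate for the biased preset.
#' @param ... Further arguments passed to [simulate_counts()].
#' @return List with `genome`, `variants`, `d2_genome`, `geno`,
#'   `annotation`, `tss`, `counts_custom` (unthinned), `counts_ref`
#'   (thinned under `"biased"`, identical otherwise), `bias` (the
#'   [inject_reference_bias()] output or `NULL`) and `ledger`.
#' @export
simulate_bxd_study <- function(seed, preset = c("unbiased", "biased", "null"),
                               n_genes = 500, n_lines = 33,
                               loss_per_variant = 0.02, ...) {
  preset <- match.arg(preset)
  g <- simulate_genome(seed)
  vr <- simulate_variants(g, seed = seed + 1L)
  geno <- simulate_panel_genotypes(g, n_lines = n_lines, seed = seed + 2L)
  ann <- simulate_annotation(g, n_genes = n_genes, seed = seed + 3L)
  cf <- if (preset == "null") 0 else 0.3
  sim <- simulate_counts(geno, ann, causal_fraction = cf,
                         seed = seed + 4L, ...)
  bias <- NULL
  counts_ref <- sim$counts
  if (preset == "biased") {
    bias <- inject_reference_bias(sim$counts, geno, ann, vr$variants,
                                  tss = sim$tss,
                                  loss_per_variant = loss_per_variant,
                                  seed = seed + 5L)
    counts_ref <- bias$counts
  }
  list(genome = g, variants = vr$variants, d2_genome = vr$d2_genome,
       geno = geno, annotation = ann, tss = sim$tss,
       counts_custom = sim$counts, counts_ref = counts_ref,
       samples = sim$samples, bias = bias, ledger = sim$ledger,
       preset = preset, seed = seed)
}
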