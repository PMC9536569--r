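---
title: "Strain-aware references and reference-bias statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-aware references and reference-bias statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainref)
```

# The problem

RNA-seq reads from genetically diverse samples are usually mapped to a
single reference genome. Reads carrying non-reference alleles then align
worse — or not at all — than reads carrying reference alleles, so apparent
expression is systematically skewed toward the reference strain. In a
recombinant inbred panel such as BXD (mosaics of the C57BL/6J "B6" and
DBA/2J "D2" genomes), this *reference bias* propagates into downstream
statistics, most visibly into local (cis) eQTL slopes: with a B6-based
reference, too many eQTLs appear to have the B6 allele increasing
expression.

`strainref` implements the remedy end to end for a panel whose lines are
genotyped at sparse recombination markers while dense variants are known
only for the donor parent (D2):

1. **Imputation** — delineate D2 haplotype blocks per line from the marker
   table and impute the dense D2 variants falling inside them.
2. **Reference construction** — splice the imputed variants into the base
   genome to obtain one custom reference per line, with a UCSC chain file
   and coordinate liftover of the annotation.
3. **Statistics** — count filtering, TMM/log2-cpm normalization, a paired
   differential-mapping test between quantifications of the same samples
   under two references, permutation-based local eQTL detection with
   Storey q-values, and the reference-bias skewness and similarity
   summaries.
4. **Synthetic data** — a seeded generator with a planted ground-truth
   ledger, including an injectable allele-loss mechanism, so that every
   step can be validated against known truth.

# Haplotype-block imputation

A line's D2 haplotype block is a maximal run of **at least two**
consecutive markers (in chromosome and position order) carrying the D
allele. Any B, H (heterozygous, used by panel providers as an uncertainty
flag) or U (missing) call breaks a run, as does a chromosome boundary: a
single D marker is never a block, and we do not impute across unobserved
or uncertain genotypes. The block interval is the closed span from the
first to the last D marker of the run — marker positions themselves, not
extended toward the flanking non-D markers, which is the conservative
reading: variants in the inter-marker uncertainty zone are *not* imputed.
No cap is placed on the physical gap between consecutive markers of a
run.

A variant is imputed into a line when its footprint
`[pos, pos + nchar(ref) - 1]` overlaps any block on the same chromosome by
at least one base (the bedtools-intersect default). Zygosity labels ride
along unchanged; HET-labelled variants are rejected later, at genome
editing time, mirroring the order of operations of variant-aware
reference builders.

# Genome editing and liftover

`apply_variants()` produces the haploid "paternal"-style genome: unphased
heterozygous variants are counted and skipped (in strain variant archives
the Het flag mostly marks low-quality calls), and only homozygous variants
are spliced, left to right. Three policies cover the cases the input
format leaves open:

* **REF mismatch** — the REF allele is compared case-insensitively to the
  base genome; disagreement (routine archive/assembly discordance) skips
  the variant and increments a counter rather than failing the build.
* **Overlap** — a variant whose footprint overlaps an already-applied
  variant is skipped; first wins in coordinate order, ties by input order.
  This is the simplest deterministic rule.
* **Case** — unedited bases keep their soft-mask case; spliced-in bases
  take the ALT string verbatim.

The chain between the two coordinate systems breaks blocks only at
applied indels; SNVs are mismatches inside blocks. For a normalized indel
the shared REF/ALT prefix (the anchor base) stays inside the preceding
block, so a deletion `CG -> C` at position 2 of `ACGT` yields blocks
`[0,2)` and `[3,4) -> [2,3)` with a one-base gap on the reference side.
Serialization is deterministic (score = summed block length, sequential
ids), and the files are consumable by external chain implementations —
the test suite checks position-by-position agreement with
`rtracklayer::liftOver`.

`lift_position()` maps affinely inside blocks and returns `NA` for
positions in a source-side gap (deleted bases going forward, inserted
bases in reverse). Annotation lifting moves feature endpoints
independently and drops (and reports) any feature with an unmapped
endpoint; because the mapping is monotone, surviving features always keep
`start <= end`.

# Expression processing

Genes are kept when their counts-per-million — computed on raw library
sizes, before normalization — exceed `min_cpm = 0.5` **strictly** in at
least `min_samples = 20` samples (the convention for a 66-sample tissue;
scale `min_samples` with your design). Normalization factors are weighted
trimmed means of M-values (TMM) as implemented in edgeR, with the
reference sample chosen by the 75th-percentile rule; factors are rescaled
to geometric mean 1. An independent straight-line reimplementation of the
published recipe lives in the test suite and must agree to 1e-8.
Log-expression is the damped transform

    log2( (count + 0.5) / (libsize * factor + 1) * 1e6 )

whose 0.5/1 prior constants follow the common log-cpm convention; a zero
count at a one-million library is about -1, and doubling a count adds
strictly less than one log2 unit until counts are large.

# Differential mapping

When the *same* samples are quantified against two references, the only
varying factor is the reference, so the natural test is paired. For each
gene we take per-sample differences of log2-cpm, and moderate the
gene-wise variances by empirical Bayes: the first two moments of
`log s^2` are matched to a scaled chi-square model, giving closed-form,
seed-free estimates of the prior degrees of freedom `d0` and prior
variance `s0^2` (a Newton inverse of the trigamma function is the only
iteration involved; the result agrees with limma's estimator to 1e-6 in
the tests). The moderated statistic

    t = mean(d) * sqrt(n) / sqrt( (d0 s0^2 + (n-1) s^2) / (d0 + n - 1) )

is referred to a t distribution with `d0 + n - 1` degrees of freedom,
p-values are BH-adjusted, and genes are flagged DM at adjusted p < 0.05.
With `prior_df = 0` the ordinary paired t-test is recovered exactly.
Mean-variance precision weights (voom-style) are deliberately not
implemented: the loess weighting machinery is orthogonal to the question
asked here, and the paired moderated-t is a standard, documented
approximation. Strata (tissue x condition) should be analyzed separately;
the package does not model them jointly.

# Local eQTL detection

For each gene, markers within 2 Mb of the TSS (feature start on `+`,
feature end on `-`; the 5'-most per strand when several transcripts
exist) are tested by simple linear regression of expression on allele
dose, coded B = 0, D = 1. H and U genotypes are excluded per marker
rather than imputed to 0.5 — H means "uncertain", so exclusion is the
faithful reading. With this coding a **negative slope means the B6 allele
increases expression**, which makes the skewness statistic below come out
positive under B6 bias.

Numerical conventions: expression is mean-centered per gene before the
scan (a pure conditioning step — the per-marker intercept absorbs any
shift); a zero-variance fit (constant expression, or a marker
monomorphic among usable lines) is reported as slope 0, p = 1; a perfect
fit gives p = 0. The best marker per gene minimizes the nominal p, ties
broken by distance to the TSS and then by marker id (the tie-break is
this package's choice; upstream tools leave it unspecified).

Marker multiplicity is adjusted by phenotype permutation with the
empirical estimator

    p_perm = (1 + #{ permuted best p <= observed best p }) / (1 + n_perm)

using one seeded set of permutations shared by all genes, which makes
runs bit-reproducible and keeps gene results independent under the null.
The default is `n_perm = 1000` with seed 1; the simulation suite uses
`n_perm = 200`, which bounds the smallest attainable adjusted p at
1/201 and is sufficient for calibration checks at 500 genes. A
beta-distribution approximation of the permutation null is deliberately
not implemented: the empirical estimator targets the same quantity and is
exact up to Monte-Carlo error at these scales.

Gene-level FDR uses Storey q-values: `pi0` is estimated on the lambda
grid 0.05-0.95 (step 0.05), smoothed by a 3-df spline evaluated at 0.95
and clamped to (0, 1]; with fewer than 100 genes or a degenerate estimate
the method falls back to Benjamini-Hochberg (`pi0 = 1`). Significance is
q < 0.05.

Two summaries follow the field's definitions:

* **percent significant** = 100 x #significant / #expressed genes. The
  denominator is *all* genes surviving the expression filter, including
  genes with no marker in their cis window (which can never be
  significant) — "expressed genes" means exactly that.
* **skewness** = 100 x (#significant with negative slope − #significant
  with positive slope) / #expressed genes. Zero means no reference bias;
  positive values mean B6 bias. Slope-zero significant results count in
  neither term.

`compare_eqtls()` evaluates, per gene, whether two analyses agree on the
best marker (identical id), the slope, and the q-value, where "similar"
means a relative difference under 5%: `|a - b| / |mean(a, b)| < 0.05`.
When the mean is zero the formula is undefined; the convention here is
similar only if both values are exactly zero, so opposite-sign
equal-magnitude slopes are maximally dissimilar. A gene is *unaffected*
when all three criteria hold; the summary reports the Venn counts over
the three criteria.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with every draw traceable to a recorded seed:

| quantity | default | rationale |
|---|---|---|
| chromosomes | 2 x 1 Mb | smallest layout exercising per-chromosome logic |
| SNV / indel rate | 5e-3 / 1e-3 per bp | ~5:1 SNV:indel ratio of strain archives, scaled to the toy genome |
| HET label fraction | 0.08 | the 7-8% Het flag rate of strain archives |
| markers | 50 per chromosome | sparse relative to variants, as real panels are |
| lines | 33 | a typical panel subset |
| switch probability | 0.1 per interval | a few recombination blocks per chromosome |
| H call rate | 0.01 | occasional uncertain panel calls |
| genes | 500, spans 0.5-3 kb, 1-5 exons | enough for stable q-value estimation within desk-scale runtime |
| causal fraction | 0.3, beta ~ N(0, 1) | minority of genes cis-regulated, effects up to a few log2 units |
| NB dispersion | 0.1 | bulk RNA-seq-like biological noise |
| library sizes | 0.8-1.2 million | uniform, pooled-by-line design (one sample per line) |
| allele loss | 0.02 per exonic variant, capped at 0.5 | a few percent of reads lost per disrupting variant |

The donor (D2) genome is assembled by direct sequence surgery during
variant planting — an independent code path from `apply_variants()` — so
the identity between the two constructions is a genuine cross-module
oracle, exercised byte-for-byte (soft-mask case included) in the tests.

Reference bias is injected at the **count level**: for each gene the
burden is the number of HOM variants overlapping its exons, and samples
whose line carries the D allele at the marker nearest the TSS have their
counts thinned binomially by `1 - min(cap, burden * loss_per_variant)`.
Binomial thinning keeps counts integer with NB-like noise. Read-level
simulation and alignment are outside the generator's scope: the package
starts upstream (reference construction) and downstream (statistics) of
the aligner, which the workflow treats as an external tool.

## What the generator does and does not show

The injected mechanism reproduces the *skewness* signature faithfully: at
the defaults, the thinned ("B6-reference") counts show positive skewness
in 18 of 20 seeds while the unthinned counts stay within the 99% binomial
band of zero — the qualitative picture of a B6-biased versus a custom
reference analysis.

It does **not** reproduce the direction of the *detection-rate*
comparison seen with real reads. Count-level thinning keyed to the D
allele at the TSS marker is itself genuine cis-genetic signal, so the
thinned matrix yields *more* significant local eQTLs than the unthinned
one, whereas with real data a custom reference recovers slightly more
eQTLs than a biased one. Real mapping loss degrades data quality in ways
a clean binomial thin does not (reads lost entirely, multi-mapping,
exon-boundary artifacts). Interpreting the generator's detection-rate
comparison as evidence about real pipelines would be wrong, and the
package documents this as a known limitation of count-level bias
injection rather than adjusting the mechanism's parameters to force the
real-data direction.

Two further limitations: marker LD in the Markov mosaic means the best
marker of a true eQTL is often a tight proxy of the causal marker rather
than the causal marker itself (exact recovery is ~75% at beta/sigma = 1.5
with 33 lines; recovery of a proxy with dose correlation > 0.7 exceeds
90%), and tissue-dependent mappability differences observed in real data
have no mechanism here and are not modeled.

# Worked example

```{r example, eval = FALSE}
st <- simulate_bxd_study(1, preset = "biased")

# impute the panel and build one line's custom reference
imp <- impute_panel(st$geno, st$variants, quiet = TRUE)
ref <- build_line_reference(st$genome, st$annotation,
                            imp$BXD01$variants, tempdir(), "BXD01")
ref$report

# reference-bias statistics under the two quantifications
biased <- eqtl_pipeline(st$counts_ref, st$geno, st$tss, n_perm = 200)
custom <- eqtl_pipeline(st$counts_custom, st$geno, st$tss, n_perm = 200)
c(skew_biased = biased$skewness, skew_custom = custom$skewness)

cmp <- compare_eqtls(biased$results, custom$results)
cmp$venn
```

The problem sizes used throughout the simulation suite (500 genes, 33
lines, 200 permutations, 20 replicate seeds for the bias experiment) are
the package's chosen desk-scale study conditions; all of them are plain
arguments and can be raised for production analyses.
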