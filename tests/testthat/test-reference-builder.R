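test_that("variant splicing follows the haploid 'paternal' semantics", {
  g <- genome(c(chr1 = "ACGT"))
  # HOM SNV is spliced; chain stays a single block
  r <- apply_variants(g, variants("chr1", 2, "C", "G"))
  expect_identical(as.character(r$custom), c(chr1 = "AGGT"))
  expect_equal(r$chain$chr1$blocks,
               data.frame(ref_start = 0L, custom_start = 0L, length = 4L))
  expect_equal(r$report$n_applied_snv, 1L)
  # HET variant is ignored entirely
  r <- apply_variants(g, variants("chr1", 2, "C", "G", "HET"))
  expect_identical(as.character(r$custom), c(chr1 = "ACGT"))
  expect_equal(r$report$n_skipped_het, 1L)
  # deletion: block 0-2, 1 bp ref gap, block 3-4 <-> 2-3
  r <- apply_variants(g, variants("chr1", 2, "CG", "C"))
  expect_identical(as.character(r$custom), c(chr1 = "ACT"))
  expect_equal(r$chain$chr1$blocks,
               data.frame(ref_start = c(0L, 3L), custom_start = c(0L, 2L),
                          length = c(2L, 1L)))
  # insertion
  r <- apply_variants(g, variants("chr1", 2, "C", "CTT"))
  expect_identical(as.character(r$custom), c(chr1 = "ACTTGT"))
})

test_that("REF mismatches and overlapping variants are skipped and counted", {
  g <- genome(c(chr1 = "ACGTACGT"))
  v <- variants("chr1", c(2, 3, 6), c("C", "GTA", "C"), c("A", "G", "T"))
  r <- apply_variants(g, v)
  # pos 3 deletion overlaps nothing applied before it... applies; pos 6 ref C ok
  expect_equal(r$report$n_applied_snv, 2L)
  expect_equal(r$report$n_applied_del, 1L)
  # overlap: two deletions sharing footprint -> first wins
  v2 <- variants("chr1", c(2, 3), c("CGT", "GT"), c("C", "G"))
  r2 <- apply_variants(g, v2)
  expect_equal(r2$report$n_applied_del, 1L)
  expect_equal(r2$report$n_skipped_overlap, 1L)
  expect_identical(as.character(r2$custom), c(chr1 = "ACACGT"))
  # ref mismatch
  r3 <- apply_variants(g, variants("chr1", 2, "G", "A"))
  expect_equal(r3$report$n_skipped_ref_mismatch, 1L)
  expect_identical(as.character(r3$custom), c(chr1 = "ACGTACGT"))
  # REF comparison is case-insensitive (soft-masked base still edits)
  g2 <- genome(c(chr1 = "AcGT"))
  r4 <- apply_variants(g2, variants("chr1", 2, "C", "G"))
  expect_identical(as.character(r4$custom), c(chr1 = "AGGT"))
  # unsorted input and unknown chromosome are hard errors
  vun <- rbind(variants("chr1", 5, "A", "T"), variants("chr1", 2, "C", "G"))
  expect_error(apply_variants(g, vun), "sorted")
  expect_error(apply_variants(g, variants("chrX", 2, "C", "G")),
               "not in genome")
})

test_that("edit accounting and length conservation hold on random inputs", {
  set.seed(301)
  for (i in 1:15) {
    cs <- rand_edit_case(len = 400, n_var = 20)
    v <- cs$variants
    v$zygosity <- sample(c("HOM", "HET"), nrow(v), TRUE, c(.8, .2))
    r <- apply_variants(cs$genome, v)
    rep <- r$report
    applied <- rep$n_applied_snv + rep$n_applied_ins + rep$n_applied_del
    skipped <- rep$n_skipped_het + rep$n_skipped_ref_mismatch +
      rep$n_skipped_overlap
    expect_equal(applied + skipped, nrow(v))
    # conservation: custom length = base + sum(len(alt) - len(ref)) applied
    ap <- attr(r, "applied")
    delta <- sum(nchar(v$alt[ap]) - nchar(v$ref[ap]))
    expect_equal(nchar(r$custom[["chr1"]]),
                 nchar(cs$genome[["chr1"]]) + delta)
    # applied SNVs read ALT at the lifted position; soft-mask case kept
    snv <- which(ap & nchar(v$ref) == 1 & nchar(v$alt) == 1)
    for (j in snv) {
      lp <- lift_position(r$chain, "chr1", v$pos[j])
      expect_identical(substr(r$custom[["chr1"]], lp, lp), v$alt[j])
    }
  }
})

test_that("liftover is affine inside blocks and NA in deleted gaps", {
  g <- genome(c(chr1 = "ACGT"))
  # identity chain: every position maps to itself, both directions
  ident <- apply_variants(g, variants(character(0), integer(0),
                                      character(0), character(0)))$chain
  expect_equal(lift_positions(ident, "chr1", 1:4), 1:4)
  expect_equal(lift_positions(ident, "chr1", 1:4, "reverse"), 1:4)
  # deletion CG->C at pos 2: retained C maps, deleted G is unmapped
  del <- apply_variants(g, variants("chr1", 2, "CG", "C"))$chain
  expect_equal(lift_position(del, "chr1", 2), 2L)
  expect_true(is.na(lift_position(del, "chr1", 3)))
  expect_equal(lift_position(del, "chr1", 4), 3L)
  expect_error(lift_position(del, "chr1", 5), "out of bounds")
  expect_error(lift_position(del, "chr1", 0), "out of bounds")
})

test_that("forward-then-reverse lift is identity off deleted footprints", {
  set.seed(302)
  for (i in 1:20) {
    cs <- rand_edit_case()
    ed <- apply_variants(cs$genome, cs$variants)
    L <- nchar(cs$genome[["chr1"]])
    fwd <- lift_positions(ed$chain, "chr1", 1:L)
    back <- rep(NA_integer_, L)
    ok <- !is.na(fwd)
    back[ok] <- lift_positions(ed$chain, "chr1", fwd[ok], "reverse")
    expect_equal(back[ok], (1:L)[ok])
    # reverse-then-forward identity off inserted footprints
    Lc <- nchar(ed$custom[["chr1"]])
    rev <- lift_positions(ed$chain, "chr1", 1:Lc, "reverse")
    ok2 <- !is.na(rev)
    fwd2 <- lift_positions(ed$chain, "chr1", rev[ok2])
    expect_equal(fwd2, (1:Lc)[ok2])
  }
})

test_that("liftover agrees with rtracklayer's chain implementation", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  set.seed(303)
  for (i in 1:5) {
    cs <- rand_edit_case(len = 400, n_var = 25)
    ed <- apply_variants(cs$genome, cs$variants)
    tf <- withr::local_tempfile(fileext = ".chain")
    write_chain(ed$chain, tf)
    ch <- rtracklayer::import.chain(tf)
    L <- nchar(cs$genome[["chr1"]])
    mine <- lift_positions(ed$chain, "chr1", 1:L)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:L, 1:L))
    lo <- rtracklayer::liftOver(gr, ch)
    theirs <- vapply(lo, function(x)
      if (length(x) == 1) GenomicRanges::start(x) else NA_integer_,
      integer(1))
    expect_identical(unname(mine), unname(theirs))
  }
})

test_that("annotation lifting drops deleted endpoints and shifts the rest", {
  g <- genome(c(chr1 = paste(rep("ACGT", 10), collapse = "")))  # 40 bp
  feats <- data.frame(seqname = "chr1", source = "s",
                      feature = c("exon", "exon"),
                      start = c(5L, 20L), end = c(10L, 30L), score = ".",
                      strand = "+", frame = ".",
                      attributes = c('gene_id "g1";', 'gene_id "g2";'),
                      gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  # no-indel chain: everything identical
  snv <- apply_variants(g, variants("chr1", 6, "C", "G"))
  ann <- lift_annotation(snv$chain, feats)
  expect_equal(ann$lifted, feats)
  expect_equal(nrow(ann$dropped), 0L)
  # 2 bp deletion upstream of g2 (pos 12, ref 3 bases, removes pos 13-14)
  del <- apply_variants(g, variants("chr1", 12, "TAC", "T"))
  ann2 <- lift_annotation(del$chain, feats)
  g2row <- ann2$lifted[ann2$lifted$gene_id == "g2", ]
  expect_equal(g2row$start, 18L)
  expect_equal(g2row$end, 28L)
  # deleting an exon's start base drops the feature, reported
  del2 <- apply_variants(g, variants("chr1", 19, "GTA", "G"))  # removes 20-21
  ann3 <- lift_annotation(del2$chain, feats)
  expect_equal(ann3$dropped$gene_id, "g2")
  expect_equal(ann3$lifted$gene_id, "g1")
  expect_true(all(ann3$lifted$start <= ann3$lifted$end))
})

test_that("build_line_reference composes files faithfully", {
  set.seed(304)
  g <- simulate_genome(304, n_chrom = 1, chrom_len = 20000)
  ann <- simulate_annotation(g, n_genes = 4, seed = 305)
  out <- withr::local_tempdir()
  novar <- variants(character(0), integer(0), character(0), character(0))
  bl <- build_line_reference(g, ann, novar, out, prefix = "empty")
  expect_identical(as.character(read_fasta(bl$fasta)), as.character(g))
  reread <- read_gtf(bl$gtf)
  expect_equal(reread$start, ann$start)
  expect_equal(reread$attributes, ann$attributes)
  # HET-only variant list behaves exactly like the empty list
  vr <- simulate_variants(g, het_fraction = 1, seed = 306)
  bl2 <- build_line_reference(g, ann, vr$variants, out, prefix = "het")
  expect_identical(readLines(bl2$fasta), readLines(bl$fasta))
  expect_equal(bl2$report$n_skipped_het, nrow(vr$variants))
  # ground-truth donor genome is reproduced from the HOM variant set
  vr2 <- simulate_variants(g, het_fraction = 0.2, seed = 307)
  hom <- vr2$variants[vr2$variants$zygosity == "HOM", ]
  bl3 <- build_line_reference(g, ann, hom, out, prefix = "d2")
  expect_identical(as.character(read_fasta(bl3$fasta)),
                   as.character(vr2$d2_genome))
})
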