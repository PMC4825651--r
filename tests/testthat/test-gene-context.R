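# Gene assignment, subregion classification, metagene and anchor profiles,
# expression association.

# one explicit two-exon coding gene on each strand
fixture_genes <- function() {
  span <- GRanges(
    "c1", IRanges(c(20001, 60001), c(23000, 63000)),
    strand = c("+", "-"),
    gene_id = c("gPlus", "gMinus"),
    cds_start = c(20201L, 60201L), cds_end = c(22800L, 62800L))
  exons <- list(
    gPlus = GRanges("c1", IRanges(c(20001, 22001), c(20500, 23000))),
    gMinus = GRanges("c1", IRanges(c(60001, 62001), c(60500, 63000))))
  gene_models(span, exons)
}

test_that("assignment uses the TSS-5kb..TTS window on the gene's own strand", {
  gm <- fixture_genes()
  # 3 kb upstream of the + gene's TSS -> assigned, upstream region
  a <- assign_to_genes(make_sites("c1", 17001), gm)
  expect_equal(a$gene_id, "gPlus")
  expect_match(a$regions, "upstream")
  # 6 kb upstream -> intergenic
  expect_equal(nrow(assign_to_genes(make_sites("c1", 14000), gm)), 0L)
  # for the minus gene, upstream means higher coordinates
  b <- assign_to_genes(make_sites("c1", 66000), gm)
  expect_equal(b$gene_id, "gMinus")
  expect_match(b$regions, "upstream")
  expect_equal(nrow(assign_to_genes(make_sites("c1", 57000), gm)), 0L)
  # past the TTS is not assigned under the default window
  expect_equal(nrow(assign_to_genes(make_sites("c1", 23500), gm)), 0L)
  # ... but is under the expression rule (±5 kb of TSS and TTS)
  e <- assign_to_genes(make_sites("c1", 23500), gm, downstream_bp = 5000)
  expect_equal(e$gene_id, "gPlus")
})

test_that("sites inside two overlapping genes yield two assignments", {
  span <- GRanges("c1", IRanges(c(1000, 1500), c(3000, 3500)),
                  strand = "+", gene_id = c("gA", "gB"),
                  cds_start = c(1100L, 1600L), cds_end = c(2900L, 3400L))
  gm <- gene_models(span, list(
    gA = GRanges("c1", IRanges(1000, 3000)),
    gB = GRanges("c1", IRanges(1500, 3500))))
  a <- assign_to_genes(make_sites("c1", 2000), gm, upstream_bp = 0)
  expect_setequal(a$gene_id, c("gA", "gB"))
})

test_that("subregion classification splits exons at the CDS bounds", {
  gm <- fixture_genes()
  # + gene: exon sequence before cds_start is 5' UTR
  expect_equal(classify_region(make_sites("c1", 20100), gm, 1),
               "five_prime_utr")
  expect_equal(classify_region(make_sites("c1", 20300), gm, 1),
               "coding_exon")
  expect_equal(classify_region(make_sites("c1", 21000), gm, 1), "intron")
  expect_equal(classify_region(make_sites("c1", 22900), gm, 1),
               "three_prime_utr")
  # minus gene mirrors: low-coordinate exon sequence is the 3' UTR
  expect_equal(classify_region(make_sites("c1", 60100), gm, 2),
               "three_prime_utr")
  expect_equal(classify_region(make_sites("c1", 62900), gm, 2),
               "five_prime_utr")
  # an 8-bp TSD across the exon/intron boundary reports both
  tsd <- make_sites("c1", 20497, width = 8)
  expect_setequal(classify_region(tsd, gm, 1), c("coding_exon", "intron"))
})

test_that("every in-span base of a single-exon coding gene maps to exactly one region", {
  span <- GRanges("c1", IRanges(101, 400), strand = "+", gene_id = "g1",
                  cds_start = 151L, cds_end = 350L)
  gm <- gene_models(span, list(g1 = GRanges("c1", IRanges(101, 400))))
  for (p in seq(101, 400, by = 7)) {
    r <- classify_region(make_sites("c1", p), gm, 1)
    expect_equal(length(r), 1L)
    expect_true(r %in% c("five_prime_utr", "coding_exon", "three_prime_utr"))
  }
  expect_equal(classify_region(make_sites("c1", 150), gm, 1), "five_prime_utr")
  expect_equal(classify_region(make_sites("c1", 151), gm, 1), "coding_exon")
  expect_equal(classify_region(make_sites("c1", 350), gm, 1), "coding_exon")
  expect_equal(classify_region(make_sites("c1", 351), gm, 1), "three_prime_utr")
})

test_that("metagene position normalises gene length to 100% along orientation", {
  gm <- fixture_genes()
  expect_equal(metagene_position(make_sites("c1", 20001), gm, 1), 0)
  expect_equal(metagene_position(make_sites("c1", 23000), gm, 1), 100)
  # odd-length span so the midpoint is an exact base
  mid <- gene_models(
    GRanges("c1", IRanges(1001, 2001), strand = "+", gene_id = "gm",
            cds_start = 1001L, cds_end = 2001L),
    list(gm = GRanges("c1", IRanges(1001, 2001))))
  expect_equal(metagene_position(make_sites("c1", 1501), mid, 1), 50)
  # minus gene: the span's lowest coordinate is the TTS (100%)
  expect_equal(metagene_position(make_sites("c1", 60001), gm, 2), 100)
  expect_equal(metagene_position(make_sites("c1", 63000), gm, 2), 0)
  expect_error(metagene_position(make_sites("c1", 10), gm, 1), "outside")
})

test_that("metagene position is strand-equivariant under genome mirroring", {
  L <- 100000
  span <- GRanges("c1", IRanges(40001, 50000), strand = "+",
                  gene_id = "g", cds_start = 40101L, cds_end = 49900L)
  gm <- gene_models(span, list(g = GRanges("c1", IRanges(40001, 50000))))
  mspan <- GRanges("c1", IRanges(L - 50000 + 1, L - 40001 + 1),
                   strand = "-", gene_id = "g",
                   cds_start = L - 49900L + 1L, cds_end = L - 40101L + 1L)
  mgm <- gene_models(mspan, list(g = GRanges("c1", ranges(mspan))))
  for (p in c(40001, 42500, 47000, 50000)) {
    expect_equal(metagene_position(make_sites("c1", p), gm, 1),
                 metagene_position(make_sites("c1", L - p + 1), mgm, 1))
  }
})

test_that("anchor offsets are signed along the gene orientation", {
  gm <- fixture_genes()
  # 100 bp downstream of the minus gene's TSS (TSS at 63000, downstream
  # means decreasing coordinate)
  pr <- anchor_profile(make_sites("c1", 62900), gm, "TSS", window_bp = 1000)
  expect_equal(pr$offsets, 100L)
  # site exactly at the + gene's TTS
  pr2 <- anchor_profile(make_sites("c1", 23000), gm, "TTS", window_bp = 1000)
  expect_equal(pr2$offsets, 0L)
  # upstream of the + TSS is negative
  pr3 <- anchor_profile(make_sites("c1", 19800), gm, "TSS", window_bp = 1000)
  expect_equal(pr3$offsets, -201L)
  expect_equal(sum(pr3$histogram$count), 1L)
})

test_that("uniform sites give an approximately flat anchor histogram", {
  g <- make_genome(c(c1 = 2e5), gc = 0.5, seed = 101)
  span <- GRanges("c1", IRanges(100001, 150000), strand = "+",
                  gene_id = "g", cds_start = 100101L, cds_end = 149900L)
  gm <- gene_models(span, list(g = GRanges("c1", IRanges(100001, 150000))))
  set.seed(102)
  s <- make_sites("c1", sample(99001:101000, 2000, replace = TRUE))
  pr <- anchor_profile(s, gm, "TSS", window_bp = 1000, bin_bp = 100)
  cnt <- pr$histogram$count
  expect_gt(stats::chisq.test(cnt)$p.value, 1e-4)
})

test_that("expression classes follow the thresholded pre/post-ZGA pattern", {
  expr <- data.frame(
    gene_id = c("m", "z", "mz", "s"),
    t1 = c(5, 0.2, 3, 0.1), t2 = c(2, 0.4, 2, 0.2),
    t3 = c(0.3, 6, 4, 0.3), t4 = c(0.1, 8, 5, 0.4))
  cls <- classify_expression(expr, zga_index = 3)
  expect_equal(cls$class, c("maternal_only", "zygotic_only",
                            "maternal_zygotic", "silent"))
  expect_equal(cls$overall, rowSums(expr[, -1]))
})

test_that("synthetic expression tables are classified back perfectly", {
  g <- make_genome(c(c1 = 5e5), gc = 0.5, seed = 111)
  gm <- make_gene_models(g, n_genes = 40, seed = 112)
  expr <- make_expression_table(gm$genes, seed = 113)
  cls <- classify_expression(expr, zga_index = attr(expr, "zga_index"))
  expect_equal(cls$class, attr(expr, "truth")$class)
})

test_that("expression association recovers a planted zygotic bias", {
  g <- make_genome(c(c1 = 1e6), gc = 0.5, seed = 121)
  gm <- make_gene_models(g, n_genes = 60, seed = 122)
  expr <- make_expression_table(gm$genes, seed = 123)
  cls <- classify_expression(expr, zga_index = attr(expr, "zga_index"))
  zyg_genes <- cls$gene_id[cls$class == "zygotic_only"]
  sp <- gm$genes$span
  zi <- match(zyg_genes, mcols(sp)$gene_id)
  # sites planted inside zygotic-only genes
  pos <- floor((start(sp)[zi] + end(sp)[zi]) / 2)
  s <- make_sites("c1", pos)
  asg <- assign_to_genes(s, gm$genes, downstream_bp = 5000)
  set.seed(124)
  ctrl_sites <- make_sites("c1", sample.int(1e6 - 100, 200))
  casg <- assign_to_genes(ctrl_sites, gm$genes, downstream_bp = 5000)
  out <- expression_association(asg, cls, casg)
  zfrac <- function(grp) {
    d <- out$classes
    d$fraction[d$group == grp & d$class == "zygotic_only"]
  }
  expect_gt(zfrac("experimental"), zfrac("control") + 0.2)
  # identical assignments give identical summaries
  same <- expression_association(asg, cls, asg)
  expect_equal(same$summary$mean_fpkm[1], same$summary$mean_fpkm[2])
})
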