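# Genome, interval and format primitives.

test_that("FASTA reading uppercases, validates alphabet and headers", {
  p <- write_temp_fasta(c(c1 = "ACGT"))
  g <- read_genome(p)
  expect_equal(unname(genome_lengths(g)), 4L)
  expect_equal(as.character(g[["c1"]]), "ACGT")

  p2 <- write_temp_fasta(c(c1 = "acgt"))
  expect_equal(as.character(read_genome(p2)[["c1"]]), "ACGT")

  p3 <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "GG"), p3)
  expect_error(read_genome(p3), "duplicate")

  p4 <- write_temp_fasta(c(c1 = "ACXT"))
  expect_error(read_genome(p4), "outside")
})

test_that("window extraction is oriented and bounds-checked", {
  g <- toy_genome(c(c1 = "ACGTAC"))
  plus <- GRanges("c1", IRanges(2, 4), strand = "+")
  expect_equal(extract_window(g, plus), "CGT")
  minus <- GRanges("c1", IRanges(2, 4), strand = "-")
  expect_equal(extract_window(g, minus), "ACG")
  expect_error(extract_window(g, GRanges("c1", IRanges(5, 10))), "bounds")
})

test_that("minus-strand extraction equals reverse complement of plus", {
  set.seed(7)
  g <- make_genome(c(c1 = 500), gc = 0.5, seed = 1)
  st <- sample.int(400, 25)
  for (i in seq_along(st)) {
    iv <- IRanges(st[i], width = 30)
    p <- extract_window(g, GRanges("c1", iv, strand = "+"))
    m <- extract_window(g, GRanges("c1", iv, strand = "-"))
    expect_equal(m, revcomp(p))
  }
})

test_that("motif scanning finds all (overlapping) occurrences", {
  g <- toy_genome(c(c1 = "TTAATTAA"))
  hits <- scan_motif_sites(g, "TTAA")
  expect_equal(start(hits), c(1L, 5L))
  expect_equal(unique(width(hits)), 4L)

  expect_equal(length(scan_motif_sites(toy_genome(c(c1 = "AAAA")), "TTAA")), 0L)
  expect_equal(start(scan_motif_sites(toy_genome(c(c1 = "TTTAA")), "TTAA")), 2L)
  # overlapping occurrences are all reported
  expect_equal(start(scan_motif_sites(toy_genome(c(c1 = "AAAAA")), "AA")),
               1:4)
  expect_error(scan_motif_sites(g, ""), "non-empty")
  expect_error(scan_motif_sites(g, "TTNA"), "A,C,G,T")
})

test_that("motif scanning agrees with a naive string-scan oracle", {
  g <- make_genome(c(c1 = 4000, c2 = 2000), gc = 0.5, seed = 3)
  for (motif in c("TTAA", "CTAG", "GTAC")) {
    hits <- scan_motif_sites(g, motif)
    for (ch in names(g)) {
      s <- as.character(g[[ch]])
      naive <- c()
      for (i in seq_len(nchar(s) - nchar(motif) + 1))
        if (substr(s, i, i + nchar(motif) - 1) == motif)
          naive <- c(naive, i)
      got <- start(hits)[as.character(seqnames(hits)) == ch]
      expect_equal(got, if (is.null(naive)) integer(0) else as.integer(naive))
    }
  }
})

test_that("N never matches a motif and non-palindromes hit both strands", {
  g <- toy_genome(c(c1 = "TTNATTAA"))
  expect_equal(start(scan_motif_sites(g, "TTAA")), 5L)
  # AACC occurs only as its reverse complement GGTT on the forward strand
  g2 <- toy_genome(c(c1 = "AGGTTA"))
  expect_equal(start(scan_motif_sites(g2, "AACC")), 2L)
})

test_that("motif density on a random genome matches 4^-k expectation", {
  L <- 2e5; k <- 4
  g <- make_genome(c(c1 = L), gc = 0.5, seed = 11)
  n <- length(scan_motif_sites(g, "TTAA"))
  expn <- (L - k + 1) * 4^(-k)
  expect_lt(abs(n - expn), 4 * sqrt(expn))   # ~binomial error
})

test_that("overlap counting follows the 1-bp rule and matches brute force", {
  sites <- GRanges("c1", IRanges(6, 6))
  track <- GRanges("c1", IRanges(1, 6))
  expect_equal(overlap_count(sites, track), 1L)
  expect_equal(overlap_count(GRanges("c1", IRanges(7, 7)), track), 0L)

  set.seed(5)
  for (rep in 1:20) {
    s <- random_intervals(50)
    t <- random_intervals(30)
    expect_equal(overlap_count(s, t), oracle_overlap_count(s, t))
  }
})

test_that("site tables and BED round-trip through disk", {
  s <- make_sites("c1", c(100, 200, 300), strand = c("+", "-", "+"),
                  fragment_count = c(51, 7, 1000),
                  method = c("NGS", "NGS", "TAIL"))
  p <- tempfile(fileext = ".tsv")
  write_sites(s, p)
  s2 <- read_sites(p)
  expect_equal(start(s2), start(s))
  expect_equal(as.character(strand(s2)), as.character(strand(s)))
  expect_equal(s2$fragment_count, s$fragment_count)
  expect_equal(s2$method, s$method)
  # BED native 0-based half-open: "c1 10 20" reads to 1-based [11,20]
  pb <- tempfile(fileext = ".bed")
  writeLines("c1\t10\t20\tx\t0\t+", pb)
  b <- read_bed(pb)
  expect_equal(start(b), 11L)
  expect_equal(end(b), 20L)
  pb2 <- tempfile(fileext = ".bed")
  write_bed(b, pb2)
  b2 <- read_bed(pb2)
  expect_equal(ranges(b2), ranges(b))
})

test_that("site tables reject malformed records", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tvector\tfragment_count\tmethod",
               "c1\t10\t10\t+\tDs\t5\tNGS"), p)
  expect_error(read_sites(p), "line 2")
})

test_that("gene models round-trip through GFF3 with 1-based coordinates", {
  g <- make_genome(c(chr1 = 1e5), gc = 0.5, seed = 2)
  gm <- make_gene_models(g, n_genes = 5, gene_length = c(2000, 5000),
                         seed = 3)
  p <- tempfile(fileext = ".gff3")
  write_genes_gff(gm$genes, p)
  gm2 <- read_genes_gff(p)
  expect_equal(length(gm2), 5L)
  expect_equal(start(gm2$span), start(gm$genes$span))
  expect_equal(end(gm2$span), end(gm$genes$span))
  expect_equal(mcols(gm2$span)$cds_start, mcols(gm$genes$span)$cds_start)
  for (id in mcols(gm$genes$span)$gene_id)
    expect_equal(ranges(gm2$exons[[id]]), ranges(gm$genes$exons[[id]]))
  # a gene written as 11..20 in GFF3 stays 11..20 (1-based inclusive)
  one <- gene_models(
    GRanges("chr1", IRanges(11, 20), strand = "+", gene_id = "gX",
            cds_start = 11L, cds_end = 20L),
    list(gX = GRanges("chr1", IRanges(11, 20))))
  p2 <- tempfile(fileext = ".gff3")
  write_genes_gff(one, p2)
  expect_match(grep("\tgene\t", readLines(p2), value = TRUE)[1],
               "\t11\t20\t")
  expect_equal(start(read_genes_gff(p2)$span), 11L)
})
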