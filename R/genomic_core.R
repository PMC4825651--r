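#' @import methods
#' @importFrom stats median quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils read.delim write.table head tail
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom IRanges IRanges
#' @importFrom graphics hist
#' @importFrom BiocGenerics start end width strand setdiff intersect sort
#' @importFrom GenomicRanges GRanges seqnames countOverlaps findOverlaps
#'   reduce resize granges restrict
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   reverseComplement matchPattern extractAt alphabetFrequency
NULL

# -- genome -------------------------------------------------------------------

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased on read.  Only the unambiguous DNA alphabet plus
#' `N` is accepted; any other character, or a duplicated header, is an error.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one entry per chromosome).
#' @export
read_genome <- function(path) {
  g <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("FASTA contains characters outside {A,C,G,T,N}")
      invokeRestart("muffleWarning")
    })
  # keep only the first word of each header, as aligners do
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate FASTA header(s): ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  bad <- Biostrings::alphabetFrequency(g, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  other <- bad[, setdiff(colnames(bad), allowed), drop = FALSE]
  if (any(other > 0))
    stop("FASTA contains characters outside {A,C,G,T,N}")
  g
}

#' Chromosome lengths of a genome
#' @param genome A named `DNAStringSet`.
#' @return Named integer vector of chromosome lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(BiocGenerics::width(genome), names(genome))
}

#' Attach chromosome lengths from a genome to a GRanges
#' @param gr A `GRanges`.
#' @param genome A named `DNAStringSet`.
#' @return `gr` with `seqlengths` set (and validated against bounds).
#' @export
set_genome_info <- function(gr, genome) {
  len <- genome_lengths(genome)
  miss <- setdiff(as.character(GenomeInfoDb::seqlevels(gr)), names(len))
  if (length(miss))
    stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(len)
  GenomeInfoDb::seqlengths(gr) <- len
  gr
}

# -- window extraction --------------------------------------------------------

#' Extract a genomic window as an oriented nucleotide string
#'
#' Returns the genome substring covered by `gr`; minus-strand intervals are
#' reverse-complemented so that the returned string reads 5'->3' on the
#' interval's own strand.
#'
#' @param genome A named `DNAStringSet`.
#' @param gr A `GRanges` (any length); out-of-bounds intervals are an error.
#' @return Character vector of sequences, one per interval.
#' @export
extract_window <- function(genome, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  len <- genome_lengths(genome)
  if (any(!chrom %in% names(len)))
    stop("interval on chromosome absent from genome")
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > len[chrom]))
    stop("interval out of chromosome bounds")
  out <- character(length(gr))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- as.character(Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = GenomicRanges::start(gr)[i],
                       end   = GenomicRanges::end(gr)[i])))
  }
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus))
    out[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(out[minus])))
  out
}

#' Reverse complement of nucleotide strings
#' @param x Character vector over {A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# -- motif scanning -----------------------------------------------------------

#' Locate all exact occurrences of a motif in a genome
#'
#' Scans the forward strand for exact matches (overlapping occurrences are
#' all reported; `N` in the genome never matches).  Non-palindromic motifs
#' are additionally scanned as their reverse complement and the two hit sets
#' are merged without duplicates, so occurrences on either strand are found.
#'
#' @param genome A named `DNAStringSet`.
#' @param motif Non-empty string over {A,C,G,T}.
#' @return A `GRanges` of motif occurrences (strand `*`).
#' @export
scan_motif_sites <- function(genome, motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("motif must be a single non-empty string")
  if (grepl("[^ACGT]", motif))
    stop("motif must be over {A,C,G,T}")
  pats <- unique(c(motif, revcomp(motif)))
  chrom <- character(0); st <- integer(0)
  for (ch in names(genome)) {
    s <- integer(0)
    for (p in pats)
      s <- c(s, BiocGenerics::start(
        Biostrings::matchPattern(p, genome[[ch]], fixed = TRUE)))
    s <- sort(unique(s))
    chrom <- c(chrom, rep(ch, length(s)))
    st <- c(st, s)
  }
  gr <- GenomicRanges::GRanges(
    factor(chrom, levels = names(genome)),
    IRanges::IRanges(start = st, width = nchar(motif)))
  set_genome_info(gr, genome)
}

# -- overlap ------------------------------------------------------------------

#' Count query intervals overlapping a feature track
#'
#' An interval overlaps the track if it shares at least 1 bp with any track
#' interval; each query interval is counted at most once.  Strand is
#' ignored.
#'
#' @param sites A `GRanges` of query intervals.
#' @param track A `GRanges` feature track.
#' @return Integer count of query intervals with any overlap.
#' @export
overlap_count <- function(sites, track) {
  if (length(sites) == 0L || length(track) == 0L) return(0L)
  sum(GenomicRanges::countOverlaps(sites, track, minoverlap = 1L,
                                   ignore.strand = TRUE) > 0L)
}

# -- integration-site tables --------------------------------------------------

.site_columns <- c("chrom", "start", "end", "strand", "vector",
                   "fragment_count", "method")

#' Read an integration-site table
#'
#' Expects a TSV with header columns `chrom, start, end, strand, vector,
#' fragment_count, method` where `start`/`end` are BED-style 0-based
#' half-open.  A point insertion is a 1-bp interval; an annotated 8-bp
#' target-site duplication is an 8-bp interval.
#'
#' @param path Path to the TSV file.
#' @return A `GRanges` with metadata columns `vector`, `fragment_count`,
#'   `method`.
#' @export
read_sites <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(.site_columns, names(d))
  if (length(miss))
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(d$strand %in% c("+", "-")) | d$end <= d$start |
                 d$fragment_count < 0)
  if (length(bad))
    stop("malformed site record at line ", bad[1] + 1L)
  GenomicRanges::GRanges(
    d$chrom,
    IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = d$strand,
    vector = d$vector,
    fragment_count = as.integer(d$fragment_count),
    method = d$method)
}

#' Write an integration-site table
#' @param sites A `GRanges` as returned by [read_sites()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    vector = S4Vectors::mcols(sites)$vector,
    fragment_count = S4Vectors::mcols(sites)$fragment_count,
    method = S4Vectors::mcols(sites)$method)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a BED feature track
#'
#' Thin wrappers around [rtracklayer::import]/[rtracklayer::export]; BED is
#' 0-based half-open on disk and converted to 1-based closed `GRanges` in
#' memory.
#'
#' @param path BED file path.
#' @return `read_bed`: a `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' @rdname read_bed
#' @param track A `GRanges`.
#' @export
write_bed <- function(track, path) {
  rtracklayer::export(track, path, format = "bed")
  invisible(path)
}

# -- gene models --------------------------------------------------------------

#' Construct a gene-model set
#'
#' @param span `GRanges` of gene spans (strand `+`/`-`) with metadata column
#'   `gene_id` and genomic (1-based, strand-agnostic) `cds_start`,
#'   `cds_end`.
#' @param exons Named list (by `gene_id`) of `GRanges`, exons per gene,
#'   sorted and non-overlapping within each gene.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(span, exons) {
  stopifnot(all(c("gene_id", "cds_start", "cds_end") %in%
                  names(S4Vectors::mcols(span))))
  stopifnot(all(as.character(GenomicRanges::strand(span)) %in% c("+", "-")))
  stopifnot(setequal(names(exons), S4Vectors::mcols(span)$gene_id))
  exons <- exons[S4Vectors::mcols(span)$gene_id]
  structure(list(span = span, exons = exons), class = "gene_models")
}

#' @export
length.gene_models <- function(x) length(x$span)

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$span), "genes on",
      length(unique(GenomicRanges::seqnames(x$span))), "chromosome(s)\n")
  invisible(x)
}

#' Transcription start / termination sites of gene models
#'
#' The TSS is the 5' end of the gene span on its own strand; the TTS the
#' 3' end.  Positions are 1-based genomic coordinates.
#'
#' @param genes A `gene_models` object.
#' @return Integer vector, one position per gene.
#' @export
gene_tss <- function(genes) {
  plus <- as.character(GenomicRanges::strand(genes$span)) == "+"
  ifelse(plus, GenomicRanges::start(genes$span),
         GenomicRanges::end(genes$span))
}

#' @rdname gene_tss
#' @export
gene_tts <- function(genes) {
  plus <- as.character(GenomicRanges::strand(genes$span)) == "+"
  ifelse(plus, GenomicRanges::end(genes$span),
         GenomicRanges::start(genes$span))
}

#' Read gene models from a GFF3 file
#'
#' Understands `gene` features carrying an `ID`, with child `exon` and `CDS`
#' features carrying `Parent`.  GFF3 coordinates are 1-based inclusive and
#' are kept as such in the returned `GRanges`.
#'
#' @param path GFF3 file path.
#' @return A `gene_models` object.
#' @export
read_genes_gff <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  genes <- g[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  if (anyDuplicated(gid)) stop("duplicate gene ID in ", path)
  ex <- g[type == "exon"]
  cds <- g[type == "CDS"]
  parent_of <- function(x) vapply(x$Parent, function(p) as.character(p)[1], "")
  ex_par <- parent_of(ex)
  cds_par <- parent_of(cds)
  exons <- lapply(gid, function(id) {
    e <- BiocGenerics::sort(GenomicRanges::granges(ex[ex_par == id]))
    if (length(e) == 0L) stop("gene ", id, " has no exons")
    e
  })
  names(exons) <- gid
  cds_start <- cds_end <- integer(length(gid))
  for (i in seq_along(gid)) {
    cc <- cds[cds_par == gid[i]]
    if (length(cc) == 0L) {
      cds_start[i] <- NA_integer_; cds_end[i] <- NA_integer_
    } else {
      cds_start[i] <- min(GenomicRanges::start(cc))
      cds_end[i] <- max(GenomicRanges::end(cc))
    }
  }
  span <- GenomicRanges::granges(genes)
  S4Vectors::mcols(span) <- S4Vectors::DataFrame(
    gene_id = gid, cds_start = cds_start, cds_end = cds_end)
  gene_models(span, exons)
}

#' Write gene models to a GFF3 file
#' @param genes A `gene_models` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genes_gff <- function(genes, path) {
  gid <- S4Vectors::mcols(genes$span)$gene_id
  rows <- character(0)
  fmt <- function(chrom, type, s, e, strand, attr)
    paste(chrom, "intsitepref", type, s, e, ".", strand, ".", attr,
          sep = "\t")
  for (i in seq_along(gid)) {
    sp <- genes$span[i]
    ch <- as.character(GenomicRanges::seqnames(sp))
    st <- as.character(GenomicRanges::strand(sp))
    rows <- c(rows, fmt(ch, "gene", GenomicRanges::start(sp),
                        GenomicRanges::end(sp), st,
                        paste0("ID=", gid[i])))
    ex <- genes$exons[[gid[i]]]
    for (j in seq_along(ex))
      rows <- c(rows, fmt(ch, "exon", GenomicRanges::start(ex)[j],
                          GenomicRanges::end(ex)[j], st,
                          paste0("ID=", gid[i], ".exon", j,
                                 ";Parent=", gid[i])))
    cs <- S4Vectors::mcols(sp)$cds_start
    ce <- S4Vectors::mcols(sp)$cds_end
    if (!is.na(cs) && !is.na(ce)) {
      cdsp <- GenomicRanges::restrict(ex, start = cs, end = ce)
      cdsp <- cdsp[GenomicRanges::width(cdsp) > 0]
      for (j in seq_along(cdsp))
        rows <- c(rows, fmt(ch, "CDS", GenomicRanges::start(cdsp)[j],
                            GenomicRanges::end(cdsp)[j], st,
                            paste0("ID=", gid[i], ".cds", j,
                                   ";Parent=", gid[i])))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
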