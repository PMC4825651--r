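# Fixtures and independent brute-force oracles used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# small fixed genome for exact-coordinate tests
toy_genome <- function(seqs = c(c1 = "ACGTAC")) {
  Biostrings::DNAStringSet(seqs)
}

write_temp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

# a site GRanges with standard metadata
make_sites <- function(chrom, pos, strand = "+", width = 1L,
                       vector = "Ds", fragment_count = 100L,
                       method = "NGS") {
  GRanges(chrom, IRanges(pos, width = width), strand = strand,
          vector = vector,
          fragment_count = as.integer(fragment_count),
          method = method)
}

# O(n*m) all-pairs overlap oracle (1-bp rule, strand-blind)
oracle_overlap_count <- function(sites, track) {
  if (length(sites) == 0 || length(track) == 0) return(0L)
  sc <- as.character(seqnames(sites)); tc <- as.character(seqnames(track))
  n <- 0L
  for (i in seq_along(sites)) {
    hit <- FALSE
    for (j in seq_along(track)) {
      if (sc[i] == tc[j] &&
          start(sites)[i] <= end(track)[j] &&
          end(sites)[i] >= start(track)[j]) { hit <- TRUE; break }
    }
    n <- n + hit
  }
  n
}

# exhaustive nearest-restriction-site oracle
oracle_nearest_re <- function(sites, index) {
  out <- data.frame(enzyme = character(length(sites)),
                    distance = integer(length(sites)))
  for (i in seq_along(sites)) {
    ch <- as.character(seqnames(sites))[i]
    p <- start(sites)[i]
    best <- Inf; beste <- NA_character_
    for (e in names(index$motifs)) {
      occ <- index$positions[[e]][[ch]]
      if (is.null(occ) || !length(occ)) next
      d <- min(abs(occ - p))
      if (d < best) { best <- d; beste <- e }
    }
    out$enzyme[i] <- beste; out$distance[i] <- best
  }
  out
}

# transitive-closure single-linkage oracle for site merging: number of
# clusters of insertion points within tolerance on (chrom, strand)
oracle_merge_count <- function(sites, tolerance_bp) {
  key <- paste(as.character(seqnames(sites)), as.character(strand(sites)))
  total <- 0L
  for (k in unique(key)) {
    p <- sort(start(sites)[key == k])
    grp <- 1L
    if (length(p) > 1) grp <- grp + sum(diff(p) > tolerance_bp)
    total <- total + grp
  }
  total
}

# hand formula for the bootstrap enrichment statistic
oracle_enrichment <- function(x_exp, control_counts) {
  nz <- control_counts > 0
  list(ratio = if (any(nz)) mean(x_exp / control_counts[nz]) else NA_real_,
       p_enrich = mean(control_counts >= x_exp),
       p_deplete = mean(control_counts <= x_exp),
       n_zero = sum(!nz))
}

# build a control_sets object directly from a list of GRanges replicates
manual_controls <- function(set_list, mode = "uniform") {
  gr <- do.call(c, unname(lapply(seq_along(set_list), function(i) {
    g <- set_list[[i]]; mcols(g)$set <- i; g
  })))
  structure(list(sites = gr, n_sets = length(set_list),
                 set_size = length(set_list[[1]]), mode = mode,
                 seed = NULL, keys = NULL),
            class = "control_sets")
}

# random toy instance: genome-free intervals on a small chromosome set
random_intervals <- function(n, chroms = c("c1", "c2"), chrom_len = 10000,
                             max_w = 200) {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(chrom_len - max_w, n, replace = TRUE)
  GRanges(ch, IRanges(st, width = sample.int(max_w, n, replace = TRUE)))
}
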