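# Synthetic genomes, gene models, expression tables and integration-site
# sets with planted, parameterised biases.  The generator exists so that
# every pipeline stage can be validated by parameter recovery: a bias of
# known size is planted, and the corresponding analysis stage must measure
# it back.

#' Simulate a random genome
#'
#' I.i.d. bases with a configurable GC fraction.
#'
#' @param lengths Named integer vector of chromosome lengths (bp).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed (or `NULL`).
#' @return A named `DNAStringSet`.
#' @export
make_genome <- function(lengths = c(chr1 = 2e6), gc = 0.5, seed = NULL) {
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("gc must be strictly between 0 and 1")
  stopifnot(all(lengths >= 1), !is.null(names(lengths)))
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lengths, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(setNames(seqs, names(lengths)))
  })
}

#' Simulate non-overlapping gene models and derived feature tracks
#'
#' Genes are placed without overlap (uniform random gaps), given a uniform
#' random strand, a random exon/intron structure and UTRs confined to the
#' first and last exon.
#'
#' @param genome Genome `DNAStringSet`.
#' @param n_genes Number of genes.
#' @param gene_length Range of gene span lengths (bp).
#' @param n_exons Range of exon counts per gene.
#' @param utr_length Target UTR length (bp; clipped to the terminal exon).
#' @param min_segment Minimum exon/intron segment length (bp).
#' @param seed Integer seed (or `NULL`).
#' @return A list with `genes` (a `gene_models`) and `tracks` (named list
#'   of `GRanges`: `exon`, `intron`, `coding_exon`, `five_prime_utr`,
#'   `three_prime_utr`, `upstream_5kb`, `gene_span`, `intergenic`).
#' @export
make_gene_models <- function(genome, n_genes = 100,
                             gene_length = c(2000, 20000),
                             n_exons = c(2, 8), utr_length = 200,
                             min_segment = 100, seed = NULL) {
  len <- genome_lengths(genome)
  .with_seed(seed, {
    glen <- sample(gene_length[1]:gene_length[2], n_genes, replace = TRUE)
    # allot genes to chromosomes proportionally to length, then place each
    # chromosome's genes left-to-right with uniform random gaps
    chrom <- sample(names(len), n_genes, replace = TRUE, prob = len)
    starts <- integer(n_genes)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      i <- i[sample.int(length(i))]
      k <- length(i)
      slack <- len[ch] - sum(glen[i])
      if (slack < k + 1L)
        stop("cannot place ", k, " genes on ", ch,
             ": total gene length exceeds chromosome")
      gaps <- floor(diff(c(0, sort(runif(k)) * slack)))
      starts[i] <- cumsum(gaps) + c(0, head(cumsum(glen[i]), -1L)) + 1L
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gid <- sprintf("gene%04d", seq_len(n_genes))
    exons <- vector("list", n_genes)
    cds_start <- cds_end <- integer(n_genes)
    for (g in seq_len(n_genes)) {
      gs <- starts[g]; ge <- gs + glen[g] - 1L
      k <- sample(n_exons[1]:n_exons[2], 1)
      L <- glen[g]
      # short exons, long introns: exon lengths ~ U[min_segment, exon_max];
      # the remaining span is split into k-1 introns of >= min_segment bp
      kmax <- max(1L, (L + min_segment) %/% (2L * min_segment))
      if (k > kmax) k <- kmax
      exon_max <- max(min_segment, min(300L, L %/% (2L * k)))
      if (k == 1L) {
        elen <- L
        seg <- L
      } else {
        elen <- sample(min_segment:exon_max, k, replace = TRUE)
        slack <- L - sum(elen) - (k - 1L) * min_segment
        gaps2 <- floor(diff(c(0, sort(runif(k - 1L)) * slack, slack)))
        ilen <- min_segment + gaps2[seq_len(k - 1L)]
        # absorb rounding remainder into the last intron
        ilen[k - 1L] <- L - sum(elen) - sum(ilen[-(k - 1L)])
        seg <- as.integer(rbind(elen, c(ilen, 0L)))[seq_len(2L * k - 1L)]
      }
      bounds <- cumsum(seg)
      ss <- gs + c(0L, head(bounds, -1L))
      ee <- gs + bounds - 1L
      ex_i <- seq(1L, 2L * k - 1L, by = 2L)
      exons[[g]] <- GenomicRanges::GRanges(
        factor(rep(chrom[g], length(ex_i)), levels = names(len)),
        IRanges::IRanges(ss[ex_i], ee[ex_i]))
      # UTRs confined to the terminal exons (which UTR is 5' vs 3'
      # follows from the strand)
      ulo <- max(min(utr_length, elen[1] - 10L), 0L)
      uhi <- max(min(utr_length, elen[k] - 10L), 0L)
      cds_start[g] <- gs + ulo
      cds_end[g] <- ge - uhi
    }
    names(exons) <- gid
    span <- GenomicRanges::GRanges(
      factor(chrom, levels = names(len)),
      IRanges::IRanges(starts, width = glen), strand = strand,
      gene_id = gid, cds_start = cds_start, cds_end = cds_end)
    genes <- gene_models(span, exons)
    list(genes = genes, tracks = derive_gene_tracks(genes, genome))
  })
}

#' Feature tracks derived from gene models
#'
#' @param genes A `gene_models` object.
#' @param genome Genome `DNAStringSet` (for chromosome bounds).
#' @param upstream_bp Size of the promoter-window track (default 5000).
#' @return Named list of `GRanges` tracks.
#' @export
derive_gene_tracks <- function(genes, genome, upstream_bp = 5000) {
  sp <- genes$span
  len <- genome_lengths(genome)
  ex_all <- GenomicRanges::reduce(
    do.call(c, unname(lapply(genes$exons, identity))))
  span_t <- GenomicRanges::reduce(GenomicRanges::granges(sp),
                                  ignore.strand = TRUE)
  intron <- BiocGenerics::setdiff(span_t, ex_all, ignore.strand = TRUE)
  cs <- S4Vectors::mcols(sp)$cds_start
  ce <- S4Vectors::mcols(sp)$cds_end
  plus <- as.character(GenomicRanges::strand(sp)) == "+"
  gs <- GenomicRanges::start(sp); ge <- GenomicRanges::end(sp)
  piece <- function(lo, hi) {
    ok <- !is.na(lo) & !is.na(hi) & lo <= hi
    GenomicRanges::GRanges(GenomicRanges::seqnames(sp)[ok],
                           IRanges::IRanges(lo[ok], hi[ok]))
  }
  cds_t <- piece(cs, ce)
  utr5 <- piece(ifelse(plus, gs, ce + 1L), ifelse(plus, cs - 1L, ge))
  utr3 <- piece(ifelse(plus, ce + 1L, gs), ifelse(plus, ge, cs - 1L))
  coding_exon <- BiocGenerics::intersect(ex_all, cds_t,
                                         ignore.strand = TRUE)
  up <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sp),
    IRanges::IRanges(
      pmax(1, ifelse(plus, gs - upstream_bp, ge + 1L)),
      pmin(unname(len[as.character(GenomicRanges::seqnames(sp))]),
           ifelse(plus, gs - 1L, ge + upstream_bp))))
  whole <- GenomicRanges::GRanges(names(len), IRanges::IRanges(1L, unname(len)))
  near <- GenomicRanges::reduce(
    GenomicRanges::GRanges(GenomicRanges::seqnames(sp),
                           IRanges::IRanges(pmax(1, gs - upstream_bp),
                                            ge + upstream_bp)),
    ignore.strand = TRUE)
  intergenic <- BiocGenerics::setdiff(whole, near, ignore.strand = TRUE)
  list(exon = ex_all, intron = intron, coding_exon = coding_exon,
       five_prime_utr = GenomicRanges::reduce(utr5, ignore.strand = TRUE),
       three_prime_utr = GenomicRanges::reduce(utr3, ignore.strand = TRUE),
       upstream_5kb = GenomicRanges::reduce(up, ignore.strand = TRUE),
       gene_span = span_t, intergenic = intergenic)
}

#' Simulate integration sites with planted biases
#'
#' Candidate insertion points are drawn uniformly over the genome and
#' accepted by rejection sampling with a weight that multiplies:
#'
#' * per-track fold factors `feature_folds` (weight `f` inside the track,
#'   1 outside; several tracks multiply),
#' * a TSS-proximity factor `tss_bias = list(fold, window_bp)`,
#' * a window-flexibility factor `flexibility_bias = list(parameter,
#'   beta)`: acceptance proportional to `exp(beta * z)` where `z` is the
#'   candidate's 48-bp window-mean step parameter standardised against the
#'   genome-wide distribution (estimated from `n_std` random windows;
#'   `z` clipped to +-4).
#'
#' Fragment counts are drawn from a log-normal model; a configured fraction
#' of sites are low-count noise singletons (count 1) planted adjacent to
#' restriction-enzyme motifs when `re_index` is given, emulating the
#' spurious junctions that the stringent filter path removes.
#'
#' @param genome Genome `DNAStringSet`.
#' @param n_sites Number of sites to generate.
#' @param tracks Named list of `GRanges` feature tracks referenced by
#'   `feature_folds`.
#' @param feature_folds Named numeric vector of fold factors (>= 0).
#' @param genes Optional `gene_models`, required for `tss_bias`.
#' @param tss_bias Optional `list(fold =, window_bp =)`.
#' @param flexibility_bias Optional `list(parameter =, beta =)`.
#' @param fragment_count `list(meanlog =, sdlog =)` of the log-normal
#'   fragment-count model.
#' @param noise_singleton_fraction Fraction of sites emitted as count-1
#'   noise (in `[0, 1]`).
#' @param re_index Optional `restriction_index` used to place noise
#'   singletons near restriction motifs.
#' @param tsd Annotate sites as 8-bp target-site duplications
#'   (transposon-style) instead of 1-bp points.
#' @param vector,method Labels stored on the output sites.
#' @param n_std Random windows used to standardise the flexibility bias.
#' @param max_batches Rejection-sampling budget (batches of `n_sites`
#'   candidates).
#' @param seed Integer seed (or `NULL`).
#' @return A site `GRanges` with `vector`, `fragment_count`, `method`
#'   metadata and a `truth` attribute recording all planted parameters.
#' @export
simulate_sites <- function(genome, n_sites, tracks = list(),
                           feature_folds = numeric(0), genes = NULL,
                           tss_bias = NULL, flexibility_bias = NULL,
                           fragment_count = list(meanlog = log(150),
                                                 sdlog = 1.2),
                           noise_singleton_fraction = 0,
                           re_index = NULL, tsd = FALSE,
                           vector = "Ds", method = "NGS",
                           n_std = 1e4, max_batches = 200, seed = NULL) {
  stopifnot(n_sites >= 1, noise_singleton_fraction >= 0,
            noise_singleton_fraction <= 1)
  if (length(feature_folds)) {
    stopifnot(!is.null(names(feature_folds)),
              all(names(feature_folds) %in% names(tracks)),
              all(is.finite(feature_folds)), all(feature_folds >= 0))
  }
  if (!is.null(tss_bias)) stopifnot(!is.null(genes))
  len <- genome_lengths(genome)
  site_w <- if (tsd) 8L else 1L
  margin <- 30L   # keeps every site's 48-bp window on the chromosome
  tss_win <- NULL
  if (!is.null(tss_bias)) {
    ap <- gene_tss(genes)
    tss_win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes$span),
      IRanges::IRanges(pmax(1, ap - tss_bias$window_bp),
                       ap + tss_bias$window_bp))
  }
  .with_seed(seed, {
    flex_std <- NULL
    if (!is.null(flexibility_bias)) {
      flex_std <- .flex_standardizer(genome, flexibility_bias$parameter,
                                     n_std, margin)
    }
    n_noise <- round(n_sites * noise_singleton_fraction)
    n_clean <- n_sites - n_noise
    acc_chrom <- character(0); acc_pos <- integer(0)
    wmax <- prod(pmax(feature_folds, 1), 1,
                 if (!is.null(tss_bias)) max(tss_bias$fold, 1) else 1) *
      (if (!is.null(flexibility_bias))
        exp(abs(flexibility_bias$beta) * 4) else 1)
    batches <- 0L
    while (length(acc_pos) < n_clean) {
      batches <- batches + 1L
      if (batches > max_batches)
        stop("rejection sampling exhausted its budget; ",
             "reduce the planted bias (e.g. smaller beta)")
      nb <- max(n_clean, 1000L)
      ch <- sample(names(len), nb, replace = TRUE, prob = len)
      pos <- margin + 1L +
        floor(runif(nb) * (unname(len[ch]) - 2L * margin - site_w))
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos,
                                                          width = site_w))
      w <- rep(1, nb)
      for (nm in names(feature_folds)) {
        inn <- GenomicRanges::countOverlaps(cand, tracks[[nm]],
                                            ignore.strand = TRUE) > 0
        w[inn] <- w[inn] * feature_folds[[nm]]
      }
      if (!is.null(tss_bias)) {
        inn <- GenomicRanges::countOverlaps(cand, tss_win,
                                            ignore.strand = TRUE) > 0
        w[inn] <- w[inn] * tss_bias$fold
      }
      if (!is.null(flexibility_bias)) {
        z <- flex_std(cand, genome)
        w <- w * exp(flexibility_bias$beta * pmax(pmin(z, 4), -4))
      }
      keep <- runif(nb) < w / wmax
      acc_chrom <- c(acc_chrom, ch[keep])
      acc_pos <- c(acc_pos, pos[keep])
    }
    acc_chrom <- acc_chrom[seq_len(n_clean)]
    acc_pos <- acc_pos[seq_len(n_clean)]
    fc <- pmax(2L, as.integer(round(rlnorm(n_clean,
                                           fragment_count$meanlog,
                                           fragment_count$sdlog))))
    # noise singletons: count 1, planted next to restriction motifs
    if (n_noise > 0) {
      if (!is.null(re_index)) {
        occ <- unlist(lapply(re_index$positions, function(p)
          unlist(p, use.names = FALSE)), use.names = FALSE)
        occh <- unlist(lapply(re_index$positions, function(p)
          rep(names(p), lengths(p))), use.names = FALSE)
        k <- sample.int(length(occ), n_noise, replace = TRUE)
        npos <- occ[k] + sample(-10:10, n_noise, replace = TRUE)
        nch <- occh[k]
        npos <- pmin(pmax(npos, margin + 1L),
                     unname(len[nch]) - margin - site_w)
      } else {
        nch <- sample(names(len), n_noise, replace = TRUE, prob = len)
        npos <- margin + 1L +
          floor(runif(n_noise) * (unname(len[nch]) - 2L * margin - site_w))
      }
      acc_chrom <- c(acc_chrom, nch)
      acc_pos <- c(acc_pos, as.integer(npos))
      fc <- c(fc, rep(1L, n_noise))
    }
    gr <- GenomicRanges::GRanges(
      acc_chrom, IRanges::IRanges(acc_pos, width = site_w),
      strand = sample(c("+", "-"), length(acc_pos), replace = TRUE),
      vector = vector, fragment_count = fc, method = method)
    attr(gr, "truth") <- list(
      n_sites = n_sites, feature_folds = feature_folds,
      tss_bias = tss_bias, flexibility_bias = flexibility_bias,
      fragment_count = fragment_count,
      noise_singleton_fraction = noise_singleton_fraction,
      tsd = tsd, seed = seed)
    gr
  })
}

# returns function(candidate GRanges, genome) -> standardized window-mean
# parameter of the 48-bp window centred on each candidate's start
.flex_standardizer <- function(genome, parameter, n_std, margin) {
  len <- genome_lengths(genome)
  ch <- sample(names(len), n_std, replace = TRUE, prob = len)
  pos <- margin + 1L + floor(runif(n_std) * (unname(len[ch]) - 2L * margin))
  win_mean <- function(chrom, p) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(p - 20L, p + 27L))
    seqs <- extract_window(genome, gr)
    ok <- !grepl("[^ACGT]", seqs)
    v <- rep(NA_real_, length(seqs))
    if (any(ok)) {
      enc <- .encode_windows(seqs[ok])
      vals <- .STEP_TABLE[, parameter]
      L <- ncol(enc)
      idx <- 4L * (enc[, -L, drop = FALSE] - 1L) + enc[, -1L, drop = FALSE]
      v[ok] <- rowMeans(matrix(vals[idx], nrow = nrow(enc)))
    }
    v
  }
  ref <- win_mean(ch, pos)
  mu <- mean(ref, na.rm = TRUE); sg <- sd(ref, na.rm = TRUE)
  function(cand, genome) {
    z <- (win_mean(as.character(GenomicRanges::seqnames(cand)),
                   GenomicRanges::start(cand)) - mu) / sg
    z[is.na(z)] <- 0
    z
  }
}

#' Simulate a developmental expression table
#'
#' Each gene is assigned a maternal/zygotic class and FPKM values drawn to
#' match it: expressed phases are log-normal above the detection floor
#' (FPKM >= 1), silent phases uniform below it.
#'
#' @param genes A `gene_models` object.
#' @param timepoints Character vector of timepoint labels, in order.
#' @param zga_index Index of the first post-ZGA timepoint.
#' @param class_fractions Named fractions over `maternal_only`,
#'   `zygotic_only`, `maternal_zygotic`, `silent` (must sum to 1).
#' @param seed Integer seed (or `NULL`).
#' @return A data.frame `gene_id` + one FPKM column per timepoint, with
#'   attributes `zga_index` and `truth` (the planted classes).
#' @export
make_expression_table <- function(genes,
                                  timepoints = c("t2h", "t4h", "t6h", "t8h"),
                                  zga_index = 3,
                                  class_fractions = c(maternal_only = 0.25,
                                                      zygotic_only = 0.25,
                                                      maternal_zygotic = 0.25,
                                                      silent = 0.25),
                                  seed = NULL) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8,
            zga_index >= 2, zga_index <= length(timepoints))
  gid <- S4Vectors::mcols(genes$span)$gene_id
  n <- length(gid)
  .with_seed(seed, {
    cls <- sample(names(class_fractions), n, replace = TRUE,
                  prob = class_fractions)
    on_val <- function(k) 1 + rlnorm(k, meanlog = 2, sdlog = 1)
    off_val <- function(k) runif(k, 0, 0.5)
    m <- matrix(0, n, length(timepoints),
                dimnames = list(NULL, timepoints))
    pre <- seq_len(zga_index - 1)
    post <- zga_index:length(timepoints)
    for (i in seq_len(n)) {
      mat <- cls[i] %in% c("maternal_only", "maternal_zygotic")
      zyg <- cls[i] %in% c("zygotic_only", "maternal_zygotic")
      m[i, pre] <- if (mat) on_val(length(pre)) else off_val(length(pre))
      m[i, post] <- if (zyg) on_val(length(post)) else off_val(length(post))
    }
    out <- data.frame(gene_id = gid, m, check.names = FALSE)
    attr(out, "zga_index") <- zga_index
    attr(out, "truth") <- data.frame(gene_id = gid, class = cls)
    out
  })
}
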