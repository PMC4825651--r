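# Gene assignment, subregion classification, metagene and TSS/TTS window
# profiles, and expression-class association.

.site_point <- function(sites) {
  # midpoint for interval (e.g. 8-bp TSD) sites, the point itself otherwise
  as.integer(floor((GenomicRanges::start(sites) +
                      GenomicRanges::end(sites)) / 2))
}

.gene_window <- function(genes, upstream_bp, downstream_bp) {
  sp <- genes$span
  plus <- as.character(GenomicRanges::strand(sp)) == "+"
  gstart <- ifelse(plus, GenomicRanges::start(sp) - upstream_bp,
                   GenomicRanges::start(sp) - downstream_bp)
  gend <- ifelse(plus, GenomicRanges::end(sp) + downstream_bp,
                 GenomicRanges::end(sp) + upstream_bp)
  GenomicRanges::GRanges(GenomicRanges::seqnames(sp),
                         IRanges::IRanges(pmax(1, gstart), gend))
}

#' Assign integration sites to genes
#'
#' A site is assigned to every gene whose strand-oriented window
#' `[TSS - upstream_bp, TTS + downstream_bp]` overlaps the site interval by
#' at least 1 bp.  The default window (5 kb upstream of the TSS through
#' the TTS) is the one used for gene-region analyses; for
#' expression association use `upstream_bp = 5000, downstream_bp = 5000`
#' (within 5 kb of TSS and TTS).  Sites assigned to no gene are intergenic.
#'
#' @param sites Site `GRanges`.
#' @param genes A `gene_models` object.
#' @param upstream_bp Window extension upstream of the TSS (bp).
#' @param downstream_bp Window extension downstream of the TTS (bp).
#' @return A data.frame with one row per (site, gene) assignment:
#'   `site` (index into `sites`), `gene_id`, `regions` (`;`-joined
#'   subregion labels), `metagene_pct` (percent position within the span,
#'   `NA` outside it), `tss_offset` and `tts_offset` (signed
#'   strand-oriented bp of the site point from each anchor).
#' @export
assign_to_genes <- function(sites, genes, upstream_bp = 5000,
                            downstream_bp = 0) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  win <- .gene_window(genes, upstream_bp, downstream_bp)
  ov <- GenomicRanges::findOverlaps(sites, win, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  gid <- S4Vectors::mcols(genes$span)$gene_id
  if (length(si) == 0L)
    return(data.frame(site = integer(0), gene_id = character(0),
                      regions = character(0), metagene_pct = numeric(0),
                      tss_offset = integer(0), tts_offset = integer(0)))
  regions <- vapply(seq_along(si), function(k)
    paste(classify_region(sites[si[k]], genes, gi[k]), collapse = ";"),
    character(1))
  pct <- vapply(seq_along(si), function(k)
    metagene_position(sites[si[k]], genes, gi[k], strict = FALSE),
    numeric(1))
  pt <- .site_point(sites)[si]
  tss <- gene_tss(genes)[gi]
  tts <- gene_tts(genes)[gi]
  sgn <- ifelse(as.character(GenomicRanges::strand(genes$span))[gi] == "+",
                1L, -1L)
  data.frame(site = si, gene_id = gid[gi], regions = regions,
             metagene_pct = pct,
             tss_offset = sgn * (pt - tss),
             tts_offset = sgn * (pt - tts))
}

#' Classify the gene subregion(s) a site falls in
#'
#' Reports every subregion the site interval overlaps: `upstream`
#' (promoter window before the TSS), `five_prime_utr`, `coding_exon`,
#' `three_prime_utr` (exonic sequence split at the CDS bounds), `intron`
#' (span minus exons) and `downstream` (window past the TTS).  A site
#' spanning a boundary (e.g. an 8-bp duplication across an exon/intron
#' junction) reports all touched subregions.
#'
#' @param site A length-1 site `GRanges`.
#' @param genes A `gene_models` object.
#' @param gene_index Index of the gene within `genes`.
#' @param upstream_bp,downstream_bp Promoter / downstream window sizes.
#' @return Character vector of subregion labels.
#' @export
classify_region <- function(site, genes, gene_index,
                            upstream_bp = 5000, downstream_bp = 5000) {
  sp <- genes$span[gene_index]
  gid <- S4Vectors::mcols(sp)$gene_id
  ex <- genes$exons[[gid]]
  plus <- as.character(GenomicRanges::strand(sp)) == "+"
  cs <- S4Vectors::mcols(sp)$cds_start
  ce <- S4Vectors::mcols(sp)$cds_end
  s0 <- GenomicRanges::start(site); e0 <- GenomicRanges::end(site)
  touches <- function(a, b) length(a) > 0 && s0 <= b && e0 >= a
  hit_iv <- function(gr) any(GenomicRanges::start(gr) <= e0 &
                               GenomicRanges::end(gr) >= s0)
  out <- character(0)
  gs <- GenomicRanges::start(sp); ge <- GenomicRanges::end(sp)
  # promoter / downstream windows, strand-oriented
  up <- if (plus) c(gs - upstream_bp, gs - 1) else c(ge + 1, ge + upstream_bp)
  dn <- if (plus) c(ge + 1, ge + downstream_bp) else
    c(gs - downstream_bp, gs - 1)
  if (upstream_bp > 0 && s0 <= up[2] && e0 >= up[1]) out <- c(out, "upstream")
  if (downstream_bp > 0 && s0 <= dn[2] && e0 >= dn[1])
    out <- c(out, "downstream")
  if (hit_iv(ex)) {
    if (is.na(cs) || is.na(ce)) {
      out <- c(out, "noncoding_exon")
    } else {
      exs <- GenomicRanges::start(ex); exe <- GenomicRanges::end(ex)
      # exonic pieces left of the CDS, within it, and right of it
      cut <- function(lo, hi) {
        a <- pmax(exs, lo); b <- pmin(exe, hi)
        any(a <= b & a <= e0 & b >= s0)
      }
      left <- cut(gs, cs - 1)
      mid <- cut(cs, ce)
      right <- cut(ce + 1, ge)
      if (mid) out <- c(out, "coding_exon")
      if (left) out <- c(out, if (plus) "five_prime_utr" else
        "three_prime_utr")
      if (right) out <- c(out, if (plus) "three_prime_utr" else
        "five_prime_utr")
    }
  }
  # introns: span minus exons
  introns <- BiocGenerics::setdiff(GenomicRanges::granges(sp),
                                   GenomicRanges::granges(ex),
                                   ignore.strand = TRUE)
  if (hit_iv(introns)) out <- c(out, "intron")
  unique(out)
}

#' Position of a site within a gene as percent of gene length
#'
#' Gene size is normalised to 100%: the TSS maps to 0 and the TTS to 100,
#' along the gene's own orientation, using the unspliced span.  For
#' interval sites the midpoint is used.
#'
#' @inheritParams classify_region
#' @param strict Error when the site lies outside the span (default); with
#'   `strict = FALSE` return `NA`.
#' @return Percent in `[0, 100]`.
#' @export
metagene_position <- function(site, genes, gene_index, strict = TRUE) {
  sp <- genes$span[gene_index]
  pt <- .site_point(site)
  gs <- GenomicRanges::start(sp); ge <- GenomicRanges::end(sp)
  if (pt < gs || pt > ge) {
    if (strict) stop("site point outside gene span")
    return(NA_real_)
  }
  plus <- as.character(GenomicRanges::strand(sp)) == "+"
  d <- if (plus) pt - gs else ge - pt
  100 * d / (ge - gs)
}

#' Histogram of site offsets around the TSS or TTS
#'
#' For every (site, gene) pair whose signed strand-oriented offset of the
#' site point from the anchor lies within `[-window_bp, window_bp]`, the
#' offset is recorded (negative = upstream of the anchor along the gene's
#' orientation) and binned.
#'
#' @param sites Site `GRanges`.
#' @param genes A `gene_models` object.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param window_bp Half-width of the window (default 1000).
#' @param bin_bp Bin width (default 50).
#' @return A list with `offsets` (integer vector, one per in-window pair)
#'   and `histogram` (data.frame `bin_start`, `bin_end`, `count`).
#' @export
anchor_profile <- function(sites, genes, anchor = c("TSS", "TTS"),
                           window_bp = 1000, bin_bp = 50) {
  anchor <- match.arg(anchor)
  stopifnot(window_bp > 0, bin_bp > 0)
  ap <- if (anchor == "TSS") gene_tss(genes) else gene_tts(genes)
  sp <- genes$span
  anchors <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sp),
    IRanges::IRanges(pmax(1, ap - window_bp), ap + window_bp))
  pts <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites),
    IRanges::IRanges(.site_point(sites), width = 1L))
  ov <- GenomicRanges::findOverlaps(pts, anchors, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  sgn <- ifelse(as.character(GenomicRanges::strand(sp))[gi] == "+", 1L, -1L)
  off <- sgn * (.site_point(sites)[si] - ap[gi])
  off <- off[abs(off) <= window_bp]
  breaks <- seq(-window_bp, window_bp, by = bin_bp)
  if (breaks[length(breaks)] < window_bp) breaks <- c(breaks, window_bp)
  h <- graphics::hist(off, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  list(offsets = off,
       histogram = data.frame(bin_start = head(breaks, -1),
                              bin_end = tail(breaks, -1),
                              count = h$counts))
}

# -- expression ---------------------------------------------------------------

#' Classify genes by maternal/zygotic expression pattern
#'
#' Expression across developmental timepoints is split at the zygotic
#' genome activation (ZGA) boundary.  A gene is maternally expressed if its
#' FPKM reaches `threshold` at any pre-ZGA timepoint, zygotically if at any
#' post-ZGA timepoint; the four classes are `maternal_only`,
#' `zygotic_only`, `maternal_zygotic` and `silent`.
#'
#' @param expr A data.frame with column `gene_id` and one numeric FPKM
#'   column per timepoint (in developmental order).
#' @param zga_index Index of the first post-ZGA timepoint column (among
#'   the timepoint columns).
#' @param threshold Detection floor in FPKM (default 1).
#' @return A data.frame `gene_id`, `overall` (summed FPKM across
#'   timepoints), `class`.
#' @export
classify_expression <- function(expr, zga_index, threshold = 1) {
  tp <- setdiff(names(expr), "gene_id")
  stopifnot(zga_index >= 2, zga_index <= length(tp))
  m <- as.matrix(expr[, tp])
  pre <- m[, seq_len(zga_index - 1), drop = FALSE]
  post <- m[, zga_index:length(tp), drop = FALSE]
  mat <- apply(pre >= threshold, 1, any)
  zyg <- apply(post >= threshold, 1, any)
  cls <- ifelse(mat & zyg, "maternal_zygotic",
                ifelse(mat, "maternal_only",
                       ifelse(zyg, "zygotic_only", "silent")))
  data.frame(gene_id = expr$gene_id, overall = rowSums(m), class = cls)
}

#' Expression association of targeted versus control-targeted genes
#'
#' Compares the overall expression and maternal/zygotic class composition
#' of genes hit by the experimental sites against genes hit by matched
#' control sites (both assigned with the same rule, conventionally within
#' 5 kb of the TSS and TTS).
#'
#' @param assignments Assignment data.frame for the experimental sites
#'   (from [assign_to_genes()]).
#' @param expr_classes Output of [classify_expression()].
#' @param control_assignments Assignment data.frame for control sites.
#' @return A list with `summary` (per group: number of distinct genes,
#'   mean and median overall FPKM), `classes` (per group and class: count
#'   and fraction) and `n_missing_expr` (targeted genes absent from the
#'   expression table; they are counted as silent with overall 0).
#' @export
expression_association <- function(assignments, expr_classes,
                                   control_assignments) {
  lookup <- function(gid) {
    i <- match(gid, expr_classes$gene_id)
    data.frame(gene_id = gid,
               overall = ifelse(is.na(i), 0, expr_classes$overall[i]),
               class = ifelse(is.na(i), "silent",
                              expr_classes$class[i]))
  }
  one <- function(asg, group) {
    gid <- unique(asg$gene_id)
    d <- lookup(gid)
    cls <- table(factor(d$class, levels = c("maternal_only", "zygotic_only",
                                            "maternal_zygotic", "silent")))
    list(summary = data.frame(group = group, n_genes = length(gid),
                              mean_fpkm = if (length(gid)) mean(d$overall)
                              else NA_real_,
                              median_fpkm = if (length(gid))
                                median(d$overall) else NA_real_),
         classes = data.frame(group = group, class = names(cls),
                              n = as.integer(cls),
                              fraction = if (length(gid))
                                as.numeric(cls) / length(gid) else 0),
         n_missing = sum(!gid %in% expr_classes$gene_id))
  }
  e <- one(assignments, "experimental")
  c_ <- one(control_assignments, "control")
  list(summary = rbind(e$summary, c_$summary),
       classes = rbind(e$classes, c_$classes),
       n_missing_expr = e$n_missing + c_$n_missing)
}
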