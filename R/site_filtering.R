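# Fragment-count filtering of putative integration sites.
#
# NGS-detected insertions from linker-mediated PCR come with a fragment
# count (number of distinct sequenced fragments supporting the site), which
# is the confidence signal: genuine inserts in selected (single-insert)
# lines are supported by many fragments, while artefacts -- in particular
# spurious junctions at restriction-enzyme recognition sites used by the
# library protocol -- tend to be singletons.

#' Default restriction-enzyme recognition motifs
#'
#' MseI, BfaI and Csp6I, the three frequent cutters used in
#' linker-mediated-PCR integration-site libraries.  All three motifs are
#' palindromic.
#' @return Named character vector of recognition motifs.
#' @export
re_motifs_default <- function() {
  c(MseI = "TTAA", BfaI = "CTAG", Csp6I = "GTAC")
}

.filter_report <- function(n_input, kept, n_re_kept = 0L) {
  n_kept <- length(kept)
  list(n_input = n_input,
       n_kept = n_kept,
       n_dropped = n_input - n_kept,
       n_kept_with_RE_motif = n_re_kept,
       fraction_RE = if (n_kept > 0) n_re_kept / n_kept else 0)
}

#' Filter NGS sites from selected (single-insert) lines
#'
#' A putative integration site is kept iff its fragment count is strictly
#' greater than `min_count` (default 50).  Sites detected by TAIL-PCR or
#' inverse PCR carry their own validation and pass unconditionally.
#'
#' @param sites `GRanges` of sites with `fragment_count` and `method`
#'   metadata columns.
#' @param min_count Strict lower bound on fragment counts for NGS sites.
#' @return List with elements `sites` (the kept `GRanges`) and `report`
#'   (a filter report list).
#' @export
filter_selected <- function(sites, min_count = 50) {
  m <- S4Vectors::mcols(sites)
  keep <- m$method != "NGS" | m$fragment_count > min_count
  kept <- sites[keep]
  list(sites = kept, report = .filter_report(length(sites), kept))
}

#' Flag sites whose neighbourhood contains a restriction motif
#'
#' @param sites `GRanges` of sites.
#' @param genome Genome `DNAStringSet`.
#' @param re_motifs Named character vector of recognition motifs.
#' @param window_bp Half-width of the window around the insertion point in
#'   which a motif occurrence counts as "contained".
#' @return Logical vector, one per site.
#' @export
site_has_re_motif <- function(sites, genome,
                              re_motifs = re_motifs_default(),
                              window_bp = 20) {
  if (length(sites) == 0L) return(logical(0))
  occ <- lapply(re_motifs, scan_motif_sites, genome = genome)
  occ <- do.call(c, unname(occ))
  pt <- insertion_point(sites)
  len <- genome_lengths(genome)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites),
    IRanges::IRanges(
      start = pmax(1L, pt - as.integer(window_bp)),
      end = pmin(len[as.character(GenomicRanges::seqnames(sites))],
                 pt + as.integer(window_bp))))
  GenomicRanges::countOverlaps(win, occ, ignore.strand = TRUE) > 0L
}

#' Insertion point of a site
#'
#' The first base of the integration interval (for an annotated 8-bp
#' target-site duplication, the first duplicated base).
#' @param sites `GRanges` of sites.
#' @return Integer vector of 1-based positions.
#' @export
insertion_point <- function(sites) GenomicRanges::start(sites)

#' Filter NGS sites from unselected (multi-insert, diluted) pools
#'
#' The general fragment-count cut-off is lowered to `min_count` (default 7,
#' inclusive) because each insert is diluted in the pool; sites whose
#' insertion-point neighbourhood contains a recognition motif of one of the
#' library's restriction enzymes instead require at least `re_min_count`
#' fragments (default 50, inclusive), because spurious single-fragment
#' junctions concentrate at those motifs.
#'
#' @inheritParams site_has_re_motif
#' @param sites `GRanges` of NGS sites with `fragment_count` metadata.
#' @param min_count Inclusive cut-off for sites without a nearby motif.
#' @param re_min_count Inclusive cut-off for motif-containing sites.
#' @return List with elements `sites` and `report`; the report's
#'   `fraction_RE` is the fraction of kept sites containing a motif.
#' @export
filter_unselected <- function(sites, genome,
                              re_motifs = re_motifs_default(),
                              window_bp = 20,
                              min_count = 7, re_min_count = 50) {
  has_re <- site_has_re_motif(sites, genome, re_motifs, window_bp)
  fc <- S4Vectors::mcols(sites)$fragment_count
  keep <- ifelse(has_re, fc >= re_min_count, fc >= min_count)
  kept <- sites[keep]
  list(sites = kept,
       report = .filter_report(length(sites), kept, sum(has_re & keep)))
}

#' Collapse near-duplicate sites detected by multiple methods
#'
#' Sites on the same chromosome and strand whose insertion points lie
#' within `tolerance_bp` of each other (single linkage) collapse to one
#' record keeping the maximum fragment count and the union of detection
#' methods.  The representative location is that of the max-count member.
#'
#' @param site_lists A list of site `GRanges` (e.g. TAIL and NGS sets), or
#'   a single `GRanges`.
#' @param tolerance_bp Non-negative clustering radius in bp.
#' @return A `GRanges` of unique sites; `method` holds the `+`-joined
#'   union of methods per site.
#' @export
merge_unique_sites <- function(site_lists, tolerance_bp = 5) {
  stopifnot(tolerance_bp >= 0)
  all <- if (inherits(site_lists, "GRanges")) site_lists else
    do.call(c, unname(site_lists))
  if (length(all) == 0L) return(all)
  chrom <- as.character(GenomicRanges::seqnames(all))
  str <- as.character(GenomicRanges::strand(all))
  pt <- insertion_point(all)
  key <- paste(chrom, str)
  cluster <- integer(length(all))
  next_id <- 0L
  for (k in unique(key)) {
    i <- which(key == k)
    o <- i[order(pt[i])]
    # single linkage on a line: break where the gap exceeds the tolerance
    gaps <- diff(pt[o])
    brk <- cumsum(c(0L, as.integer(gaps > tolerance_bp)))
    cluster[o] <- next_id + brk + 1L
    next_id <- next_id + max(brk) + 1L
  }
  groups <- split(seq_along(all), cluster)
  reps <- unname(vapply(groups, function(i) {
    i[which.max(S4Vectors::mcols(all)$fragment_count[i])]
  }, integer(1)))
  out <- all[reps]
  S4Vectors::mcols(out)$method <- unname(vapply(groups, function(i) {
    paste(sort(unique(S4Vectors::mcols(all)$method[i])), collapse = "+")
  }, character(1)))
  S4Vectors::mcols(out)$fragment_count <- as.integer(unname(vapply(
    groups, function(i) max(S4Vectors::mcols(all)$fragment_count[i]),
    numeric(1))))
  names(out) <- NULL
  BiocGenerics::sort(out, ignore.strand = TRUE)
}
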