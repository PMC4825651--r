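# Bootstrap empirical enrichment statistics.
#
# For a feature track, the experimental overlap count is compared with the
# overlap count of each of N replicate matched control sets.  The
# enrichment value is the mean over replicates of (experimental count /
# control count); the empirical P-values count the replicates at least as
# extreme as the experimental set and divide by N.

.control_overlap_counts <- function(controls, track) {
  cnt <- integer(controls$n_sets)
  if (length(track) > 0L && length(controls$sites) > 0L) {
    hit <- GenomicRanges::countOverlaps(controls$sites, track,
                                        ignore.strand = TRUE) > 0L
    cnt <- tabulate(S4Vectors::mcols(controls$sites)$set[hit],
                    nbins = controls$n_sets)
  }
  cnt
}

#' Bootstrap enrichment of sites over a feature track
#'
#' @param sites Experimental site `GRanges`.
#' @param controls A `control_sets` object with sets of the same size.
#' @param track Feature `GRanges`.
#' @param feature Label for the feature (used in reports).
#' @return An object of class `enrichment_result`: a list with `feature`,
#'   `x_exp`, `control_counts`, `ratio` (mean over replicates with a
#'   non-zero control count of x_exp / x_ctrl; `NA` if every replicate has
#'   zero overlap), `p_enrich` (fraction of replicates with
#'   x_ctrl >= x_exp), `p_deplete` (fraction with x_ctrl <= x_exp; ties
#'   count in both) and `n_zero_control_sets`.
#' @export
site_enrichment <- function(sites, controls, track, feature = "feature") {
  stopifnot(inherits(controls, "control_sets"), controls$n_sets >= 1)
  if (controls$set_size != length(sites))
    warning("control set size (", controls$set_size,
            ") differs from experimental size (", length(sites), ")")
  x_exp <- overlap_count(sites, track)
  cnt <- .control_overlap_counts(controls, track)
  nz <- cnt > 0L
  ratio <- if (any(nz)) mean(x_exp / cnt[nz]) else NA_real_
  if (!any(nz))
    warning("all control overlap counts are zero for '", feature,
            "'; enrichment ratio undefined")
  structure(list(
    feature = feature,
    x_exp = x_exp,
    control_counts = cnt,
    ratio = ratio,
    p_enrich = mean(cnt >= x_exp),
    p_deplete = mean(cnt <= x_exp),
    n_zero_control_sets = sum(!nz)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  n <- length(x$control_counts)
  pfmt <- function(p) if (p == 0) sprintf("< %g", 1 / n) else sprintf("%g", p)
  cat(sprintf(
    "%s: x_exp=%d, ratio=%s, p_enrich=%s, p_deplete=%s (N=%d, zero-ctrl=%d)\n",
    x$feature, x$x_exp,
    ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio)),
    pfmt(x$p_enrich), pfmt(x$p_deplete), n, x$n_zero_control_sets))
  invisible(x)
}

#' Enrichment over a panel of feature tracks
#'
#' @inheritParams site_enrichment
#' @param tracks Named list of feature `GRanges`.
#' @param bh Add Benjamini-Hochberg adjusted columns (off by default; the
#'   per-feature empirical P-values are reported unadjusted).
#' @return A data.frame with one row per feature: `feature`, `x_exp`,
#'   `ratio`, `p_enrich`, `p_deplete`, `n_zero_control_sets` (plus
#'   `p_enrich_bh`, `p_deplete_bh` when `bh = TRUE`).
#' @export
enrichment_panel <- function(sites, controls, tracks, bh = FALSE) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  res <- lapply(names(tracks), function(nm)
    site_enrichment(sites, controls, tracks[[nm]], feature = nm))
  out <- data.frame(
    feature = vapply(res, `[[`, "", "feature"),
    x_exp = vapply(res, `[[`, 0L, "x_exp"),
    ratio = vapply(res, `[[`, 0, "ratio"),
    p_enrich = vapply(res, `[[`, 0, "p_enrich"),
    p_deplete = vapply(res, `[[`, 0, "p_deplete"),
    n_zero_control_sets = vapply(res, `[[`, 0L, "n_zero_control_sets"))
  if (bh) {
    out$p_enrich_bh <- stats::p.adjust(out$p_enrich, method = "BH")
    out$p_deplete_bh <- stats::p.adjust(out$p_deplete, method = "BH")
  }
  out
}

#' Per-chromosome distribution of sites versus controls
#'
#' @inheritParams site_enrichment
#' @return A data.frame with one row per chromosome: `chrom`, `observed`
#'   site count, `control_mean` and `control_sd` over replicates.
#' @export
chromosome_distribution <- function(sites, controls) {
  chroms <- unique(c(as.character(GenomicRanges::seqnames(sites)),
                     as.character(GenomicRanges::seqnames(controls$sites))))
  chroms <- sort(chroms)
  obs <- table(factor(as.character(GenomicRanges::seqnames(sites)),
                      levels = chroms))
  cc <- table(
    factor(S4Vectors::mcols(controls$sites)$set,
           levels = seq_len(controls$n_sets)),
    factor(as.character(GenomicRanges::seqnames(controls$sites)),
           levels = chroms))
  data.frame(chrom = chroms,
             observed = as.integer(obs),
             control_mean = apply(cc, 2, mean),
             control_sd = apply(cc, 2, sd),
             row.names = NULL)
}
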