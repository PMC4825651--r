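# Null calibration of the bootstrap enrichment statistic.

#' Empirical null flag rate of the bootstrap enrichment test
#'
#' Simulation study of the enrichment statistic's calibration: experimental
#' sites are drawn from the very generator that produces the matched
#' controls (uniform random locations on a simulated genome), so every
#' feature is null by construction.  For `n_features` independent random
#' feature tracks (each `n_intervals` intervals of `interval_bp` bp,
#' covering about `coverage` of the genome), the empirical enrichment
#' P-value is computed against `n_sets` control sets and the fraction of
#' features flagged at the `alpha` significance threshold is returned.  A
#' calibrated test flags about `alpha`; the tie-inclusive counting of the
#' empirical P makes it mildly conservative.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param genome_length Simulated genome length in bp.
#' @param n_sites Experimental set size.
#' @param n_sets Number of control replicate sets.
#' @param n_features Number of random feature tracks tested.
#' @param coverage Approximate fraction of the genome each track covers.
#' @param interval_bp Length of each track interval.
#' @param site_len Length of the random locations (pool and experimental).
#' @param pool_size Size of the shared random-location pool.
#' @param alpha Significance threshold on `p_enrich`.
#' @return The fraction of features with `p_enrich <= alpha`, with the
#'   per-feature P-values as attribute `p_enrich`.
#' @export
null_calibration_fraction <- function(seed, genome_length = 2e6,
                                      n_sites = 500, n_sets = 200,
                                      n_features = 200, coverage = 0.1,
                                      interval_bp = 1000, site_len = 50,
                                      pool_size = 1e6, alpha = 0.05) {
  g <- make_genome(c(chr1 = genome_length), gc = 0.5,
                   seed = .derive_seed(seed, "null-genome"))
  # n_sets + 1 draws from the same generator; the last one plays the
  # experimental set
  ctrl <- uniform_controls(g, set_size = n_sites, n_sets = n_sets + 1L,
                           site_len = site_len, pool_size = pool_size,
                           seed = .derive_seed(seed, "null-controls"))
  exp_sites <- control_set(ctrl, n_sets + 1L)
  ctrl$sites <- ctrl$sites[S4Vectors::mcols(ctrl$sites)$set <= n_sets]
  ctrl$n_sets <- as.integer(n_sets)
  n_iv <- max(1L, round(coverage * genome_length / interval_bp))
  p <- withr::with_seed(.derive_seed(seed, "null-features"), {
    vapply(seq_len(n_features), function(i) {
      st <- sample.int(genome_length - interval_bp, n_iv)
      track <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(st, width = interval_bp))
      site_enrichment(exp_sites, ctrl, track)$p_enrich
    }, numeric(1))
  })
  structure(mean(p <= alpha), p_enrich = p)
}
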