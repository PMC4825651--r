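# Matched random control generation.
#
# Enrichment of integration sites over genomic features is only meaningful
# against controls that share the detection biases of the experimental
# protocol.  Two modes are provided:
#   * uniform  -- a large pool of fixed-length random locations (optionally
#     restricted to a mappability track) sampled repeatedly into control
#     sets of the experimental size;
#   * re_matched -- for library protocols based on restriction digestion,
#     each control site is placed at exactly the same distance from a
#     (randomly chosen) recognition site of the same enzyme as its
#     experimental counterpart.

.derive_seed <- function(seed, label) {
  # stable small-integer stream split: fold a label into the master seed
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Build a restriction-site index for a genome
#'
#' Locates every occurrence of each enzyme's recognition motif and stores
#' the sorted start positions per chromosome.
#'
#' @param genome Genome `DNAStringSet`.
#' @param motifs Named character vector of recognition motifs
#'   (default [re_motifs_default()]); the name order fixes the tie-break
#'   order used downstream.
#' @return An object of class `restriction_index`.
#' @export
restriction_index <- function(genome, motifs = re_motifs_default()) {
  stopifnot(length(motifs) >= 1, !is.null(names(motifs)))
  pos <- lapply(motifs, function(m) {
    gr <- scan_motif_sites(genome, m)
    split(GenomicRanges::start(gr),
          as.character(GenomicRanges::seqnames(gr)))
  })
  structure(list(motifs = motifs, positions = pos,
                 chrom_lengths = genome_lengths(genome)),
            class = "restriction_index")
}

#' @export
print.restriction_index <- function(x, ...) {
  n <- vapply(x$positions, function(p) sum(lengths(p)), numeric(1))
  cat("restriction_index:",
      paste(sprintf("%s(%s)=%d", names(x$motifs), x$motifs, n),
            collapse = ", "), "\n")
  invisible(x)
}

#' Distance from each site to the nearest restriction site
#'
#' For every insertion point, the absolute distance (bp, either direction)
#' to the nearest recognition-motif start over all indexed enzymes.  Ties
#' between enzymes are broken by the index's enzyme order; ties between two
#' equidistant occurrences of one enzyme by the lower coordinate.
#'
#' @param sites `GRanges` of sites.
#' @param index A `restriction_index`.
#' @return A data.frame with columns `enzyme` and `distance`, one row per
#'   site.
#' @export
nearest_re_distance <- function(sites, index) {
  n <- length(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  pt <- insertion_point(sites)
  enz <- names(index$motifs)
  best_d <- rep(Inf, n)
  best_e <- rep(NA_character_, n)
  for (e in enz) {
    for (ch in unique(chrom)) {
      p <- index$positions[[e]][[ch]]
      i <- which(chrom == ch)
      if (is.null(p) || length(p) == 0L) next
      # nearest sorted-vector neighbour via findInterval
      j <- findInterval(pt[i], p)
      lo <- ifelse(j >= 1L, p[pmax(j, 1L)], NA_integer_)
      hi <- ifelse(j < length(p), p[pmin(j + 1L, length(p))], NA_integer_)
      dlo <- abs(pt[i] - lo); dhi <- abs(hi - pt[i])
      dlo[is.na(dlo)] <- Inf; dhi[is.na(dhi)] <- Inf
      d <- pmin(dlo, dhi)
      upd <- d < best_d[i]   # strict: earlier enzyme wins ties
      best_d[i[upd]] <- d[upd]
      best_e[i[upd]] <- e
    }
  }
  if (any(is.infinite(best_d))) {
    bad <- which(is.infinite(best_d))[1]
    stop("no restriction-site occurrence on chromosome ", chrom[bad],
         " for site at ", chrom[bad], ":", pt[bad])
  }
  data.frame(enzyme = best_e, distance = as.integer(best_d))
}

.control_collection <- function(sites, n_sets, set_size, mode, seed,
                                keys = NULL) {
  structure(list(sites = sites, n_sets = n_sets, set_size = set_size,
                 mode = mode, seed = seed, keys = keys),
            class = "control_sets")
}

#' @export
print.control_sets <- function(x, ...) {
  cat(sprintf("control_sets: %d sets x %d sites, mode=%s, seed=%s\n",
              x$n_sets, x$set_size, x$mode,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Extract one replicate control set
#' @param controls A `control_sets` object.
#' @param i Replicate index in `1..n_sets`.
#' @return `GRanges` of the i-th control set.
#' @export
control_set <- function(controls, i) {
  stopifnot(i >= 1, i <= controls$n_sets)
  controls$sites[S4Vectors::mcols(controls$sites)$set == i]
}

#' Uniform random control sets
#'
#' Generates a pool of `pool_size` fixed-length random genomic locations
#' (uniform over the mappable region), then draws `n_sets` independent
#' samples of `set_size` locations without replacement from the pool.
#'
#' @param genome Genome `DNAStringSet`.
#' @param set_size Size of each control set (the experimental set size).
#' @param n_sets Number of replicate sets (default 1000).
#' @param site_len Length of each random location in bp (default 50).
#' @param pool_size Size of the random-location pool (default 1e6).
#' @param mappability Optional `GRanges` of mappable regions; controls are
#'   restricted to lie entirely within it.
#' @param seed Integer seed for reproducibility (or `NULL`).
#' @return A `control_sets` object whose `sites` is a single `GRanges`
#'   with a `set` metadata column.
#' @export
uniform_controls <- function(genome, set_size, n_sets = 1000,
                             site_len = 50, pool_size = 1e6,
                             mappability = NULL, seed = NULL) {
  stopifnot(set_size >= 1, n_sets >= 1, site_len >= 1,
            pool_size >= set_size)
  len <- genome_lengths(genome)
  if (is.null(mappability)) {
    allowed <- GenomicRanges::GRanges(
      names(len), IRanges::IRanges(1L, unname(len)))
  } else {
    allowed <- GenomicRanges::reduce(mappability, ignore.strand = TRUE)
  }
  nstart <- BiocGenerics::width(allowed) - as.integer(site_len) + 1L
  ok <- nstart >= 1L
  allowed <- allowed[ok]; nstart <- nstart[ok]
  if (length(allowed) == 0L)
    stop("no mappable region long enough for site_len=", site_len)
  .with_seed(seed, {
    iv <- sample.int(length(allowed), pool_size, replace = TRUE,
                     prob = nstart)
    off <- floor(runif(pool_size) * nstart[iv])
    pool_chrom <- as.character(GenomicRanges::seqnames(allowed))[iv]
    pool_start <- GenomicRanges::start(allowed)[iv] + as.integer(off)
    idx <- unlist(lapply(seq_len(n_sets), function(s)
      sample.int(pool_size, set_size, replace = FALSE)))
    gr <- GenomicRanges::GRanges(
      pool_chrom[idx],
      IRanges::IRanges(start = pool_start[idx], width = site_len),
      set = rep(seq_len(n_sets), each = set_size))
    .control_collection(gr, n_sets, set_size, "uniform", seed)
  })
}

#' Restriction-site / distance matched control sets
#'
#' For each experimental site, its nearest restriction site (enzyme and
#' absolute distance) is computed; each replicate control is then placed at
#' exactly that distance from a uniformly chosen genome-wide occurrence of
#' the same enzyme, on a uniformly chosen side.  Placements falling off the
#' chromosome are redrawn.  Matching is constructive: the control carries
#' its experimental site's key by construction, its own nearest occurrence
#' may be closer.
#'
#' @param sites Experimental site `GRanges`.
#' @param index A `restriction_index` for the genome.
#' @param n_sets Number of replicate sets (default 1000).
#' @param seed Integer seed (or `NULL`).
#' @param max_retry Redraw rounds for out-of-bounds placements.
#' @return A `control_sets` object; `keys` holds the per-site match keys
#'   (recycled across replicates), and each control's `enzyme`,
#'   `distance` and `occ_pos` metadata record its construction.
#' @export
re_matched_controls <- function(sites, index, n_sets = 1000, seed = NULL,
                                max_retry = 100) {
  set_size <- length(sites)
  stopifnot(set_size >= 1, n_sets >= 1)
  keys <- nearest_re_distance(sites, index)
  # flat genome-wide occurrence lists per enzyme
  occ <- lapply(names(index$motifs), function(e) {
    p <- index$positions[[e]]
    list(chrom = rep(names(p), lengths(p)), pos = unlist(p, use.names = FALSE))
  })
  names(occ) <- names(index$motifs)
  clen <- index$chrom_lengths
  .with_seed(seed, {
    n_tot <- set_size * n_sets
    key_i <- rep(seq_len(set_size), times = n_sets)
    enz <- keys$enzyme[key_i]
    dist <- keys$distance[key_i]
    chrom <- character(n_tot); pos <- integer(n_tot)
    occp <- integer(n_tot)
    todo <- seq_len(n_tot)
    for (r in seq_len(max_retry)) {
      if (length(todo) == 0L) break
      for (e in unique(enz[todo])) {
        i <- todo[enz[todo] == e]
        oe <- occ[[e]]
        if (length(oe$pos) == 0L)
          stop("no genome-wide occurrence for enzyme ", e)
        k <- sample.int(length(oe$pos), length(i), replace = TRUE)
        side <- sample(c(-1L, 1L), length(i), replace = TRUE)
        chrom[i] <- oe$chrom[k]
        pos[i] <- oe$pos[k] + side * dist[i]
        occp[i] <- oe$pos[k]
      }
      bad <- pos[todo] < 1L | pos[todo] > unname(clen[chrom[todo]])
      todo <- todo[bad]
    }
    if (length(todo))
      stop("could not place ", length(todo),
           " matched controls within ", max_retry, " retries")
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = pos, width = 1L),
      set = rep(seq_len(n_sets), each = set_size),
      enzyme = enz, distance = dist, occ_pos = occp)
    .control_collection(gr, n_sets, set_size, "re_matched", seed,
                        keys = keys)
  })
}
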