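# Flanking-window extraction, aggregated motif matrices, and dinucleotide
# step-parameter (DNA flexibility) profiles around integration sites.
#
# The structural proxy for local DNA deformability is the set of six
# rigid-body base-pair step parameters (Twist, Tilt, Roll in degrees;
# Shift, Slide, Rise in Angstrom) averaged over protein-DNA crystal
# structures.  Each aligned flanking window is reduced to its 47 (for
# 48-mers) overlapping dinucleotide steps, each step is assigned its mean
# crystallographic value, and values are averaged per position across
# windows; the same is done for replicate control window sets to obtain a
# null envelope.

.STEPS <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
            "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

# Mean base-pair step parameters from the crystallographic compilation of
# protein-bound DNA, in the orientation convention in which the GC step has
# Twist 36.1 deg / Slide 0.41 A and the GG step 32.9 deg / -0.22 A.
# Columns: twist, tilt (deg); roll (deg); shift, slide, rise (A).
.STEP_TABLE <- matrix(c(
  # twist  tilt   roll  shift  slide  rise
    35.1, -1.4,   0.7, -0.03, -0.08, 3.27,  # AA
    37.3, -0.5,   4.7,  0.09,  0.53, 3.33,  # AC
    36.3, -1.5,   1.9, -0.28,  0.09, 3.37,  # AG
    37.8,  0.0,   3.3,  0.00,  0.05, 3.42,  # AT
    31.5, -0.1,   0.7,  0.13, -0.58, 3.36,  # CA
    32.9,  0.1,   3.6, -0.05, -0.22, 3.42,  # CC
    33.6,  0.0,   0.3,  0.00, -0.38, 3.40,  # CG
    36.3,  1.5,   1.9,  0.28,  0.09, 3.37,  # CT
    31.9, -1.7,   4.5,  0.09, -0.25, 3.34,  # GA
    36.1,  0.0,   5.4,  0.00,  0.41, 3.39,  # GC
    32.9, -0.1,   3.6,  0.05, -0.22, 3.42,  # GG
    37.3,  0.5,   4.7, -0.09,  0.53, 3.33,  # GT
    29.3,  0.0,   1.1,  0.00, -0.59, 3.31,  # TA
    31.9,  1.7,   4.5, -0.09, -0.25, 3.34,  # TC
    31.5,  0.1,   0.7, -0.13, -0.58, 3.36,  # TG
    35.1,  1.4,   0.7,  0.03, -0.08, 3.27), # TT
  nrow = 16, byrow = TRUE,
  dimnames = list(.STEPS,
                  c("twist", "tilt", "roll", "shift", "slide", "rise")))

#' Dinucleotide step-parameter table
#'
#' Mean values of the six rigid-body step parameters for all 16
#' dinucleotide steps, taken from the crystallographic compilation of
#' protein-DNA complexes.  The table satisfies reverse-complement symmetry
#' (Twist/Roll/Rise/Slide equal, Tilt/Shift negated between a step and its
#' reverse complement); four anchor values (Twist and Slide of the GC and
#' GG steps) are asserted at every call.
#'
#' @return A 16 x 6 data.frame (rows = steps, columns `twist`, `tilt`,
#'   `roll`, `shift`, `slide`, `rise`).
#' @export
step_table <- function() {
  t <- .STEP_TABLE
  stopifnot(t["GC", "twist"] == 36.1, t["GC", "slide"] == 0.41,
            t["GG", "twist"] == 32.9, t["GG", "slide"] == -0.22)
  as.data.frame(t)
}

# -- flanking windows ---------------------------------------------------------

#' Extract aligned flanking windows around integration sites
#'
#' Two layouts, both producing windows of `2 * flank + tsd_len = 48` nt by
#' default, oriented along the site's own strand (minus-strand windows are
#' reverse-complemented):
#'
#' * `"tsd"` -- for transposons with an annotated 8-bp target-site
#'   duplication (8-bp site intervals): `flank` bases before and after the
#'   duplicated site, so the TSD occupies positions 21--28 (1-based).
#' * `"point"` -- for point integrations (1-bp site intervals): `flank`
#'   bases before and `flank + 8` bases after the insertion point, so the
#'   first integrated base sits at position 21.
#'
#' Windows running off the chromosome or containing `N` are excluded and
#' tallied.
#'
#' @param sites Site `GRanges` with strand `+`/`-` (controls without
#'   strand are treated as `+`).
#' @param genome Genome `DNAStringSet`.
#' @param layout `"tsd"` or `"point"`.
#' @param flank Bases of flank before the site (default 20).
#' @param tsd_len Length of the duplicated target site (default 8).
#' @return An object of class `flank_windows`: list with `seq` (character
#'   vector of windows), `layout`, `width`, `site_position` (1-based
#'   position of the first integration-site base) and `n_excluded`.
#' @export
extract_flank_windows <- function(sites, genome, layout = c("tsd", "point"),
                                  flank = 20, tsd_len = 8) {
  layout <- match.arg(layout)
  w <- 2L * flank + tsd_len
  str <- as.character(GenomicRanges::strand(sites))
  str[!str %in% c("+", "-")] <- "+"
  if (layout == "tsd") {
    if (!all(GenomicRanges::width(sites) == tsd_len))
      stop("tsd layout requires ", tsd_len, "-bp site intervals")
    ws <- GenomicRanges::start(sites) - flank
    we <- GenomicRanges::end(sites) + flank
  } else {
    if (!all(GenomicRanges::width(sites) == 1L))
      stop("point layout requires 1-bp site intervals")
    p <- GenomicRanges::start(sites)
    after <- flank + tsd_len - 1L
    ws <- ifelse(str == "+", p - flank, p - after)
    we <- ifelse(str == "+", p + after, p + flank)
  }
  chrom <- as.character(GenomicRanges::seqnames(sites))
  len <- genome_lengths(genome)
  inb <- ws >= 1L & we <= unname(len[chrom]) & chrom %in% names(len)
  gr <- GenomicRanges::GRanges(chrom[inb],
                               IRanges::IRanges(ws[inb], we[inb]),
                               strand = str[inb])
  seqs <- extract_window(genome, gr)
  clean <- !grepl("[^ACGT]", seqs)
  structure(list(seq = seqs[clean], layout = layout, width = w,
                 site_position = flank + 1L,
                 n_excluded = sum(!inb) + sum(!clean)),
            class = "flank_windows")
}

#' @export
print.flank_windows <- function(x, ...) {
  cat(sprintf("flank_windows: %d windows of %d nt (layout=%s, %d excluded)\n",
              length(x$seq), x$width, x$layout, x$n_excluded))
  invisible(x)
}

# integer-encode windows: matrix n x L with A=1,C=2,G=3,T=4
.encode_windows <- function(seqs) {
  if (length(seqs) == 0L) stop("no windows to profile")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("windows of unequal length")
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)),
                    c("A", "C", "G", "T")),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("windows contain characters outside {A,C,G,T}")
  m
}

# -- position matrix ----------------------------------------------------------

#' Per-position base probabilities and information content
#'
#' Column-wise base frequencies of an aligned window set, with information
#' content per position computed against a uniform background as
#' `2 + sum_b p_b log2 p_b` bits (`0 log 0 = 0`).  No small-sample
#' correction is applied by default; `correct = TRUE` subtracts the
#' standard `e(n) = 3 / (2 ln 2 n)` term for logo-tool parity.
#'
#' @param windows A `flank_windows` object (or character vector of
#'   equal-length windows).
#' @param correct Apply the small-sample correction (default `FALSE`).
#' @return An object of class `position_matrix`: list with `prob`
#'   (L x 4 matrix, columns A,C,G,T), `bits` (length-L vector) and `n`.
#' @export
position_matrix <- function(windows, correct = FALSE) {
  seqs <- if (inherits(windows, "flank_windows")) windows$seq else windows
  m <- .encode_windows(seqs)
  n <- nrow(m)
  prob <- t(apply(m, 2, function(col) tabulate(col, nbins = 4) / n))
  colnames(prob) <- c("A", "C", "G", "T")
  plogp <- prob * log2(prob)
  plogp[prob == 0] <- 0
  bits <- 2 + rowSums(plogp)
  if (correct) bits <- pmax(0, bits - 3 / (2 * log(2) * n))
  structure(list(prob = prob, bits = bits, n = n),
            class = "position_matrix")
}

#' Write a position matrix as a logo-tool-importable TSV
#' @param pm A `position_matrix`.
#' @param path Output path (columns: position, A, C, G, T, bits).
#' @return Invisibly, `path`.
#' @export
write_position_matrix <- function(pm, path) {
  d <- data.frame(position = seq_len(nrow(pm$prob)), pm$prob,
                  bits = pm$bits)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- flexibility profiles -----------------------------------------------------

# per-position mean of one step parameter over a set of encoded windows
.step_profile <- function(enc, parameter) {
  vals <- .STEP_TABLE[, parameter]
  L <- ncol(enc)
  idx <- 4L * (enc[, -L, drop = FALSE] - 1L) + enc[, -1L, drop = FALSE]
  prof <- matrix(vals[idx], nrow = nrow(enc))
  colMeans(prof)
}

#' Dinucleotide step-parameter profile of aligned windows versus controls
#'
#' Reduces each window to its overlapping dinucleotide steps, assigns each
#' step its mean crystallographic parameter value, and averages per
#' dinucleotide position across windows (profile length = window length
#' - 1).  When replicate control window sets are supplied, the same
#' reduction is applied to each replicate to obtain a per-position null
#' mean and standard deviation.
#'
#' @param windows A `flank_windows` object (or character vector) of
#'   experimental windows.
#' @param parameter One of `"twist"`, `"tilt"`, `"roll"`, `"shift"`,
#'   `"slide"`, `"rise"`.
#' @param control_windows Optional list of `flank_windows` (or character
#'   vectors), one per control replicate.
#' @return An object of class `flexibility_profile`: list with
#'   `parameter`, `position` (dinucleotide position index), `exp`
#'   (experimental per-position means), and -- when controls are given --
#'   `ctrl_mean`, `ctrl_sd`, `n_ctrl` and the replicate profile matrix
#'   `ctrl_profiles`.
#' @export
flexibility_profile <- function(windows,
                                parameter = c("twist", "tilt", "roll",
                                              "shift", "slide", "rise"),
                                control_windows = NULL) {
  parameter <- match.arg(parameter)
  seqs <- if (inherits(windows, "flank_windows")) windows$seq else windows
  enc <- .encode_windows(seqs)
  expv <- .step_profile(enc, parameter)
  out <- list(parameter = parameter, position = seq_along(expv),
              exp = expv, ctrl_mean = NULL, ctrl_sd = NULL,
              n_ctrl = 0L, ctrl_profiles = NULL)
  if (!is.null(control_windows)) {
    profs <- t(vapply(control_windows, function(cw) {
      s <- if (inherits(cw, "flank_windows")) cw$seq else cw
      .step_profile(.encode_windows(s), parameter)
    }, numeric(length(expv))))
    out$ctrl_profiles <- profs
    out$ctrl_mean <- colMeans(profs)
    out$ctrl_sd <- apply(profs, 2, sd)
    out$n_ctrl <- nrow(profs)
  }
  structure(out, class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("flexibility_profile: %s over %d positions (%d control sets)\n",
              x$parameter, length(x$exp), x$n_ctrl))
  invisible(x)
}

#' Extract windows for every replicate of a control collection
#'
#' Convenience helper: applies [extract_flank_windows()] with the point
#' layout to each replicate set of a `control_sets` object (control sites
#' are unstranded 1-bp points).
#'
#' @param controls A `control_sets` object.
#' @param genome Genome `DNAStringSet`.
#' @param flank,tsd_len Window geometry, as in [extract_flank_windows()].
#' @return List of `flank_windows`, one per replicate.
#' @export
control_flank_windows <- function(controls, genome, flank = 20,
                                  tsd_len = 8) {
  pts <- GenomicRanges::resize(controls$sites, width = 1L, fix = "start")
  lapply(seq_len(controls$n_sets), function(i) {
    extract_flank_windows(
      pts[S4Vectors::mcols(pts)$set == i], genome,
      layout = "point", flank = flank, tsd_len = tsd_len)
  })
}

#' Per-position divergence of an experimental profile from its null
#'
#' Quantifies the visual experimental-versus-control comparison:
#' `z = (exp - ctrl_mean) / ctrl_sd` per dinucleotide position, plus the
#' empirical fraction of control replicates whose deviation from the
#' control mean is at least as large as the experimental deviation.
#'
#' @param profile A `flexibility_profile` computed with at least 30
#'   control replicates.
#' @return A data.frame `position`, `exp`, `ctrl_mean`, `ctrl_sd`, `z`
#'   (`NA` where `ctrl_sd` is 0, flagged in `sd_zero`), `p_empirical`.
#' @export
profile_divergence <- function(profile) {
  stopifnot(inherits(profile, "flexibility_profile"))
  if (profile$n_ctrl < 30)
    stop("profile_divergence requires >= 30 control replicates")
  dev <- profile$exp - profile$ctrl_mean
  sd0 <- profile$ctrl_sd == 0
  z <- ifelse(sd0, NA_real_, dev / profile$ctrl_sd)
  cdev <- abs(sweep(profile$ctrl_profiles, 2, profile$ctrl_mean))
  p_emp <- vapply(seq_along(dev), function(i)
    mean(cdev[, i] >= abs(dev[i])), numeric(1))
  data.frame(position = profile$position, exp = profile$exp,
             ctrl_mean = profile$ctrl_mean, ctrl_sd = profile$ctrl_sd,
             z = z, sd_zero = sd0, p_empirical = p_emp)
}

#' Write a flexibility profile (with envelope) as TSV
#' @param profile A `flexibility_profile` with controls.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_flexibility_profile <- function(profile, path) {
  stopifnot(profile$n_ctrl >= 1)
  z <- ifelse(profile$ctrl_sd == 0, NA_real_,
              (profile$exp - profile$ctrl_mean) / profile$ctrl_sd)
  d <- data.frame(position = profile$position, exp = profile$exp,
                  ctrl_mean = profile$ctrl_mean,
                  ctrl_sd = profile$ctrl_sd, z = z)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
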