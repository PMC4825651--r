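# End-to-end orchestration: filter -> controls -> enrichment panel ->
# gene context -> motif matrix -> flexibility profile, with a single
# master seed, per-stage derived seeds, and a machine-readable report.

#' Default run configuration
#'
#' All thresholds trace to the filtering and control-generation defaults
#' documented on the individual stage functions: selected-set fragment
#' counts strictly > 50; unselected cut-off >= 7 with >= 50 for sites near
#' a restriction motif (+-20 bp window); 1000 control sets from a pool of
#' one million 50-bp random locations; gene windows 5 kb upstream of the
#' TSS; 1-kb anchor windows.
#'
#' @param ... Named overrides of any default entry.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "selected",            # selected | unselected
    selected_gt = 50,
    unselected_ge = 7,
    re_ge = 50,
    re_window = 20,
    control_mode = "uniform",     # uniform | re_matched
    n_sets = 1000,
    pool_size = 1e6,
    site_len = 50,
    upstream_bp = 5000,
    window_bp = 1000,
    bin_bp = 50,
    layout = "tsd",               # tsd | point
    flex_parameter = "twist",
    merge_tolerance_bp = 5,
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  stopifnot(cfg$n_sets >= 1, cfg$pool_size >= 1, cfg$site_len >= 1,
            cfg$selected_gt >= 0, cfg$unselected_ge >= 0, cfg$re_ge >= 0,
            cfg$re_window >= 0, cfg$upstream_bp >= 0, cfg$window_bp > 0,
            cfg$mode %in% c("selected", "unselected"),
            cfg$control_mode %in% c("uniform", "re_matched"),
            cfg$layout %in% c("tsd", "point"))
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return `read_config`: a `run_config` list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full integration-site preference pipeline
#'
#' Stages: fragment-count filtering, matched-control generation, feature
#' enrichment panel, chromosome distribution, gene-context profiling
#' (assignments, metagene, TSS/TTS anchors), aggregated motif matrix, and
#' the flexibility profile of the configured step parameter.  Every
#' stochastic stage is seeded deterministically from `config$seed`, so a
#' rerun with the same inputs and config reproduces all outputs.
#'
#' @param genome Genome `DNAStringSet`.
#' @param sites Site `GRanges` (as from [read_sites()]).
#' @param genes Optional `gene_models`.
#' @param tracks Named list of feature `GRanges` for the enrichment panel.
#' @param expr Optional expression data.frame (with `zga_index` attribute
#'   or ZGA at the default position used by [classify_expression()]).
#' @param config A `run_config` (see [default_config()]).
#' @param outdir Optional directory; when given, all tabular outputs and a
#'   JSON report are written there.
#' @return A list with per-stage results and a `report` list.
#' @export
run_pipeline <- function(genome, sites, genes = NULL, tracks = list(),
                         expr = NULL, config = default_config(),
                         outdir = NULL) {
  .validate_config(config)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  report <- list(config = unclass(config), stages = list())
  out <- list()

  # 1. filter
  filt <- if (config$mode == "selected") {
    filter_selected(sites, min_count = config$selected_gt)
  } else {
    filter_unselected(sites, genome, window_bp = config$re_window,
                      min_count = config$unselected_ge,
                      re_min_count = config$re_ge)
  }
  kept <- filt$sites
  report$stages$filter <- filt$report
  out$filter <- filt
  if (length(kept) == 0L) stop("stage 'filter': no sites pass the filter")

  # 2. controls
  controls <- if (config$control_mode == "uniform") {
    uniform_controls(genome, set_size = length(kept),
                     n_sets = config$n_sets, site_len = config$site_len,
                     pool_size = config$pool_size,
                     seed = .derive_seed(config$seed, "controls"))
  } else {
    idx <- restriction_index(genome)
    re_matched_controls(kept, idx, n_sets = config$n_sets,
                        seed = .derive_seed(config$seed, "controls"))
  }
  out$controls <- controls
  report$stages$controls <- list(mode = controls$mode,
                                 n_sets = controls$n_sets,
                                 set_size = controls$set_size,
                                 seed = controls$seed)

  # 3. enrichment panel + chromosome distribution
  if (length(tracks)) {
    out$enrichment <- enrichment_panel(kept, controls, tracks)
    report$stages$enrichment <- list(n_features = nrow(out$enrichment))
    if (!is.null(outdir))
      utils::write.table(out$enrichment,
                         file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out$chromosomes <- chromosome_distribution(kept, controls)
  if (!is.null(outdir))
    utils::write.table(out$chromosomes,
                       file.path(outdir, "chromosome_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # 4. gene context
  if (!is.null(genes)) {
    asg <- assign_to_genes(kept, genes, upstream_bp = config$upstream_bp)
    out$assignments <- asg
    out$tss_profile <- anchor_profile(kept, genes, "TSS",
                                      window_bp = config$window_bp,
                                      bin_bp = config$bin_bp)
    out$tts_profile <- anchor_profile(kept, genes, "TTS",
                                      window_bp = config$window_bp,
                                      bin_bp = config$bin_bp)
    report$stages$gene_context <- list(
      n_assignments = nrow(asg),
      n_intergenic = length(kept) - length(unique(asg$site)))
    if (!is.null(outdir)) {
      utils::write.table(asg, file.path(outdir, "assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$tss_profile$histogram,
                         file.path(outdir, "tss_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(out$tts_profile$histogram,
                         file.path(outdir, "tts_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(expr)) {
      zga <- attr(expr, "zga_index")
      if (is.null(zga)) zga <- 2L
      cls <- classify_expression(expr, zga_index = zga)
      casg <- assign_to_genes(control_set(controls, 1L), genes,
                              upstream_bp = config$upstream_bp,
                              downstream_bp = config$upstream_bp)
      easg <- assign_to_genes(kept, genes,
                              upstream_bp = config$upstream_bp,
                              downstream_bp = config$upstream_bp)
      out$expression <- expression_association(easg, cls, casg)
    }
  }

  # 5. motif + flexibility
  fw <- extract_flank_windows(kept, genome, layout = config$layout)
  out$windows <- fw
  out$pwm <- position_matrix(fw)
  cw <- control_flank_windows(controls, genome)
  out$flexibility <- flexibility_profile(fw, config$flex_parameter,
                                         control_windows = cw)
  report$stages$sequence_profile <- list(
    n_windows = length(fw$seq), n_excluded = fw$n_excluded,
    layout = fw$layout, parameter = config$flex_parameter)
  if (!is.null(outdir)) {
    write_position_matrix(out$pwm, file.path(outdir, "pwm.tsv"))
    write_flexibility_profile(out$flexibility,
                              file.path(outdir, "flexibility.tsv"))
    write_sites(kept, file.path(outdir, "kept_sites.tsv"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$report <- report
  out
}
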