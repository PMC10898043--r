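#' Validated pipeline configuration
#'
#' A declarative configuration for [run_pipeline()]. Unknown keys are
#' rejected before any computation. Defaults follow the standard analysis
#' parameters: CH filter at 3, combined-coverage threshold 100 (sum rule),
#' promoters 1 kb upstream / 500 bp downstream, 100-kb windows, variance
#' prefilter 0.009 within TSS +/- 2 kb.
#'
#' @param ... Named settings overriding the defaults, or a single `file`
#'   argument naming a YAML document (explicit `...` values override the
#'   file).
#' @param file Optional YAML config file.
#' @return A list of class `rrmp_config`.
#' @export
rrmp_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    n_islands = 30L,
    island_gc = 0.65,
    background_gc = 0.25,
    library_mode = "cfdna",
    n_fragments = 20000L,
    mean_len = 170L,
    panel = "one_cut",
    max_ch = 3L,
    capture_threshold = 100L,
    capture_rule = "sum",
    depth_grid = NULL,
    window = 100000L,
    cohort = FALSE,
    cohort_n_bc = 30L,
    cohort_n_nbc = 30L,
    cohort_tumor_fraction = 0.3,
    cohort_effect_delta = 0.5,
    cohort_depth = 200L,
    classifier_features = 500L,
    out_dir = NULL
  )
  overrides <- list(...)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    overrides <- utils::modifyList(from_file, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_param("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (!cfg$panel %in% c("one_cut", "four_cut")) {
    stop_param("'panel' must be one_cut or four_cut")
  }
  structure(cfg, class = "rrmp_config")
}

#' Run the end-to-end in silico RRMP pipeline
#'
#' Composes the package: simulate genome -> fragment -> convert -> CH
#' filter -> digest -> enrichment analytics, and optionally a synthetic
#' cohort with QC, feature prefilter and LOO classification. When
#' `out_dir` is set, writes `summary.json`, the retained-library coverage
#' track (bismark dialect), the converted-space site map (BED6) and the
#' saturation curve (TSV); every file is re-readable by the package's own
#' readers. The summary is deterministic for a fixed config.
#'
#' @param config An [rrmp_config()].
#' @return The summary list, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = rrmp_config()) {
  stopifnot(inherits(config, "rrmp_config"))
  seed <- as.integer(config$seed)

  sim <- simulate_genome(n_islands = config$n_islands,
                         island_gc = config$island_gc,
                         background_gc = config$background_gc,
                         seed = derive_seed(seed, 1L))
  frags <- fragment_genome(sim$genome, mode = config$library_mode,
                           mean_len = config$mean_len,
                           n_fragments = config$n_fragments,
                           seed = derive_seed(seed, 2L))
  mol <- convert_molecules(frags, sim$genome, sim$profile,
                           conversion_params(seed = derive_seed(seed, 3L)))
  flt <- filter_non_conversion(mol, max_ch = config$max_ch)
  panel <- enzyme_panel(config$panel)
  dig <- digest_library(flt$retained, panel)

  genome_bp <- sum(Biostrings::width(sim$genome))
  grid <- config$depth_grid
  if (is.null(grid)) {
    grid <- round(genome_bp * c(0.2, 0.5, 1, 2))
  }
  total_retained_bp <- sum(BiocGenerics::width(dig$retained$fragments))
  grid <- grid[grid <= total_retained_bp]
  if (length(grid) == 0L) grid <- total_retained_bp
  sat <- saturation_curve(dig$retained, sim$annotation$cpg_island,
                          depth_grid = grid,
                          threshold = config$capture_threshold,
                          rule = config$capture_rule,
                          seed = derive_seed(seed, 4L))
  track <- accumulate_coverage(dig$retained)
  fractions <- read_fraction_by_element(dig$retained, sim$annotation)
  fractions_in <- read_fraction_by_element(flt$retained, sim$annotation)
  lens <- fragment_length_stats(dig$retained)

  summary <- list(
    seed = seed,
    panel = config$panel,
    genome_bp = genome_bp,
    n_islands = length(sim$annotation$cpg_island),
    input_molecules = length(mol),
    ch_filtered = length(flt$removed),
    digested = length(dig$digested),
    retained = length(dig$retained),
    retained_fraction = length(dig$retained) / length(flt$retained),
    cg_fraction_input = mean_gc(flt$retained$sequence),
    cg_fraction_retained = mean_gc(dig$retained$sequence),
    island_read_fraction_input =
      fractions_in$fraction[fractions_in$label == "cpg_island"],
    island_read_fraction_retained =
      fractions$fraction[fractions$label == "cpg_island"],
    modal_fragment_length = lens$mode,
    islands_captured = stats::setNames(as.list(sat$captured),
                                       paste0("bases_", sat$bases))
  )

  if (isTRUE(config$cohort)) {
    design <- cohort_design(n_bc = config$cohort_n_bc,
                            n_nbc = config$cohort_n_nbc,
                            tumor_fraction = config$cohort_tumor_fraction,
                            effect_delta = config$cohort_effect_delta,
                            depth = config$cohort_depth,
                            seed = derive_seed(seed, 5L))
    mm <- simulate_cohort(design, sim$profile, sim$annotation$tss)
    qc <- qc_filter(mm)
    # locality filter here; the variance filter runs fold-safe inside LOO
    feats <- feature_prefilter(qc$matrix, sim$annotation$tss, var_min = 0)
    cls <- loo_classify(feats, n_features = config$classifier_features,
                        seed = derive_seed(seed, 6L))
    summary$cohort <- list(
      samples = ncol(mm$beta),
      samples_after_qc = ncol(qc$matrix$beta),
      features_after_prefilter = nrow(feats$beta),
      auc = cls$auc
    )
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_bismark_cov(track, file.path(config$out_dir,
                                       "retained_coverage.tsv"))
    sm <- converted_site_map(sim$genome, sim$profile, panel,
                             methylation_rule = "threshold")
    site_map_to_bed(sm, panel, file.path(config$out_dir, "site_map.bed"))
    write.table(sat, file.path(config$out_dir, "saturation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(summary))
  }
  summary
}
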