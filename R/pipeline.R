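#' Default pipeline configuration
#'
#' Returns the fully resolved configuration list used by [run_all()], with
#' any overrides applied. Inputs are either a synthetic clade (field
#' `synthetic`, a `synthetic_clade_spec`) or paths (`metadata_path`,
#' `spectra_dir`, `tree_path`).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    clade_name = "synthetic",
    visual_system = "VS",
    weber = DEFAULT_WEBER,
    black_threshold = 0.02,
    reference_volume = TETRA_VOLUME,
    taxon_col = "species",
    sex_filter_scores = "male_only",
    sex_filter_extremes = "all",
    allow_undertail = FALSE,
    hist_bin_width = 0.2,
    n_rand = 1000,
    n_perm = 999,
    seed = 1L,
    synthetic = NULL,
    metadata_path = NULL,
    spectra_dir = NULL,
    tree_path = NULL,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()] fields.
#' @return Resolved configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$weber)) raw$weber <- unlist(raw$weber)
  do.call(pipeline_config, raw)
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full plumage color-space analysis
#'
#' Executes the stages in order: input/validation, cone catches,
#' tetrahedral space and volumes, receptor-noise XYZ, major axis and
#' scores, complementary-color tests, and (when a tree is available)
#' phylogenetic signal. All intermediate artifacts are plain CSV/JSON in
#' `out_dir`, and a manifest records parameters, seeds, completed stages
#' and output checksums, so reruns with an identical configuration are
#' byte-identical.
#'
#' @param config A configuration list from [pipeline_config()] /
#'   [read_config()] (or a YAML path).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(pipeline_config, config)  # validate + fill defaults
  out_dir <- cfg$out_dir %||% tempfile("plumacolor_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  notices <- character(0)
  files <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  # --- io ---
  io <- stage("io", {
    if (!is.null(cfg$synthetic)) {
      clade <- if (inherits(cfg$synthetic, "synthetic_clade_spec"))
        simulate_clade(cfg$synthetic)
      else simulate_clade(do.call(synthetic_clade_spec, cfg$synthetic))
      metadata <- clade$metadata
      spectra <- clade$spectra
      tree <- clade$tree
    } else {
      if (is.null(cfg$metadata_path)) stop("no synthetic spec and no metadata_path")
      metadata <- read_patch_metadata(cfg$metadata_path, cfg$allow_undertail)
      base <- dirname(cfg$metadata_path)
      spectra <- lapply(stats::setNames(metadata$spectrum_path, metadata$patch_id),
                        function(p) read_spectrum(file.path(base, p)))
      tree <- if (!is.null(cfg$tree_path)) ape::read.tree(cfg$tree_path) else NULL
    }
    validate_regions(metadata$region, cfg$allow_undertail)
    spectra <- lapply(spectra, resample)
    metadata$is_black <- vapply(spectra[metadata$patch_id], flag_black,
                                logical(1), threshold = cfg$black_threshold)
    list(metadata = metadata, spectra = spectra, tree = tree)
  })
  files <- c(files, write_stage_csv(io$metadata, out_dir, "metadata.csv"))

  # --- catches ---
  vs <- build_visual_system(cfg$visual_system, weber = cfg$weber)
  catches <- stage("catches", catch_table(io$metadata, io$spectra, vs))
  files <- c(files, write_stage_csv(catches, out_dir, "catches.csv"))

  # --- tetra ---
  tetra <- stage("tetra", {
    tt <- to_tetra(catches)
    vols <- group_volumes(tt, paste(io$metadata$species, io$metadata$sex),
                          cfg$reference_volume)
    overall <- hull_volume(tt, cfg$reference_volume)
    list(points = tt, volumes = vols, overall = overall)
  })
  files <- c(files, write_stage_csv(tetra$points, out_dir, "tetra.csv"),
             write_stage_csv(tetra$volumes, out_dir, "volumes.csv"))

  # --- rnl ---
  xyz <- stage("rnl", achromatic_origin(xyz_from_catches(catches, cfg$weber),
                                        cfg$weber))
  files <- c(files, write_stage_csv(xyz, out_dir, "xyz.csv"))

  # --- axis ---
  axis <- stage("axis", {
    ax <- pca_axis(xyz)
    scores <- spherical_scores(xyz)
    clade_ds <- aggregate_scores(scores, catches, io$metadata,
                                 sex_filter = cfg$sex_filter_scores,
                                 taxon_col = cfg$taxon_col)
    list(axis = ax, scores = scores, clade = clade_ds)
  })
  files <- c(files, write_stage_csv(axis$scores, out_dir, "scores.csv"),
             write_stage_csv(as.data.frame(axis$clade$color), out_dir,
                             "color_matrix.csv"),
             write_stage_csv(as.data.frame(axis$clade$luminance), out_dir,
                             "luminance_matrix.csv"))

  # --- complementary ---
  comp <- stage("complementary", {
    ext <- extreme_scores(axis$scores, io$metadata,
                          taxon_col = cfg$taxon_col,
                          sex_filter = cfg$sex_filter_extremes)
    list(extremes = ext, tests = complementary_tests(ext),
         histograms = score_histograms(ext, cfg$hist_bin_width))
  })
  files <- c(files, write_stage_csv(comp$extremes, out_dir, "extremes.csv"),
             write_stage_csv(comp$histograms, out_dir, "histograms.csv"))

  # --- phylo ---
  signal <- NULL
  if (is.null(io$tree)) {
    notices <- c(notices, "no tree supplied: phylo stage skipped")
  } else {
    signal <- stage("phylo", signal_table(axis$clade, io$tree,
                                          n_rand = cfg$n_rand,
                                          n_perm = cfg$n_perm,
                                          seed = cfg$seed))
    files <- c(files, write_stage_csv(signal, out_dir, "signal.csv"))
  }

  manifest <- list(
    package = "plumacolor",
    version = as.character(utils::packageVersion("plumacolor")),
    clade = cfg$clade_name,
    visual_system = cfg$visual_system,
    weber = as.list(cfg$weber),
    black_threshold = cfg$black_threshold,
    reference_volume = cfg$reference_volume,
    seed = cfg$seed,
    n_rand = cfg$n_rand, n_perm = cfg$n_perm,
    stages_completed = stages,
    notices = notices,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = cfg, out_dir = out_dir, io = io, catches = catches,
                 tetra = tetra, xyz = xyz, axis = axis, comp = comp,
                 signal = signal, manifest = manifest))
}

#' Human-readable summary of a pipeline run
#'
#' Per-clade summary in the structure of comparative plumage reports:
#' color-volume occupancy, PC1 loadings and variance fraction, color-score
#' range, complementary-color tests, and the phylogenetic-signal table.
#'
#' @param run The list returned by [run_all()].
#' @return Character vector of report lines (also printed).
#' @export
run_report <- function(run) {
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  cfg <- run$config
  add("== Clade: %s (visual system %s) ==", cfg$clade_name, cfg$visual_system)
  add("-- Color volume occupancy --")
  add("overall hull volume %.6f (%.2f%% of reference %.6f)%s",
      run$tetra$overall$hull_volume, run$tetra$overall$pct_of_reference,
      run$tetra$overall$reference_volume,
      if (run$tetra$overall$degenerate) " [degenerate]" else "")
  for (i in seq_len(nrow(run$tetra$volumes)))
    add("  %s: %.2f%% (n = %d)", run$tetra$volumes$group[i],
        run$tetra$volumes$pct_of_reference[i], run$tetra$volumes$n_points[i])
  add("-- Major chromatic axis --")
  add("PC1 explains %.1f%% of chromatic variation; loadings X %.3f, Y %.3f, Z %.3f",
      100 * run$axis$axis$pc_variance_fractions[1],
      run$axis$axis$pc1_loadings["X"], run$axis$axis$pc1_loadings["Y"],
      run$axis$axis$pc1_loadings["Z"])
  phis <- run$axis$scores$phi
  add("-- Color scores --")
  add("elevation scores span %.3f to %.3f rad", min(phis, na.rm = TRUE),
      max(phis, na.rm = TRUE))
  add("-- Complementary-color tests --")
  ct <- run$comp$tests
  add("n = %d taxa, dF = %d; fraction opposite-signed = %.3f", ct$n_taxa,
      ct$df, ct$fraction_opposite)
  add("max vs 0: t = %.2f, p = %.3g; min vs 0: t = %.2f, p = %.3g; paired: t = %.2f, p = %.3g",
      ct$t_max, ct$p_max, ct$t_min, ct$p_min, ct$t_paired, ct$p_paired)
  add("-- Phylogenetic signal --")
  if (is.null(run$signal)) {
    add("not run (no tree supplied)")
  } else {
    for (i in seq_len(nrow(run$signal))) {
      s <- run$signal[i, ]
      add("  %s / %s: lambda = %s, p = %s; Mantel r = %s, p = %s; CV = %s (n = %d)%s",
          s$region, s$trait,
          ifelse(is.na(s$lambda), "NA", sprintf("%.3f", s$lambda)),
          ifelse(is.na(s$p_lambda), "NA", sprintf("%.3g", s$p_lambda)),
          ifelse(is.na(s$mantel_r), "NA", sprintf("%.3f", s$mantel_r)),
          ifelse(is.na(s$p_mantel), "NA", sprintf("%.3g", s$p_mantel)),
          ifelse(is.na(s$cv), "NA", sprintf("%.3f", s$cv)),
          s$n_species,
          ifelse(nzchar(s$flag), paste0(" [", s$flag, "]"), ""))
    }
  }
  cat(paste(L, collapse = "\n"), "\n")
  invisible(L)
}
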