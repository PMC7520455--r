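#' Reflectance spectrum template
#'
#' Phenomenological templates for the main classes of plumage reflectance:
#' `long_pass_sigmoid` (carotenoid-like red/yellow long-pass step),
#' `short_wave_gaussian` (structural blue/UV peak), `flat_low`
#' (melanin-like brown: gentle rise from baseline to a low plateau),
#' `flat_high` (white) and `near_zero` (black).
#'
#' @param family Template family (see above).
#' @param peak Inflection (sigmoid) or peak (Gaussian) wavelength, nm.
#' @param width Logistic scale (sigmoid) or Gaussian sd, nm.
#' @param plateau Plateau reflectance, proportion in \[0, 1\].
#' @param baseline Baseline reflectance, proportion in \[0, 1\].
#' @return List of class `spectrum_template`.
#' @export
spectrum_template <- function(family = c("long_pass_sigmoid",
                                         "short_wave_gaussian",
                                         "flat_low", "flat_high", "near_zero"),
                              peak = 550, width = 30,
                              plateau = 0.8, baseline = 0.02) {
  family <- match.arg(family)
  stopifnot(plateau >= 0, plateau <= 1, baseline >= 0, baseline <= 1,
            width > 0)
  structure(list(family = family, peak = peak, width = width,
                 plateau = plateau, baseline = baseline),
            class = "spectrum_template")
}

template_curve <- function(template, grid) {
  with(template, switch(family,
    long_pass_sigmoid = baseline + (plateau - baseline) /
      (1 + exp(-(grid - peak) / width)),
    short_wave_gaussian = baseline + (plateau - baseline) *
      exp(-(grid - peak)^2 / (2 * width^2)),
    flat_low = baseline + (plateau - baseline) *
      (grid - min(grid)) / (max(grid) - min(grid)),
    flat_high = rep(plateau, length(grid)),
    near_zero = rep(baseline, length(grid))
  ))
}

#' Generate a reflectance spectrum from a template
#'
#' Evaluates the template on `grid` and applies multiplicative Gaussian
#' noise (sd `noise_sd`) clipped to \[0, 1\]; the multiplicative form keeps
#' spectra physical and preserves patch identity (intraspecific variation
#' stays below interspecific variation).
#'
#' @param template A `spectrum_template`.
#' @param grid Strictly increasing wavelengths within \[300, 700\] nm.
#' @param noise_sd Multiplicative noise sd (0 = deterministic template).
#' @param seed Optional seed for reproducibility.
#' @return A `reflectance_spectrum`.
#' @export
make_spectrum <- function(template, grid = CANONICAL_GRID, noise_sd = 0,
                          seed = NULL) {
  stopifnot(inherits(template, "spectrum_template"))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (min(grid) < 300 || max(grid) > 700)
    stop("grid outside the supported 300-700 nm range")
  base <- template_curve(template, grid)
  refl <- if (noise_sd > 0) {
    with_seed(seed, base * (1 + stats::rnorm(length(grid), 0, noise_sd)))
  } else base
  reflectance_spectrum(grid, pmin(pmax(refl, 0), 1))
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Ultrametric binary tree with tip labels `sp01, sp02, ...`, rescaled to
#' unit root-to-tip depth so Brownian rates are per total tree depth.
#'
#' @param n_tips Number of tips (>= 3).
#' @param model Only `"yule"` is supported.
#' @param seed Optional seed.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_tips, model = "yule", seed = NULL) {
  model <- match.arg(model, "yule")
  if (n_tips < 3) stop("n_tips must be >= 3")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate tip traits under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal trait vector with covariance equal to the
#' Brownian-motion covariance of the tree with off-diagonal entries scaled
#' by `lambda_true` (Pagel's lambda transformation): `lambda_true = 1` is
#' pure Brownian motion, `lambda_true = 0` gives iid tips with variance
#' `sigma2` x root-to-tip depth.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda_true Pagel's lambda in \[0, 1\].
#' @param seed Optional seed.
#' @return Named numeric vector of tip traits.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda_true = 1,
                               seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (lambda_true < 0 || lambda_true > 1) stop("lambda_true must be in [0, 1]")
  C <- ape::vcv.phylo(tree)
  Cl <- lambda_true * C
  diag(Cl) <- diag(C)
  y <- with_seed(seed,
                 MASS::mvrnorm(1, mu = rep(0, nrow(Cl)), Sigma = sigma2 * Cl))
  stats::setNames(as.numeric(y), rownames(Cl))
}

#' Specification of a synthetic clade
#'
#' Defaults emulate a mid-sized tropical bird clade: 20 species, the seven
#' standard body regions, and a complementary pair of a carotenoid-like
#' long-pass red and a structural short-wavelength blue, with moderate
#' multiplicative measurement noise.
#'
#' @param n_species Number of species (>= 3).
#' @param n_regions Number of body regions (<= 7; the first `n_regions`
#'   standard regions are used).
#' @param complementary_pair List of two `spectrum_template`s: a long-wave
#'   class and a short-wave class.
#' @param assignment_model `"redistributed"` (each species carries both
#'   classes, split across randomly chosen regions) or `"one_sided"` (only
#'   the long-wave class present).
#' @param trait_evolution `"brownian"` (region hue shifts evolve on a Yule
#'   tree) or `"star"` (iid species effects).
#' @param noise_sd Multiplicative spectral noise sd.
#' @param peak_shift_sd Between-species sd of the template peak shift (nm).
#' @param dimorphic Also emit female specimens (duller copies).
#' @param seed Master seed; all sub-streams derive from it.
#' @return List of class `synthetic_clade_spec`.
#' @export
synthetic_clade_spec <- function(n_species = 20, n_regions = 7,
                                 complementary_pair = list(
                                   long = spectrum_template("long_pass_sigmoid",
                                     peak = 605, width = 25,
                                     plateau = 0.65, baseline = 0.03),
                                   short = spectrum_template("short_wave_gaussian",
                                     peak = 460, width = 40,
                                     plateau = 0.5, baseline = 0.03)),
                                 assignment_model = c("redistributed",
                                                      "one_sided"),
                                 trait_evolution = c("brownian", "star"),
                                 noise_sd = 0.05, peak_shift_sd = 8,
                                 dimorphic = FALSE, seed = 1L) {
  assignment_model <- match.arg(assignment_model)
  trait_evolution <- match.arg(trait_evolution)
  if (n_species < 3) stop("n_species must be >= 3")
  if (n_regions < 2 || n_regions > 7) stop("n_regions must be in 2..7")
  structure(list(n_species = n_species, n_regions = n_regions,
                 complementary_pair = complementary_pair,
                 assignment_model = assignment_model,
                 trait_evolution = trait_evolution,
                 noise_sd = noise_sd, peak_shift_sd = peak_shift_sd,
                 dimorphic = dimorphic, seed = seed),
            class = "synthetic_clade_spec")
}

#' Simulate a synthetic clade of plumage spectra
#'
#' Generates a Yule phylogeny, assigns the complementary template pair to
#' body regions per species (under `redistributed`, every species carries
#' at least one region of each class), evolves species-level hue shifts
#' (template peak, nm) under Brownian motion on the tree (or iid under
#' `star`), and renders one noisy spectrum per patch. One male specimen per
#' species by default; with `dimorphic = TRUE` a female specimen with
#' duller (lower-plateau) versions is added.
#'
#' @param spec A `synthetic_clade_spec`.
#' @return List of class `synthetic_clade`: `metadata` (patch table with
#'   ground-truth `true_class`), `spectra` (named list keyed by patch_id),
#'   `tree`, and the generating `spec`.
#' @export
simulate_clade <- function(spec = synthetic_clade_spec()) {
  stopifnot(inherits(spec, "synthetic_clade_spec"))
  ns <- spec$n_species
  regions <- STANDARD_REGIONS[seq_len(spec$n_regions)]
  tree <- simulate_tree(ns, seed = derive_seed(spec$seed, 1))
  species <- tree$tip.label

  # species-level hue shifts (nm) for each class, on the tree or iid
  shift_for <- function(k) {
    if (spec$trait_evolution == "brownian") {
      simulate_bm_traits(tree, sigma2 = spec$peak_shift_sd^2,
                         lambda_true = 1, seed = derive_seed(spec$seed, k))
    } else {
      with_seed(derive_seed(spec$seed, k),
                stats::setNames(stats::rnorm(ns, 0, spec$peak_shift_sd),
                                species))
    }
  }
  shift_long <- shift_for(2)
  shift_short <- shift_for(3)

  # region-class assignment per species
  assign_classes <- with_seed(derive_seed(spec$seed, 4), {
    lapply(seq_len(ns), function(i) {
      if (spec$assignment_model == "one_sided") {
        rep("long", length(regions))
      } else {
        k <- sample(seq_len(length(regions) - 1), 1)  # 1..(n_regions-1) long
        cls <- rep("short", length(regions))
        cls[sample(length(regions), k)] <- "long"
        cls
      }
    })
  })

  sexes <- if (spec$dimorphic) c("M", "F") else "M"
  meta_rows <- list()
  spectra <- list()
  patch_counter <- 0L
  for (i in seq_len(ns)) {
    for (sx in sexes) {
      specimen <- sprintf("%s_%s1", species[i], sx)
      for (j in seq_along(regions)) {
        cls <- assign_classes[[i]][j]
        tpl <- spec$complementary_pair[[if (cls == "long") "long" else "short"]]
        shift <- if (cls == "long") shift_long[i] else shift_short[i]
        tpl2 <- tpl
        tpl2$peak <- tpl$peak + shift
        if (sx == "F") tpl2$plateau <- tpl2$plateau * 0.6  # duller females
        patch_counter <- patch_counter + 1L
        pid <- sprintf("p%04d", patch_counter)
        spectra[[pid]] <- make_spectrum(
          tpl2, noise_sd = spec$noise_sd,
          seed = derive_seed(spec$seed, 100L + patch_counter))
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          specimen_id = specimen, species = species[i], sex = sx,
          region = regions[j], patch_id = pid, true_class = cls)
      }
    }
  }
  metadata <- do.call(rbind, meta_rows)
  rownames(metadata) <- NULL
  structure(list(metadata = metadata, spectra = spectra, tree = tree,
                 spec = spec),
            class = "synthetic_clade")
}

#' Write a synthetic clade to disk in the pipeline's input formats
#'
#' Emits one two-column CSV per patch spectrum, a patch metadata CSV (with
#' `spectrum_path` and `clade` columns as read by [read_patch_metadata()]),
#' and the tree as Newick.
#'
#' @param clade A `synthetic_clade`.
#' @param dir Output directory (created if needed).
#' @param clade_name Value for the metadata `clade` column.
#' @return Invisibly, a list with `metadata_path` and `tree_path`.
#' @export
write_clade <- function(clade, dir, clade_name = "synthetic") {
  stopifnot(inherits(clade, "synthetic_clade"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  md <- clade$metadata
  md$spectrum_path <- file.path("spectra", paste0(md$patch_id, ".csv"))
  md$clade <- clade_name
  for (i in seq_len(nrow(md)))
    write_spectrum(clade$spectra[[md$patch_id[i]]],
                   file.path(dir, md$spectrum_path[i]))
  metadata_path <- file.path(dir, "patches.csv")
  utils::write.csv(md, metadata_path, row.names = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(clade$tree, tree_path)
  invisible(list(metadata_path = metadata_path, tree_path = tree_path))
}
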