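#' Major chromatic axis by PCA on XYZ coordinates
#'
#' Eigendecomposition of the covariance of the XYZ coordinates (coordinates
#' share JND units, so covariance rather than correlation). PC1's variance
#' fraction measures how one-dimensional the clade's chromatic variation is.
#' Loadings are sign-fixed so the Z weight is non-negative, making reports
#' reproducible across runs (the overall sign is otherwise arbitrary).
#'
#' @param xyz data.frame with columns `X, Y, Z` (NA rows dropped).
#' @return List: `pc1_loadings` (unit norm), `pc_variance_fractions`
#'   (sums to 1), `centering` (mean XYZ), `n`, `degenerate`.
#' @export
pca_axis <- function(xyz) {
  M <- as.matrix(as.data.frame(xyz)[, c("X", "Y", "Z")])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 3) stop("need at least 3 points for PCA")
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  load1 <- pc$rotation[, 1]
  if (load1["Z"] < 0) load1 <- -load1
  list(pc1_loadings = load1,
       pc_variance_fractions = fr,
       centering = pc$center,
       n = nrow(M),
       degenerate = pc$sdev[1] < 1e-12 || sum(pc$sdev > 1e-12) < 3)
}

#' Spherical color scores from XYZ coordinates
#'
#' Converts receptor-noise XYZ (achromatic point at the origin) into
#' spherical coordinates. The elevation `phi` (radians, in \[-pi/2, +pi/2\])
#' is the one-dimensional "color score": colors on opposite sides of the
#' achromatic point along the elevation axis have `phi` of opposite sign.
#' The azimuth `theta` is retained for diagnostics but not used downstream.
#'
#' @param xyz data.frame with columns `X, Y, Z` (optionally `patch_id`).
#' @param origin_tol Points within this JND of the origin get `phi = NA`
#'   (elevation undefined at the achromatic point).
#' @return data.frame with `phi, theta, r_jnd` (plus `patch_id` if present).
#' @export
spherical_scores <- function(xyz, origin_tol = 1e-12) {
  xyz <- as.data.frame(xyz)
  X <- xyz$X; Y <- xyz$Y; Z <- xyz$Z
  r <- sqrt(X^2 + Y^2 + Z^2)
  phi <- atan2(Z, sqrt(X^2 + Y^2))
  theta <- atan2(Y, X)
  phi[!is.na(r) & r <= origin_tol] <- NA_real_
  out <- data.frame(phi = phi, theta = theta, r_jnd = r)
  if ("patch_id" %in% names(xyz)) out <- cbind(patch_id = xyz$patch_id, out)
  out
}

#' Species x region score matrices for a clade
#'
#' Aggregates patch-level color scores (`phi`) and luminance scores into
#' species x region matrices. Averaging is nested: patches are first
#' averaged within specimen, then specimens within species, so heavily
#' sampled specimens do not dominate. Black patches contribute to luminance
#' means but never to `phi` means; cells with no measurement are `NA`,
#' never zero.
#'
#' @param scores data.frame with `patch_id, phi` (from [spherical_scores()]).
#' @param catches data.frame with `patch_id, luminance` (from [catch_table()]).
#' @param metadata Patch metadata (`specimen_id, species, sex, region, patch_id`).
#' @param sex_filter `"male_only"` (default, matching the comparative
#'   analyses) or `"all"`.
#' @param taxon_col Metadata column used as the row grouping (default
#'   `"species"`; set to a subspecies-level column to keep taxa separate).
#' @return List of class `clade_dataset`: matrices `color`, `luminance`,
#'   `counts` (species x region), and `sex_filter`.
#' @export
aggregate_scores <- function(scores, catches, metadata,
                             sex_filter = c("male_only", "all"),
                             taxon_col = "species") {
  sex_filter <- match.arg(sex_filter)
  if (!taxon_col %in% names(metadata)) stop("metadata lacks column ", taxon_col)
  md <- metadata
  if (sex_filter == "male_only") {
    dropped <- setdiff(unique(md[[taxon_col]]),
                       unique(md[[taxon_col]][md$sex == "M"]))
    if (length(dropped))
      warning("no male specimens for: ", paste(dropped, collapse = ", "),
              " (dropped)")
    md <- md[md$sex == "M", , drop = FALSE]
    if (nrow(md) == 0) stop("no rows left after male_only filter")
  }
  df <- merge(md[, c("specimen_id", taxon_col, "region", "patch_id")],
              merge(scores[, c("patch_id", "phi")],
                    catches[, c("patch_id", "luminance")], by = "patch_id"),
              by = "patch_id")
  if (nrow(df) == 0) stop("no patches after joining scores with metadata")
  species <- sort(unique(df[[taxon_col]]))
  regions <- unique(metadata$region)
  regions <- regions[order(match(regions, c(STANDARD_REGIONS, "undertail")))]
  nested_mean <- function(values, sub) {
    # specimen-first nesting; NA patch values (e.g. phi of black patches)
    # are excluded at the patch level
    spec_means <- tapply(values, sub$specimen_id,
                         function(v) mean(v, na.rm = TRUE))
    spec_means <- spec_means[is.finite(spec_means)]
    if (length(spec_means) == 0) NA_real_ else mean(spec_means)
  }
  shape <- function(fun) {
    m <- matrix(NA_real_, length(species), length(regions),
                dimnames = list(species, regions))
    for (sp in species) for (rg in regions) {
      sub <- df[df[[taxon_col]] == sp & df$region == rg, , drop = FALSE]
      if (nrow(sub)) m[sp, rg] <- fun(sub)
    }
    m
  }
  color <- shape(function(sub) nested_mean(sub$phi, sub))
  lum <- shape(function(sub) nested_mean(sub$luminance, sub))
  counts <- shape(function(sub) nrow(sub))
  counts[is.na(counts)] <- 0
  structure(list(color = color, luminance = lum, counts = counts,
                 sex_filter = sex_filter),
            class = "clade_dataset")
}

#' @export
print.clade_dataset <- function(x, ...) {
  cat(sprintf("<clade_dataset: %d species x %d regions (%s), %d patches>\n",
              nrow(x$color), ncol(x$color), x$sex_filter, sum(x$counts)))
  invisible(x)
}

#' Coefficient of variation of region scores across species
#'
#' CV = sample standard deviation / |mean| of the per-species region means.
#' Regions whose mean is zero within tolerance get `NA` with a flag (the
#' ratio is not meaningful there).
#'
#' @param clade A `clade_dataset`.
#' @param trait `"color"` or `"luminance"`.
#' @param regions Region names (default: all columns).
#' @param zero_tol Mean magnitude below which CV is undefined.
#' @return data.frame: `region, cv, n, zero_mean`.
#' @export
coefficient_of_variation <- function(clade, trait = c("color", "luminance"),
                                     regions = NULL, zero_tol = 1e-10) {
  trait <- match.arg(trait)
  m <- clade[[trait]]
  regions <- regions %||% colnames(m)
  rows <- lapply(regions, function(rg) {
    v <- m[, rg]
    v <- v[!is.na(v)]
    if (length(v) < 2)
      return(data.frame(region = rg, cv = NA_real_, n = length(v),
                        zero_mean = FALSE))
    mu <- mean(v)
    if (abs(mu) < zero_tol)
      return(data.frame(region = rg, cv = NA_real_, n = length(v),
                        zero_mean = TRUE))
    data.frame(region = rg, cv = stats::sd(v) / abs(mu), n = length(v),
               zero_mean = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
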