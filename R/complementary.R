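#' Per-taxon extreme color scores
#'
#' Maximum and minimum patch-level color score (`phi`) for each taxon,
#' pooling sexes by default (extremes are taken over individual patches,
#' not region means, so a single saturated patch can carry a taxon's
#' extreme). Taxa with no chromatic patch (all `phi` missing) are dropped
#' with a warning.
#'
#' @param scores data.frame with `patch_id, phi`.
#' @param metadata Patch metadata containing `patch_id` and the taxon column.
#' @param taxon_col Grouping column (default `"species"`).
#' @param sex_filter `"all"` (default; histograms pool sexes) or `"male_only"`.
#' @return data.frame: `taxon, max_phi, min_phi, n_patches`.
#' @export
extreme_scores <- function(scores, metadata, taxon_col = "species",
                           sex_filter = c("all", "male_only")) {
  sex_filter <- match.arg(sex_filter)
  md <- metadata
  if (sex_filter == "male_only") md <- md[md$sex == "M", , drop = FALSE]
  df <- merge(md[, c("patch_id", taxon_col)],
              scores[, c("patch_id", "phi")], by = "patch_id")
  if (nrow(df) == 0) stop("no patches to score")
  by_taxon <- split(df$phi, df[[taxon_col]])
  rows <- lapply(names(by_taxon), function(tx) {
    v <- by_taxon[[tx]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    data.frame(taxon = tx, max_phi = max(v), min_phi = min(v),
               n_patches = length(v))
  })
  dropped <- names(by_taxon)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("taxa with no chromatic patches dropped: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no taxon has a chromatic patch")
  rownames(out) <- NULL
  out
}

# one-sample or paired t machinery that reports zero-variance inputs as
# infinite t with an exact-tie flag rather than erroring
safe_t <- function(x, mu = 0) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 2) return(list(t = NA_real_, p = NA_real_, df = n - 1, tie = FALSE))
  if (s == 0) {
    tval <- if (mean(x) == mu) NaN else Inf * sign(mean(x) - mu)
    return(list(t = tval, p = if (is.nan(tval)) NA_real_ else 0,
                df = n - 1, tie = TRUE))
  }
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), tie = FALSE)
}

#' Complementary-color tests on per-taxon extremes
#'
#' Tests whether taxa hold colors on opposite sides of the achromatic
#' point: two-sided one-sample t-tests of the maxima and of the minima
#' against zero, and a paired t-test of maxima vs minima. Also reports the
#' fraction of taxa whose maximum is positive and minimum negative.
#'
#' @param extremes data.frame from [extreme_scores()].
#' @return List of class `complementary_report`: `fraction_opposite`,
#'   `t_max, p_max, t_min, p_min, t_paired, p_paired`, `df` (= n_taxa - 1),
#'   `n_taxa`, `exact_tie` flags, and the `extremes` table.
#' @export
complementary_tests <- function(extremes) {
  if (nrow(extremes) < 3) stop("need at least 3 taxa")
  mx <- extremes$max_phi
  mn <- extremes$min_phi
  tmax <- safe_t(mx)
  tmin <- safe_t(mn)
  tpair <- safe_t(mx - mn)
  structure(list(
    fraction_opposite = mean(mx > 0 & mn < 0),
    t_max = tmax$t, p_max = tmax$p,
    t_min = tmin$t, p_min = tmin$p,
    t_paired = tpair$t, p_paired = tpair$p,
    df = nrow(extremes) - 1L,
    n_taxa = nrow(extremes),
    exact_tie = c(max = tmax$tie, min = tmin$tie, paired = tpair$tie),
    extremes = extremes), class = "complementary_report")
}

#' @export
print.complementary_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Complementary-color tests (n = %d taxa, dF = %d)\n",
    "  fraction with max > 0 and min < 0: %.3f\n",
    "  one-sample t (max vs 0):  t = %.3f, p = %.3g\n",
    "  one-sample t (min vs 0):  t = %.3f, p = %.3g\n",
    "  paired t (max vs min):    t = %.3f, p = %.3g\n"),
    x$n_taxa, x$df, x$fraction_opposite,
    x$t_max, x$p_max, x$t_min, x$p_min, x$t_paired, x$p_paired))
  invisible(x)
}

#' Histograms of per-taxon maximum and minimum color scores
#'
#' Bins are aligned at zero (the achromatic point) and extended to cover
#' \[-pi/2, +pi/2\], so the sign structure of the distributions is visible
#' regardless of bin width. Empty bins are retained with count 0.
#'
#' @param extremes data.frame from [extreme_scores()].
#' @param bin_width Bin width in radians (default 0.2).
#' @return data.frame: `bin_lo, bin_hi, count_max, count_min`.
#' @export
score_histograms <- function(extremes, bin_width = 0.2) {
  stopifnot(bin_width > 0)
  half <- pi / 2
  breaks <- sort(unique(c(-seq(0, half + bin_width, by = bin_width),
                          seq(0, half + bin_width, by = bin_width))))
  count <- function(v) {
    as.integer(table(cut(v, breaks = breaks, right = FALSE,
                         include.lowest = TRUE)))
  }
  data.frame(bin_lo = utils::head(breaks, -1),
             bin_hi = utils::tail(breaks, -1),
             count_max = count(extremes$max_phi),
             count_min = count(extremes$min_phi))
}
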