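#' Govardovskii A1 visual-pigment template
#'
#' Absorbance template for vitamin-A1 pigments: alpha band plus beta band,
#' normalized to unit peak on the evaluated grid.
#'
#' @param wavelength Wavelengths (nm).
#' @param lambda_max Peak absorbance wavelength (nm).
#' @return Numeric sensitivity values in \[0, 1\] with max 1.
#' @export
govardovskii_a1 <- function(wavelength, lambda_max) {
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max   # beta-band peak
  bb <- -40.5 + 0.195 * lambda_max  # beta-band width
  beta <- 0.26 * exp(-((wavelength - lmb) / bb)^2)
  s <- alpha + beta
  s / max(s)
}

# Default cone peak wavelengths (nm) for averaged avian visual systems, and
# the blue tit double cone used as the luminance channel.
CONE_LMAX <- list(
  UVS = c(u = 372, s = 456, m = 544, l = 609),
  VS  = c(u = 418, s = 478, m = 542, l = 607)
)
DOUBLE_CONE_LMAX <- 563

# Weber fractions from single-cone noise 0.1 in the most abundant (l) cone
# and relative cone densities u:s:m:l = 1:2:2:4 ("Leiothrix-like"):
# e_i = e_l * sqrt(n_l / n_i).
DEFAULT_WEBER <- c(u = 0.2, s = 0.1 * sqrt(2), m = 0.1 * sqrt(2), l = 0.1)

#' Build an avian visual system
#'
#' Tabulates the four single-cone sensitivities and the double-cone
#' (luminance) sensitivity on the canonical grid, either from the
#' Govardovskii A1 nomogram at the configured peak wavelengths or from a
#' user-supplied table, and attaches Weber fractions and an illuminant.
#'
#' @param system `"UVS"` or `"VS"` (ultraviolet- vs violet-sensitive).
#' @param lambda_max Optional named vector `c(u=,s=,m=,l=)` of cone peaks (nm)
#'   overriding the averaged-system defaults.
#' @param weber Named Weber fractions `c(u=,s=,m=,l=)`; all > 0.
#' @param illuminant Irradiance spectrum on `grid`, or `NULL` for the
#'   idealized uniform (white) illuminant.
#' @param sensitivities Optional data.frame with columns
#'   `wavelength, u, s, m, l, d` of tabulated sensitivities (unit-peak
#'   normalization applied after interpolation onto `grid`).
#' @param grid Wavelength grid (nm).
#' @return An object of class `visual_system`.
#' @export
build_visual_system <- function(system = c("UVS", "VS"),
                                lambda_max = NULL,
                                weber = DEFAULT_WEBER,
                                illuminant = NULL,
                                sensitivities = NULL,
                                grid = CANONICAL_GRID) {
  system <- match.arg(system)
  cones <- c("u", "s", "m", "l")
  if (!all(cones %in% names(weber)) || any(weber[cones] <= 0))
    stop("weber must be a named positive vector with entries u, s, m, l")
  weber <- weber[cones]
  if (is.null(sensitivities)) {
    lmax <- lambda_max %||% CONE_LMAX[[system]]
    if (!all(cones %in% names(lmax))) stop("lambda_max needs entries u,s,m,l")
    S <- vapply(cones, function(i) govardovskii_a1(grid, lmax[[i]]),
                numeric(length(grid)))
    D <- govardovskii_a1(grid, DOUBLE_CONE_LMAX)
  } else {
    need <- c("wavelength", cones, "d")
    if (!all(need %in% names(sensitivities)))
      stop("tabulated sensitivities need columns: ",
           paste(need, collapse = ", "))
    interp1 <- function(y) {
      v <- stats::approx(sensitivities$wavelength, y, xout = grid,
                         rule = 2)$y
      if (any(v < 0)) stop("negative sensitivity values")
      v / max(v)
    }
    S <- vapply(cones, function(i) interp1(sensitivities[[i]]),
                numeric(length(grid)))
    D <- interp1(sensitivities$d)
  }
  colnames(S) <- cones
  if (is.null(illuminant)) {
    illuminant <- rep(1, length(grid))
  } else if (length(illuminant) != length(grid) || any(illuminant < 0)) {
    stop("illuminant must be a non-negative vector on the grid")
  }
  structure(list(system = system, grid = grid, S = S, D = D,
                 weber = weber, illuminant = illuminant),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  peaks <- apply(x$S, 2, function(s) x$grid[which.max(s)])
  cat(sprintf("<visual_system %s: cone peaks %s nm; weber %s>\n", x$system,
              paste(peaks, collapse = "/"),
              paste(signif(x$weber, 3), collapse = "/")))
  invisible(x)
}

#' Cone quantum catches of a patch
#'
#' Raw catch per cone is the trapezoidal integral of reflectance x
#' sensitivity x illuminant over wavelength. The von Kries correction
#' divides each cone's catch by its catch for the illuminant alone
#' (chromatic adaptation), and relative catches normalize the corrected
#' values to sum to one.
#'
#' @param spectrum A `reflectance_spectrum` on the visual system's grid.
#' @param vs A `visual_system`.
#' @return A list with `Q` (raw), `q` (von Kries-corrected) and `rel`
#'   (relative, summing to 1), each named `u, s, m, l`.
#' @export
quantum_catch <- function(spectrum, vs) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"),
            inherits(vs, "visual_system"))
  if (!isTRUE(all.equal(spectrum$wavelength, as.numeric(vs$grid))))
    stop("spectrum must be resampled onto the visual system's grid")
  R <- spectrum$reflectance
  if (all(R == 0))
    stop("all-zero spectrum: flag and exclude black patches before computing chromatic catches")
  wl <- as.numeric(vs$grid)
  Q <- apply(vs$S, 2, function(s) pracma::trapz(wl, R * s * vs$illuminant))
  norm <- apply(vs$S, 2, function(s) pracma::trapz(wl, s * vs$illuminant))
  q <- Q / norm
  list(Q = Q, q = q, rel = q / sum(q))
}

#' Double-cone catch (luminance score)
#'
#' Von Kries-normalized double-cone catch; a flat reflectance of r under the
#' idealized illuminant scores exactly r, so the score lies in \[0, 1\].
#'
#' @param spectrum A `reflectance_spectrum` on the grid (black allowed).
#' @param vs A `visual_system`.
#' @return Luminance score in \[0, 1\] under the idealized illuminant.
#' @export
double_cone_catch <- function(spectrum, vs) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"),
            inherits(vs, "visual_system"))
  wl <- as.numeric(vs$grid)
  pracma::trapz(wl, spectrum$reflectance * vs$D * vs$illuminant) /
    pracma::trapz(wl, vs$D * vs$illuminant)
}

#' Catch table for a set of patches
#'
#' One row per patch with corrected and relative catches plus luminance.
#' Black-flagged patches get luminance only; their chromatic fields are the
#' achromatic sentinel `NA` (they are excluded from chromatic analyses, not
#' placed at zero).
#'
#' @param patches data.frame with columns `patch_id` and `is_black`.
#' @param spectra Named list of resampled `reflectance_spectrum`, keyed by
#'   `patch_id`.
#' @param vs A `visual_system`.
#' @return data.frame: `patch_id, q_u..q_l, rel_u..rel_l, luminance, is_black`.
#' @export
catch_table <- function(patches, spectra, vs) {
  stopifnot(is.data.frame(patches),
            all(c("patch_id", "is_black") %in% names(patches)))
  missing <- setdiff(patches$patch_id, names(spectra))
  if (length(missing))
    stop("no spectrum for patch(es): ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(patches)), function(i) {
    pid <- patches$patch_id[i]
    sp <- spectra[[pid]]
    lum <- double_cone_catch(sp, vs)
    if (patches$is_black[i]) {
      data.frame(patch_id = pid, q_u = NA_real_, q_s = NA_real_,
                 q_m = NA_real_, q_l = NA_real_, rel_u = NA_real_,
                 rel_s = NA_real_, rel_m = NA_real_, rel_l = NA_real_,
                 luminance = lum, is_black = TRUE)
    } else {
      qc <- quantum_catch(sp, vs)
      data.frame(patch_id = pid, q_u = qc$q[["u"]], q_s = qc$q[["s"]],
                 q_m = qc$q[["m"]], q_l = qc$q[["l"]],
                 rel_u = qc$rel[["u"]], rel_s = qc$rel[["s"]],
                 rel_m = qc$rel[["m"]], rel_l = qc$rel[["l"]],
                 luminance = lum, is_black = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
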