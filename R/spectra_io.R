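#' Construct a reflectance spectrum
#'
#' A reflectance spectrum is a pair of equal-length numeric vectors:
#' wavelengths in nm (strictly increasing) and reflectance as a proportion
#' in \[0, 1\]. Duplicate wavelengths are averaged; rows are sorted.
#'
#' @param wavelength Numeric vector of wavelengths (nm).
#' @param reflectance Numeric vector of reflectance proportions.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelength, reflectance) {
  if (length(wavelength) != length(reflectance))
    stop("wavelength and reflectance must have the same length")
  if (length(wavelength) < 2)
    stop("a spectrum needs at least 2 samples")
  if (anyNA(wavelength) || anyNA(reflectance) ||
      any(!is.finite(wavelength)) || any(!is.finite(reflectance)))
    stop("non-finite values in spectrum")
  if (any(reflectance < 0))
    stop("negative reflectance values")
  ord <- order(wavelength)
  wavelength <- wavelength[ord]
  reflectance <- reflectance[ord]
  if (anyDuplicated(wavelength)) {
    reflectance <- as.numeric(tapply(reflectance, wavelength, mean))
    wavelength <- sort(unique(wavelength))
  }
  if (length(wavelength) < 2)
    stop("a spectrum needs at least 2 distinct wavelengths")
  structure(list(wavelength = wavelength, reflectance = reflectance),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum: %d samples, %.0f-%.0f nm, mean R = %.3f>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              mean(x$reflectance)))
  invisible(x)
}

#' Read a two-column reflectance spectrum file
#'
#' Reads delimited text (comma, tab or whitespace; optional header) with
#' wavelength in the first column and reflectance in the second. Percent
#' input (0-100) is detected when the maximum value exceeds 1.5 and divided
#' by 100; override with `unit_hint`.
#'
#' @param path File path.
#' @param unit_hint One of `"auto"`, `"percent"`, `"proportion"`.
#' @return A `reflectance_spectrum` with reflectance as proportions.
#' @export
read_spectrum <- function(path, unit_hint = c("auto", "percent", "proportion")) {
  unit_hint <- match.arg(unit_hint)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty spectrum file: ", path)
  sep <- if (grepl(",", lines[[length(lines)]])) "," else ""
  dat <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  # drop a header row if the first row is non-numeric
  first <- suppressWarnings(as.numeric(dat[1, 1:2]))
  if (anyNA(first)) dat <- dat[-1, , drop = FALSE]
  if (ncol(dat) < 2) stop("expected two columns in ", path)
  wl <- suppressWarnings(as.numeric(dat[[1]]))
  rf <- suppressWarnings(as.numeric(dat[[2]]))
  if (anyNA(wl) || anyNA(rf))
    stop("non-numeric rows in spectrum file: ", path)
  if (length(wl) < 2) stop("fewer than 2 samples in ", path)
  if (any(rf < 0)) stop("negative reflectance in ", path)
  if (unit_hint == "percent" || (unit_hint == "auto" && max(rf) > 1.5)) {
    rf <- rf / 100
  }
  if (any(rf > 1 + 1e-9))
    stop("reflectance > 1 after unit inference in ", path,
         " (pass unit_hint = \"percent\" if values are 0-100)")
  reflectance_spectrum(wl, pmin(rf, 1))
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum A `reflectance_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  utils::write.csv(
    data.frame(wavelength = spectrum$wavelength,
               reflectance = spectrum$reflectance),
    path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a uniform wavelength grid
#'
#' Linear interpolation onto `grid` (default 300-700 nm at 1 nm). Up to
#' `margin` nm of missing coverage at either edge is filled by holding the
#' nearest measured value; larger gaps are an error.
#'
#' @param spectrum A `reflectance_spectrum`.
#' @param grid Target wavelength grid (strictly increasing, within 300-700 nm
#'   conventions of the visual models used downstream).
#' @param margin Edge extrapolation margin in nm (default 5).
#' @return A `reflectance_spectrum` on `grid`.
#' @export
resample <- function(spectrum, grid = CANONICAL_GRID, margin = 5) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  lo <- min(spectrum$wavelength); hi <- max(spectrum$wavelength)
  if (min(grid) < lo - margin)
    stop(sprintf("spectrum does not cover %.0f-%.0f nm (starts at %.0f, margin %g nm)",
                 min(grid), lo - margin, lo, margin))
  if (max(grid) > hi + margin)
    stop(sprintf("spectrum does not cover %.0f-%.0f nm (ends at %.0f, margin %g nm)",
                 hi + margin, max(grid), hi, margin))
  out <- stats::approx(spectrum$wavelength, spectrum$reflectance, xout = grid,
                       method = "linear", rule = 2)$y
  reflectance_spectrum(grid, pmin(pmax(out, 0), 1))
}

#' Flag a patch as black (effectively zero reflectance)
#'
#' Black patches are special-cased downstream: tetrahedral and receptor-noise
#' chromatic coordinates are undefined for them (log of zero catches), so
#' they are excluded from chromatic analyses and contribute only luminance.
#'
#' @param spectrum A resampled `reflectance_spectrum`.
#' @param threshold Mean-reflectance threshold (default 0.02).
#' @return Logical flag.
#' @export
flag_black <- function(spectrum, threshold = 0.02) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  mean(spectrum$reflectance) < threshold
}

#' Read a patch metadata table
#'
#' Delimited text (CSV/TSV inferred from extension) with required columns
#' `specimen_id, species, sex, region, patch_id, spectrum_path` and optional
#' `clade`; unknown extra columns are preserved. Regions are validated
#' against the seven standard regions, plus `undertail` when
#' `allow_undertail = TRUE`.
#'
#' @param path Metadata file path.
#' @param allow_undertail Allow the extra `undertail` region.
#' @return A `data.frame`.
#' @export
read_patch_metadata <- function(path, allow_undertail = FALSE) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("specimen_id", "species", "sex", "region", "patch_id",
                "spectrum_path")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata missing required columns: ", paste(missing, collapse = ", "))
  validate_regions(md$region, allow_undertail)
  if (!all(md$sex %in% c("M", "F", "U")))
    stop("sex must be one of M, F, U")
  if (anyDuplicated(md$patch_id))
    stop("duplicate patch_id values in metadata")
  md
}

validate_regions <- function(regions, allow_undertail = FALSE) {
  allowed <- STANDARD_REGIONS
  if (allow_undertail) allowed <- c(allowed, "undertail")
  bad <- setdiff(unique(regions), allowed)
  if (length(bad))
    stop("unknown body region(s): ", paste(bad, collapse = ", "),
         if (!allow_undertail && "undertail" %in% bad)
           " (set allow_undertail = TRUE for parakeet-style layouts)" else "")
  invisible(TRUE)
}
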