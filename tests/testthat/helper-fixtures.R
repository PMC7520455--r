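# Shared fixtures: built once per test run.

# visual systems are deterministic; cache them
VS_SYS <- build_visual_system("VS")
UVS_SYS <- build_visual_system("UVS")

flat_spectrum <- function(level = 1, grid = 300:700) {
  reflectance_spectrum(grid, rep(level, length(grid)))
}

gaussian_spectrum <- function(peak = 550, sd = 20, height = 0.8,
                              grid = 300:700) {
  reflectance_spectrum(grid, height * exp(-(grid - peak)^2 / (2 * sd^2)))
}

# random smooth synthetic spectra drawn from the template families
random_template <- function() {
  fam <- sample(c("long_pass_sigmoid", "short_wave_gaussian",
                  "flat_low", "flat_high"), 1)
  spectrum_template(fam,
                    peak = stats::runif(1, 380, 650),
                    width = stats::runif(1, 15, 60),
                    plateau = stats::runif(1, 0.2, 0.95),
                    baseline = stats::runif(1, 0.01, 0.1))
}

# independent fine-grid (0.1 nm) quantum-catch oracle: re-tabulates the
# pigment nomogram and re-integrates by trapezoid on the fine grid
fine_grid_catch_oracle <- function(spectrum, vs_label = "VS") {
  fine <- seq(300, 700, by = 0.1)
  lmax <- plumacolor:::CONE_LMAX[[vs_label]]
  R <- stats::approx(spectrum$wavelength, spectrum$reflectance,
                     xout = fine, rule = 2)$y
  q <- vapply(c("u", "s", "m", "l"), function(i) {
    S <- govardovskii_a1(fine, lmax[[i]])
    pracma::trapz(fine, R * S) / pracma::trapz(fine, S)
  }, numeric(1))
  q / sum(q)
}

# small synthetic metadata/scores pair for aggregation tests
toy_scores <- function() {
  metadata <- data.frame(
    specimen_id = c("s1", "s1", "s1", "s2", "s2"),
    species = c("A", "A", "A", "A", "B"),
    sex = c("M", "M", "M", "M", "M"),
    region = c("crown", "crown", "wing", "crown", "crown"),
    patch_id = paste0("p", 1:5))
  scores <- data.frame(patch_id = paste0("p", 1:5),
                       phi = c(0.2, 0.4, -0.5, 0.8, 1.0))
  catches <- data.frame(patch_id = paste0("p", 1:5),
                        luminance = c(0.1, 0.3, 0.5, 0.7, 0.9))
  list(metadata = metadata, scores = scores, catches = catches)
}
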