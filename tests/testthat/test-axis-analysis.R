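test_that("pca_axis recovers degenerate, isotropic and planted-axis structure", {
  # points exactly on a line: PC1 fraction 1
  t <- seq(-1, 1, length.out = 20)
  line <- data.frame(X = t, Y = 2 * t, Z = 3 * t)
  ax <- pca_axis(line)
  expect_equal(ax$pc_variance_fractions[1], 1)
  expect_true(ax$degenerate)
  expect_equal(sum(ax$pc1_loadings^2), 1)
  expect_gte(ax$pc1_loadings["Z"], 0)

  # isotropic cloud: fractions near 1/3 each
  set.seed(31)
  iso <- data.frame(X = rnorm(10000), Y = rnorm(10000), Z = rnorm(10000))
  axi <- pca_axis(iso)
  expect_lt(max(abs(axi$pc_variance_fractions - 1 / 3)), 0.02)
  expect_false(axi$degenerate)

  # planted axis: fraction follows (sa^2 + sn^2) / (sa^2 + 3 sn^2)
  sa <- 2; sn <- 0.5
  axis_dir <- c(1, 1, 1) / sqrt(3)
  amp <- rnorm(10000, 0, sa)
  planted <- outer(amp, axis_dir) + matrix(rnorm(30000, 0, sn), ncol = 3)
  colnames(planted) <- c("X", "Y", "Z")
  expected <- (sa^2 + sn^2) / (sa^2 + 3 * sn^2)
  axp <- pca_axis(as.data.frame(planted))
  expect_lt(abs(axp$pc_variance_fractions[1] - expected) / expected, 0.02)

  expect_error(pca_axis(line[1:2, ]), "at least 3")
})

test_that("spherical scores match closed forms and invert exactly", {
  sc <- spherical_scores(data.frame(X = c(0, 1, 0), Y = c(0, 0, 1),
                                    Z = c(1, 0, -1)))
  expect_equal(sc$phi, c(pi / 2, 0, -pi / 4))

  # origin: elevation undefined
  expect_true(is.na(spherical_scores(data.frame(X = 0, Y = 0, Z = 0))$phi))

  # reconstruction r,theta,phi -> XYZ is the identity
  set.seed(41)
  xyz <- data.frame(X = rnorm(50), Y = rnorm(50), Z = rnorm(50))
  sc <- spherical_scores(xyz)
  back <- data.frame(X = sc$r_jnd * cos(sc$phi) * cos(sc$theta),
                     Y = sc$r_jnd * cos(sc$phi) * sin(sc$theta),
                     Z = sc$r_jnd * sin(sc$phi))
  expect_equal(back, xyz, tolerance = 1e-10)
  expect_true(all(sc$phi >= -pi / 2 & sc$phi <= pi / 2))
})

test_that("sign of phi separates planted long- vs short-wave classes in a noiseless clade", {
  cl <- simulate_clade(synthetic_clade_spec(n_species = 8, noise_sd = 0,
                                            peak_shift_sd = 2, seed = 13))
  md <- cl$metadata
  md$is_black <- vapply(cl$spectra[md$patch_id], flag_black, logical(1))
  ct <- catch_table(md, cl$spectra, VS_SYS)
  xyz <- achromatic_origin(xyz_from_catches(ct))
  sc <- spherical_scores(xyz)
  agreement <- table(sign(sc$phi), md$true_class)
  # each class maps to exactly one sign
  expect_equal(length(unique(sign(sc$phi[md$true_class == "long"]))), 1)
  expect_equal(length(unique(sign(sc$phi[md$true_class == "short"]))), 1)
  expect_true(sign(sc$phi[md$true_class == "long"][1]) !=
              sign(sc$phi[md$true_class == "short"][1]))
})

test_that("aggregate_scores nests specimen before species and respects filters", {
  toy <- toy_scores()
  cd <- aggregate_scores(toy$scores, toy$catches, toy$metadata,
                         sex_filter = "all")
  # species A crown: specimen s1 mean (0.2+0.4)/2 = 0.3, specimen s2 = 0.8
  # -> species mean 0.55
  expect_equal(cd$color["A", "crown"], 0.55)
  expect_equal(cd$color["B", "crown"], 1.0)
  # unmeasured cells missing, never zero
  expect_true(is.na(cd$color["B", "wing"]))
  expect_equal(cd$counts["B", "wing"], 0)

  # patch row order does not matter
  perm <- sample(nrow(toy$scores))
  cd2 <- aggregate_scores(toy$scores[perm, ], toy$catches, toy$metadata,
                          sex_filter = "all")
  expect_equal(cd2$color, cd$color)

  # male_only drops female-only species with a warning
  md <- toy$metadata
  md$sex[md$species == "B"] <- "F"
  expect_warning(cdm <- aggregate_scores(toy$scores, toy$catches, md),
                 "no male")
  expect_false("B" %in% rownames(cdm$color))

  # black patches: luminance contributes, phi does not
  sc <- toy$scores; sc$phi[sc$patch_id == "p5"] <- NA
  cdb <- aggregate_scores(sc, toy$catches, toy$metadata, sex_filter = "all")
  expect_true(is.na(cdb$color["B", "crown"]))
  expect_equal(cdb$luminance["B", "crown"], 0.9)
})

test_that("coefficient of variation follows its closed form and degenerate rule", {
  m <- matrix(c(1, 2, 3, 5, 5, 5, -1, 1, NA), ncol = 3,
              dimnames = list(c("a", "b", "c"),
                              c("crown", "wing", "tail")))
  cd <- structure(list(color = m, luminance = m,
                       counts = (!is.na(m)) * 1, sex_filter = "all"),
                  class = "clade_dataset")
  cv <- coefficient_of_variation(cd, "color")
  expect_equal(cv$cv[cv$region == "crown"], 0.5)  # sd 1 / mean 2
  expect_equal(cv$cv[cv$region == "wing"], 0)
  expect_true(is.na(cv$cv[cv$region == "tail"]))
  expect_true(cv$zero_mean[cv$region == "tail"])
})
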