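test_that("spectrum templates honour their closed forms and physical bounds", {
  grid <- 300:700
  white <- make_spectrum(spectrum_template("flat_high", plateau = 1), grid)
  expect_equal(white$reflectance, rep(1, 401))

  black <- make_spectrum(spectrum_template("near_zero", baseline = 0), grid)
  expect_equal(black$reflectance, rep(0, 401))

  # logistic closed form: plateau reached at 700 nm, baseline at 400 nm
  tpl <- spectrum_template("long_pass_sigmoid", peak = 550, width = 30,
                           plateau = 0.9, baseline = 0.02)
  sig <- make_spectrum(tpl, grid)
  expected_700 <- 0.02 + (0.9 - 0.02) / (1 + exp(-(700 - 550) / 30))
  expect_equal(sig$reflectance[grid == 700], expected_700)
  expect_lt(abs(sig$reflectance[grid == 700] - 0.9) / 0.9, 0.01)
  expect_lt(abs(sig$reflectance[grid == 400] - 0.02), 0.01)
  # monotone non-decreasing
  expect_true(all(diff(sig$reflectance) >= 0))

  # gaussian template is unimodal
  g <- make_spectrum(spectrum_template("short_wave_gaussian", peak = 460,
                                       width = 40, plateau = 0.5), grid)
  d <- sign(diff(g$reflectance))
  expect_lte(sum(diff(d[d != 0]) != 0), 1)

  # noisy spectra stay in [0, 1] and are seed-deterministic
  for (i in 1:20) {
    tpl <- with_seed(i, random_template())
    sp <- make_spectrum(tpl, grid, noise_sd = 0.3, seed = i)
    expect_true(all(sp$reflectance >= 0 & sp$reflectance <= 1))
    expect_identical(sp, make_spectrum(tpl, grid, noise_sd = 0.3, seed = i))
  }

  expect_error(make_spectrum(tpl, grid = 250:700), "300-700")
  expect_error(make_spectrum(tpl, grid = c(400, 350)), "increasing")
})

test_that("simulate_tree yields seeded ultrametric binary trees", {
  expect_error(simulate_tree(2), ">= 3")
  tr3 <- simulate_tree(3, seed = 5)
  expect_equal(tr3$Nnode, 2L)  # binary: n - 1 internal nodes
  for (n in c(3, 8, 16)) {
    tr <- simulate_tree(n, seed = 11)
    expect_equal(tr$Nnode + length(tr$tip.label), 2L * n - 1L)
    expect_true(all(tr$edge.length > 0))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_true(ape::is.binary(tr))
    expect_identical(ape::write.tree(tr),
                     ape::write.tree(simulate_tree(n, seed = 11)))
  }
})

test_that("simulate_clade plants the complementary structure it claims", {
  cl <- simulate_clade(synthetic_clade_spec(n_species = 20, seed = 2))
  md <- cl$metadata
  expect_equal(length(unique(md$species)), 20)
  expect_equal(nrow(md), 20 * 7)
  # redistributed: every species carries both classes
  by_sp <- split(md$true_class, md$species)
  expect_true(all(vapply(by_sp, function(x)
    all(c("long", "short") %in% x), logical(1))))
  # reproducibility: identical metadata and spectra under the same seed
  cl2 <- simulate_clade(synthetic_clade_spec(n_species = 20, seed = 2))
  expect_identical(cl$metadata, cl2$metadata)
  expect_identical(cl$spectra, cl2$spectra)
  expect_identical(ape::write.tree(cl$tree), ape::write.tree(cl2$tree))

  one <- simulate_clade(synthetic_clade_spec(n_species = 8,
                                             assignment_model = "one_sided",
                                             seed = 3))
  expect_true(all(one$metadata$true_class == "long"))

  dim <- simulate_clade(synthetic_clade_spec(n_species = 4, dimorphic = TRUE,
                                             seed = 4))
  expect_setequal(unique(dim$metadata$sex), c("M", "F"))
})

test_that("simulate_clade writes inputs the readers accept", {
  dir <- withr::local_tempdir()
  cl <- simulate_clade(synthetic_clade_spec(n_species = 4, seed = 9))
  paths <- write_clade(cl, dir)
  md <- read_patch_metadata(paths$metadata_path)
  expect_equal(nrow(md), nrow(cl$metadata))
  sp <- read_spectrum(file.path(dir, md$spectrum_path[1]))
  expect_equal(sp$reflectance, cl$spectra[[md$patch_id[1]]]$reflectance)
  tr <- ape::read.tree(paths$tree_path)
  expect_setequal(tr$tip.label, unique(md$species))
})

test_that("lambda-scaled Brownian traits have the advertised covariance", {
  tree <- simulate_tree(8, seed = 21)
  C <- ape::vcv.phylo(tree)

  expect_error(simulate_bm_traits(tree, sigma2 = 0), "sigma2")
  expect_identical(simulate_bm_traits(tree, seed = 1),
                   simulate_bm_traits(tree, seed = 1))

  # lambda = 1: Monte-Carlo sample covariance approaches the BM covariance
  reps <- t(vapply(1:2500, function(i)
    simulate_bm_traits(tree, sigma2 = 1, lambda_true = 1, seed = i),
    numeric(8)))
  S <- stats::cov(reps)
  expect_lt(max(abs(S - C)), 0.15)

  # lambda = 0: tips iid with variance sigma2 x depth
  reps0 <- t(vapply(1:2500, function(i)
    simulate_bm_traits(tree, sigma2 = 2, lambda_true = 0, seed = 10000 + i),
    numeric(8)))
  S0 <- stats::cov(reps0)
  depth <- C[1, 1]
  expect_lt(max(abs(diag(S0) - 2 * depth)), 0.3)
  expect_lt(max(abs(S0[row(S0) != col(S0)])), 0.3)
})
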