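test_that("bm_covariance does path-length bookkeeping", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), rep(2, 3))

  # star tree: diagonal covariance
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  Cs <- bm_covariance(star)
  expect_equal(Cs, diag(1.5, 4), ignore_attr = TRUE)

  # ultrametric tree: constant diagonal
  tr2 <- simulate_tree(12, seed = 3)
  expect_lt(diff(range(diag(bm_covariance(tr2)))), 1e-8)

  # pruning and missing species
  Cp <- bm_covariance(tr, species = c("A", "C"))
  expect_equal(rownames(Cp), c("A", "C"))
  expect_error(bm_covariance(tr, species = c("A", "Z")), "Z")
})

test_that("lambda likelihood reduces to the iid fit at lambda = 0", {
  tree <- simulate_tree(16, seed = 7)
  y <- simulate_bm_traits(tree, seed = 8)
  C <- bm_covariance(tree)
  ll <- plumacolor:::lambda_profile(as.numeric(y[rownames(C)]), C)
  yv <- as.numeric(y[rownames(C)])
  # iid MLE log-likelihood (variance profiled out); the depth factor
  # reparametrizes sigma^2 and cancels, so the two maxima agree
  iid_ll <- sum(stats::dnorm(yv, mean(yv),
                             sqrt(mean((yv - mean(yv))^2)), log = TRUE))
  expect_equal(ll(0), iid_ll, tolerance = 1e-9)
})

test_that("pagels_lambda recovers signal, destroys it under shuffling, and is seeded", {
  tree <- simulate_tree(48, seed = 101)
  y <- simulate_bm_traits(tree, lambda_true = 1, seed = 102)
  res <- pagels_lambda(y, tree, n_rand = 199, seed = 5)
  expect_gt(res$lambda_hat, 0.7)
  expect_lt(res$p_randomization, 0.05)
  expect_lt(res$p_lr, 0.05)
  expect_lte(res$lambda_hat, res$lambda_max)

  # shuffling tips destroys signal
  yperm <- with_seed(9, stats::setNames(sample(as.numeric(y)), names(y)))
  resp <- pagels_lambda(yperm, tree, n_rand = 0)
  expect_lt(resp$lambda_hat, 0.3)

  # deterministic given seed
  res2 <- pagels_lambda(y, tree, n_rand = 199, seed = 5)
  expect_identical(res$p_randomization, res2$p_randomization)
  expect_identical(res$lambda_hat, res2$lambda_hat)

  # affine invariance of the estimate
  res3 <- pagels_lambda(3 * y + 10, tree, n_rand = 0)
  expect_equal(res3$lambda_hat, pagels_lambda(y, tree, n_rand = 0)$lambda_hat,
               tolerance = 1e-5)

  # star phylogeny: unidentifiable flag
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  ystar <- stats::setNames(rnorm(5), star$tip.label)
  expect_true(pagels_lambda(ystar, star, n_rand = 0)$unidentifiable)

  # zero variance flagged
  yc <- stats::setNames(rep(1, 48), tree$tip.label)
  expect_true(pagels_lambda(yc, tree, n_rand = 0)$zero_variance)

  expect_error(pagels_lambda(y[1:3], tree), ">= 4")
})

test_that("lambda ML agrees with the phytools reference implementation", {
  skip_if_not_installed("phytools")
  tree <- simulate_tree(32, seed = 55)
  for (lt in c(0.3, 1)) {
    y <- simulate_bm_traits(tree, lambda_true = lt, seed = 50 + 10 * lt)
    ours <- pagels_lambda(y, tree, n_rand = 0)
    ref <- phytools::phylosig(tree, y, method = "lambda")
    expect_equal(ours$lambda_hat, ref$lambda, tolerance = 1e-3)
    expect_equal(ours$loglik, ref$logL, tolerance = 1e-4)
  }
})

test_that("mantel_test: perfect correlation, identical-permutation invariance, determinism", {
  tree <- simulate_tree(12, seed = 61)
  d <- stats::cophenetic(tree)
  res <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_permutation, 1 / 100)

  y <- simulate_bm_traits(tree, seed = 62)
  dt <- abs(outer(y, y, "-"))[rownames(d), colnames(d)]
  r1 <- mantel_test(dt, d, n_perm = 99, seed = 2)
  # permuting species order of both matrices identically leaves r unchanged
  p <- sample(nrow(d))
  r2 <- mantel_test(dt[p, p], d[p, p], n_perm = 99, seed = 2)
  expect_equal(r1$r, r2$r)
  # deterministic given seed
  expect_identical(r1$p_permutation,
                   mantel_test(dt, d, n_perm = 99, seed = 2)$p_permutation)
  # mismatched orderings rejected
  q <- seq_len(nrow(d)); q[1:2] <- q[2:1]
  expect_error(mantel_test(dt[q, q], d, n_perm = 9), "ordering")
  # constant matrix flagged
  expect_true(mantel_test(matrix(0, 12, 12), unname(d), n_perm = 9)$constant)
})

test_that("signal_table gives one row per region x trait with sensible flags", {
  cl <- simulate_clade(synthetic_clade_spec(n_species = 10, seed = 77))
  md <- cl$metadata
  md$is_black <- FALSE
  ct <- catch_table(md, cl$spectra, VS_SYS)
  sc <- spherical_scores(achromatic_origin(xyz_from_catches(ct)))
  cd <- aggregate_scores(sc, ct, md)
  st <- signal_table(cd, cl$tree, n_rand = 99, n_perm = 99, seed = 4)
  expect_equal(nrow(st), 2 * 7)
  expect_setequal(unique(st$trait), c("color", "luminance"))
  expect_true(all(st$n_species == 10))
  expect_true(all(is.na(st$lambda) | st$lambda >= 0))

  # identical trait columns give identical rows
  cd2 <- cd
  cd2$color[, "cheek"] <- cd2$color[, "crown"]
  st2 <- signal_table(cd2, cl$tree, n_rand = 99, n_perm = 99, seed = 4)
  a <- st2[st2$region == "crown" & st2$trait == "color", -1]
  b <- st2[st2$region == "cheek" & st2$trait == "color", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  # too few species -> flagged, not an error
  cd3 <- cd
  cd3$color[4:10, "crown"] <- NA
  st3 <- signal_table(cd3, cl$tree, n_rand = 9, n_perm = 9, seed = 4)
  expect_equal(st3$flag[st3$region == "crown" & st3$trait == "color"],
               "insufficient")
})
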