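#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` the root-to-tip depth. When `species` is given the tree is
#' pruned to those tips first; species absent from the tree are an error.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param species Optional species names to prune to.
#' @return Covariance matrix with tip-label dimnames.
#' @export
bm_covariance <- function(tree, species = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(species)) {
    missing <- setdiff(species, tree$tip.label)
    if (length(missing))
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    tree <- ape::keep.tip(tree, species)
  }
  ape::vcv.phylo(tree)
}

# zero-length branches make C singular; perturb them slightly
fix_zero_branches <- function(tree, eps = 1e-8) {
  if (any(tree$edge.length <= 0)) {
    warning("zero-length branches perturbed by ", eps)
    tree$edge.length[tree$edge.length <= 0] <- eps
  }
  tree
}

# Profile log-likelihood of lambda: mean and variance are concentrated out
# by GLS. For ultrametric trees (constant diagonal of C) the eigenvectors
# of C_lambda = lambda*C + (1-lambda)*T*I do not depend on lambda, so one
# eigendecomposition serves every lambda and every permuted trait vector.
lambda_profile <- function(y, C) {
  n <- length(y)
  ultra <- diag(C)
  ultrametric <- max(ultra) - min(ultra) < 1e-8 * max(ultra)
  if (ultrametric) {
    Tdepth <- ultra[1]
    eig <- eigen(C, symmetric = TRUE)
    V <- eig$vectors
    d <- eig$values
    ones_t <- crossprod(V, rep(1, n))
    function(lambda, yy = y) {
      w <- lambda * d + (1 - lambda) * Tdepth
      if (any(w <= 0)) return(-Inf)
      yt <- crossprod(V, yy)
      mu <- sum(ones_t * yt / w) / sum(ones_t^2 / w)
      rss <- sum((yt - mu * ones_t)^2 / w)
      s2 <- rss / n
      if (s2 <= 0) return(-Inf)
      -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    }
  } else {
    function(lambda, yy = y) {
      Cl <- lambda * C
      diag(Cl) <- diag(C)
      ch <- tryCatch(chol(Cl), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      z <- backsolve(ch, cbind(yy, rep(1, n)), transpose = TRUE)
      mu <- sum(z[, 1] * z[, 2]) / sum(z[, 2]^2)
      rss <- sum((z[, 1] - mu * z[, 2])^2)
      s2 <- rss / n
      if (s2 <= 0) return(-Inf)
      -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
    }
  }
}

#' Pagel's lambda with randomization significance
#'
#' Maximum-likelihood estimate of Pagel's lambda (off-diagonal scaling of
#' the Brownian covariance) for a tip trait, with mean and rate profiled
#' out by GLS and lambda optimized on \[0, lambda_max\], where lambda_max
#' keeps the scaled covariance positive-definite (about 1 for ultrametric
#' trees). Significance is the proportion of tip-label permutations whose
#' re-estimated lambda is at least the observed one (the randomization
#' scheme applied to the observed statistic); a likelihood-ratio test
#' against lambda = 0 is reported as a cross-check.
#'
#' @param trait Named numeric vector (names = tip labels); `NA`s pruned.
#' @param tree An `ape::phylo` tree.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Optional seed for the permutations.
#' @return List of class `lambda_result`: `lambda_hat`, `loglik`,
#'   `lambda_max`, `p_randomization`, `n_randomizations`, `p_lr`, `n`,
#'   and flags `unidentifiable` (star tree) / `zero_variance`.
#' @export
pagels_lambda <- function(trait, tree, n_rand = 1000, seed = NULL) {
  trait <- trait[!is.na(trait)]
  if (length(trait) < 4) stop("need >= 4 species with non-missing trait")
  if (is.null(names(trait))) stop("trait must be named by tip label")
  tree <- fix_zero_branches(tree)
  C <- bm_covariance(tree, names(trait))
  y <- trait[rownames(C)]
  base <- list(lambda_hat = NA_real_, loglik = NA_real_,
               lambda_max = NA_real_, p_randomization = NA_real_,
               n_randomizations = n_rand, p_lr = NA_real_,
               n = length(y), unidentifiable = FALSE, zero_variance = FALSE)
  if (stats::sd(y) == 0) {
    base$zero_variance <- TRUE
    return(structure(base, class = "lambda_result"))
  }
  offdiag <- C[row(C) != col(C)]
  if (max(offdiag) <= 1e-12 * max(diag(C))) {
    # star phylogeny: lambda does not enter the likelihood
    base$unidentifiable <- TRUE
    return(structure(base, class = "lambda_result"))
  }
  lmax <- max(diag(C)) / max(offdiag)
  ll <- lambda_profile(as.numeric(y), C)
  fit_one <- function(yy) {
    opt <- stats::optimize(function(l) ll(l, yy), c(0, lmax),
                           maximum = TRUE, tol = 1e-8)
    # the optimum can sit at a boundary; compare endpoints explicitly
    cand <- c(opt$maximum, 0, lmax)
    vals <- c(opt$objective, ll(0, yy), ll(lmax, yy))
    best <- which.max(vals)
    c(cand[best], vals[best])
  }
  obs <- fit_one(as.numeric(y))
  p_rand <- NA_real_
  if (n_rand > 0) {
    perm_lambdas <- with_seed(seed, vapply(seq_len(n_rand), function(i)
      fit_one(sample(as.numeric(y)))[1], numeric(1)))
    p_rand <- (1 + sum(perm_lambdas >= obs[1])) / (n_rand + 1)
  }
  lr <- 2 * (obs[2] - ll(0, as.numeric(y)))
  base$lambda_hat <- obs[1]
  base$loglik <- obs[2]
  base$lambda_max <- lmax
  base$p_randomization <- p_rand
  base$p_lr <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  structure(base, class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  if (x$zero_variance) cat("<lambda_result: zero trait variance>\n")
  else if (x$unidentifiable) cat("<lambda_result: star tree, lambda unidentifiable>\n")
  else cat(sprintf("<lambda_result: lambda = %.3f (max %.3f), p_rand = %.4g, p_LR = %.4g, n = %d>\n",
                   x$lambda_hat, x$lambda_max, x$p_randomization, x$p_lr, x$n))
  invisible(x)
}

#' Mantel correlation between a trait distance and a phylogenetic distance
#'
#' Pearson correlation of the off-diagonal entries, with significance by
#' simultaneous row/column permutation of one matrix (one-tailed, greater).
#' The permutation machinery is vegan's.
#'
#' @param dist_trait,dist_phylo Symmetric matrices (or `dist`) over the
#'   same species in the same order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return List of class `mantel_result`: `r`, `p_permutation`, `n_perm`,
#'   `n`, `constant` flag.
#' @export
mantel_test <- function(dist_trait, dist_phylo, n_perm = 999, seed = NULL) {
  mt <- as.matrix(dist_trait)
  mp <- as.matrix(dist_phylo)
  if (!all(dim(mt) == dim(mp))) stop("distance matrices differ in size")
  if (!is.null(rownames(mt)) && !is.null(rownames(mp)) &&
      !identical(rownames(mt), rownames(mp)))
    stop("distance matrices must share the same species ordering")
  n <- nrow(mt)
  base <- list(r = NA_real_, p_permutation = NA_real_, n_perm = n_perm,
               n = n, constant = FALSE)
  if (stats::sd(mt[lower.tri(mt)]) == 0 ||
      stats::sd(mp[lower.tri(mp)]) == 0) {
    base$constant <- TRUE
    return(structure(base, class = "mantel_result"))
  }
  res <- with_seed(seed,
    vegan::mantel(stats::as.dist(mt), stats::as.dist(mp),
                  method = "pearson", permutations = n_perm))
  base$r <- unname(res$statistic)
  base$p_permutation <- res$signif
  structure(base, class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (x$constant) cat("<mantel_result: constant distance matrix>\n")
  else cat(sprintf("<mantel_result: r = %.3f, p = %.4g (%d permutations, n = %d)>\n",
                   x$r, x$p_permutation, x$n_perm, x$n))
  invisible(x)
}

#' Region-wise phylogenetic-signal table
#'
#' For each body region and each of the two traits (color score,
#' luminance), estimates Pagel's lambda with randomization p, a Mantel
#' correlation between the absolute pairwise difference of region means and
#' the patristic (cophenetic) distance, and the coefficient of variation —
#' mirroring the per-region signal tables of comparative plumage studies.
#'
#' @param clade A `clade_dataset` (male-only scores feed this analysis).
#' @param tree An `ape::phylo` tree containing the dataset's species.
#' @param n_rand Randomizations for lambda.
#' @param n_perm Permutations for Mantel.
#' @param seed Optional master seed.
#' @return data.frame: one row per region x trait with `lambda`,
#'   `p_lambda`, `mantel_r`, `p_mantel`, `cv`, `n_species`, `flag`.
#' @export
signal_table <- function(clade, tree, n_rand = 1000, n_perm = 999,
                         seed = NULL) {
  stopifnot(inherits(clade, "clade_dataset"))
  tree <- fix_zero_branches(tree)
  rows <- list()
  k <- 0L
  for (trait in c("color", "luminance")) {
    m <- clade[[trait]]
    cvs <- coefficient_of_variation(clade, trait)
    for (rg in colnames(m)) {
      k <- k + 1L
      v <- m[, rg]
      v <- v[!is.na(v)]
      cv <- cvs$cv[cvs$region == rg]
      row <- data.frame(region = rg, trait = trait, lambda = NA_real_,
                        p_lambda = NA_real_, mantel_r = NA_real_,
                        p_mantel = NA_real_, cv = cv,
                        n_species = length(v), flag = "")
      if (length(v) < 4) {
        row$flag <- "insufficient"
      } else if (stats::sd(v) == 0) {
        row$flag <- "zero_variance"
      } else {
        # one shared sub-seed per test family so that identical trait
        # columns yield identical rows
        lam <- pagels_lambda(v, tree, n_rand = n_rand,
                             seed = derive_seed(seed, 1L))
        sp <- names(v)
        dphy <- stats::cophenetic(ape::keep.tip(tree, sp))[sp, sp]
        dtrait <- abs(outer(v, v, "-"))
        man <- mantel_test(dtrait, dphy, n_perm = n_perm,
                           seed = derive_seed(seed, 2L))
        row$lambda <- lam$lambda_hat
        row$p_lambda <- lam$p_randomization
        row$mantel_r <- man$r
        row$p_mantel <- man$p_permutation
        if (isTRUE(lam$unidentifiable)) row$flag <- "star_tree"
      }
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
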