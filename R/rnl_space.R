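#' Receptor-noise-limited chromatic distance (tetrachromatic)
#'
#' Vorobyev-Osorio discriminability between two stimuli in just noticeable
#' differences (JND), from log catch contrasts weighted by per-cone Weber
#' fractions:
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (e_k e_l)^2 (\Delta f_i - \Delta f_j)^2}
#'                         {\sum_{\mathrm{triples}} (e_a e_b e_c)^2}}
#' with \eqn{\Delta f_i = \ln q_i^A - \ln q_i^B} and \eqn{(k,l)} the cones
#' not in pair \eqn{(i,j)}.
#'
#' @param catch_a,catch_b Named von Kries-corrected catches `c(u=,s=,m=,l=)`,
#'   all strictly positive (black patches must be excluded upstream).
#' @param weber Named Weber fractions `c(u=,s=,m=,l=)`.
#' @return Chromatic distance in JND.
#' @export
delta_s <- function(catch_a, catch_b, weber = DEFAULT_WEBER) {
  cones <- c("u", "s", "m", "l")
  qa <- as.numeric(catch_a[cones]); qb <- as.numeric(catch_b[cones])
  e <- as.numeric(weber[cones])
  if (anyNA(qa) || anyNA(qb) || any(qa <= 0) || any(qb <= 0))
    stop("catches must be strictly positive (exclude black patches upstream)")
  df <- log(qa) - log(qb)
  pairs <- utils::combn(4, 2)
  num <- 0
  for (k in seq_len(ncol(pairs))) {
    ij <- pairs[, k]
    kl <- setdiff(1:4, ij)
    num <- num + (e[kl[1]] * e[kl[2]])^2 * (df[ij[1]] - df[ij[2]])^2
  }
  den <- sum(vapply(1:4, function(i) prod(e[-i])^2, numeric(1)))
  sqrt(num / den)
}

# 3x4 matrix A such that ||A (fA - fB)|| equals delta_s for log catches f in
# cone order (u, s, m, l). Sequential noise-weighted orthogonalization:
# X is the l-vs-m opponent axis, Y brings in s, Z carries the u contrast
# with a positive weight on f_u (increasing u-catch increases Z). Rows
# annihilate the uniform direction, so intensity changes do not move points
# and the equal-catch (achromatic) stimulus maps to the origin.
rnl_transform_matrix <- function(weber = DEFAULT_WEBER) {
  e <- as.numeric(weber[c("l", "m", "s", "u")])  # construction order
  e1 <- e[1]; e2 <- e[2]; e3 <- e[3]; e4 <- e[4]
  s12 <- e1^2 + e2^2
  s123 <- (e1 * e2)^2 + (e1 * e3)^2 + (e2 * e3)^2
  s1234 <- (e1 * e2 * e3)^2 + (e1 * e2 * e4)^2 +
           (e1 * e3 * e4)^2 + (e2 * e3 * e4)^2
  # rows act on (f_l, f_m, f_s, f_u)
  A <- rbind(
    sqrt(1 / s12) * c(1, -1, 0, 0),
    sqrt(s12 / s123) * c(-e2^2 / s12, -e1^2 / s12, 1, 0),
    sqrt(s123 / s1234) * c(-(e2 * e3)^2 / s123, -(e1 * e3)^2 / s123,
                           -(e1 * e2)^2 / s123, 1)
  )
  A[, c(4, 3, 2, 1)]  # reorder columns to (u, s, m, l)
}

#' Receptor-noise XYZ coordinates from corrected catches
#'
#' Fixed linear map of the log catches onto three axes such that Euclidean
#' distance between any two points equals [delta_s()] (JND isometry). The
#' orientation is frozen: X is the l/m opponent contrast, Y adds s, and Z
#' carries the u contrast with positive sign. Uniform intensity changes
#' (adding a constant to every log catch) leave coordinates unchanged.
#'
#' @param catches data.frame with columns `q_u, q_s, q_m, q_l` (and
#'   optionally `patch_id`); rows with any non-positive or `NA` catch are an
#'   error unless flagged black, in which case they yield `NA` coordinates.
#' @param weber Named Weber fractions.
#' @return data.frame with columns `X, Y, Z` in JND units (plus `patch_id`
#'   when present in the input).
#' @export
xyz_from_catches <- function(catches, weber = DEFAULT_WEBER) {
  catches <- as.data.frame(catches)
  qc <- c("q_u", "q_s", "q_m", "q_l")
  if (!all(qc %in% names(catches))) stop("need columns q_u, q_s, q_m, q_l")
  Q <- as.matrix(catches[, qc])
  black <- if ("is_black" %in% names(catches)) catches$is_black
           else rep(FALSE, nrow(Q))
  bad <- !black & (rowSums(is.na(Q)) > 0 | rowSums(Q <= 0, na.rm = TRUE) > 0)
  if (any(bad))
    stop("non-positive catches in non-black rows: ",
         paste(utils::head(which(bad)), collapse = ", "))
  A <- rnl_transform_matrix(weber)
  XYZ <- matrix(NA_real_, nrow(Q), 3, dimnames = list(NULL, c("X", "Y", "Z")))
  ok <- !black
  if (any(ok)) XYZ[ok, ] <- log(Q[ok, , drop = FALSE]) %*% t(A)
  out <- as.data.frame(XYZ)
  if ("patch_id" %in% names(catches)) out <- cbind(patch_id = catches$patch_id, out)
  out
}

#' Express XYZ coordinates relative to the achromatic point
#'
#' Translates the table so that the image of a hypothetical equal-catch
#' stimulus is exactly at the origin. Under the frozen transform the
#' achromatic image is already (0,0,0), so this is the identity there; the
#' explicit step keeps the convention visible and is idempotent.
#'
#' @param xyz data.frame with columns `X, Y, Z`.
#' @param weber Named Weber fractions (used to locate the achromatic image).
#' @return The translated data.frame.
#' @export
achromatic_origin <- function(xyz, weber = DEFAULT_WEBER) {
  A <- rnl_transform_matrix(weber)
  origin <- as.numeric(A %*% rep(0, 4))  # image of equal log catches f = 0
  xyz$X <- xyz$X - origin[1]
  xyz$Y <- xyz$Y - origin[2]
  xyz$Z <- xyz$Z - origin[3]
  xyz
}
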