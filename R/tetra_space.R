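# Full volume of the color tetrahedron (circumradius 0.75, edge
# a = 0.75*sqrt(8/3), volume a^3/(6*sqrt(2))).
TETRA_VOLUME <- (0.75 * sqrt(8 / 3))^3 / (6 * sqrt(2))

#' Map relative cone catches into Goldsmith's tetrahedral color space
#'
#' The four pure-cone stimuli sit at the vertices of a regular tetrahedron
#' of circumradius 0.75 centred on the achromatic point (equal catches),
#' which maps to the origin. `r` (distance from the origin) measures
#' saturation; `theta_h`/`phi_h` are hue angles.
#'
#' @param rel Either a named numeric vector `c(u=,s=,m=,l=)` summing to 1,
#'   or a data.frame/matrix with columns `rel_u, rel_s, rel_m, rel_l`
#'   (rows of all-`NA` pass through as `NA` coordinates, the achromatic
#'   sentinel used for black patches).
#' @return data.frame with columns `x, y, z, r, theta_h, phi_h`.
#' @export
to_tetra <- function(rel) {
  if (is.null(dim(rel))) {
    rel <- as.data.frame(as.list(stats::setNames(rel[c("u", "s", "m", "l")],
                                                 c("rel_u", "rel_s", "rel_m", "rel_l"))))
  }
  rel <- as.data.frame(rel)
  cols <- c("rel_u", "rel_s", "rel_m", "rel_l")
  if (!all(cols %in% names(rel))) stop("need columns rel_u, rel_s, rel_m, rel_l")
  u <- rel$rel_u; s <- rel$rel_s; m <- rel$rel_m; l <- rel$rel_l
  ok <- !is.na(u)
  if (any(ok & (pmin(u, s, m, l) < -1e-9 |
                abs(u + s + m + l - 1) > 1e-6)))
    stop("relative catches must be non-negative and sum to 1")
  x <- ((1 - 2 * s - m - u) / 2) * sqrt(3 / 2)
  y <- (-1 + 3 * m + u) / (2 * sqrt(2))
  z <- u - 1 / 4
  r <- sqrt(x^2 + y^2 + z^2)
  theta_h <- atan2(y, x)
  phi_h <- ifelse(r > 0, asin(pmin(pmax(z / r, -1), 1)), 0)
  out <- data.frame(x = x, y = y, z = z, r = r,
                    theta_h = theta_h, phi_h = phi_h)
  if ("patch_id" %in% names(rel)) out <- cbind(patch_id = rel$patch_id, out)
  out
}

# --- 3-D convex hull volume (incremental beneath-beyond) -------------------
#
# Faces are kept as triangles with outward-oriented vertex triples. A point
# outside the current hull sees a set of faces; the horizon (edges used by
# exactly one visible face) is re-capped with new triangles through the
# point. Volume is then the sum of signed tetrahedra against an interior
# point. Adequate for the few hundred patch points typical of a clade.

convex_hull_volume_3d <- function(P, tol = 1e-10) {
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  P <- unique(P)
  n <- nrow(P)
  if (n < 4) return(list(volume = 0, degenerate = TRUE))
  scale <- max(1, max(abs(P)))
  eps <- tol * scale^3

  # initial simplex: farthest pair, then max-area third, max-volume fourth
  d1 <- which.max(rowSums((P - matrix(P[1, ], n, 3, byrow = TRUE))^2))
  d2 <- which.max(rowSums((P - matrix(P[d1, ], n, 3, byrow = TRUE))^2))
  ab <- P[d2, ] - P[d1, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  areas <- vapply(seq_len(n), function(i)
    sum(cr(ab, P[i, ] - P[d1, ])^2), numeric(1))
  d3 <- which.max(areas)
  nrm <- cr(ab, P[d3, ] - P[d1, ])
  vols <- abs(as.numeric((P - matrix(P[d1, ], n, 3, byrow = TRUE)) %*% nrm))
  d4 <- which.max(vols)
  if (vols[d4] < 6 * eps) return(list(volume = 0, degenerate = TRUE))

  interior <- colMeans(P[c(d1, d2, d3, d4), ])
  orient <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c_ <- P[tri[3], ]
    nv <- cr(b - a, c_ - a)
    if (sum(nv * (interior - a)) > 0) tri[c(1, 3, 2)] else tri
  }
  faces <- list(orient(c(d1, d2, d3)), orient(c(d1, d2, d4)),
                orient(c(d1, d3, d4)), orient(c(d2, d3, d4)))

  face_plane <- function(tri) {
    a <- P[tri[1], ]
    nv <- cr(P[tri[2], ] - a, P[tri[3], ] - a)
    c(nv, sum(nv * a))
  }
  planes <- lapply(faces, face_plane)

  rest <- setdiff(seq_len(n), c(d1, d2, d3, d4))
  for (pi_ in rest) {
    p <- P[pi_, ]
    vis <- vapply(planes, function(pl)
      sum(pl[1:3] * p) - pl[4] > eps, logical(1))
    if (!any(vis)) next
    vis_faces <- faces[vis]
    keep_faces <- faces[!vis]
    keep_planes <- planes[!vis]
    # horizon: undirected edges of visible faces used exactly once
    edges <- do.call(rbind, lapply(vis_faces, function(tr)
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    new_faces <- lapply(seq_len(nrow(horizon)), function(k)
      orient(c(horizon[k, 1], horizon[k, 2], pi_)))
    faces <- c(keep_faces, new_faces)
    planes <- c(keep_planes, lapply(new_faces, face_plane))
  }

  vol <- 0
  for (tri in faces) {
    a <- P[tri[1], ] - interior
    b <- P[tri[2], ] - interior
    c_ <- P[tri[3], ] - interior
    vol <- vol + abs(sum(a * cr(b, c_))) / 6
  }
  if (vol < tol) return(list(volume = 0, degenerate = TRUE))
  list(volume = vol, degenerate = FALSE)
}

#' Convex-hull color volume and percentage of a reference volume
#'
#' Occupied color volume is the volume of the convex hull of the patch
#' points in tetrahedral space, expressed as a percentage of
#' `reference_volume`. The default reference is the full tetrahedron
#' (0.21650635 cubic tetra-units); to follow the convention of reporting
#' against the published total avian plumage color-space volume, supply that
#' value instead — the report records which reference was used.
#'
#' @param points data.frame/matrix with columns `x, y, z` (NA rows dropped).
#' @param reference_volume Reference volume in cubic tetra-units.
#' @return List: `hull_volume`, `reference_volume`, `pct_of_reference`,
#'   `n_points`, `degenerate`.
#' @export
hull_volume <- function(points, reference_volume = TETRA_VOLUME) {
  pts <- as.data.frame(points)[, c("x", "y", "z")]
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  hv <- if (nrow(pts) < 4) list(volume = 0, degenerate = TRUE)
        else convex_hull_volume_3d(as.matrix(pts))
  list(hull_volume = hv$volume,
       reference_volume = reference_volume,
       pct_of_reference = 100 * hv$volume / reference_volume,
       n_points = nrow(pts),
       degenerate = hv$degenerate)
}

#' Per-group color-volume occupancy
#'
#' @param tetra data.frame from [to_tetra()] with `x, y, z` columns.
#' @param groups Vector of group labels (e.g. genus, or genus x sex), one
#'   per row of `tetra`.
#' @param reference_volume Reference volume (see [hull_volume()]).
#' @return data.frame: one row per group with hull volume, percentage of
#'   reference, group size and degeneracy flag.
#' @export
group_volumes <- function(tetra, groups, reference_volume = TETRA_VOLUME) {
  stopifnot(nrow(tetra) == length(groups))
  out <- lapply(split(seq_len(nrow(tetra)), groups), function(idx) {
    v <- hull_volume(tetra[idx, , drop = FALSE], reference_volume)
    data.frame(hull_volume = v$hull_volume,
               pct_of_reference = v$pct_of_reference,
               n_points = v$n_points, degenerate = v$degenerate)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}
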