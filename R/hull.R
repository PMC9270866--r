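#' Convex-hull volume of a 3D point set
#'
#' Volume of the convex hull of the crystal cloud, reported in ml
#' (mm^3 / 1000) as an RV size index. With 20 crystals an exact
#' brute-force hull is cheap: every supporting plane is found by
#' enumerating point triples and testing whether all remaining points
#' lie on one side; coplanar facets (e.g. the faces of a cube) are
#' merged per unique plane and fan-triangulated from their 2D hull, so
#' the signed-tetrahedron volume sum is exact.
#'
#' @param points n x 3 matrix, n >= 4, coordinates in mm.
#' @param tol coplanarity tolerance in mm (default 1e-9 scaled by the
#'   cloud extent).
#' @return hull volume in ml.
#' @export
convex_hull_volume <- function(points, tol = 1e-9) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  n <- nrow(P)
  if (n < 4) stopf("need >= 4 points for a 3D hull, got %d", n)
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  scale <- max(row_norms(X), 1)
  eps <- tol * scale
  if (max(svd(X, nu = 0)$d[3], 0) <= 1e-9 * scale)
    stopf("degenerate point set: all points (near) coplanar")

  combs <- utils::combn(n, 3)
  a <- X[combs[1, ], , drop = FALSE]
  b <- X[combs[2, ], , drop = FALSE]
  cc <- X[combs[3, ], , drop = FALSE]
  nrm <- rowwise_cross(b - a, cc - a)
  nn <- row_norms(nrm)
  ok <- nn > eps
  nrm <- nrm[ok, , drop = FALSE] / nn[ok]
  offs <- rowSums(nrm * a[ok, , drop = FALSE])
  # signed distances of all points to each candidate plane
  D <- nrm %*% t(X) - offs           # (n_planes x n)
  sup_pos <- rowSums(D > eps) == 0
  sup_neg <- rowSums(D < -eps) == 0
  flip <- sup_neg & !sup_pos
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  offs[flip] <- -offs[flip]
  sup <- sup_pos | sup_neg
  if (!any(sup)) stopf("hull construction failed")
  nrm <- nrm[sup, , drop = FALSE]; offs <- offs[sup]

  # deduplicate supporting planes (normal + offset to tolerance)
  key <- paste(round(nrm[, 1] / 1e-7), round(nrm[, 2] / 1e-7),
               round(nrm[, 3] / 1e-7), round(offs / (1e-7 * scale)))
  uniq <- !duplicated(key)
  nrm <- nrm[uniq, , drop = FALSE]; offs <- offs[uniq]

  vol <- 0
  for (f in seq_len(nrow(nrm))) {
    nv <- nrm[f, ]
    on_plane <- which(abs(X %*% nv - offs[f]) <= eps)
    if (length(on_plane) < 3) next
    # 2D hull of the facet's points, fan-triangulated
    ref <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- unit_vec(vec_cross(nv, ref)); v <- vec_cross(nv, u)
    Q <- X[on_plane, , drop = FALSE]
    uv <- cbind(Q %*% u, Q %*% v)
    h <- grDevices::chull(uv[, 1], uv[, 2])
    poly <- on_plane[h]
    m <- length(poly)
    if (m < 3) next
    # orient the facet polygon so its normal matches the outward nv
    e1 <- X[poly[2], ] - X[poly[1], ]
    e2 <- X[poly[3], ] - X[poly[1], ]
    if (sum(vec_cross(e1, e2) * nv) < 0) poly <- rev(poly)
    for (k in 2:(m - 1)) {
      tetra <- det(rbind(X[poly[1], ], X[poly[k], ], X[poly[k + 1], ]))
      vol <- vol + tetra / 6
    }
  }
  abs(vol) / 1000
}
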