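#' Least-squares plane through 3D points
#'
#' Total-least-squares fit minimizing the sum of squared orthogonal
#' distances (smallest singular vector of the centred coordinates).
#' The normal sign is fixed deterministically: positive projection on
#' `orient` when given, otherwise the first non-zero component
#' positive.
#'
#' @param points n x 3 matrix (n >= 3), mm.
#' @param orient optional length-3 vector toward which the normal is
#'   oriented (e.g. the apex-to-base axis).
#' @return list with `centroid` (length 3) and unit `normal`.
#' @export
fit_plane <- function(points, orient = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stopf("need >= 3 points to fit a plane")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1))
    stopf("degenerate point set (collinear or coincident): cannot fit plane")
  normal <- sv$v[, 3]
  if (!is.null(orient)) {
    if (sum(normal * orient) < 0) normal <- -normal
  } else {
    nz <- which(abs(normal) > 1e-12)[1]
    if (normal[nz] < 0) normal <- -normal
  }
  list(centroid = ctr, normal = normal)
}

# Orthonormal in-plane basis for a plane.
plane_basis <- function(plane) {
  n <- plane$normal
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit_vec(vec_cross(n, ref))
  v <- vec_cross(n, u)
  rbind(u, v)
}

# Project points into the 2D coordinates of their plane.
project_to_plane <- function(points, plane) {
  B <- plane_basis(plane)
  sweep(as.matrix(points), 2, plane$centroid) %*% t(B)
}

#' Planar-projected polygon area of ordered 3D points
#'
#' Points taken in circumferential order are orthogonally projected
#' onto their least-squares plane and the shoelace area of the
#' projected polygon is returned. The annulus and the free-wall
#' parallels are never exactly planar, so the projection step is part
#' of the area definition. A self-intersecting projection is flagged
#' via the `"self_intersecting"` attribute rather than rejected.
#'
#' @param points n x 3 matrix, n >= 3, in polygon order.
#' @return area in mm^2 (non-negative), with attribute
#'   `self_intersecting`.
#' @export
polygon_area_3d <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stopf("polygon needs >= 3 points, got %d", n)
  plane <- tryCatch(fit_plane(points), error = function(e) NULL)
  if (is.null(plane)) {
    # collinear points enclose zero area
    area <- 0
    attr(area, "self_intersecting") <- FALSE
    return(area)
  }
  P <- project_to_plane(points, plane)
  i2 <- c(2:n, 1)
  area <- abs(sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2])) / 2
  attr(area, "self_intersecting") <- polygon_self_intersects(P)
  area
}

# Segment-intersection test between non-adjacent polygon edges.
polygon_self_intersects <- function(P) {
  n <- nrow(P)
  seg <- cbind(seq_len(n), c(2:n, 1))
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      share <- length(intersect(seg[i, ], seg[j, ])) > 0
      if (share) next
      a <- P[seg[i, 1], ]; b <- P[seg[i, 2], ]
      c <- P[seg[j, 1], ]; d <- P[seg[j, 2], ]
      if (ccw(a, c, d) != ccw(b, c, d) && ccw(a, b, c) != ccw(a, b, d))
        return(TRUE)
    }
  }
  FALSE
}

#' Tricuspid annular area at a time point
#'
#' Area of the polygon spanned by the 6 annular crystals in their
#' circumferential layout order, projected on the annular best-fit
#' plane; see [polygon_area_3d()].
#'
#' @param x a `channel_recording` (with `timepoint` a sample index) or
#'   an `averaged_beat` (with `timepoint` `"ED"`, `"ES"` or percent of
#'   cycle).
#' @param layout a `crystal_layout`.
#' @param timepoint where in the cycle to evaluate (default `"ED"`).
#' @return annular area in mm^2.
#' @export
annular_area <- function(x, layout, timepoint = "ED") {
  pts <- frame_at(x, layout$annular, timepoint)
  as.numeric(polygon_area_3d(pts))
}

frame_at <- function(x, labels, timepoint) {
  if (inherits(x, "channel_recording")) {
    if (!is.numeric(timepoint))
      stopf("for a raw recording, timepoint must be a sample index")
    crystal_frame(x$crystals, labels, as.integer(timepoint))
  } else if (inherits(x, "averaged_beat")) {
    beat_frame(x, labels, beat_grid_index(x, timepoint))
  } else stopf("x must be a channel_recording or averaged_beat")
}

#' Percent annular area reduction between states
#'
#' `100 * (1 - area_tra / area_baseline)`: the fractional area lost
#' going from the Baseline annulus to the ring-annuloplasty (TRA)
#' annulus, in percent.
#'
#' @param area_baseline,area_tra areas in mm^2, both > 0.
#' @return percent reduction (negative if the annulus enlarged).
#' @export
percent_area_reduction <- function(area_baseline, area_tra) {
  if (area_baseline <= 0 || area_tra <= 0)
    stopf("areas must be positive")
  100 * (1 - area_tra / area_baseline)
}

#' Regional cross-sectional area of a free-wall parallel
#'
#' Projected polygon area of one crystal row (basal, mid or lower) in
#' circumferential order; the polygon is closed by the chord between
#' the end crystals, which is the natural closure whether the row spans
#' part or all of the circumference.
#'
#' @inheritParams annular_area
#' @param row `"basal"`, `"mid"` or `"lower"`.
#' @return area in mm^2, attribute `self_intersecting` preserved.
#' @export
cross_sectional_area <- function(x, layout, row = c("basal", "mid", "lower"),
                                 timepoint = "ED") {
  row <- match.arg(row)
  labels <- layout$parallels[[row]]
  if (length(labels) < 3) stopf("row '%s' has < 3 crystals", row)
  pts <- frame_at(x, labels, timepoint)
  polygon_area_3d(pts)
}

#' Radius of curvature by in-plane circle fit
#'
#' Points are projected onto their least-squares plane; a circle is
#' fitted in that plane by the algebraic Kasa least-squares formulation
#' and refined by one geometric Gauss-Newton step. Exact on noise-free
#' circular data for any n >= 3 (for n = 3 this is the circumscribed
#' circle).
#'
#' @param points n x 3 matrix, n >= 3, mm.
#' @return fitted radius in mm.
#' @export
fit_circle_radius <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stopf("need >= 3 points to fit a circle")
  plane <- fit_plane(points)  # errors on collinear input
  P <- project_to_plane(points, plane)
  x <- P[, 1]; y <- P[, 2]
  # Kasa: minimize ||x^2+y^2 + D x + E y + F||
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- qr.solve(A, b)
  cx <- -coef[1] / 2; cy <- -coef[2] / 2
  r <- sqrt(max(cx^2 + cy^2 - coef[3], 0))
  # one geometric Gauss-Newton pass on (cx, cy, r)
  for (pass in 1) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    if (any(di == 0)) break
    J <- cbind(-dx / di, -dy / di, -1)
    res <- di - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  r
}

#' Regional radius of curvature of a free-wall parallel
#'
#' @inheritParams cross_sectional_area
#' @return radius in mm; see [fit_circle_radius()].
#' @export
radius_of_curvature <- function(x, layout, row = c("basal", "mid", "lower"),
                                timepoint = "ED") {
  row <- match.arg(row)
  labels <- layout$parallels[[row]]
  pts <- frame_at(x, labels, timepoint)
  fit_circle_radius(pts)
}

#' Table-style geometry summary for a Baseline/TRA pair
#'
#' Computes, at end-diastole of each state's averaged beat: tricuspid
#' annular area (TAA), convex-hull RV volume over all crystals (EDV),
#' and per-row cross-sectional area (CSA) and radius of curvature
#' (ROC), plus the percent annular reduction from Baseline to TRA.
#' A row missing from the layout's recording yields NA fields rather
#' than an error.
#'
#' @param baseline,tra `averaged_beat` objects with matched layouts.
#' @param layout the shared `crystal_layout`.
#' @return object of class `geometry_summary`: a data.frame with one
#'   row per variable (`taa_mm2`, `edv_ml`, `csa_<row>_mm2`,
#'   `roc_<row>_mm`) and columns `baseline`, `tra`, `delta`, plus the
#'   attribute `taa_reduction_pct`.
#' @export
geometry_summary <- function(baseline, tra, layout) {
  one_state <- function(beat) {
    frame20 <- frame_at(beat, layout_labels(layout), "ED")
    vals <- c(taa_mm2 = annular_area(beat, layout, "ED"),
              edv_ml = convex_hull_volume(frame20))
    for (row in names(layout$parallels)) {
      csa <- tryCatch(as.numeric(cross_sectional_area(beat, layout, row, "ED")),
                      error = function(e) NA_real_)
      roc <- tryCatch(radius_of_curvature(beat, layout, row, "ED"),
                      error = function(e) NA_real_)
      vals[[paste0("csa_", row, "_mm2")]] <- csa
      vals[[paste0("roc_", row, "_mm")]] <- roc
    }
    vals
  }
  b <- one_state(baseline); t_ <- one_state(tra)
  out <- data.frame(variable = names(b), baseline = unname(b),
                    tra = unname(t_), delta = unname(t_ - b))
  attr(out, "taa_reduction_pct") <- percent_area_reduction(b[["taa_mm2"]],
                                                           t_[["taa_mm2"]])
  class(out) <- c("geometry_summary", "data.frame")
  out
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("RV geometry at end-diastole (Baseline vs TRA)\n")
  print.data.frame(cbind(x[1], round(x[-1], 2)), row.names = FALSE)
  cat(sprintf("Tricuspid annular area reduction: %.1f %%\n",
              attr(x, "taa_reduction_pct")))
  invisible(x)
}
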