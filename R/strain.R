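# Per-face membrane kinematics on triangulated crystal meshes.
#
# Each triangle carries an orthonormal tangent frame (first axis along
# its first edge, second in-plane perpendicular). In that frame the
# edge-vector matrix is upper triangular, so the 2x2 deformation
# gradient F = B A^-1 of a face pair has a closed form and det F > 0
# whenever both triangles are non-degenerate.

# Frames and 2x2 upper-triangular edge matrices for all faces at once.
# Returns list(u1, u2, normal: F x 3; a11, a12, a22: length F).
face_frames <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  a11 <- row_norms(e1)
  if (any(a11 == 0)) stopf("degenerate face: zero-length edge")
  u1 <- e1 / a11
  a12 <- rowSums(e2 * u1)
  w <- e2 - a12 * u1
  a22 <- row_norms(w)
  if (any(a22 <= 1e-12 * a11)) stopf("degenerate face: zero area")
  u2 <- w / a22
  normal <- rowwise_cross(u1, u2)
  list(u1 = u1, u2 = u2, normal = normal, a11 = a11, a12 = a12, a22 = a22)
}

#' Deformation gradient between a reference and a deformed triangle
#'
#' Builds an orthonormal tangent frame on each triangle and returns the
#' unique 2x2 linear map `F` taking reference in-plane edge coordinates
#' to deformed in-plane edge coordinates. `det F` equals the triangle
#' area ratio and is positive for any pair of non-degenerate triangles.
#'
#' @param ref_face,def_face 3 x 3 matrices: the triangle's vertices as
#'   rows, in corresponding order, mm.
#' @return 2x2 matrix `F` (upper triangular in these frames).
#' @export
face_deformation_gradient <- function(ref_face, def_face) {
  fr <- face_frames(as.matrix(ref_face), matrix(1:3, 1))
  fd <- face_frames(as.matrix(def_face), matrix(1:3, 1))
  F11 <- fd$a11 / fr$a11
  F22 <- fd$a22 / fr$a22
  F12 <- (fd$a12 - F11 * fr$a12) / fr$a22
  matrix(c(F11, 0, F12, F22), 2, 2)
}

#' Green-Lagrange strain tensor from a deformation gradient
#'
#' `E = (F'F - I) / 2`: zero for any rigid motion, so the measure is
#' objective by construction.
#'
#' @param F 2x2 deformation gradient.
#' @return symmetric 2x2 strain tensor.
#' @export
green_lagrange <- function(F) {
  if (any(!is.finite(F))) stopf("non-finite deformation gradient")
  (crossprod(F) - diag(2)) / 2
}

#' Normal strain along a material direction
#'
#' `d' E d` for a unit direction `d` expressed in the reference tangent
#' frame: the Green-Lagrange normal strain of fibres along `d`.
#'
#' @param E symmetric 2x2 strain tensor.
#' @param direction length-2 unit vector in the reference frame.
#' @return dimensionless strain.
#' @export
directional_strain <- function(E, direction) {
  nd <- vec_norm(direction)
  if (nd == 0) stopf("direction must be non-zero")
  d <- direction / nd
  as.numeric(t(d) %*% E %*% d)
}

#' Areal strain from a deformation gradient
#'
#' Relative change of local surface area, `det F - 1 = dA/dA0 - 1`.
#'
#' @param F 2x2 deformation gradient.
#' @return dimensionless areal strain (> -1).
#' @export
areal_strain <- function(F) {
  d <- det(F)
  if (d <= 0) stopf("inverted element: det F = %g <= 0", d)
  d - 1
}

#' Per-face circumferential and longitudinal material directions
#'
#' The ventricular long axis is the unit vector from the centroid of
#' the annular crystals to the apex crystal, both taken at the
#' reference configuration. On each face the longitudinal direction is
#' the long axis projected into the face plane and normalized; the
#' circumferential direction is its in-plane perpendicular
#' (`n x l`). Faces whose normal is (near) parallel to the long axis
#' fall back to the average direction of their region's faces and are
#' flagged.
#'
#' @param mesh a `surface_mesh` at the reference configuration.
#' @param layout the `crystal_layout` the mesh was built from.
#' @return list with `circ` and `long` (F x 3 unit vectors in 3D),
#'   `circ2`, `long2` (F x 2, coordinates in each face's tangent
#'   frame), `long_axis`, and logical `fallback` per face.
#' @export
material_directions <- function(mesh, layout) {
  labels <- mesh$labels
  ann_idx <- match(layout$annular, labels)
  apex_idx <- match(layout$apex, labels)
  # base mesh vertices 1..20 are the crystals in layout order; after
  # subdivision the originals keep their indices only at level 0, so
  # recover the axis from the stored base positions when present.
  Vb <- if (!is.null(mesh$base_vertices)) mesh$base_vertices else mesh$vertices
  axis <- Vb[apex_idx, ] - colMeans(Vb[ann_idx, , drop = FALSE])
  L <- unit_vec(axis)
  fr <- face_frames(mesh$vertices, mesh$faces)
  Fc <- nrow(mesh$faces)
  ln <- fr$normal %*% L   # component of L along each normal
  Lmat <- matrix(L, Fc, 3, byrow = TRUE)
  lvec <- Lmat - as.numeric(ln) * fr$normal
  lnorm <- row_norms(lvec)
  fallback <- lnorm < 1e-6
  lvec[!fallback, ] <- lvec[!fallback, , drop = FALSE] / lnorm[!fallback]
  if (any(fallback)) {
    for (f in which(fallback)) {
      same <- which(mesh$face_region == mesh$face_region[f] & !fallback)
      v <- colSums(lvec[same, , drop = FALSE])
      # re-project the neighbour average into this face's plane
      v <- v - sum(v * fr$normal[f, ]) * fr$normal[f, ]
      lvec[f, ] <- unit_vec(v)
    }
  }
  cvec <- rowwise_cross(fr$normal, lvec)
  list(circ = cvec, long = lvec,
       circ2 = cbind(rowSums(cvec * fr$u1), rowSums(cvec * fr$u2)),
       long2 = cbind(rowSums(lvec * fr$u1), rowSums(lvec * fr$u2)),
       long_axis = L, fallback = fallback)
}

# Vectorized per-face strain between two vertex configurations sharing
# one face table. Directions (circ2/long2) are in reference frames.
strain_field_core <- function(ref_vertices, def_vertices, faces, dirs) {
  fr <- face_frames(ref_vertices, faces)
  fd <- face_frames(def_vertices, faces)
  F11 <- fd$a11 / fr$a11
  F22 <- fd$a22 / fr$a22
  F12 <- (fd$a12 - F11 * fr$a12) / fr$a22
  # E = (F'F - I)/2 with F upper triangular
  E11 <- (F11^2 - 1) / 2
  E12 <- F11 * F12 / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  quad <- function(d) E11 * d[, 1]^2 + 2 * E12 * d[, 1] * d[, 2] + E22 * d[, 2]^2
  list(F11 = F11, F12 = F12, F22 = F22,
       E_cc = quad(dirs$circ2), E_ll = quad(dirs$long2),
       areal = F11 * F22 - 1,
       ref_area = fr$a11 * fr$a22 / 2)
}

new_strain_field <- function(core, mesh, timepoint, reference) {
  df <- data.frame(face = seq_len(nrow(mesh$faces)),
                   region = mesh$face_region,
                   E_cc = core$E_cc, E_ll = core$E_ll, areal = core$areal,
                   ref_area = core$ref_area)
  structure(df, F11 = core$F11, F12 = core$F12, F22 = core$F22,
            timepoint = timepoint, reference = reference,
            class = c("strain_field", "data.frame"))
}

#' Cardiac strain over the averaged beat
#'
#' Strain of each state versus its own end-diastole: the free-wall
#' mesh is built at the beat's ED frame, refined by Loop subdivision,
#' and the same (linear, connectivity-only) refinement operator is
#' applied to every other frame of the normalized cycle. Per-face
#' Green-Lagrange circumferential, longitudinal and areal strains are
#' computed against the ED reference, and summarized as
#' reference-area-weighted regional means.
#'
#' @param beat an `averaged_beat`.
#' @param layout the `crystal_layout`.
#' @param levels Loop subdivision levels (default 2).
#' @return object of class `strain_timecourse`: `grid` (percent of
#'   cycle), `regional` (array time x region x component of weighted
#'   means), `regional_sd`, per-face arrays `E_cc`, `E_ll`, `areal`
#'   (time x face), `face_region`, `ref_area`, the landmark phases,
#'   and the reference `mesh`.
#' @export
cardiac_strain_timecourse <- function(beat, layout, levels = 2) {
  labels <- layout_labels(layout)
  ed_idx <- beat_grid_index(beat, "ED")
  base_ref <- build_base_mesh(layout, beat_frame(beat, labels, ed_idx))
  ref <- loop_subdivide(base_ref, levels)
  ref$base_vertices <- base_ref$vertices
  S <- subdivision_operator(ref)
  # evaluate the reference through the same composed operator as the
  # deformed frames, so identical configurations give identically zero
  # strain
  ref$vertices <- as.matrix(S %*% base_ref$vertices)
  dirs <- material_directions(ref, layout)
  nt <- length(beat$grid)
  nf <- nrow(ref$faces)
  E_cc <- E_ll <- areal <- matrix(NA_real_, nt, nf)
  base_traj <- lapply(labels, function(lab) beat$crystals[[lab]])
  for (ti in seq_len(nt)) {
    Vb <- t(vapply(base_traj, function(m) m[ti, ], numeric(3)))
    def <- as.matrix(S %*% Vb)
    core <- strain_field_core(ref$vertices, def, ref$faces, dirs)
    E_cc[ti, ] <- core$E_cc; E_ll[ti, ] <- core$E_ll; areal[ti, ] <- core$areal
  }
  ref_area <- strain_field_core(ref$vertices, ref$vertices, ref$faces, dirs)$ref_area
  regions <- c("basal", "mid", "lower", "apex")
  comp <- list(E_cc = E_cc, E_ll = E_ll, areal = areal)
  regional <- array(NA_real_, c(nt, length(regions), 3),
                    dimnames = list(NULL, regions, names(comp)))
  regional_sd <- regional
  for (r in seq_along(regions)) {
    in_r <- ref$face_region == regions[r]
    if (!any(in_r)) next
    w <- ref_area[in_r] / sum(ref_area[in_r])
    for (k in 1:3) {
      Xc <- comp[[k]][, in_r, drop = FALSE]
      mu <- as.numeric(Xc %*% w)
      regional[, r, k] <- mu
      regional_sd[, r, k] <- sqrt(pmax(as.numeric(Xc^2 %*% w) - mu^2, 0))
    }
  }
  structure(
    list(grid = beat$grid, regional = regional, regional_sd = regional_sd,
         E_cc = E_cc, E_ll = E_ll, areal = areal,
         face_region = ref$face_region, ref_area = ref_area,
         es_phase = beat$es_phase, eivc_phase = beat$eivc_phase,
         eivr_phase = beat$eivr_phase, state_tag = beat$state_tag,
         mesh = ref, directions = dirs),
    class = "strain_timecourse")
}

#' @export
print.strain_timecourse <- function(x, ...) {
  es <- which.min(abs(x$grid - x$es_phase))
  cat(sprintf("Cardiac strain timecourse [%s]: %d faces, %d time points\n",
              x$state_tag, length(x$face_region), length(x$grid)))
  cat("Regional means at end-systole:\n")
  print(round(x$regional[es, c("basal", "mid"), ], 4))
  invisible(x)
}

#' Interventional strain: TRA versus Baseline at a matched time point
#'
#' Strain of the annuloplasty (TRA) configuration relative to Baseline
#' at the same cycle phase: the reference mesh is Baseline at the
#' requested timepoint, the deformed mesh is TRA at the same point,
#' both refined by the identical subdivision operator so faces
#' correspond one-to-one.
#'
#' @param baseline_beat,tra_beat `averaged_beat` objects with matched
#'   layouts.
#' @param layout the shared `crystal_layout`.
#' @param timepoint `"ED"` or `"ES"` (or percent of cycle).
#' @param levels Loop subdivision levels (default 2).
#' @return a `strain_field` data.frame: per-face `region`, `E_cc`,
#'   `E_ll`, `areal` and reference area.
#' @export
interventional_strain <- function(baseline_beat, tra_beat, layout,
                                  timepoint = "ED", levels = 2) {
  labels <- layout_labels(layout)
  i_ref <- beat_grid_index(baseline_beat, timepoint)
  i_def <- beat_grid_index(tra_beat, timepoint)
  base_ref <- build_base_mesh(layout, beat_frame(baseline_beat, labels, i_ref))
  ref <- loop_subdivide(base_ref, levels)
  ref$base_vertices <- base_ref$vertices
  S <- subdivision_operator(ref)
  ref$vertices <- as.matrix(S %*% base_ref$vertices)  # same path as def
  def_base <- beat_frame(tra_beat, labels, i_def)
  def <- as.matrix(S %*% def_base)
  dirs <- material_directions(ref, layout)
  core <- strain_field_core(ref$vertices, def, ref$faces, dirs)
  new_strain_field(core, ref, timepoint,
                   sprintf("Baseline at %s", as.character(timepoint)))
}

#' Regional aggregation of a strain field
#'
#' Mean and SD of each strain component per region, weighted by the
#' reference face areas (default) or unweighted. Empty regions are
#' reported with NA rather than dropped.
#'
#' @param field a `strain_field`.
#' @param weights `"area"` (reference-area-weighted, default) or
#'   `"unweighted"`.
#' @return data.frame: region x component rows with `mean`, `sd`,
#'   `n_faces`.
#' @export
regional_aggregate <- function(field, weights = c("area", "unweighted")) {
  weights <- match.arg(weights)
  regions <- unique(field$region)
  comps <- c("E_cc", "E_ll", "areal")
  rows <- list()
  for (r in regions) {
    in_r <- field$region == r
    w <- if (weights == "area") field$ref_area[in_r] else rep(1, sum(in_r))
    w <- w / sum(w)
    for (cp in comps) {
      v <- field[[cp]][in_r]
      mu <- sum(w * v)
      sdv <- sqrt(max(sum(w * v^2) - mu^2, 0))
      rows[[length(rows) + 1]] <-
        data.frame(region = r, component = cp, mean = mu, sd = sdv,
                   n_faces = sum(in_r))
    }
  }
  do.call(rbind, rows)
}
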