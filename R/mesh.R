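#' Triangulated RV free-wall crystal mesh
#'
#' Builds the deterministic base triangulation of the crystal cloud:
#' successive rows (annulus -> basal -> mid -> lower) are zipped into
#' triangle strips, and an apex fan closes the surface. The zipper
#' advances whichever row's next vertex comes first in nominal
#' circumferential phase (vertex index / row size; ties advance the
#' upper row) — the shorter-diagonal choice for evenly spread rows,
#' but decided from the layout alone. Connectivity therefore depends
#' only on the layout, never on the frame: meshes built for Baseline
#' and TRA always correspond face-by-face, which is the requirement
#' for computing strains between them. Vertex order is the canonical
#' layout order.
#'
#' The mesh is a manifold disk: its single open boundary is the
#' annular ring.
#'
#' @param layout a `crystal_layout`.
#' @param frame crystal coordinates at the reference time: a matrix
#'   with rownames covering all layout labels (see
#'   [crystal_frame()]-style output of `frame_at`), in mm.
#' @return object of class `surface_mesh`: `vertices` (V x 3),
#'   `faces` (F x 3, consistent outward orientation), `boundary`
#'   (logical per vertex), `vertex_row` (row label per vertex),
#'   `face_region` (strip label per face), `subdivision_level` (0).
#' @export
build_base_mesh <- function(layout, frame) {
  labels <- layout_labels(layout)
  missing <- setdiff(labels, rownames(frame))
  if (length(missing))
    stopf("frame is missing crystal(s): %s", paste(missing, collapse = ", "))
  V <- frame[labels, , drop = FALSE]
  rows <- list(annular = layout$annular, basal = layout$parallels$basal,
               mid = layout$parallels$mid, lower = layout$parallels$lower)
  idx_of <- stats::setNames(seq_along(labels), labels)
  row_idx <- lapply(rows, function(ls) unname(idx_of[ls]))
  apex <- unname(idx_of[layout$apex])

  faces <- NULL; region <- character()
  strips <- list(c("annular", "basal"), c("basal", "mid"), c("mid", "lower"))
  strip_region <- c("basal", "mid", "lower")
  for (s in seq_along(strips)) {
    f <- zip_rows(row_idx[[strips[[s]][1]]], row_idx[[strips[[s]][2]]])
    faces <- rbind(faces, f)
    region <- c(region, rep(strip_region[s], nrow(f)))
  }
  low <- row_idx$lower
  m <- length(low)
  fan <- cbind(low[c(2:m, 1)], low, apex)
  faces <- rbind(faces, fan)
  region <- c(region, rep("apex", m))

  vertex_row <- rep(names(rows), lengths(rows))
  vertex_row <- c(vertex_row, "apex")
  mesh <- structure(
    list(vertices = unname(V), faces = unname(faces),
         boundary = vertex_row == "annular", vertex_row = vertex_row,
         face_region = region, subdivision_level = 0L,
         labels = labels),
    class = "surface_mesh")
  mesh
}

# Zip two closed circumferential loops (index vectors into the vertex
# table) into a triangle strip. Advancing on the top loop emits
# (t_i, b_j, t_{i+1}); advancing on the bottom emits (t_i, b_j,
# b_{j+1}). The loop advanced is the one whose next vertex has the
# smaller nominal phase (i+1)/m vs (j+1)/n; ties advance the top.
zip_rows <- function(top, bottom) {
  m <- length(top); n <- length(bottom)
  faces <- matrix(0L, m + n, 3)
  i <- 0L; j <- 0L; k <- 0L
  tv <- function(i) top[(i %% m) + 1L]
  bv <- function(j) bottom[(j %% n) + 1L]
  while (i < m || j < n) {
    k <- k + 1L
    adv_top <- if (i >= m) FALSE else if (j >= n) TRUE
    else (i + 1) / m <= (j + 1) / n
    if (adv_top) {
      faces[k, ] <- c(tv(i), bv(j), tv(i + 1L)); i <- i + 1L
    } else {
      faces[k, ] <- c(tv(i), bv(j), bv(j + 1L)); j <- j + 1L
    }
  }
  faces
}

# Edge table of a triangle mesh: unique undirected edges plus, per
# edge, the 1-2 adjacent faces and their opposite vertices.
mesh_edges <- function(faces) {
  F_ <- nrow(faces)
  all_e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  opp <- c(faces[, 3], faces[, 1], faces[, 2])
  key_a <- pmin(all_e[, 1], all_e[, 2])
  key_b <- pmax(all_e[, 1], all_e[, 2])
  key <- paste(key_a, key_b)
  first <- !duplicated(key)
  edges <- cbind(key_a[first], key_b[first])
  eid <- match(key, key[first])
  opp1 <- rep(NA_integer_, nrow(edges))
  opp2 <- rep(NA_integer_, nrow(edges))
  count <- integer(nrow(edges))
  for (r in seq_along(eid)) {
    e <- eid[r]
    count[e] <- count[e] + 1L
    if (count[e] == 1L) opp1[e] <- opp[r] else opp2[e] <- opp[r]
  }
  if (any(count > 2L)) stopf("non-manifold mesh: edge shared by > 2 faces")
  list(edges = edges, opp1 = opp1, opp2 = opp2, n_faces = count,
       eid_by_corner = matrix(eid, F_, 3))
}

check_orientation <- function(faces) {
  dir_e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(dir_e[, 1], dir_e[, 2])
  if (anyDuplicated(key))
    stopf("inconsistent face orientation: repeated directed edge")
  invisible(TRUE)
}

#' Loop subdivision with boundary rules
#'
#' One or more rounds of Loop's triangle subdivision scheme. Interior
#' odd (edge) vertices use the 3/8-3/8-1/8-1/8 mask and interior even
#' vertices the valence-dependent mask with
#' `beta = (5/8 - (3/8 + cos(2 pi / n) / 4)^2) / n`; the open boundary
#' is treated as a cubic B-spline: boundary edge midpoints average
#' their endpoints and boundary vertices use the (1/8, 3/4, 1/8) mask.
#' The operator is linear in the vertex positions and depends only on
#' connectivity, so the same refinement applies to reference and
#' deformed configurations of one mesh — use [subdivision_operator()]
#' to extract the matrix.
#'
#' Face regions and vertex row labels propagate to children (an edge
#' midpoint inherits the row of its endpoint nearer the base).
#'
#' @param mesh a `surface_mesh`.
#' @param levels number of subdivision rounds (>= 0).
#' @return the refined `surface_mesh`; element `operator` holds the
#'   sparse matrix mapping base vertices to refined vertices.
#' @export
loop_subdivide <- function(mesh, levels = 1) {
  if (levels < 0) stopf("levels must be >= 0")
  S_total <- Matrix::Diagonal(nrow(mesh$vertices))
  out <- mesh
  lv <- 0L
  while (lv < levels) {
    step <- loop_subdivide_once(out)
    out <- step$mesh
    S_total <- step$S %*% S_total
    lv <- lv + 1L
  }
  out$subdivision_level <- mesh$subdivision_level + as.integer(levels)
  out$operator <- S_total
  out
}

#' Extract the linear subdivision operator
#'
#' @param mesh a subdivided `surface_mesh` from [loop_subdivide()].
#' @return sparse matrix `S` with `refined_vertices = S %*% base_vertices`.
#' @export
subdivision_operator <- function(mesh) {
  if (is.null(mesh$operator)) Matrix::Diagonal(nrow(mesh$vertices))
  else mesh$operator
}

loop_subdivide_once <- function(mesh) {
  V <- nrow(mesh$vertices)
  faces <- mesh$faces
  et <- mesh_edges(faces)
  edges <- et$edges
  E <- nrow(edges)
  boundary_edge <- et$n_faces == 1L
  boundary_vertex <- rep(FALSE, V)
  boundary_vertex[unique(as.vector(edges[boundary_edge, , drop = FALSE]))] <- TRUE

  ii <- integer(); jj <- integer(); xx <- numeric()
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }

  # even (old) vertices keep indices 1..V
  adj <- vector("list", V)
  for (e in seq_len(E)) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (v in seq_len(V)) {
    nb <- adj[[v]]
    if (boundary_vertex[v]) {
      bnb <- nb[boundary_vertex[nb]]
      # neighbours along boundary edges only
      be <- edges[boundary_edge, , drop = FALSE]
      bnb <- unique(c(be[be[, 1] == v, 2], be[be[, 2] == v, 1]))
      if (length(bnb) == 2) {
        push(v, v, 3 / 4)
        push(c(v, v), bnb, c(1 / 8, 1 / 8))
      } else {  # boundary corner fallback: interpolate
        push(v, v, 1)
      }
    } else {
      k <- length(nb)
      beta <- (5 / 8 - (3 / 8 + cos(2 * pi / k) / 4)^2) / k
      push(v, v, 1 - k * beta)
      push(rep(v, k), nb, rep(beta, k))
    }
  }

  # odd (edge midpoint) vertices get indices V + e
  for (e in seq_len(E)) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (boundary_edge[e]) {
      push(rep(V + e, 2), c(a, b), c(1 / 2, 1 / 2))
    } else {
      push(rep(V + e, 4), c(a, b, et$opp1[e], et$opp2[e]),
           c(3 / 8, 3 / 8, 1 / 8, 1 / 8))
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(V + E, V))

  eidc <- et$eid_by_corner
  m12 <- V + eidc[, 1]; m23 <- V + eidc[, 2]; m31 <- V + eidc[, 3]
  new_faces <- rbind(
    cbind(faces[, 1], m12, m31),
    cbind(m12, faces[, 2], m23),
    cbind(m31, m23, faces[, 3]),
    cbind(m12, m23, m31))
  new_region <- rep(mesh$face_region, 4)

  row_rank <- c(annular = 1, basal = 2, mid = 3, lower = 4, apex = 5)
  vr <- mesh$vertex_row
  mid_row <- ifelse(row_rank[vr[edges[, 1]]] <= row_rank[vr[edges[, 2]]],
                    vr[edges[, 1]], vr[edges[, 2]])
  new_vr <- c(vr, mid_row)
  new_boundary <- c(boundary_vertex, boundary_edge)

  new_mesh <- structure(
    list(vertices = as.matrix(S %*% mesh$vertices), faces = new_faces,
         boundary = new_boundary, vertex_row = unname(new_vr),
         face_region = new_region,
         subdivision_level = mesh$subdivision_level + 1L,
         labels = mesh$labels),
    class = "surface_mesh")
  list(mesh = new_mesh, S = S)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces (subdivision level %d)\n",
              nrow(x$vertices), nrow(x$faces), x$subdivision_level))
  invisible(x)
}

# Euler characteristic V - E + F (disk topology gives 1).
euler_characteristic <- function(mesh) {
  et <- mesh_edges(mesh$faces)
  nrow(mesh$vertices) - nrow(et$edges) + nrow(mesh$faces)
}
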