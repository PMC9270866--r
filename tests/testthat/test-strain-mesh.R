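# Mesh construction, Loop subdivision, deformation gradients,
# Green-Lagrange strain, material directions, and strain pipelines.

cylinder_frame <- function(layout = default_layout, r = 30, h = 80) {
  labs <- layout_labels(layout)
  z <- c(rep(0, 6), rep(-0.25 * h, 5), rep(-0.5 * h, 4), rep(-0.75 * h, 4), -h)
  counts <- c(6, 5, 4, 4, 1)
  th <- unlist(lapply(counts, function(k) 2 * pi * (seq_len(k) - 1) / k))
  out <- cbind(r * cos(th), r * sin(th), z)
  out[20, ] <- c(0, 0, -h)  # apex on the axis
  rownames(out) <- labs
  out
}

test_that("base mesh is deterministic with disk topology", {
  frame <- cylinder_frame()
  m1 <- build_base_mesh(default_layout, frame)
  m2 <- build_base_mesh(default_layout, frame[sample(20), ])
  expect_identical(m1$faces, m2$faces)           # layout order, not row order
  expect_identical(m1$vertices, m2$vertices)
  expect_equal(nrow(m1$faces), 32)               # 11 + 9 + 8 strip + 4 fan
  expect_equal(rvkin:::euler_characteristic(m1), 1)
  expect_silent(rvkin:::check_orientation(m1$faces))
  expect_equal(sum(m1$boundary), 6)

  bad <- frame[-3, ]
  expect_error(build_base_mesh(default_layout, bad), "A3")
})

test_that("Loop subdivision has the right combinatorics", {
  mesh <- build_base_mesh(default_layout, cylinder_frame())
  for (lv in 1:3) {
    sub <- loop_subdivide(mesh, lv)
    expect_equal(nrow(sub$faces), nrow(mesh$faces) * 4^lv)
    expect_equal(rvkin:::euler_characteristic(sub), 1)
    expect_silent(rvkin:::check_orientation(sub$faces))
    # closed boundary loop doubles its vertex count each level
    expect_equal(sum(sub$boundary), 6 * 2^lv)
  }
})

test_that("subdivision is linear and planar-invariant", {
  frame <- cylinder_frame()
  mesh <- build_base_mesh(default_layout, frame)
  sub <- loop_subdivide(mesh, 2)
  S <- subdivision_operator(sub)
  # operator reproduces the subdivided vertices
  expect_equal(as.matrix(S %*% mesh$vertices), sub$vertices, tolerance = 1e-12)
  # affine equivariance: subdivide(A x + b) = A subdivide(x) + b
  A <- matrix(c(1.2, 0.1, 0, -0.3, 0.9, 0.2, 0, 0.1, 1.1), 3, 3)
  b <- c(4, -2, 7)
  moved <- sweep(frame %*% t(A), 2, b, `+`)
  sub2 <- loop_subdivide(build_base_mesh(default_layout, moved), 2)
  expect_identical(sub2$faces, sub$faces)        # connectivity-only operator
  expect_equal(sub2$vertices,
               sweep(sub$vertices %*% t(A), 2, b, `+`), tolerance = 1e-9)
  # planar input stays planar
  flatf <- frame; flatf[, 3] <- 2
  subflat <- loop_subdivide(build_base_mesh(default_layout, flatf), 2)
  expect_equal(subflat$vertices[, 3], rep(2, nrow(subflat$vertices)),
               tolerance = 1e-12)
})

test_that("non-manifold input is rejected", {
  mesh <- build_base_mesh(default_layout, cylinder_frame())
  mesh$faces <- rbind(mesh$faces, mesh$faces[1, ])   # edge now in 3 faces
  expect_error(loop_subdivide(mesh, 1), "non-manifold")
})

test_that("face deformation gradient matches constructed maps", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0.5, 1.5, 0))
  expect_equal(face_deformation_gradient(tri, tri), diag(2), tolerance = 1e-12)
  expect_equal(face_deformation_gradient(tri, 0.8 * tri), 0.8 * diag(2),
               tolerance = 1e-12)
  stretch <- tri %*% diag(c(1.3, 1, 1))
  F1 <- face_deformation_gradient(tri, stretch)
  expect_equal(F1, diag(c(1.3, 1)), tolerance = 1e-12)
  expect_error(face_deformation_gradient(tri, rbind(c(0, 0, 0), c(1, 0, 0),
                                                    c(2, 0, 0))), "degenerate")
})

test_that("Green-Lagrange strain, directional and areal measures", {
  expect_equal(green_lagrange(diag(2)), matrix(0, 2, 2))
  E <- green_lagrange(diag(c(1.1, 1)))
  expect_equal(E[1, 1], 0.105, tolerance = 1e-12)
  expect_equal(E[2, 2], 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(green_lagrange(R), matrix(0, 2, 2), tolerance = 1e-12)

  Eu <- green_lagrange(diag(c(0.92, 1)))
  expect_equal(directional_strain(Eu, c(1, 0)), (0.92^2 - 1) / 2,
               tolerance = 1e-12)
  expect_equal(directional_strain(Eu, c(0, 1)), 0)
  expect_error(directional_strain(Eu, c(0, 0)), "non-zero")

  expect_equal(areal_strain(0.9 * diag(2)), -0.19, tolerance = 1e-12)
  expect_equal(areal_strain(diag(2)), 0)
  expect_equal(areal_strain(diag(c(1.2, 0.8))), -0.04, tolerance = 1e-12)
  expect_error(areal_strain(diag(c(-1, 1))), "inverted")
})

test_that("material directions are orthonormal and anatomically aligned", {
  # base mesh of an exact cylinder: side-face normals are radial
  mesh <- build_base_mesh(default_layout, cylinder_frame())
  dirs <- material_directions(mesh, default_layout)
  nf <- nrow(mesh$faces)
  expect_equal(row_norms_t(dirs$circ), rep(1, nf), tolerance = 1e-9)
  expect_equal(row_norms_t(dirs$long), rep(1, nf), tolerance = 1e-9)
  expect_equal(rowSums(dirs$circ * dirs$long), rep(0, nf), tolerance = 1e-9)
  # longitudinal along the axis, circumferential along the hoop
  # rows with unequal vertex counts facet the cylinder, tilting face
  # planes slightly off-axis; alignment is near-exact, not exact
  side <- !(mesh$face_region %in% "apex")
  expect_true(all(abs(dirs$long[side, 3]) > 0.9))
  expect_true(all(abs(dirs$circ[side, 3]) < 0.4))
  expect_gt(mean(abs(dirs$long[side, 3])), 0.97)
  # orthonormality also holds after subdivision (curved faces)
  sub <- loop_subdivide(mesh, 1)
  sub$base_vertices <- mesh$vertices
  dsub <- material_directions(sub, default_layout)
  expect_equal(row_norms_t(dsub$circ), rep(1, nrow(sub$faces)), tolerance = 1e-9)
  expect_equal(rowSums(dsub$circ * dsub$long), rep(0, nrow(sub$faces)),
               tolerance = 1e-9)
})

test_that("cardiac strain is zero at its own reference and exact for affine maps", {
  ph <- generate_phantom(quick_config(seed = 23))
  cyc <- segment_cycles(ph$baseline)
  beat <- average_beats(ph$baseline, cyc)
  tc <- cardiac_strain_timecourse(beat, default_layout, levels = 2)
  expect_lt(max(abs(tc$E_cc[1, ]), abs(tc$E_ll[1, ]), abs(tc$areal[1, ])), 1e-9)
  es <- which.min(abs(tc$grid - tc$es_phase))
  truth <- analytic_truth(ph$truth, tc$mesh, tc$directions, tc$es_phase / 100)
  for (r in c("basal", "mid")) {
    expect_lt(abs(tc$regional[es, r, "E_cc"] -
                    region_mean(truth$E_cc, truth$region, tc$ref_area, r)), 0.01)
    expect_lt(abs(tc$regional[es, r, "E_ll"] -
                    region_mean(truth$E_ll, truth$region, tc$ref_area, r)), 0.01)
    expect_lt(abs(tc$regional[es, r, "areal"] -
                    region_mean(truth$areal, truth$region, tc$ref_area, r)), 0.01)
  }
})

test_that("regional strain means converge under subdivision refinement", {
  ph <- generate_phantom(quick_config(seed = 29))
  cyc <- segment_cycles(ph$baseline)
  beat <- average_beats(ph$baseline, cyc)
  tc2 <- cardiac_strain_timecourse(beat, default_layout, levels = 2)
  tc3 <- cardiac_strain_timecourse(beat, default_layout, levels = 3)
  es2 <- which.min(abs(tc2$grid - tc2$es_phase))
  es3 <- which.min(abs(tc3$grid - tc3$es_phase))
  for (r in c("basal", "mid"))
    for (cp in c("E_cc", "E_ll", "areal"))
      expect_lt(abs(tc2$regional[es2, r, cp] - tc3$regional[es3, r, cp]), 0.005)
})

test_that("interventional strain null, affine recovery and inverse identity", {
  ph0 <- generate_phantom(quick_config(seed = 31, tra_ring_scale = 1))
  cyc <- segment_cycles(ph0$baseline)
  beat <- average_beats(ph0$baseline, cyc)
  null_field <- interventional_strain(beat, beat, default_layout, "ED")
  expect_lt(max(abs(null_field$E_cc), abs(null_field$E_ll),
                abs(null_field$areal)), 1e-12)

  M <- diag(c(0.95, 0.95, 0.97))
  ph <- generate_phantom(quick_config(seed = 31, tra_ring_scale = 1,
                                      tra_wall_affine = M))
  bb <- average_beats(ph$baseline, segment_cycles(ph$baseline))
  bt <- average_beats(ph$tra, segment_cycles(ph$tra))
  for (tp in c("ED", "ES")) {
    field <- interventional_strain(bb, bt, default_layout, tp)
    # reference geometry/directions of this field for the analytic value
    truth_interv <- list(A_at = function(phase) M)
    ref_mesh <- loop_subdivide(build_base_mesh(
      default_layout, rvkin:::beat_frame(bb, layout_labels(default_layout),
                                         rvkin:::beat_grid_index(bb, tp))), 2)
    ref_mesh$base_vertices <- rvkin:::beat_frame(
      bb, layout_labels(default_layout), rvkin:::beat_grid_index(bb, tp))
    dirs <- material_directions(ref_mesh, default_layout)
    tr <- analytic_truth(truth_interv, ref_mesh, dirs, 0)
    expect_lt(max(abs(field$E_cc - tr$E_cc)), 0.01)
    expect_lt(max(abs(field$areal - tr$areal)), 0.01)
  }
  # swapped arguments give the inverse deformation per face
  f12 <- interventional_strain(bb, bt, default_layout, "ED")
  f21 <- interventional_strain(bt, bb, default_layout, "ED")
  expect_equal((1 + f12$areal) * (1 + f21$areal),
               rep(1, nrow(f12)), tolerance = 1e-9)
})

test_that("regional aggregation weights behave", {
  ph <- generate_phantom(quick_config(seed = 37, tra_ring_scale = 1))
  beat <- average_beats(ph$baseline, segment_cycles(ph$baseline))
  field <- interventional_strain(beat, beat, default_layout, "ED")
  field$E_cc <- rep(0.07, nrow(field))            # uniform field
  agg_a <- regional_aggregate(field, "area")
  agg_u <- regional_aggregate(field, "unweighted")
  ecc_a <- agg_a[agg_a$component == "E_cc", ]
  ecc_u <- agg_u[agg_u$component == "E_cc", ]
  expect_equal(ecc_a$mean, rep(0.07, nrow(ecc_a)), tolerance = 1e-12)
  expect_equal(ecc_u$mean, rep(0.07, nrow(ecc_u)), tolerance = 1e-12)
  expect_equal(ecc_a$sd, rep(0, nrow(ecc_a)), tolerance = 1e-9)
  # two equal-area faces, values 0 and 0.2 -> mean 0.1
  toy <- field[1:2, ]
  toy$ref_area <- c(3, 3); toy$E_cc <- c(0, 0.2); toy$region <- "basal"
  agg <- regional_aggregate(toy)
  expect_equal(agg$mean[agg$component == "E_cc"], 0.1, tolerance = 1e-12)
})
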