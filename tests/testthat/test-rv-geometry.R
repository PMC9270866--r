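# Planes, polygon areas, hull volume, circle fits, and their
# invariances under rigid motion and scaling.

regular_polygon <- function(n, r, z = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), z)
}

test_that("plane fit recovers constructed planes", {
  set.seed(1)
  pts <- cbind(stats::rnorm(6), stats::rnorm(6), 5)
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$centroid[3], 5, tolerance = 1e-9)

  x <- stats::rnorm(8); y <- stats::rnorm(8)
  pl2 <- fit_plane(cbind(x, y, x))  # z = x
  expect_equal(abs(pl2$normal), c(1, 0, 1) / sqrt(2), tolerance = 1e-9)

  line <- cbind(1:3, 2 * (1:3), 3 * (1:3))
  expect_error(fit_plane(line), "degenerate")
})

test_that("projected polygon area matches closed forms", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 5)
  expect_equal(as.numeric(polygon_area_3d(square)), 1.0, tolerance = 1e-12)

  hex <- regular_polygon(6, 10)
  expect_equal(as.numeric(polygon_area_3d(hex)), 3 * sqrt(3) / 2 * 100,
               tolerance = 1e-9)
  hex_annulus <- regular_polygon(6, 19.58)
  expect_equal(as.numeric(polygon_area_3d(hex_annulus)), 996,
               tolerance = 0.005)
  expect_error(polygon_area_3d(square[1:2, ]), ">= 3")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1), 0)
  expect_true(attr(polygon_area_3d(bowtie), "self_intersecting"))
  expect_false(attr(polygon_area_3d(hex), "self_intersecting"))
})

test_that("percent annular reduction is the stated ratio", {
  expect_equal(percent_area_reduction(996, 516), 48.19, tolerance = 0.005)
  expect_equal(percent_area_reduction(123.4, 123.4), 0)
  expect_equal(percent_area_reduction(100, 53), 47.0)
  expect_error(percent_area_reduction(-1, 5), "positive")
})

test_that("convex hull volume is exact on solids with known volume", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  expect_equal(convex_hull_volume(cube), 1.000, tolerance = 1e-12)
  # regular tetrahedron, edge a: V = a^3 / (6 sqrt(2))
  a <- 10
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (a / (2 * sqrt(2)))
  expect_equal(convex_hull_volume(tetra), a^3 / (6 * sqrt(2)) / 1000,
               tolerance = 1e-12)
  # interior points must not change the hull
  cube_plus <- rbind(cube, c(5, 5, 5), c(2, 3, 4))
  expect_equal(convex_hull_volume(cube_plus), 1.000, tolerance = 1e-12)
  expect_error(convex_hull_volume(cube[1:3, ]), ">= 4")
  flat <- cbind(stats::rnorm(10), stats::rnorm(10), 0)
  expect_error(convex_hull_volume(flat), "coplanar")
})

test_that("hull volume grows monotonically as points are added", {
  set.seed(7)
  pts <- matrix(stats::rnorm(3 * 6, sd = 15), ncol = 3)
  vol <- convex_hull_volume(pts)
  for (k in 1:10) {
    pts <- rbind(pts, stats::rnorm(3, sd = 15))
    vol_new <- convex_hull_volume(pts)
    expect_gte(vol_new, vol - 1e-12)
    vol <- vol_new
  }
})

test_that("phantom crystal hull is bounded by the half-ellipsoid volume", {
  ph <- generate_phantom(quick_config(seed = 2))
  cyc <- segment_cycles(ph$baseline)
  beat <- average_beats(ph$baseline, cyc)
  frame <- do.call(rbind, lapply(beat$crystals, function(m) m[1, ]))
  vol <- convex_hull_volume(frame)
  expect_lt(vol, ph$truth$hull_bound_ml)
  expect_gt(vol, 0.4 * ph$truth$hull_bound_ml)  # sparse polygons lose the rest
})

test_that("row cross-sectional area approximates known sections", {
  # 5 points on a semicircle, chord-closed: the inscribed polygon has
  # exact area r^2/2 * sum(sin(dtheta)) = 2 sqrt(2) r^2 / ... here
  # 4 * sin(pi/4) / 2 * r^2, a 10 % deficit against pi r^2 / 2.
  r <- 30
  th <- seq(0, pi, length.out = 5)
  semi <- cbind(r * cos(th), r * sin(th), 2)
  a <- as.numeric(polygon_area_3d(semi))
  expect_equal(a, r^2 / 2 * 4 * sin(pi / 4), tolerance = 1e-9)
  expect_lt(abs(a - pi * r^2 / 2) / (pi * r^2 / 2), 0.11)

  collinear <- cbind(1:3, 1:3, 0)
  expect_equal(as.numeric(polygon_area_3d(collinear)), 0)
})

test_that("circle fit is exact on noise-free circles and robust to noise", {
  circ <- regular_polygon(5, 51.4, z = 3)
  expect_equal(fit_circle_radius(circ), 51.4, tolerance = 1e-6)
  # arcs, not only full circles
  th <- seq(0.3, 2.1, length.out = 7)
  arc <- cbind(12 * cos(th) + 4, 12 * sin(th) - 2, 1)
  expect_equal(fit_circle_radius(arc), 12, tolerance = 1e-6)
  # n = 3: circumscribed circle, R = abc / (4K)
  tri <- rbind(c(0, 0, 0), c(4, 0, 0), c(1, 3, 0))
  ab <- 4; bc <- sqrt(9 + 9); ca <- sqrt(1 + 9)
  K <- 0.5 * 4 * 3
  expect_equal(fit_circle_radius(tri), ab * bc * ca / (4 * K),
               tolerance = 1e-6)
  expect_error(fit_circle_radius(cbind(1:4, 1:4, 0)), "degenerate")

  set.seed(31)
  r0 <- 40
  for (draw in 1:200) {
    th <- sort(stats::runif(10, 0, 2 * pi))
    noisy <- cbind(r0 * cos(th), r0 * sin(th), 0) +
      matrix(stats::rnorm(30, sd = 0.1), ncol = 3)
    expect_lt(abs(fit_circle_radius(noisy) - r0), 0.3)
  }
})

test_that("geometry outputs are rigid-motion invariant and scale covariantly", {
  set.seed(13)
  ph <- generate_phantom(quick_config(seed = 13))
  cyc <- segment_cycles(ph$baseline)
  beat <- average_beats(ph$baseline, cyc)
  lay <- default_layout
  base <- list(taa = annular_area(beat, lay, "ED"),
               csa = as.numeric(cross_sectional_area(beat, lay, "basal", "ED")),
               roc = radius_of_curvature(beat, lay, "mid", "ED"),
               vol = convex_hull_volume(beat_frame_all(beat, lay)))
  for (k in 1:3) {
    rm <- random_rigid()
    rec2 <- transform_recording(ph$baseline, rm)
    beat2 <- average_beats(rec2, cyc)
    expect_equal(annular_area(beat2, lay, "ED"), base$taa, tolerance = 1e-9)
    expect_equal(as.numeric(cross_sectional_area(beat2, lay, "basal", "ED")),
                 base$csa, tolerance = 1e-9)
    expect_equal(radius_of_curvature(beat2, lay, "mid", "ED"), base$roc,
                 tolerance = 1e-9)
    expect_equal(convex_hull_volume(beat_frame_all(beat2, lay)), base$vol,
                 tolerance = 1e-9)
  }
  s <- 1.7
  rec_s <- ph$baseline
  rec_s$crystals <- lapply(rec_s$crystals, function(m) s * m)
  beat_s <- average_beats(rec_s, cyc)
  expect_equal(annular_area(beat_s, lay, "ED"), s^2 * base$taa,
               tolerance = 1e-9)
  expect_equal(convex_hull_volume(beat_frame_all(beat_s, lay)),
               s^3 * base$vol, tolerance = 1e-9)
  expect_equal(radius_of_curvature(beat_s, lay, "mid", "ED"), s * base$roc,
               tolerance = 1e-9)
})

test_that("geometry summary of identical states has zero deltas", {
  ph <- generate_phantom(quick_config(seed = 17, tra_ring_scale = 1))
  cyc <- segment_cycles(ph$baseline)
  beat <- average_beats(ph$baseline, cyc)
  gs <- geometry_summary(beat, beat, default_layout)
  expect_true(all(gs$delta == 0))
  expect_equal(attr(gs, "taa_reduction_pct"), 0)
})
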