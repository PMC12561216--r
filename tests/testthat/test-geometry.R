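test_that("opening degree and center distance convert exactly both ways", {
  expect_equal(delta_L_from_od(0, 15), 0)
  expect_equal(delta_L_from_od(50, 15), 7.5)
  expect_equal(delta_L_from_od(30, 15), 4.5)
  for (od in c(0, 1, 12.5, 33.3, 50, 77, 100)) {
    for (R in c(0.5, 1, 13, 15)) {
      expect_equal(od_from_delta_L(delta_L_from_od(od, R), R), od,
                   tolerance = 1e-14)
    }
  }
  expect_error(delta_L_from_od(-1, 15))
  expect_error(delta_L_from_od(10, -2))
})

test_that("commissure span is the inscribed-triangle chord", {
  # chord-length oracle: distance between two vertices of the equilateral
  # triangle inscribed in the circle of radius R
  chord <- function(R) {
    p1 <- R * c(cos(pi / 2), sin(pi / 2))
    p2 <- R * c(cos(pi / 2 + 2 * pi / 3), sin(pi / 2 + 2 * pi / 3))
    sqrt(sum((p1 - p2)^2))
  }
  expect_equal(commissure_span(15), chord(15), tolerance = 1e-12)
  expect_equal(commissure_span(15), 25.98076, tolerance = 1e-5)
  expect_equal(commissure_span(1), sqrt(3))
  expect_equal(commissure_span(0.5 * 15), 0.5 * commissure_span(15))
  expect_error(commissure_span(0))
})

test_that("default commissure height is 10% of the valve diameter", {
  expect_equal(commissure_height_default(30), 3)
  expect_equal(commissure_height_default(0), 0)
  expect_equal(commissure_height_default(26), 2.6)
})

test_that("free-edge profiles follow the parabolic formulas", {
  s <- commissure_span(15)
  pc <- free_edge_profile("concave", h = 3, s = s, n_samples = 33)
  expect_equal(pc$y[(nrow(pc) + 1) / 2], 3)         # apex at x = 0
  expect_equal(pc$y[1], 0)                          # endpoints at 0
  expect_equal(pc$y[nrow(pc)], 0)
  pv <- free_edge_profile("convex", h = 3, s = s, n_samples = 33)
  expect_equal(pv$y[nrow(pv)], 0)
  expect_equal(pv$y[(nrow(pv) + 1) / 2], -3)
  pl <- free_edge_profile("linear", h = 3, s = s)
  expect_true(all(pl$y == 0))
  # mirror identity, pointwise
  expect_equal(pc$y, -pv$y, tolerance = 1e-14)
  # symmetry about x = 0
  expect_equal(pc$y, rev(pc$y), tolerance = 1e-12)
  expect_error(free_edge_profile("concave", 3, s, n_samples = 10))  # even
  expect_error(free_edge_profile("concave", 3, -1))
})

test_that("the packaged designs reproduce the reference (OD, shape) matrix", {
  ds <- valve_designs()
  expect_named(ds, paste0("G", 0:6))
  od <- vapply(ds, `[[`, numeric(1), "opening_degree")
  sh <- vapply(ds, `[[`, character(1), "free_edge_shape")
  expect_equal(unname(od), c(0, 20, 20, 25, 25, 30, 50))
  expect_equal(unname(sh), c("linear", "convex", "concave", "linear",
                             "concave", "linear", "linear"))
  expect_true(all(vapply(ds, `[[`, numeric(1), "radius") == 15))
  expect_equal(ds$G0$commissure_height, 3)
  # linear free edge cannot retract beyond the inscribed triangle
  expect_error(valve_design("bad", 15, 60, "linear"))
})

test_that("leaflet surfaces realize the design boundary curves", {
  g0 <- valve_designs()$G0
  m0 <- build_leaflet_surface(g0, n_circ = 16, n_rad = 8)
  fe <- m0$vertices[m0$free_edge, ]
  # closed design: free edge endpoints on the cylinder, midpoint at axis
  expect_equal(sqrt(sum(fe[1, 1:2]^2)), 15, tolerance = 1e-9)
  mid <- fe[(nrow(fe) + 1) / 2, ]
  expect_equal(sqrt(sum(mid[1:2]^2)), 0, tolerance = 1e-9)
  # attachment edge lies on the cylinder of radius R
  att <- m0$vertices[m0$attachment, ]
  expect_equal(sqrt(att[, 1]^2 + att[, 2]^2), rep(15, nrow(att)),
               tolerance = 1e-9)
  # semi-closed: minimal free-edge distance to the axis equals delta_L
  g6 <- valve_designs()$G6
  m6 <- build_leaflet_surface(g6, n_circ = 16, n_rad = 8)
  fe6 <- m6$vertices[m6$free_edge, ]
  expect_equal(min(sqrt(fe6[, 1]^2 + fe6[, 2]^2)), 7.5, tolerance = 1e-9)
  # homothety: scale 0.5 scales every vertex coordinate exactly
  m6h <- build_leaflet_surface(g6, n_circ = 16, n_rad = 8, scale = 0.5)
  expect_equal(m6h$vertices, 0.5 * m6$vertices, tolerance = 1e-12)
  expect_error(build_leaflet_surface(g6, n_circ = 2, n_rad = 8))
})

test_that("assembled valves have congruent leaflets related by 120-degree rotation", {
  vm <- assemble_valve(valve_designs()$G5, n_circ = 12, n_rad = 6)
  v1 <- vm$vertices[vm$leaflet_id == 1, ]
  v2 <- vm$vertices[vm$leaflet_id == 2, ]
  v3 <- vm$vertices[vm$leaflet_id == 3, ]
  rot <- function(V, a) cbind(V[, 1] * cos(a) - V[, 2] * sin(a),
                              V[, 1] * sin(a) + V[, 2] * cos(a), V[, 3])
  expect_equal(v2, rot(v1, 2 * pi / 3), tolerance = 1e-9)
  expect_equal(v3, rot(v1, -2 * pi / 3), tolerance = 1e-9)
  # single-leaflet passthrough
  d1 <- valve_design("solo", 15, 25, "linear", n_leaflets = 1L)
  vm1 <- assemble_valve(d1, n_circ = 8, n_rad = 4)
  expect_length(vm1$free_edges, 1L)
})

test_that("ideal free-edge length matches polyline integration and scales linearly", {
  for (lab in c("G0", "G3", "G6")) {
    d <- valve_designs()[[lab]]
    m <- build_leaflet_surface(d, n_circ = 64, n_rad = 4)
    # brute-force polyline integration of the undeformed top-view free edge
    fe <- m$vertices[m$free_edge, 1:2]
    expect_equal(ideal_free_edge_length(d, d$radius), polyline_length(fe),
                 tolerance = 1e-6)
    # linear scaling with the deployed radius
    expect_equal(ideal_free_edge_length(d, d$radius / 2),
                 ideal_free_edge_length(d, d$radius) / 2)
  }
  # closed design: commissure -> center -> commissure = 2 R in top view
  expect_equal(ideal_free_edge_length(valve_designs()$G0, 15), 30)
  # OD 50: the inscribed-triangle chord
  expect_equal(ideal_free_edge_length(valve_designs()$G6, 15), sqrt(3) * 15)
  expect_error(ideal_free_edge_length(valve_designs()$G0, 16))
})

test_that("mesh export and import round-trip through STL, OBJ and VTK", {
  vm <- assemble_valve(valve_designs()$G5, n_circ = 8, n_rad = 4)
  for (fmt in c("stl", "obj", "vtk")) {
    f <- tempfile(fileext = paste0(".", fmt))
    export_mesh(vm, f)
    back <- import_mesh(f)
    expect_equal(nrow(back$triangles), nrow(vm$triangles))
    if (fmt == "stl") {
      # triangle soup: compare per-facet vertex coordinates
      orig <- vm$vertices[t(vm$triangles), ]
      got <- back$vertices[t(back$triangles), ]
      expect_equal(got, unname(orig), tolerance = 1e-6,
                   ignore_attr = TRUE)
    } else {
      expect_equal(unname(back$vertices), unname(vm$vertices),
                   tolerance = 1e-6, ignore_attr = TRUE)
      expect_equal(unname(back$triangles), unname(vm$triangles),
                   ignore_attr = TRUE)
    }
    unlink(f)
  }
  expect_error(export_mesh(list(vertices = matrix(0, 0, 3)), "x.stl"))
})
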