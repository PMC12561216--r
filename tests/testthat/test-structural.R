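test_that("radial crimp prescribes scaled radii with unchanged angle and height", {
  vm <- assemble_valve(valve_designs()$G0, n_circ = 8, n_rad = 4)
  bc0 <- radial_crimp_displacement(vm, 0)
  expect_equal(bc0$target, unname(vm$vertices[vm$attachment, ]),
               ignore_attr = TRUE)
  bc10 <- radial_crimp_displacement(vm, 10)
  r <- sqrt(rowSums(bc10$target[, 1:2]^2))
  expect_equal(max(r), 13.5, tolerance = 1e-9)
  expect_equal(bc10$target[, 3], vm$vertices[vm$attachment, 3])
  th0 <- atan2(vm$vertices[vm$attachment, 2], vm$vertices[vm$attachment, 1])
  th1 <- atan2(bc10$target[, 2], bc10$target[, 1])
  expect_equal(th0, th1, tolerance = 1e-12)
  # deploying a 30 mm valve into a 26 mm annulus
  bc26 <- radial_crimp_displacement(vm, 13.33)
  expect_equal(2 * max(sqrt(rowSums(bc26$target[, 1:2]^2))), 26.001,
               tolerance = 1e-3)
  expect_error(radial_crimp_displacement(vm, 100))
})

test_that("the unloaded valve is in equilibrium with zero displacement", {
  vm <- assemble_valve(valve_designs()$G0, n_circ = 10, n_rad = 6)
  lc <- crimp_loadcase(0, pressure_mmHg = 0, perturbation = 0)
  st <- solve_static(vm, pericardium_material(), lc)
  expect_true(st$converged)
  expect_lt(max(abs(st$vertices - vm$vertices)), 1e-10)
})

test_that("a pressurized circular membrane matches the axisymmetric closed form", {
  a <- 10; t_sh <- 0.2; E <- 1; nu <- 0.3; p <- 0.0005
  dm <- disc_mesh(a, n_rings = 10L)
  rim <- dm$rim
  out <- leafletlab:::.dr_relax(
    dm$vertices, dm$vertices, dm$triangles,
    rep(1L, nrow(dm$triangles)), rep(1L, nrow(dm$vertices)),
    rim - 1L, dm$vertices[rim, ],
    p, t_sh, nu, 1.0, E,          # single-segment curve: linear material
    FALSE, 0.1, 0, 25L, 0.3,
    60000L, 1e-5, 25L, 4.0, 1.0, 0, 1L, 0)
  expect_true(out$converged)
  w0 <- max(abs(out$X[, 3]))
  w_ref <- hencky_center_deflection(a, p, E, nu, t_sh)
  expect_equal(w0, w_ref, tolerance = 0.05)
})

test_that("the deformed free edge is extracted in design order", {
  vm <- assemble_valve(valve_designs()$G3, n_circ = 10, n_rad = 6)
  lc <- crimp_loadcase(0, pressure_mmHg = 0, perturbation = 0)
  st <- solve_static(vm, pericardium_material(), lc)
  for (i in 1:3) {
    expect_equal(extract_free_edge(st, i),
                 vm$vertices[vm$free_edges[[i]], ])
  }
  # after the full load case the free-edge arc length changes only within
  # the membrane strain scale (no spurious elongation)
  st1 <- cached_solve("G0", oversizing = 10)
  vm0 <- st1$mesh
  l0 <- polyline_length(vm0$vertices[vm0$free_edges[[1]], ])
  l1 <- polyline_length(extract_free_edge(st1, 1))
  expect_lt(abs(l1 / l0 - 1), 0.10)
})

test_that("closure metrics distinguish closed and semi-closed designs", {
  vm0 <- assemble_valve(valve_designs()$G0, n_circ = 16, n_rad = 10)
  cm0 <- coaptation_metrics(vm0)
  expect_true(cm0$closed)
  vm6 <- assemble_valve(valve_designs()$G6, n_circ = 16, n_rad = 10)
  cm6 <- coaptation_metrics(vm6)
  expect_false(cm6$closed)
  # polygon-area oracle: the undeformed central orifice of the OD-50 design
  # is the equilateral triangle with inradius delta_L = 7.5 mm
  expect_equal(cm6$orifice_area, 3 * sqrt(3) * 7.5^2, tolerance = 0.03)
})

test_that("the crimped pressurized valve satisfies solver invariants", {
  st <- cached_solve("G6", oversizing = 10)
  expect_true(st$converged)
  # quasi-static: kinetic energy at the reported equilibrium is negligible
  # against the peak transient
  expect_lt(st$ke_last, 1e-6 * st$ke_peak)
  # contact: no free vertex from one leaflet penetrates another leaflet
  # deeper than a quarter of the shell thickness
  mesh <- st$mesh
  thick <- st$material$thickness_mm * mesh$scale
  consider <- rep(TRUE, nrow(mesh$vertices))
  consider[mesh$attachment] <- FALSE
  dmin <- leafletlab:::.min_cross_leaflet_distance(
    st$vertices, mesh$triangles, mesh$triangle_leaflet, mesh$leaflet_id,
    consider)
  expect_gt(dmin, thick - 0.25 * thick)
  # symmetry: per-leaflet PI values agree within 2 percentage points
  pr <- pi_from_state(st)
  expect_lt(max(pr$per_leaflet$pi) - min(pr$per_leaflet$pi), 2)
  # the semi-closed valve mostly closes under crimp + pressure: the orifice
  # shrinks by more than an order of magnitude from the unloaded state
  cm <- coaptation_metrics(st)
  cm_unloaded <- coaptation_metrics(
    assemble_valve(valve_designs()$G6, n_circ = 16, n_rad = 10, scale = 0.5))
  expect_lt(cm$orifice_fraction, cm_unloaded$orifice_fraction / 5)
})

test_that("solve_static fails loudly on unconverged or invalid states", {
  vm <- assemble_valve(valve_designs()$G6, n_circ = 8, n_rad = 4)
  lc <- crimp_loadcase(10, pressure_mmHg = 20, max_iter = 10L,
                       n_incr_crimp = 1L, n_incr_pressure = 1L)
  st <- solve_static(vm, pericardium_material(), lc)
  expect_false(st$converged)
  expect_error(pi_from_state(st), "converge")
  expect_error(coaptation_metrics(st), "converge")
})

test_that("free-edge polylines export to the documented CSV layout", {
  st <- cached_solve("G6", oversizing = 10)
  f <- tempfile(fileext = ".csv")
  write_free_edges_csv(st, f)
  df <- read.csv(f)
  expect_named(df, c("leaflet", "vertex_index", "x_mm", "y_mm", "z_mm"))
  expect_equal(sort(unique(df$leaflet)), 1:3)
  expect_equal(min(df$vertex_index), 0L)
  p1 <- as.matrix(df[df$leaflet == 1, c("x_mm", "y_mm", "z_mm")])
  expect_equal(unname(p1), unname(extract_free_edge(st, 1)),
               tolerance = 1e-12)
  unlink(f)
})

test_that("material models validate their physical ranges", {
  expect_error(material_model(c(0.1, 0.05), c(1, 2)))     # non-increasing
  expect_error(material_model(0.1, -1))                   # negative stress
  expect_error(material_model(0.1, 1, poisson_ratio = 0.5))
  expect_error(material_model(0.1, 1, thickness_um = 0))
  m <- pericardium_material()
  expect_equal(m$thickness_mm, 0.2)
  expect_equal(m$poisson_ratio, 0.49)
  expect_equal(m$density, 1410)
  expect_error(crimp_loadcase(-1))
  expect_error(crimp_loadcase(10, pressure_mmHg = -5))
})
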