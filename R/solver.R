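MMHG_TO_MPA <- 133.322e-6

#' Radial crimp boundary conditions
#'
#' Prescribed displacements emulating stent crimping/deployment into a
#' smaller annulus: every attachment-edge vertex at cylindrical radius r
#' is moved to radius `r * (1 - oversizing/100)`; its angular and axial
#' coordinates are unchanged. Interior and free-edge vertices are
#' unconstrained.
#'
#' @param mesh A [assemble_valve()] mesh.
#' @param oversizing Diameter reduction in percent, `[0, 100)`.
#' @return List with `index` (attachment vertex indices) and `target`
#'   (matrix of prescribed positions, mm).
#' @export
#' @examples
#' vm <- assemble_valve(valve_designs()$G0, n_circ = 8, n_rad = 4)
#' bc <- radial_crimp_displacement(vm, 10)
#' max(sqrt(rowSums(bc$target[, 1:2]^2)))  # 13.5 for R = 15
radial_crimp_displacement <- function(mesh, oversizing) {
  stopifnot(inherits(mesh, "valve_mesh"))
  if (oversizing < 0 || oversizing >= 100)
    stop("`oversizing` must be in [0, 100) percent")
  idx <- mesh$attachment
  V <- mesh$vertices[idx, , drop = FALSE]
  f <- 1 - oversizing / 100
  target <- cbind(V[, 1] * f, V[, 2] * f, V[, 3])
  list(index = idx, target = target)
}

#' Quasi-static membrane solve: crimp then pressurize
#'
#' Finds the equilibrium of the trileaflet membrane under the load case:
#' the radial crimp is applied in increments with the structure relaxed
#' to equilibrium after each, a small seeded symmetry-breaking
#' perturbation is applied to the free-edge vertices, and the diastolic
#' pressure is then ramped in increments on the downstream (arterial)
#' face as a follower load. Equilibrium is found by dynamic relaxation
#' (explicit pseudo-time stepping with kinetic damping) of
#' constant-strain-triangle membrane elements with the tabulated
#' nonlinear isotropic response and no bending stiffness; node-to-triangle
#' penalty contact acts between distinct leaflets.
#'
#' @param mesh A [assemble_valve()] mesh built at
#'   `scale = loadcase$scale_factor`.
#' @param material A [material_model()].
#' @param loadcase A [crimp_loadcase()].
#' @param verbose Print per-increment progress.
#' @return A `deformed_valve_state`: list with `vertices` (displaced,
#'   mm), `mesh`, `material`, `loadcase`, `converged`,
#'   `residual_history`, `ke_peak`, `ke_last`, `n_contact_pairs`, `seed`.
#'   On non-convergence the state is returned with
#'   `converged = FALSE` and the residual history intact.
#' @export
solve_static <- function(mesh, material, loadcase, verbose = FALSE) {
  stopifnot(inherits(mesh, "valve_mesh"), inherits(material, "material_model"),
            inherits(loadcase, "crimp_loadcase"))
  if (abs(mesh$scale - loadcase$scale_factor) > 1e-12)
    warning("mesh scale (", mesh$scale, ") differs from loadcase scale_factor (",
            loadcase$scale_factor, "); the mesh scale is used")
  sc <- mesh$scale
  thick <- material$thickness_mm * sc   # proportional downscale incl. thickness
  V0 <- mesh$vertices
  X <- V0
  Tr <- mesh$triangles
  bc <- radial_crimp_displacement(mesh, loadcase$oversizing)
  e1_mod <- material$curve_stress[1] / material$curve_strain[1]
  k_pen <- loadcase$contact_penalty_scale * e1_mod * thick
  k_bend <- loadcase$bending_scale * e1_mod * thick^3 /
    (12 * (1 - material$poisson_ratio^2))
  gap <- thick
  search_margin <- 3 * thick
  res_hist <- list()
  conv_all <- TRUE

  relax <- function(X, fixed_pos, pressure_mpa, contact_on, max_iter,
                    viscous_eta = 0, rebuild_every = 25L) {
    .dr_relax(X, V0, Tr, mesh$triangle_leaflet, mesh$leaflet_id,
              bc$index - 1L, fixed_pos,
              pressure_mpa, thick, material$poisson_ratio,
              material$curve_strain, material$curve_stress,
              contact_on, gap, k_pen, as.integer(rebuild_every),
              search_margin,
              as.integer(max_iter), loadcase$tol, 25L, 4.0,
              loadcase$compression_retention, k_bend,
              switch(loadcase$pressure_mode, follower = 0L, axial = 1L,
                     shielded = 2L), viscous_eta)
  }

  V_att0 <- V0[bc$index, , drop = FALSE]
  # stage 1: crimp ramp
  n1 <- loadcase$n_incr_crimp
  out <- NULL
  for (k in seq_len(max(n1, 1L))) {
    f <- if (loadcase$oversizing == 0) 0 else k / n1
    tgt <- V_att0 + f * (bc$target - V_att0)
    out <- relax(X, tgt, 0, TRUE, loadcase$max_iter)
    X <- out$X
    res_hist[[length(res_hist) + 1L]] <- out$residual_history
    if (verbose)
      message(sprintf("crimp %d/%d: %d iters, residual %.2e, converged %s",
                      k, n1, out$iterations, out$residual_ratio,
                      out$converged))
    if (loadcase$oversizing == 0) break
  }

  # symmetry-breaking perturbation of the free-edge vertices before
  # pressurization: a seeded coherent tangential component (the wheeled
  # equilibrium is rotationally bistable; the seed picks the branch) plus
  # random noise, both at `perturbation` x radius amplitude
  fe_idx <- setdiff(unlist(mesh$free_edges), bc$index)
  if (loadcase$perturbation > 0 && length(fe_idx)) {
    set.seed(loadcase$seed)
    amp <- loadcase$perturbation * mesh$design$radius * sc
    twist <- sample(c(-1, 1), 1)
    th <- atan2(X[fe_idx, 2], X[fe_idx, 1])
    X[fe_idx, 1:2] <- X[fe_idx, 1:2] + amp * twist * cbind(-sin(th), cos(th))
    X[fe_idx, ] <- X[fe_idx, ] +
      matrix(rnorm(3 * length(fe_idx), sd = amp / 3), ncol = 3)
  }

  # stage 2: pressure ramp (follower load on the arterial face)
  p_full <- loadcase$pressure_mmHg * MMHG_TO_MPA
  n2 <- loadcase$n_incr_pressure
  if (p_full > 0) {
    for (k in seq_len(n2)) {
      p_k <- p_full * k / n2
      it <- if (k == n2) 2L * loadcase$max_iter else loadcase$max_iter
      out <- relax(X, bc$target, p_k, TRUE, it)
      X <- out$X
      res_hist[[length(res_hist) + 1L]] <- out$residual_history
      if (verbose)
        message(sprintf("pressure %d/%d (%.3g mmHg): %d iters, residual %.2e, converged %s",
                        k, n2, loadcase$pressure_mmHg * k / n2,
                        out$iterations, out$residual_ratio, out$converged))
    }
  }
  polish <- 0L
  while (!is.null(out) && !out$converged && polish < 3L) {
    # kinetic damping stalls on contact chatter near equilibrium: polish
    # with light viscous damping and a frozen contact-pair set (continuous
    # forces), refreshing the pairs between rounds
    polish <- polish + 1L
    out <- relax(X, bc$target, p_full, TRUE, loadcase$max_iter,
                 viscous_eta = 0.01, rebuild_every = loadcase$max_iter)
    X <- out$X
    res_hist[[length(res_hist) + 1L]] <- out$residual_history
    if (verbose)
      message(sprintf("viscous polish %d: %d iters, residual %.2e, converged %s",
                      polish, out$iterations, out$residual_ratio,
                      out$converged))
  }

  if (is.null(out)) {  # zero oversizing and zero pressure: unloaded identity
    out <- relax(X, bc$target, 0, TRUE, loadcase$max_iter)
    X <- out$X
    res_hist[[length(res_hist) + 1L]] <- out$residual_history
  }
  converged <- out$converged

  structure(list(vertices = X, mesh = mesh, material = material,
                 loadcase = loadcase, converged = converged,
                 residual = out$residual_ratio,
                 residual_history = unlist(res_hist),
                 ke_peak = out$ke_peak, ke_last = out$ke_last,
                 n_contact_pairs = out$n_contact_pairs,
                 seed = loadcase$seed),
            class = "deformed_valve_state")
}

#' @export
print.deformed_valve_state <- function(x, ...) {
  cat(sprintf("<deformed_valve_state %s>  oversizing %g%%, pressure %g mmHg (seed %d)\n",
              x$mesh$design$label, x$loadcase$oversizing,
              x$loadcase$pressure_mmHg, x$seed))
  cat(sprintf("  converged: %s (final residual ratio %.2e), %d contact pairs\n",
              x$converged, x$residual, x$n_contact_pairs))
  invisible(x)
}

#' Deformed free-edge polyline of one leaflet
#'
#' Ordered deformed positions of the tagged free-edge vertices,
#' commissure to commissure.
#'
#' @param state A `deformed_valve_state` from [solve_static()].
#' @param leaflet Leaflet index (1, 2 or 3).
#' @return n x 3 matrix of 3D points, mm.
#' @export
extract_free_edge <- function(state, leaflet) {
  stopifnot(inherits(state, "deformed_valve_state"))
  idx <- state$mesh$free_edges[[leaflet]]
  state$vertices[idx, , drop = FALSE]
}

#' Export free-edge polylines as CSV
#'
#' Layout `leaflet,vertex_index,x_mm,y_mm,z_mm` (0-based vertex index).
#'
#' @param state A `deformed_valve_state`.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_free_edges_csv <- function(state, path) {
  rows <- lapply(seq_along(state$mesh$free_edges), function(i) {
    P <- extract_free_edge(state, i)
    data.frame(leaflet = i, vertex_index = seq_len(nrow(P)) - 1L,
               x_mm = P[, 1], y_mm = P[, 2], z_mm = P[, 3])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Valve closure metrics from a solved state
#'
#' Projects the deformed leaflets onto the plane normal to the valve axis
#' and measures the central orifice area: the part of the deployed lumen
#' disc not covered by any leaflet, estimated on a regular sampling grid.
#' The valve counts as closed when the orifice area is at most
#' `closure_frac` of the deployed lumen area.
#'
#' @param state A `deformed_valve_state` (must have converged), or a
#'   `valve_mesh` for the undeformed geometry (then `oversizing = 0`).
#' @param closure_frac Closure threshold as a fraction of the deployed
#'   lumen area (default 0.005, i.e. 0.5\%).
#' @param grid_n Grid resolution across the lumen diameter (default 151).
#' @param dilate Coverage dilation radius in mm: a point within this
#'   distance of a projected triangle counts as covered. Defaults to half
#'   the shell thickness (the leaflet material extends t/2 beyond the
#'   midsurface), 0 for a bare midsurface projection.
#' @return List with `orifice_area` (mm^2), `lumen_area` (mm^2),
#'   `orifice_fraction`, `closed` (logical), `deployed_radius` (mm).
#' @export
coaptation_metrics <- function(state, closure_frac = 0.005, grid_n = 151L,
                               dilate = NULL) {
  if (inherits(state, "valve_mesh")) {
    mesh <- state
    X <- mesh$vertices
    r_dep <- mesh$design$radius * mesh$scale
    if (is.null(dilate)) dilate <- 0
  } else {
    stopifnot(inherits(state, "deformed_valve_state"))
    if (!state$converged)
      stop("state did not converge; refusing to compute closure metrics")
    mesh <- state$mesh
    X <- state$vertices
    r_dep <- mesh$design$radius * mesh$scale *
      (1 - state$loadcase$oversizing / 100)
    if (is.null(dilate))
      dilate <- state$material$thickness_mm * mesh$scale / 2
  }
  Tr <- mesh$triangles
  gx <- seq(-r_dep, r_dep, length.out = grid_n)
  pts <- expand.grid(x = gx, y = gx)
  inside <- pts$x^2 + pts$y^2 <= r_dep^2
  pts <- pts[inside, ]
  covered <- rep(FALSE, nrow(pts))
  P1 <- X[Tr[, 1], 1:2, drop = FALSE]
  P2 <- X[Tr[, 2], 1:2, drop = FALSE]
  P3 <- X[Tr[, 3], 1:2, drop = FALSE]
  eps <- 1e-9
  for (i in seq_len(nrow(Tr))) {
    if (all(covered)) break
    xmin <- min(P1[i, 1], P2[i, 1], P3[i, 1])
    xmax <- max(P1[i, 1], P2[i, 1], P3[i, 1])
    ymin <- min(P1[i, 2], P2[i, 2], P3[i, 2])
    ymax <- max(P1[i, 2], P2[i, 2], P3[i, 2])
    cand <- which(!covered & pts$x >= xmin & pts$x <= xmax &
                    pts$y >= ymin & pts$y <= ymax)
    if (!length(cand)) next
    d <- sign_area2(P1[i, ], P2[i, ], P3[i, ])
    if (abs(d) < 1e-12) next
    b1 <- sign_area2_pts(P2[i, ], P3[i, ], pts[cand, ]) / d
    b2 <- sign_area2_pts(P3[i, ], P1[i, ], pts[cand, ]) / d
    b3 <- 1 - b1 - b2
    hit <- b1 >= -eps & b2 >= -eps & b3 >= -eps
    covered[cand[hit]] <- TRUE
  }
  if (dilate > 0 && any(!covered)) {
    # second pass: a point within `dilate` of a projected triangle edge is
    # covered by the physical shell thickness
    for (i in seq_len(nrow(Tr))) {
      open_i <- which(!covered)
      if (!length(open_i)) break
      xmin <- min(P1[i, 1], P2[i, 1], P3[i, 1]) - dilate
      xmax <- max(P1[i, 1], P2[i, 1], P3[i, 1]) + dilate
      ymin <- min(P1[i, 2], P2[i, 2], P3[i, 2]) - dilate
      ymax <- max(P1[i, 2], P2[i, 2], P3[i, 2]) + dilate
      cand <- open_i[pts$x[open_i] >= xmin & pts$x[open_i] <= xmax &
                       pts$y[open_i] >= ymin & pts$y[open_i] <= ymax]
      if (!length(cand)) next
      d2 <- pmin(point_segment_dist2(pts$x[cand], pts$y[cand], P1[i, ], P2[i, ]),
                 point_segment_dist2(pts$x[cand], pts$y[cand], P2[i, ], P3[i, ]),
                 point_segment_dist2(pts$x[cand], pts$y[cand], P3[i, ], P1[i, ]))
      covered[cand[d2 <= dilate^2]] <- TRUE
    }
  }
  cell <- (gx[2] - gx[1])^2
  lumen_area <- pi * r_dep^2
  orifice_area <- sum(!covered) * cell
  list(orifice_area = orifice_area, lumen_area = lumen_area,
       orifice_fraction = orifice_area / lumen_area,
       closed = orifice_area <= closure_frac * lumen_area,
       deployed_radius = r_dep)
}

point_segment_dist2 <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  t <- ((px - a[1]) * abx + (py - a[2]) * aby) / (abx^2 + aby^2 + 1e-300)
  t <- pmin(pmax(t, 0), 1)
  (px - a[1] - t * abx)^2 + (py - a[2] - t * aby)^2
}

sign_area2 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}
sign_area2_pts <- function(a, b, pts) {
  (b[1] - a[1]) * (pts$y - a[2]) - (b[2] - a[2]) * (pts$x - a[1])
}

#' Smallest oversizing achieving valve closure
#'
#' Sweeps the oversizing grid in ascending order, solving the
#' crimp-plus-pressure problem at each value, and returns the smallest
#' diameter reduction for which [coaptation_metrics()] reports the valve
#' closed.
#'
#' @param design A [valve_design()].
#' @param material A [material_model()].
#' @param pressure_mmHg Diastolic pressure, mmHg.
#' @param grid Ascending oversizing values, percent.
#' @param scale_factor,n_circ,n_rad Mesh scale and resolution.
#' @param seed Solver perturbation seed.
#' @param full_grid Solve the entire grid instead of stopping at the
#'   first closing value (enables monotonicity checks).
#' @param verbose Progress output.
#' @param ... Passed to [crimp_loadcase()].
#' @return List with `threshold` (percent, or `NA` with
#'   `reached = FALSE` if no grid value closes the valve), `reached`,
#'   and `results` (data frame: oversizing, orifice_fraction, closed,
#'   converged).
#' @export
closure_threshold_sweep <- function(design, material, pressure_mmHg = 20,
                                    grid = 0:20, scale_factor = 1,
                                    n_circ = 16L, n_rad = 10L, seed = 1L,
                                    full_grid = FALSE, verbose = FALSE, ...) {
  if (is.unsorted(grid)) stop("`grid` must be sorted ascending")
  mesh <- assemble_valve(design, n_circ = n_circ, n_rad = n_rad,
                         scale = scale_factor)
  rows <- list()
  threshold <- NA_real_
  for (ov in grid) {
    lc <- crimp_loadcase(oversizing = ov, pressure_mmHg = pressure_mmHg,
                         scale_factor = scale_factor, seed = seed, ...)
    st <- if (ov == 0 && pressure_mmHg == 0) NULL else
      solve_static(mesh, material, lc)
    cm <- if (is.null(st)) coaptation_metrics(mesh) else {
      if (st$converged) coaptation_metrics(st) else
        list(orifice_fraction = NA_real_, closed = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      oversizing = ov, orifice_fraction = cm$orifice_fraction,
      closed = isTRUE(cm$closed),
      converged = if (is.null(st)) TRUE else st$converged)
    if (verbose)
      message(sprintf("oversizing %g%%: orifice fraction %.4f, closed %s",
                      ov, cm$orifice_fraction, isTRUE(cm$closed)))
    if (isTRUE(cm$closed) && is.na(threshold)) {
      threshold <- ov
      if (!full_grid) break
    }
  }
  list(threshold = threshold, reached = !is.na(threshold),
       results = do.call(rbind, rows))
}
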