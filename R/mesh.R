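#' Build a triangulated leaflet surface
#'
#' Realizes one leaflet of a [valve_design()] in 3D. The attachment edge is
#' a cosine-blended scallop on the cylinder of radius \eqn{R_{valve}}
#' spanning 120 degrees, rising from the nadir (height `nadir_height`,
#' default 0) at the belly midline to the commissure tops at height H.
#' The free edge runs from commissure to commissure; in top view it is the
#' two-segment trace through the innermost point at distance
#' \eqn{\Delta L} from the axis (a single chord at OD = 50\%, two radial
#' segments meeting at the axis for the closed design OD = 0), and its
#' height follows the [free_edge_profile()] of the design
#' (`z = H - y(x)`). The interior is a ruled loft between the two
#' boundary curves.
#'
#' Coordinates are right-handed with the valve axis along +z pointing
#' downstream and the leaflet belly midline along +x; the commissures sit
#' at polar angles of -60 and +60 degrees.
#'
#' @param design A [valve_design()].
#' @param n_circ Number of circumferential intervals across the leaflet
#'   (>= 4).
#' @param n_rad Number of radial intervals from attachment to free edge
#'   (>= 2).
#' @param scale Homothety factor applied to all lengths (default 1).
#' @param nadir_height Height of the attachment-scallop nadir, mm.
#' @param rotation Rotation about the valve axis in radians (used by
#'   [assemble_valve()]).
#' @return A `leaflet_mesh`: list with `vertices` (n x 3 matrix, mm),
#'   `triangles` (m x 3 integer matrix, 1-based, consistently oriented),
#'   `attachment` (vertex indices on the attachment edge), `free_edge`
#'   (ordered vertex indices, commissure to commissure), `commissures`
#'   (two vertex indices).
#' @export
#' @examples
#' m <- build_leaflet_surface(valve_designs()$G0)
#' nrow(m$vertices)
build_leaflet_surface <- function(design, n_circ = 24L, n_rad = 16L,
                                  scale = 1, nadir_height = 0,
                                  rotation = 0) {
  stopifnot(inherits(design, "valve_design"))
  n_circ <- as.integer(n_circ); n_rad <- as.integer(n_rad)
  if (n_circ < 4L) stop("`n_circ` too coarse to represent the free edge (need >= 4)")
  if (n_rad < 2L) stop("`n_rad` must be >= 2")
  if (scale <= 0) stop("`scale` must be positive")

  R <- design$radius * scale
  H <- design$height * scale
  h <- design$commissure_height * scale
  s <- design$commissure_span * scale
  dL <- design$delta_L * scale
  z0 <- nadir_height * scale

  u <- seq(0, 1, length.out = n_circ + 1L)

  # attachment scallop on the cylinder: commissures (u = 0, 1) at height H,
  # belly nadir (u = 0.5) at z0, cosine blend between
  phi <- (u - 0.5) * (2 * pi / 3)
  z_att <- z0 + (H - z0) * (1 + cos(2 * pi * u)) / 2
  A <- cbind(R * cos(phi), R * sin(phi), z_att)

  # free edge: two-segment top-view trace C1 -> M -> C2, profile in z
  C1 <- c(R * cos(-pi / 3), R * sin(-pi / 3))
  C2 <- c(R * cos(+pi / 3), R * sin(+pi / 3))
  M <- c(dL, 0)
  fx <- ifelse(u <= 0.5,
               C1[1] + 2 * u * (M[1] - C1[1]),
               M[1] + (2 * u - 1) * (C2[1] - M[1]))
  fy <- ifelse(u <= 0.5,
               C1[2] + 2 * u * (M[2] - C1[2]),
               M[2] + (2 * u - 1) * (C2[2] - M[2]))
  x_prof <- (u - 0.5) * s
  z_free <- H - free_edge_y(design$free_edge_shape, x_prof, h, s)
  Fe <- cbind(fx, fy, z_free)

  # vertex layout: commissure1, interior columns (u_1..u_{nc-1}) each with
  # n_rad+1 ruled vertices (attachment -> free edge), commissure2.
  # the boundary columns collapse to a point (A == F at the commissures).
  n_col <- n_circ - 1L
  n_per <- n_rad + 1L
  v <- seq(0, 1, length.out = n_per)
  verts <- matrix(NA_real_, nrow = 2L + n_col * n_per, ncol = 3L)
  verts[1L, ] <- A[1L, ]
  for (k in seq_len(n_col)) {
    i <- k + 1L  # row in u-grid
    block <- (1L + (k - 1L) * n_per) + seq_len(n_per)
    verts[block, ] <- outer(1 - v, A[i, ]) + outer(v, Fe[i, ])
  }
  i_c2 <- nrow(verts)
  verts[i_c2, ] <- A[n_circ + 1L, ]

  idx <- function(k, j) 1L + (k - 1L) * n_per + (j + 1L)  # j in 0..n_rad

  tri <- vector("list", 2L * n_rad * n_col)
  t_i <- 0L
  # fan at commissure 1
  for (j in 0:(n_rad - 1L)) {
    t_i <- t_i + 1L
    tri[[t_i]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  # interior quads
  if (n_col > 1L) {
    for (k in 1:(n_col - 1L)) {
      for (j in 0:(n_rad - 1L)) {
        t_i <- t_i + 1L
        tri[[t_i]] <- c(idx(k, j), idx(k + 1L, j), idx(k + 1L, j + 1L))
        t_i <- t_i + 1L
        tri[[t_i]] <- c(idx(k, j), idx(k + 1L, j + 1L), idx(k, j + 1L))
      }
    }
  }
  # fan at commissure 2
  for (j in 0:(n_rad - 1L)) {
    t_i <- t_i + 1L
    tri[[t_i]] <- c(idx(n_col, j), i_c2, idx(n_col, j + 1L))
  }
  triangles <- do.call(rbind, tri[seq_len(t_i)])

  attachment <- c(1L, vapply(seq_len(n_col), function(k) idx(k, 0L),
                             integer(1)), i_c2)
  free_edge <- c(1L, vapply(seq_len(n_col), function(k) idx(k, n_rad),
                            integer(1)), i_c2)

  if (rotation != 0) {
    cr <- cos(rotation); sr <- sin(rotation)
    verts <- cbind(verts[, 1] * cr - verts[, 2] * sr,
                   verts[, 1] * sr + verts[, 2] * cr,
                   verts[, 3])
  }

  structure(list(vertices = verts, triangles = triangles,
                 attachment = attachment, free_edge = free_edge,
                 commissures = c(1L, i_c2),
                 design = design, scale = scale,
                 n_circ = n_circ, n_rad = n_rad),
            class = "leaflet_mesh")
}

#' @export
print.leaflet_mesh <- function(x, ...) {
  cat(sprintf("<leaflet_mesh %s>  %d vertices, %d triangles (%d x %d grid, scale %g)\n",
              x$design$label, nrow(x$vertices), nrow(x$triangles),
              x$n_circ, x$n_rad, x$scale))
  invisible(x)
}

#' Assemble a trileaflet valve mesh
#'
#' Builds `n_leaflets` congruent leaflets rotated by multiples of
#' 360/n degrees about the valve axis and concatenates them into a single
#' indexed mesh. Commissure vertices of adjacent leaflets coincide
#' geometrically but remain distinct mesh vertices (each leaflet is an
#' independent membrane).
#'
#' @inheritParams build_leaflet_surface
#' @return A `valve_mesh`: list with `vertices`, `triangles`, `design`,
#'   `axis` (the +z unit vector), per-leaflet index bookkeeping
#'   (`leaflet_id` per vertex, `attachment`, `free_edges` - a list of
#'   ordered index vectors, `commissures`), and the build resolution.
#' @export
#' @examples
#' vm <- assemble_valve(valve_designs()$G6, n_circ = 12, n_rad = 6)
#' vm
assemble_valve <- function(design, n_circ = 24L, n_rad = 16L, scale = 1,
                           nadir_height = 0) {
  stopifnot(inherits(design, "valve_design"))
  nL <- design$n_leaflets
  parts <- lapply(seq_len(nL) - 1L, function(k) {
    build_leaflet_surface(design, n_circ = n_circ, n_rad = n_rad,
                          scale = scale, nadir_height = nadir_height,
                          rotation = k * 2 * pi / nL)
  })
  offs <- cumsum(c(0L, vapply(parts, function(p) nrow(p$vertices),
                              integer(1))))
  vertices <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  triangles <- do.call(rbind, lapply(seq_along(parts), function(i) {
    parts[[i]]$triangles + offs[i]
  }))
  leaflet_id <- rep(seq_len(nL),
                    vapply(parts, function(p) nrow(p$vertices), integer(1)))
  structure(list(
    vertices = vertices, triangles = triangles,
    triangle_leaflet = rep(seq_len(nL),
                           vapply(parts, function(p) nrow(p$triangles),
                                  integer(1))),
    leaflet_id = leaflet_id,
    attachment = unlist(lapply(seq_along(parts), function(i)
      parts[[i]]$attachment + offs[i])),
    free_edges = lapply(seq_along(parts), function(i)
      parts[[i]]$free_edge + offs[i]),
    commissures = lapply(seq_along(parts), function(i)
      parts[[i]]$commissures + offs[i]),
    design = design, axis = c(0, 0, 1), scale = scale,
    n_circ = as.integer(n_circ), n_rad = as.integer(n_rad),
    nadir_height = nadir_height
  ), class = "valve_mesh")
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf("<valve_mesh %s>  %d leaflets, %d vertices, %d triangles (scale %g)\n",
              x$design$label, length(x$free_edges), nrow(x$vertices),
              nrow(x$triangles), x$scale))
  cat(sprintf("  R = %g mm, OD = %g%%, %s free edge; delta_L = %g mm\n",
              x$design$radius * x$scale, x$design$opening_degree,
              x$design$free_edge_shape, x$design$delta_L * x$scale))
  invisible(x)
}

#' Ideal (unwheeled) free-edge length at a deployed radius
#'
#' Top-view length of the designed free-edge trace of one leaflet, scaled
#' from the nominal valve radius to the deployed (possibly crimped)
#' radius. The designed trace runs commissure - innermost point -
#' commissure, so
#' \deqn{L_{ideal} = 2\sqrt{(R/2-\Delta L)^2 + 3R^2/4}\;\cdot\;
#'       r_{deployed}/R.}
#' For the closed design (OD 0) this is \eqn{2 r_{deployed}} (commissure to
#' center and back out); at OD 50\% it is the inscribed-triangle chord
#' \eqn{\sqrt3\, r_{deployed}}.
#'
#' @param design A [valve_design()].
#' @param deployed_radius Deployed lumen radius in mm,
#'   `0 < deployed_radius <= radius`.
#' @return Ideal free-edge length per leaflet in mm (top view).
#' @export
#' @examples
#' ideal_free_edge_length(valve_designs()$G6, 15)   # sqrt(3)*15
#' ideal_free_edge_length(valve_designs()$G0, 13.5) # 2*13.5
ideal_free_edge_length <- function(design, deployed_radius) {
  stopifnot(inherits(design, "valve_design"))
  R <- design$radius
  if (any(deployed_radius <= 0) || any(deployed_radius > R + 1e-9))
    stop("`deployed_radius` must satisfy 0 < r <= R_valve")
  dL <- design$delta_L
  nominal <- 2 * sqrt((R / 2 - dL)^2 + 3 * R^2 / 4)
  nominal * deployed_radius / R
}

# ---- mesh export / import (plain-text formats) ------------------------------

#' Export and import surface meshes
#'
#' Writes a `valve_mesh` or `leaflet_mesh` to ASCII STL, legacy-ASCII VTK
#' (PolyData) or Wavefront OBJ; `import_mesh()` reads the same formats
#' back. STL stores a triangle soup, so connectivity is reconstructed by
#' merging identical vertices on import; OBJ and VTK preserve indexing
#' exactly.
#'
#' @param mesh A `valve_mesh` or `leaflet_mesh`.
#' @param path Output file path.
#' @param format `"stl"`, `"vtk"` or `"obj"` (default: from the file
#'   extension).
#' @return `export_mesh()` returns `path` invisibly; `import_mesh()`
#'   returns a list with `vertices` and `triangles`.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  if (!is.list(mesh) || is.null(mesh$vertices) || is.null(mesh$triangles) ||
      nrow(mesh$vertices) == 0L)
    stop("`mesh` must be a non-empty mesh with vertices and triangles")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "vtk", "obj"))
  V <- mesh$vertices; Tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "stl") {
    nrm <- triangle_normals(V, Tr)
    writeLines("solid leafletlab", con)
    for (i in seq_len(nrow(Tr))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (j in 1:3) {
        p <- V[Tr[i, j], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid leafletlab", con)
  } else if (format == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", Tr[, 1], Tr[, 2], Tr[, 3]), con)
  } else {
    writeLines(c("# vtk DataFile Version 3.0", "leafletlab surface mesh",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(V))), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(Tr), 4L * nrow(Tr)), con)
    writeLines(sprintf("3 %d %d %d", Tr[, 1] - 1L, Tr[, 2] - 1L,
                       Tr[, 3] - 1L), con)
  }
  invisible(path)
}

#' @rdname export_mesh
#' @export
import_mesh <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "vtk", "obj"))
  lines <- readLines(path)
  if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    Tr <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(x[2:4])))
  } else if (format == "vtk") {
    ip <- grep("^POINTS", lines)
    np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    V <- do.call(rbind, lapply(strsplit(lines[(ip + 1):(ip + np)], "\\s+"),
                               as.numeric))
    it <- grep("^POLYGONS", lines)
    nt <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
    Tr <- do.call(rbind, lapply(strsplit(lines[(it + 1):(it + nt)], "\\s+"),
                                function(x) as.integer(x[2:4]) + 1L))
  } else {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    soup <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    key <- apply(round(soup, 9), 1, paste, collapse = ",")
    uk <- !duplicated(key)
    V <- soup[uk, , drop = FALSE]
    map <- match(key, key[uk])
    Tr <- matrix(map, ncol = 3, byrow = TRUE)
  }
  list(vertices = V, triangles = Tr)
}

# per-triangle unit normals (consistent with vertex winding)
triangle_normals <- function(V, Tr) {
  e1 <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  e2 <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# total area of a triangulated surface
mesh_area <- function(V, Tr) {
  e1 <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  e2 <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(n^2))) / 2
}
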