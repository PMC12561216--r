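#' Project a 3D polyline to the valve top view
#'
#' Orthographic projection onto the plane normal to the valve axis,
#' preserving point order. The projected trace is expressed in an
#' orthonormal basis of that plane (for the default +z axis this is simply
#' the x-y coordinates).
#'
#' @param polyline n x 3 matrix of 3D points (mm).
#' @param axis Valve axis vector (default `c(0, 0, 1)`); need not be unit
#'   length but must be nonzero.
#' @return A `free_edge_trace`: n x 2 matrix of projected coordinates (mm)
#'   with attribute `degenerate = TRUE` if the projected trace has
#'   (near-)zero length.
#' @export
#' @examples
#' helix <- cbind(cos(seq(0, 2 * pi, length.out = 50)),
#'                sin(seq(0, 2 * pi, length.out = 50)),
#'                seq(0, 5, length.out = 50))
#' tr <- project_top_view(helix)
#' range(sqrt(rowSums(tr^2)))  # all on the unit circle
project_top_view <- function(polyline, axis = c(0, 0, 1)) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline must have >= 2 points")
  if (ncol(polyline) != 3L) stop("polyline must be n x 3")
  na <- sqrt(sum(axis^2))
  if (na == 0) stop("axis vector must be nonzero")
  a <- axis / na
  # orthonormal in-plane basis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  xy <- cbind(polyline %*% e1, polyline %*% e2)
  deg <- polyline_length(xy) < 1e-12
  if (deg)
    warning("projected trace is degenerate (polyline parallel to the axis)")
  structure(xy, degenerate = deg, class = c("free_edge_trace", "matrix"))
}

#' Polyline length
#'
#' Sum of Euclidean segment lengths of an ordered polyline in any
#' dimension.
#'
#' @param points n x d matrix of ordered points.
#' @return Length in the units of `points`.
#' @export
#' @examples
#' polyline_length(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 3
polyline_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Pinwheeling Index
#'
#' \deqn{PI = \frac{L_{actual} - L_{ideal}}{L_{actual}} \times 100\ [\%]}
#' comparing the deformed ("wheeled") free-edge trace length to the ideal
#' unwheeled length at the same deployed radius. PI is scale-invariant and
#' always below 100\%; a negative PI (actual shorter than ideal, i.e. a
#' slack/retracted edge) is permitted but flagged with a warning.
#'
#' @param l_actual Actual (wheeled) free-edge length, mm (> 0).
#' @param l_ideal Ideal free-edge length, mm (>= 0).
#' @return PI in percent.
#' @export
#' @examples
#' pinwheeling_index(2, 1)  # 50 %
pinwheeling_index <- function(l_actual, l_ideal) {
  if (any(l_actual <= 0)) stop("`l_actual` must be positive")
  if (any(l_ideal < 0)) stop("`l_ideal` must be >= 0")
  pi_val <- (l_actual - l_ideal) / l_actual * 100
  if (any(pi_val < 0))
    warning("negative Pinwheeling Index: actual edge shorter than ideal (slack edge)")
  pi_val
}

#' Relative Pinwheeling Index difference
#'
#' Relative excess of the higher PI over the lower one,
#' `(pi_high - pi_low) / pi_low * 100`, the form used to compare a closed
#' against a semi-closed design.
#'
#' @param pi_high Higher PI, percent.
#' @param pi_low Lower PI, percent (> 0).
#' @return Relative difference in percent.
#' @export
#' @examples
#' relative_pi_difference(13.63, 10.21)  # about 33.5 %
relative_pi_difference <- function(pi_high, pi_low) {
  if (any(pi_low <= 0)) stop("`pi_low` must be positive")
  (pi_high - pi_low) / pi_low * 100
}

#' Pinwheeling Index from a solved valve state
#'
#' For each leaflet of a converged [solve_static()] result, measures
#' \eqn{L_{actual}} as the top-view length of the deformed free-edge
#' polyline and \eqn{L_{ideal}} via [ideal_free_edge_length()] at the
#' deployed (crimped) radius, and evaluates the Pinwheeling Index. The 3D
#' arc lengths are reported alongside for transparency; the index itself
#' is defined on the top-view projection.
#'
#' @param state A `deformed_valve_state` from [solve_static()].
#' @return A `pi_report`: list with `per_leaflet` (data frame: leaflet,
#'   `l_actual`, `l_ideal`, `l_actual_3d`, `pi`), `mean_pi`, and the
#'   deployed radius used.
#' @export
pi_from_state <- function(state) {
  stopifnot(inherits(state, "deformed_valve_state"))
  if (!state$converged)
    stop("state did not converge; refusing to compute PI")
  mesh <- state$mesh
  design <- mesh$design
  r_dep <- design$radius * (1 - state$loadcase$oversizing / 100)
  l_ideal <- ideal_free_edge_length(design, r_dep) * mesh$scale
  nL <- length(mesh$free_edges)
  rows <- lapply(seq_len(nL), function(i) {
    poly <- extract_free_edge(state, i)
    tv <- project_top_view(poly, mesh$axis)
    l_act <- polyline_length(tv)
    data.frame(leaflet = i, l_actual = l_act, l_ideal = l_ideal,
               l_actual_3d = polyline_length(poly),
               pi = pinwheeling_index(l_act, l_ideal))
  })
  per_leaflet <- do.call(rbind, rows)
  structure(list(per_leaflet = per_leaflet,
                 mean_pi = mean(per_leaflet$pi),
                 deployed_radius = r_dep * mesh$scale,
                 label = design$label),
            class = "pi_report")
}

#' @export
print.pi_report <- function(x, ...) {
  cat(sprintf("<pi_report %s>  deployed radius %.3f mm\n", x$label,
              x$deployed_radius))
  print(x$per_leaflet, row.names = FALSE, digits = 4)
  cat(sprintf("  mean PI = %.2f %%\n", x$mean_pi))
  invisible(x)
}

#' Read a digitized free-edge trace
#'
#' Reads a top-view free-edge polyline digitized from imaging, in the
#' documented CSV layout `leaflet,point_index,x_mm,y_mm` (0-based point
#' indexing), and returns one trace per leaflet.
#'
#' @param path CSV file path.
#' @return Named list of `free_edge_trace` matrices, one per leaflet id.
#' @export
read_edge_trace_csv <- function(path) {
  df <- read.csv(path)
  need <- c("leaflet", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$leaflet), function(d) {
    d <- d[order(d$point_index), ]
    structure(cbind(d$x_mm, d$y_mm), degenerate = FALSE,
              class = c("free_edge_trace", "matrix"))
  })
  out
}
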