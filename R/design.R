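#' Valve design parameter set
#'
#' Bundles the geometric parameters that define one trileaflet valve
#' design: valve radius, valve height, commissure height and span, the
#' opening degree (OD) and the free-edge shape. The seven packaged
#' reference designs are available through [valve_designs()].
#'
#' The opening degree is the relative retraction of the leaflet free edge
#' from the valve center in the unloaded state,
#' \deqn{OD = \Delta L / R_{valve} \times 100\%,}
#' where \eqn{\Delta L} is the distance from the innermost free-edge point
#' to the valve axis. \eqn{OD = 0} is a fully closed design whose leaflets
#' coapt at the centerline; with a linear free edge OD cannot exceed 50\%
#' because at 50\% the three free edges form the inscribed equilateral
#' triangle.
#'
#' @param label Design label, e.g. `"G0"`.
#' @param radius Valve radius \eqn{R_{valve}} in mm.
#' @param opening_degree Opening degree OD in percent, in `[0, 100]`
#'   (`[0, 50]` for a linear free edge).
#' @param free_edge_shape One of `"concave"`, `"linear"`, `"convex"`.
#' @param height Valve height H in mm (commissure-top height above the
#'   attachment nadir). Defaults to `0.7 * diameter`.
#' @param commissure_height Free-edge sagitta / commissure height h in mm.
#'   Defaults to 10\% of the valve diameter.
#' @param commissure_span Commissure-to-commissure span s in mm. Defaults
#'   to `sqrt(3) * radius`, the edge of the equilateral triangle inscribed
#'   in the valve circle.
#' @param n_leaflets Number of leaflets (default 3).
#' @return An object of class `valve_design`.
#' @seealso [valve_designs()], [build_leaflet_surface()], [assemble_valve()]
#' @export
#' @examples
#' g6 <- valve_design("G6", radius = 15, opening_degree = 50,
#'                    free_edge_shape = "linear")
#' g6
valve_design <- function(label, radius, opening_degree,
                         free_edge_shape = c("linear", "concave", "convex"),
                         height = NULL, commissure_height = NULL,
                         commissure_span = NULL, n_leaflets = 3L) {
  free_edge_shape <- match.arg(free_edge_shape)
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number (mm)")
  if (!is.numeric(opening_degree) || opening_degree < 0 || opening_degree > 100)
    stop("`opening_degree` must be in [0, 100] percent")
  if (free_edge_shape == "linear" && opening_degree > 50)
    stop("with a linear free edge the opening degree cannot exceed 50%: ",
         "at OD = 50% the free edges already form the inscribed triangle")
  diameter <- 2 * radius
  if (is.null(height)) height <- 0.7 * diameter
  if (is.null(commissure_height))
    commissure_height <- commissure_height_default(diameter)
  if (is.null(commissure_span)) commissure_span <- commissure_span(radius)
  if (height <= 0) stop("`height` must be positive")
  if (commissure_height < 0) stop("`commissure_height` must be >= 0")
  if (commissure_span <= 0) stop("`commissure_span` must be positive")
  delta_L <- delta_L_from_od(opening_degree, radius)
  leaflet_length <- radius - delta_L
  if (leaflet_length <= 0 || leaflet_length > radius)
    stop("derived leaflet length must satisfy 0 < L_leaflet <= R_valve")
  structure(list(
    label = label,
    radius = radius,
    diameter = diameter,
    height = height,
    commissure_height = commissure_height,
    commissure_span = commissure_span,
    opening_degree = opening_degree,
    free_edge_shape = free_edge_shape,
    delta_L = delta_L,
    leaflet_length = leaflet_length,
    n_leaflets = as.integer(n_leaflets)
  ), class = "valve_design")
}

#' @export
print.valve_design <- function(x, ...) {
  cat(sprintf("<valve_design %s>  R = %g mm, H = %g mm, OD = %g%% (%s free edge)\n",
              x$label, x$radius, x$height, x$opening_degree, x$free_edge_shape))
  cat(sprintf("  delta_L = %g mm, leaflet length = %g mm, h = %g mm, s = %g mm\n",
              x$delta_L, x$leaflet_length, x$commissure_height,
              x$commissure_span))
  invisible(x)
}

#' Packaged reference designs G0-G6
#'
#' The seven 30 mm designs of the comparative study: the closed control G0
#' (OD 0, linear) and six semi-closed variations with incrementally reduced
#' leaflet material.
#'
#' @param diameter Valve diameter in mm (default 30).
#' @return Named list of [valve_design()] objects `G0` ... `G6`.
#' @export
#' @examples
#' names(valve_designs())
#' valve_designs()$G6
valve_designs <- function(diameter = 30) {
  tab <- data.frame(
    label = paste0("G", 0:6),
    opening_degree = c(0, 20, 20, 25, 25, 30, 50),
    free_edge_shape = c("linear", "convex", "concave", "linear", "concave",
                        "linear", "linear"),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(tab)), function(i) {
    valve_design(tab$label[i], radius = diameter / 2,
                 opening_degree = tab$opening_degree[i],
                 free_edge_shape = tab$free_edge_shape[i])
  })
  names(out) <- tab$label
  out
}

#' Convert opening degree to center distance and back
#'
#' `delta_L_from_od()` converts the opening degree OD (percent) into the
#' distance \eqn{\Delta L} from the leaflet free edge to the valve axis,
#' \eqn{\Delta L = OD/100 \cdot R_{valve}}; `od_from_delta_L()` is the
#' exact inverse.
#'
#' @param od Opening degree in percent, in `[0, 100]`.
#' @param delta_L Distance from the innermost free-edge point to the valve
#'   axis, mm.
#' @param radius Valve radius in mm (> 0).
#' @return Distance in mm, resp. opening degree in percent.
#' @export
#' @examples
#' delta_L_from_od(50, 15)   # 7.5 mm
#' od_from_delta_L(4.5, 15)  # 30 %
delta_L_from_od <- function(od, radius) {
  if (any(radius <= 0)) stop("`radius` must be positive")
  if (any(od < 0) || any(od > 100)) stop("`od` must be in [0, 100] percent")
  od / 100 * radius
}

#' @rdname delta_L_from_od
#' @export
od_from_delta_L <- function(delta_L, radius) {
  if (any(radius <= 0)) stop("`radius` must be positive")
  if (any(delta_L < 0)) stop("`delta_L` must be >= 0")
  delta_L / radius * 100
}

#' Commissure-to-commissure span
#'
#' Side length of the equilateral triangle inscribed in the valve circle,
#' \eqn{s = \sqrt{3} R_{valve}}: the straight-line distance between the two
#' commissures of one leaflet in a trileaflet valve.
#'
#' @param radius Valve radius in mm (> 0).
#' @return Span s in mm.
#' @export
#' @examples
#' commissure_span(15)  # 25.98 mm
commissure_span <- function(radius) {
  if (any(radius <= 0)) stop("`radius` must be positive")
  sqrt(3) * radius
}

#' Default commissure height
#'
#' The free-edge sagitta / commissure height h defaults to 10\% of the
#' valve diameter (3 mm for a 30 mm valve).
#'
#' @param diameter Valve diameter in mm (>= 0).
#' @return h in mm.
#' @export
#' @examples
#' commissure_height_default(30)  # 3 mm
commissure_height_default <- function(diameter) {
  if (any(diameter < 0)) stop("`diameter` must be >= 0")
  0.10 * diameter
}

#' Sample a free-edge profile curve
#'
#' The 2D outline of the leaflet free edge in the frontal projection, with
#' x spanning the commissure-to-commissure chord and y the vertical
#' deviation (sagitta) from the commissure level:
#' concave \eqn{y = -4h/s^2 x^2 + h}, convex \eqn{y = 4h/s^2 x^2 - h},
#' linear \eqn{y \equiv 0}. The concave and convex profiles are exact
#' mirror images.
#'
#' @param shape One of `"concave"`, `"linear"`, `"convex"`.
#' @param h Sagitta in mm (>= 0).
#' @param s Span in mm (> 0).
#' @param n_samples Odd number of samples >= 3 so that x = 0 is sampled.
#' @return A `free_edge_profile`: data frame with columns `x`, `y` (mm) and
#'   attributes `shape`, `h`, `s`.
#' @export
#' @examples
#' p <- free_edge_profile("concave", h = 3, s = commissure_span(15))
#' p$y[(nrow(p) + 1) / 2]  # sagitta at x = 0: 3 mm
free_edge_profile <- function(shape = c("concave", "linear", "convex"),
                              h, s, n_samples = 33L) {
  shape <- match.arg(shape)
  if (s <= 0) stop("`s` must be positive")
  if (h < 0) stop("`h` must be >= 0")
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L) stop("`n_samples` must be >= 3")
  if (n_samples %% 2L == 0L) stop("`n_samples` must be odd so x = 0 is sampled")
  x <- seq(-s / 2, s / 2, length.out = n_samples)
  y <- free_edge_y(shape, x, h, s)
  structure(data.frame(x = x, y = y),
            shape = shape, h = h, s = s,
            class = c("free_edge_profile", "data.frame"))
}

# profile ordinate; vectorized over x
free_edge_y <- function(shape, x, h, s) {
  switch(shape,
         concave = -4 * h / s^2 * x^2 + h,
         convex  =  4 * h / s^2 * x^2 - h,
         linear  = rep(0, length(x)),
         stop("unknown free-edge shape: ", shape))
}
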