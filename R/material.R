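#' Leaflet material model
#'
#' Isotropic nonlinear membrane material described by a tabulated
#' monotone strain-to-stress curve (engineering strain, MPa), a Poisson
#' ratio, density and shell thickness. The solver uses the secant modulus
#' of the curve at the element's current peak principal strain.
#'
#' @param curve_strain Increasing engineering strains (> 0).
#' @param curve_stress Corresponding stresses, MPa, monotone
#'   non-decreasing.
#' @param poisson_ratio Poisson ratio, in (0, 0.5); default 0.49 (nearly
#'   incompressible soft tissue).
#' @param density Density in kg/m^3; default 1410 (crosslinked
#'   pericardium). Metadata for the quasi-static solve.
#' @param thickness_um Shell thickness in micrometers; default 200.
#' @return A `material_model`.
#' @seealso [pericardium_material()]
#' @export
material_model <- function(curve_strain, curve_stress, poisson_ratio = 0.49,
                           density = 1410, thickness_um = 200) {
  stopifnot(length(curve_strain) == length(curve_stress),
            length(curve_strain) >= 1L)
  if (any(curve_strain <= 0) || any(diff(curve_strain) <= 0))
    stop("`curve_strain` must be positive and strictly increasing")
  if (any(curve_stress < 0) || any(diff(curve_stress) < 0))
    stop("`curve_stress` must be monotone non-decreasing")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("`poisson_ratio` must be in (0, 0.5)")
  if (thickness_um <= 0) stop("`thickness_um` must be positive")
  structure(list(curve_strain = curve_strain, curve_stress = curve_stress,
                 poisson_ratio = poisson_ratio, density = density,
                 thickness_um = thickness_um,
                 thickness_mm = thickness_um / 1000),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("<material_model>  nu = %.2f, t = %g um, rho = %g kg/m^3\n",
              x$poisson_ratio, x$thickness_um, x$density))
  cat("  strain->stress (MPa):",
      paste(sprintf("%.3g->%.3g", x$curve_strain, x$curve_stress),
            collapse = ", "), "\n")
  invisible(x)
}

#' Packaged pericardium-like membrane material
#'
#' The packaged default leaflet material: a bilinear stress-strain curve
#' with a compliant toe region (1 MPa up to 10\% strain) and a stiff
#' collagen-locked region (10 MPa tangent beyond), Poisson ratio 0.49,
#' density 1410 kg/m^3, thickness 200 um. The curve is a documented
#' placeholder with the character of crosslinked pericardium; all solver
#' results depend on it and it is configuration-replaceable.
#'
#' @inheritParams material_model
#' @return A `material_model`.
#' @export
#' @examples
#' pericardium_material()
pericardium_material <- function(poisson_ratio = 0.49, density = 1410,
                                 thickness_um = 200) {
  material_model(curve_strain = c(0.10, 1.00),
                 curve_stress = c(0.10, 0.10 + 0.90 * 10),
                 poisson_ratio = poisson_ratio, density = density,
                 thickness_um = thickness_um)
}

#' Crimp-plus-pressure load case
#'
#' Loading protocol of the in-silico deployment experiment: a uniform
#' radial diameter reduction of the attachment edge (oversizing) followed
#' by a uniform diastolic transvalvular pressure on the arterial face.
#'
#' @param oversizing Diameter reduction in percent, `[0, 100)`.
#' @param pressure_mmHg Diastolic differential pressure, mmHg (default
#'   20, the ISO normotensive pulmonary diastolic load).
#' @param scale_factor Geometric downscale factor applied to the whole
#'   model including thickness (default 1; 0.5 supported - the
#'   Pinwheeling Index is scale-invariant).
#' @param seed Seed for the symmetry-breaking free-edge perturbation.
#' @param n_incr_crimp,n_incr_pressure Number of load increments.
#' @param max_iter Dynamic-relaxation iteration cap per increment.
#' @param tol Convergence tolerance: residual force norm relative to the
#'   applied load norm.
#' @param perturbation Free-edge symmetry-breaking perturbation as a
#'   fraction of the valve radius (default 0.001).
#' @param contact_penalty_scale Contact penalty stiffness as a multiple
#'   of the membrane stiffness E1 * thickness (default 10).
#' @param compression_retention Fraction of compressive principal stress
#'   carried by the membrane (default 1: full compression, stabilized by
#'   the hinge bending forces). Values < 1 give a tension-field
#'   (wrinkling) membrane for bending-free runs; mixing strong clamping
#'   with bending is unstable.
#' @param bending_scale Multiplier on the physical plate bending
#'   stiffness E1 t^3 / (12 (1 - nu^2)) used for the discrete hinge
#'   bending forces. The default 5 sets the effective bending so that the
#'   shortest wrinkle wavelength the default mesh can represent (about two
#'   elements) is marginally stable; sub-element wrinkling that the mesh
#'   cannot resolve is thereby not replaced by spurious element-scale
#'   folds. 0 disables bending (pure membrane).
#' @param pressure_mode `"follower"` (default): uniform pressure along
#'   the current surface normals on every face. `"shielded"`: follower
#'   pressure restricted to the wetted surface - triangles beyond a
#'   closed coaptation seal (detected by flood fill with contacted
#'   triangles as barriers) carry no static fluid load. `"axial"`:
#'   projected-area axial traction (net transvalvular load only).
#' @return A `crimp_loadcase`.
#' @export
crimp_loadcase <- function(oversizing, pressure_mmHg = 20, scale_factor = 1,
                           seed = 1L, n_incr_crimp = 4L,
                           n_incr_pressure = 4L, max_iter = 20000L,
                           tol = 1e-4, perturbation = 0.001,
                           contact_penalty_scale = 10,
                           compression_retention = 1,
                           bending_scale = 5,
                           pressure_mode = c("follower", "shielded", "axial")) {
  pressure_mode <- match.arg(pressure_mode)
  if (oversizing < 0 || oversizing >= 100)
    stop("`oversizing` must be in [0, 100) percent")
  if (pressure_mmHg < 0) stop("`pressure_mmHg` must be >= 0")
  if (scale_factor <= 0) stop("`scale_factor` must be positive")
  structure(list(oversizing = oversizing, pressure_mmHg = pressure_mmHg,
                 scale_factor = scale_factor, seed = as.integer(seed),
                 n_incr_crimp = as.integer(n_incr_crimp),
                 n_incr_pressure = as.integer(n_incr_pressure),
                 max_iter = as.integer(max_iter), tol = tol,
                 perturbation = perturbation,
                 contact_penalty_scale = contact_penalty_scale,
                 compression_retention = compression_retention,
                 bending_scale = bending_scale,
                 pressure_mode = pressure_mode),
            class = "crimp_loadcase")
}

#' @export
print.crimp_loadcase <- function(x, ...) {
  cat(sprintf("<crimp_loadcase>  oversizing %g%%, pressure %g mmHg, scale %g, seed %d\n",
              x$oversizing, x$pressure_mmHg, x$scale_factor, x$seed))
  invisible(x)
}
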