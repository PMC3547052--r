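#' Section properties of a solid circular beam
#'
#' Closed-form area and moments for a solid circular cross section:
#' area \eqn{A = \pi d^2/4}, second moment of area \eqn{I = \pi d^4/64}
#' (identical about both transverse axes), and polar moment
#' \eqn{J = 2I = \pi d^4/32}. These govern axial, bending and torsional
#' stiffness of the frame elements.
#'
#' @param d Beam diameter (mm).
#' @return An object of class `circular_section`: a list with `diameter`,
#'   `area` (mm^2), `I` (mm^4) and `J` (mm^4).
#' @examples
#' circular_section_properties(0.05)
#' @export
circular_section_properties <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("beam diameter must be a single positive number", call. = FALSE)
  I <- pi * d^4 / 64
  structure(
    list(diameter = d, area = pi * d^2 / 4, I = I, J = 2 * I),
    class = "circular_section"
  )
}

#' @export
print.circular_section <- function(x, ...) {
  cat(sprintf(
    "circular section: d = %g mm, A = %g mm^2, I = %g mm^4, J = %g mm^4\n",
    x$diameter, x$area, x$I, x$J
  ))
  invisible(x)
}

#' Isotropic linear-elastic material
#'
#' Defaults are the structural-steel properties used for all beam models:
#' the absolute values are arbitrary because the analyses are comparative
#' and linear, so strains scale trivially to any other modulus.
#'
#' @param elastic_modulus Young's modulus E (MPa).
#' @param poisson_ratio Poisson's ratio (dimensionless, in (-1, 0.5)).
#' @param density Density (g/cm^3); used only for frame mass.
#' @return An object of class `material`: list with `E`, `nu`, `rho` and the
#'   derived shear modulus `G = E / (2 (1 + nu))` (MPa).
#' @examples
#' material()$G  # 80000 MPa for steel defaults
#' @export
material <- function(elastic_modulus = 200000, poisson_ratio = 0.25,
                     density = 7.87) {
  if (!is.finite(elastic_modulus) || elastic_modulus <= 0)
    stop("elastic_modulus must be positive", call. = FALSE)
  if (!is.finite(poisson_ratio) || poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (-1, 0.5)", call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  structure(
    list(E = elastic_modulus, nu = poisson_ratio, rho = density,
         G = elastic_modulus / (2 * (1 + poisson_ratio))),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("material: E = %g MPa, nu = %g, G = %g MPa, rho = %g g/cm^3\n",
              x$E, x$nu, x$G, x$rho))
  invisible(x)
}
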