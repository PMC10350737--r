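# Material model constructors and (de)serialisation.
#
# All stiffness quantities are in MPa.  Compression convention throughout the
# package: applied pressure is positive, axial stretch lambda < 1, nominal
# stress (first Piola) is negative in compression, reported displacements are
# positive compression magnitudes in micrometres.

#' Linear elastic cartilage material
#'
#' Isotropic linear elastic material used as the simplest cartilage
#' approximation.  The Young's modulus is normally obtained as the gradient of
#' a quasi-static nominal stress--strain ramp curve ([fit_material()]); the
#' Poisson's ratio defaults to the literature value used for cartilage in this
#' loading regime.
#'
#' @param youngs_modulus Young's modulus, MPa (> 0).
#' @param poisson_ratio Poisson's ratio, dimensionless, in (0, 0.5).
#' @param label Optional label carried through reports.
#' @return An object of class `c("elastic_material", "cartilage_material")`.
#' @examples
#' elastic_material(2.9, 0.45)
#' @export
elastic_material <- function(youngs_modulus, poisson_ratio = 0.45, label = NULL) {
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1L,
            is.numeric(poisson_ratio), length(poisson_ratio) == 1L)
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("'youngs_modulus' must be a positive finite number (MPa)")
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("'poisson_ratio' must lie strictly between 0 and 0.5")
  structure(
    list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio,
         label = label %||% "linear"),
    class = c("elastic_material", "cartilage_material"))
}

#' Incompressible Neo-Hookean cartilage material
#'
#' One-parameter hyperelastic law `W = C10 (I1bar - 3)` under the standard
#' convention, where `I1bar = lambda1^2 + lambda2^2 + lambda3^2` for a
#' volume-preserving deformation, so the initial shear modulus is `2 * C10`.
#' Some sources write the same law as `W = (C10 / 2) (I1bar - 3)` in which
#' case `C10` itself is the initial shear modulus; that reading is available
#' as `convention = "paper_eq2"`.  Every stress output differs by exactly a
#' factor two between the two conventions.
#'
#' @param c10 Stiffness constant C10, MPa (> 0).
#' @param convention `"standard_c10"` (default, `mu0 = 2 C10`) or
#'   `"paper_eq2"` (`mu0 = C10`).
#' @param label Optional label carried through reports.
#' @return An object of class `c("neo_hookean_material", "cartilage_material")`.
#' @examples
#' neo_hookean_material(4.89)
#' @export
neo_hookean_material <- function(c10, convention = c("standard_c10", "paper_eq2"),
                                 label = NULL) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(c10), length(c10) == 1L)
  if (!is.finite(c10) || c10 <= 0) stop("'c10' must be a positive finite number (MPa)")
  structure(
    list(c10 = c10, convention = convention, label = label %||% "neo_hookean"),
    class = c("neo_hookean_material", "cartilage_material"))
}

#' Incompressible Ogden cartilage material
#'
#' N-term Ogden strain energy in the standard incompressible form
#' \deqn{W = \sum_i \frac{2\mu_i}{\alpha_i^2}
#'           (\lambda_1^{\alpha_i} + \lambda_2^{\alpha_i} +
#'            \lambda_3^{\alpha_i} - 3),}
#' the form produced by common finite-element material-evaluation tools.
#' Individual moduli may be negative (reference femoral-head constants have
#' `mu1 < 0`); the initial shear modulus is `sum(mu)`.  Third order
#' (`length(mu) == 3`) is the configuration used throughout the package, but
#' any order is accepted.
#'
#' @param mu Moduli, MPa (signed), one per term.
#' @param alpha Exponents, dimensionless, nonzero, same length as `mu`.
#' @param label Optional label carried through reports.
#' @return An object of class `c("ogden_material", "cartilage_material")`.
#' @examples
#' ogden_material(mu = c(-26.133, 12.922, 13.227), alpha = c(2.719, 3.996, 1.504))
#' @export
ogden_material <- function(mu, alpha, label = NULL) {
  stopifnot(is.numeric(mu), is.numeric(alpha))
  if (length(mu) != length(alpha) || length(mu) < 1L)
    stop("'mu' and 'alpha' must be non-empty vectors of equal length")
  if (any(!is.finite(mu)) || any(!is.finite(alpha)))
    stop("Ogden constants must be finite")
  if (any(alpha == 0)) stop("all 'alpha' exponents must be nonzero")
  structure(
    list(mu = as.numeric(mu), alpha = as.numeric(alpha), label = label %||% "ogden3"),
    class = c("ogden_material", "cartilage_material"))
}

#' Reference regional Neo-Hookean constants for femoral-head cartilage
#'
#' The four regional C10 constants (MPa) for human femoral-head articular
#' cartilage taken from the patient-specific modelling literature, used to
#' instantiate the Neo-Hookean models of the reference study.
#'
#' @return Named numeric vector of C10 values, MPa.
#' @export
neo_hookean_regional_c10 <- function() {
  c(anterior = 4.89, posterior = 5.48, medial = 5.13, lateral = 4.48)
}

#' Reference third-order Ogden constants for femoral-head cartilage
#'
#' The canonical third-order Ogden constant set fitted to quasi-static
#' compression of human femoral-head cartilage (moduli interpreted in Pa in
#' the source table and converted to MPa here; exponents dimensionless).
#'
#' @return An [ogden_material()].
#' @export
ogden_reference_material <- function() {
  ogden_material(mu = c(-26.133, 12.922, 13.227),
                 alpha = c(2.719, 3.996, 1.504),
                 label = "ogden3_reference")
}

#' @export
print.cartilage_material <- function(x, ...) {
  cat("<cartilage material:", class(x)[1L], ">\n")
  if (inherits(x, "elastic_material"))
    cat(sprintf("  E = %.4g MPa, nu = %.3g\n", x$youngs_modulus, x$poisson_ratio))
  if (inherits(x, "neo_hookean_material"))
    cat(sprintf("  C10 = %.4g MPa (%s, mu0 = %.4g MPa)\n",
                x$c10, x$convention, initial_shear_modulus(x)))
  if (inherits(x, "ogden_material")) {
    cat(sprintf("  %d-term Ogden, mu0 = %.4g MPa\n", length(x$mu),
                initial_shear_modulus(x)))
    cat("  mu    (MPa):", paste(signif(x$mu, 6), collapse = ", "), "\n")
    cat("  alpha      :", paste(signif(x$alpha, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialise a material to a configuration list
#'
#' Converts a material to the plain-list form used in the structured-text
#' (YAML) run configuration, with units stated explicitly.  The inverse is
#' [material_from_config()].
#'
#' @param model A `cartilage_material`.
#' @return A named list with a `type` field.
#' @export
material_to_config <- function(model) {
  stopifnot(inherits(model, "cartilage_material"))
  if (inherits(model, "elastic_material"))
    list(type = "linear", youngs_modulus_MPa = model$youngs_modulus,
         poisson_ratio = model$poisson_ratio)
  else if (inherits(model, "neo_hookean_material"))
    list(type = "neo_hookean", c10_MPa = model$c10, convention = model$convention)
  else
    list(type = "ogden3", mu_MPa = model$mu, alpha = model$alpha)
}

#' Deserialise a material from a configuration list
#'
#' @param config A list as produced by [material_to_config()] or read from a
#'   YAML config block; must contain `type` among `"linear"`,
#'   `"neo_hookean"`, `"ogden3"`.
#' @return A `cartilage_material`.
#' @export
material_from_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$type))
  switch(config$type,
    linear = elastic_material(config$youngs_modulus_MPa,
                              config$poisson_ratio %||% 0.45),
    neo_hookean = neo_hookean_material(config$c10_MPa,
                                       config$convention %||% "standard_c10"),
    ogden3 = ogden_material(unlist(config$mu_MPa), unlist(config$alpha)),
    stop("unknown material type: ", config$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
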