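# Strain-energy functions, closed-form nominal stresses along the two
# idealised uniaxial paths, small-strain moduli, and Drucker stability
# screening.
#
# Both hyperelastic laws are treated as exactly incompressible here
# (lambda1 * lambda2 * lambda3 = 1); the finite-element module uses a
# near-incompressible penalty instead.

check_stretches <- function(stretches) {
  if (!is.numeric(stretches) || length(stretches) != 3L)
    stop("'stretches' must be a numeric vector of three principal stretches")
  if (any(!is.finite(stretches)) || any(stretches <= 0))
    stop("principal stretches must be positive and finite")
  stretches
}

#' Strain energy density
#'
#' Evaluates the stored energy per unit reference volume at a principal
#' stretch triple.  For the incompressible hyperelastic laws the caller is
#' expected to supply a volume-preserving triple; the energy of the isochoric
#' form is evaluated at the stretches as given.  For the linear elastic
#' material the isotropic small-strain quadratic energy in the principal
#' strains `lambda - 1` is used.
#'
#' @param model A `cartilage_material`.
#' @param stretches Numeric length-3 vector of principal stretches (> 0).
#' @return Energy density, MPa (= MJ/m^3); exactly 0 at the identity.
#' @examples
#' strain_energy(ogden_reference_material(), c(0.8, 0.8^-0.5, 0.8^-0.5))
#' @export
strain_energy <- function(model, stretches) UseMethod("strain_energy")

#' @export
strain_energy.elastic_material <- function(model, stretches) {
  e <- check_stretches(stretches) - 1
  E <- model$youngs_modulus; nu <- model$poisson_ratio
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  0.5 * lam * sum(e)^2 + mu * sum(e^2)
}

#' @export
strain_energy.neo_hookean_material <- function(model, stretches) {
  l <- check_stretches(stretches)
  c10 <- if (model$convention == "standard_c10") model$c10 else model$c10 / 2
  c10 * (sum(l^2) - 3)
}

#' @export
strain_energy.ogden_material <- function(model, stretches) {
  l <- check_stretches(stretches)
  sum(2 * model$mu / model$alpha^2 *
        (l[1]^model$alpha + l[2]^model$alpha + l[3]^model$alpha - 3))
}

check_lambda <- function(lam_axial) {
  if (!is.numeric(lam_axial) || any(!is.finite(lam_axial)) || any(lam_axial <= 0))
    stop("axial stretch must be positive and finite")
  lam_axial
}

#' Nominal stress along the idealised homogeneous deformation paths
#'
#' Closed-form axial nominal (first Piola) stress as a function of the axial
#' stretch for the two deformation modes that bracket the platen boundary
#' conditions of the compression experiment:
#' \describe{
#'   \item{`uniaxial_free`}{laterally unconstrained uniaxial stress; for the
#'     incompressible laws `lambda_lat = lambda^(-1/2)`, for the linear law
#'     the modulus is `E`.}
#'   \item{`lateral_locked`}{in-plane lateral motion suppressed
#'     (`lambda_x = 1`) with the out-of-plane direction stress-free
#'     (`lambda_z = 1/lambda` for the incompressible laws); the linear-law
#'     effective modulus is the plane-stress locked modulus `E/(1 - nu^2)`.}
#' }
#' Compression gives negative stress.  `uniaxial_nominal_stress()` and
#' `constrained_nominal_stress()` are fixed-mode wrappers.
#'
#' @param model A `cartilage_material`.
#' @param lam_axial Axial stretch(es), > 0 (vectorised).
#' @param mode `"uniaxial_free"` or `"lateral_locked"`.
#' @return Nominal stress, MPa; 0 at `lam_axial = 1`.
#' @examples
#' uniaxial_nominal_stress(neo_hookean_material(4.89), 0.99)
#' @export
nominal_stress <- function(model, lam_axial,
                           mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  l <- check_lambda(lam_axial)
  UseMethod("nominal_stress")
}

#' @export
nominal_stress.elastic_material <- function(model, lam_axial,
                                            mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  l <- check_lambda(lam_axial)
  E <- model$youngs_modulus
  E_eff <- if (mode == "uniaxial_free") E else E / (1 - model$poisson_ratio^2)
  E_eff * (l - 1)
}

#' @export
nominal_stress.neo_hookean_material <- function(model, lam_axial,
                                                mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  l <- check_lambda(lam_axial)
  mu0 <- initial_shear_modulus(model)
  if (mode == "uniaxial_free") mu0 * (l - l^-2) else mu0 * (l - l^-3)
}

#' @export
nominal_stress.ogden_material <- function(model, lam_axial,
                                          mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  l <- check_lambda(lam_axial)
  mu <- model$mu; al <- model$alpha
  lat_exp <- if (mode == "uniaxial_free") -al / 2 - 1 else -al - 1
  vapply(l, function(x) sum(2 * mu / al * (x^(al - 1) - x^lat_exp)), numeric(1))
}

#' @rdname nominal_stress
#' @export
uniaxial_nominal_stress <- function(model, lam_axial)
  nominal_stress(model, lam_axial, "uniaxial_free")

#' @rdname nominal_stress
#' @export
constrained_nominal_stress <- function(model, lam_axial)
  nominal_stress(model, lam_axial, "lateral_locked")

#' Tangent of the nominal stress along a deformation path
#'
#' Closed-form derivative `dP/dlambda` of [nominal_stress()]; at the identity
#' this equals `3 mu0` (uniaxial free) or `4 mu0` (lateral locked) for the
#' incompressible hyperelastic laws.
#'
#' @inheritParams nominal_stress
#' @return Tangent modulus, MPa.
#' @export
nominal_tangent <- function(model, lam_axial,
                            mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  l <- check_lambda(lam_axial)
  if (inherits(model, "elastic_material")) {
    E_eff <- if (mode == "uniaxial_free") model$youngs_modulus else
      model$youngs_modulus / (1 - model$poisson_ratio^2)
    return(rep(E_eff, length(l)))
  }
  if (inherits(model, "neo_hookean_material")) {
    mu0 <- initial_shear_modulus(model)
    return(if (mode == "uniaxial_free") mu0 * (1 + 2 * l^-3) else mu0 * (1 + 3 * l^-4))
  }
  mu <- model$mu; al <- model$alpha
  lat_exp <- if (mode == "uniaxial_free") -al / 2 - 1 else -al - 1
  vapply(l, function(x)
    sum(2 * mu / al * ((al - 1) * x^(al - 2) - lat_exp * x^(lat_exp - 1))),
    numeric(1))
}

#' Initial (small-strain) shear modulus
#'
#' `E / (2 (1 + nu))` for the linear material; `2 C10` (standard convention)
#' or `C10` (shear-modulus convention) for Neo-Hookean; `sum(mu)` for the
#' standard-form Ogden material.
#'
#' @param model A `cartilage_material`.
#' @return Shear modulus, MPa.
#' @examples
#' initial_shear_modulus(elastic_material(2.9, 0.45))  # 1 MPa
#' @export
initial_shear_modulus <- function(model) UseMethod("initial_shear_modulus")

#' @export
initial_shear_modulus.elastic_material <- function(model)
  model$youngs_modulus / (2 * (1 + model$poisson_ratio))

#' @export
initial_shear_modulus.neo_hookean_material <- function(model)
  if (model$convention == "standard_c10") 2 * model$c10 else model$c10

#' @export
initial_shear_modulus.ogden_material <- function(model) sum(model$mu)

# Reduced incompressible energy in principal logarithmic strain coordinates
# (e1, e2), with e3 = -e1 - e2.  Drucker stability for arbitrary
# incompressible increments is positive definiteness of its 2x2 Hessian.
reduced_log_energy <- function(model, e1, e2)
  strain_energy(model, exp(c(e1, e2, -e1 - e2)))

reduced_hessian_mineig <- function(model, e1, e2, h = 1e-5) {
  f <- function(a, b) reduced_log_energy(model, a, b)
  f0 <- f(e1, e2)
  h11 <- (f(e1 + h, e2) - 2 * f0 + f(e1 - h, e2)) / h^2
  h22 <- (f(e1, e2 + h) - 2 * f0 + f(e1, e2 - h)) / h^2
  h12 <- (f(e1 + h, e2 + h) - f(e1 + h, e2 - h) -
          f(e1 - h, e2 + h) + f(e1 - h, e2 - h)) / (4 * h^2)
  m <- (h11 + h22) / 2
  m - sqrt(((h11 - h22) / 2)^2 + h12^2)
}

#' Drucker stability screening along a homogeneous deformation path
#'
#' Scans axial stretch states along an idealised deformation path and tests
#' the Drucker (material stability) condition that every incompressible
#' strain increment does positive incremental work, i.e. that the Hessian of
#' the strain energy in principal logarithmic strains, reduced to the
#' incompressible plane, is positive definite.  This covers increments in
#' arbitrary directions, not only along the loading path, which is how
#' finite-element material evaluators screen hyperelastic constant sets.
#'
#' The linear elastic material (positive modulus, Poisson's ratio below 0.5)
#' and any Neo-Hookean material with positive C10 are globally stable; Ogden
#' constant sets with mixed-sign moduli can destabilise.
#'
#' @param model A `cartilage_material`.
#' @param lam_range Length-2 stretch interval to scan (default `c(0.5, 1.5)`).
#' @param n_scan Number of scan states (>= 2, default 1000).
#' @param mode Deformation path along which states are scanned.
#' @return A data frame with one row per violating sub-interval (columns
#'   `lam_from`, `lam_to`, `min_eigenvalue` in MPa); zero rows when the model
#'   is stable everywhere on the scanned grid.  Attribute `"min_eigenvalue"`
#'   carries the overall minimum.
#' @examples
#' nrow(drucker_stability(neo_hookean_material(4.89)))  # 0: globally stable
#' @export
drucker_stability <- function(model, lam_range = c(0.5, 1.5), n_scan = 1000,
                              mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  stopifnot(length(lam_range) == 2L, all(is.finite(lam_range)),
            all(lam_range > 0), n_scan >= 2)
  lam <- seq(min(lam_range), max(lam_range), length.out = n_scan)
  if (inherits(model, "elastic_material") || inherits(model, "neo_hookean_material")) {
    # globally Drucker-stable by construction (validated positive moduli)
    out <- data.frame(lam_from = numeric(0), lam_to = numeric(0),
                      min_eigenvalue = numeric(0))
    attr(out, "min_eigenvalue") <- NA_real_
    return(out)
  }
  me <- vapply(lam, function(x) {
    e1 <- log(x)
    e2 <- if (mode == "uniaxial_free") -e1 / 2 else 0
    reduced_hessian_mineig(model, e1, e2)
  }, numeric(1))
  bad <- me <= 0
  out <- if (!any(bad)) {
    data.frame(lam_from = numeric(0), lam_to = numeric(0),
               min_eigenvalue = numeric(0))
  } else {
    r <- rle(bad)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(lam_from = lam[starts[keep]], lam_to = lam[ends[keep]],
               min_eigenvalue = vapply(keep, function(k)
                 min(me[starts[k]:ends[k]]), numeric(1)))
  }
  attr(out, "min_eigenvalue") <- min(me)
  out
}
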