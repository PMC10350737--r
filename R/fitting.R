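# Calibration of material models from quasi-static stress-strain ramp
# curves: ordinary least squares for the linear law, one-dimensional
# optimisation for Neo-Hookean, seeded multi-start Levenberg-Marquardt for
# the third-order Ogden law, with Drucker stability screening of the result.

#' Quasi-static stress--strain curve
#'
#' Nominal strain (dimensionless) and nominal stress (MPa) samples from a
#' compressive ramp test, both stored compression-positive.  Internally
#' strains are converted to stretches `lambda = 1 - strain`.
#'
#' @param strain Nominal compressive strain, strictly increasing, first
#'   sample at or near zero.
#' @param stress Nominal compressive stress, MPa.
#' @param specimen_id Optional identifier.
#' @return Data frame of class `"stress_strain_curve"`.
#' @export
stress_strain_curve <- function(strain, stress, specimen_id = NA_character_) {
  stopifnot(is.numeric(strain), is.numeric(stress),
            length(strain) == length(stress), length(strain) >= 2)
  if (any(diff(strain) <= 0)) stop("'strain' must be strictly increasing")
  if (strain[1] > 0.02) stop("first sample must be at or near zero strain")
  if (any(strain >= 1)) stop("compressive strain must be below 1")
  structure(data.frame(strain = strain, stress = stress),
            specimen_id = specimen_id,
            class = c("stress_strain_curve", "data.frame"))
}

#' Read a stress--strain curve from delimited text
#'
#' Accepts either a two-column file (`strain`, `stress_MPa`) or a raw test
#' log (`time_s`, `force_N`, `displacement_um`) together with the specimen
#' geometry, which is converted via [stress_from_force()] and the thickness.
#'
#' @param file Path to a tab- or comma-delimited file with a header.
#' @param diameter,thickness Specimen geometry (mm), required for the raw
#'   force--displacement format.
#' @return A [stress_strain_curve()].
#' @export
read_stress_strain <- function(file, diameter = NULL, thickness = NULL) {
  d <- utils::read.table(file, header = TRUE, sep = "", dec = ".",
                         stringsAsFactors = FALSE)
  if (ncol(d) == 1) d <- utils::read.table(file, header = TRUE, sep = ",")
  nm <- tolower(names(d))
  if (all(c("strain", "stress_mpa") %in% nm)) {
    stress_strain_curve(d[[which(nm == "strain")]], d[[which(nm == "stress_mpa")]])
  } else if (all(c("force_n", "displacement_um") %in% nm)) {
    if (is.null(diameter) || is.null(thickness))
      stop("raw force-displacement input needs 'diameter' and 'thickness' (mm)")
    stress_strain_curve(d[[which(nm == "displacement_um")]] / 1000 / thickness,
                        stress_from_force(d[[which(nm == "force_n")]], diameter))
  } else stop("unrecognised curve columns: ", paste(names(d), collapse = ", "))
}

# Compression-positive model stress at the curve's stretches.
model_curve_stress <- function(model, strain, mode = "uniaxial_free")
  -nominal_stress(model, 1 - strain, mode)

fit_objective <- function(pred, obs, objective, keep) {
  r <- if (objective == "relative") (pred[keep] - obs[keep]) / obs[keep]
  else pred[keep] - obs[keep]
  sum(r^2)
}

#' Fit a material model to a stress--strain ramp curve
#'
#' The single calibration entry point.  `model = "linear"` performs ordinary
#' least squares of stress on strain (the gradient is the Young's modulus;
#' Poisson's ratio is fixed at 0.45).  `model = "neo_hookean"` minimises the
#' fitting objective over C10 against the uniaxial incompressible closed
#' form.  `model = "ogden3"` runs seeded multi-start nonlinear least squares
#' (Levenberg--Marquardt) over the six Ogden constants; because the Ogden
#' parametrisation is degenerate, recovery is judged in stress space, and the
#' result additionally carries a Drucker stability flag over the curve's
#' stretch range (reported, never enforced).
#'
#' The default objective is relative-error least squares,
#' `sum(((P_model - P_data)/P_data)^2)`, excluding near-zero-stress samples
#' (|stress| below 1% of the maximum); `objective = "absolute"` uses plain
#' residuals.
#'
#' @param curve A [stress_strain_curve()].
#' @param model `"linear"`, `"neo_hookean"` or `"ogden3"`.
#' @param objective `"relative"` (default) or `"absolute"`.
#' @param seed RNG seed for the multi-start draws (mandatory for `"ogden3"`).
#' @param n_starts Number of random starts for `"ogden3"` (default 32).
#' @param poisson_ratio Poisson's ratio assigned to linear fits.
#' @param convention Neo-Hookean convention for the fitted constant.
#' @return Object of class `"material_fit"`: the fitted
#'   `cartilage_material`, objective value, residuals, stability screen and
#'   fit diagnostics.
#' @examples
#' cv <- stress_strain_curve(seq(0, 0.3, 0.02), 2 * seq(0, 0.3, 0.02))
#' coef(fit_material(cv, "linear"))
#' @export
fit_material <- function(curve, model = c("linear", "neo_hookean", "ogden3"),
                         objective = c("relative", "absolute"), seed = 1L,
                         n_starts = 32L, poisson_ratio = 0.45,
                         convention = "standard_c10") {
  model <- match.arg(model); objective <- match.arg(objective)
  stopifnot(inherits(curve, "stress_strain_curve"))
  strain <- curve$strain; stress <- curve$stress
  if (max(abs(stress)) == 0 && model != "linear")
    stop("curve carries no stress signal; nothing to fit")
  keep <- abs(stress) >= 0.01 * max(abs(stress))
  fitted_model <- NULL; obj <- NA_real_; diag <- list()

  if (model == "linear") {
    if (diff(range(strain)) <= 0) stop("degenerate curve: zero strain span")
    # least-squares secant slope: the nominal curve passes through the
    # origin, so the linear approximation is fitted without an intercept
    E <- sum(stress * strain) / sum(strain^2)
    if (!is.finite(E) || E <= 0) stop("linear fit produced a non-positive modulus")
    fitted_model <- elastic_material(E, poisson_ratio, label = "linear_fit")
    pred <- model_curve_stress(fitted_model, strain)
    obj <- fit_objective(pred, stress, objective, keep)
    diag <- list(starts = 1L, converged = 1L)
  } else if (model == "neo_hookean") {
    f <- function(c10) {
      m <- neo_hookean_material(c10, convention)
      fit_objective(model_curve_stress(m, strain), stress, objective, keep)
    }
    ratio <- stress[keep] / strain[keep]
    sec <- max(ratio[is.finite(ratio)], 1e-3)
    opt <- stats::optimize(f, c(1e-6, 50 * sec))
    fitted_model <- neo_hookean_material(opt$minimum, convention,
                                         label = "neo_hookean_fit")
    obj <- opt$objective
    diag <- list(starts = 1L, converged = 1L)
  } else {
    if (length(strain) < 8 || diff(range(strain)) < 0.10)
      stop("ogden3 fit needs >= 8 samples spanning >= 10% strain")
    res <- fit_ogden3_multistart(strain, stress, objective, keep, seed, n_starts)
    if (is.null(res$par))
      stop("all ", n_starts, " Ogden starts failed to converge")
    fitted_model <- ogden_material(res$par[1:3], res$par[4:6],
                                   label = "ogden3_fit")
    obj <- res$objective
    diag <- list(starts = as.integer(n_starts), converged = res$n_converged)
  }

  pred <- model_curve_stress(fitted_model, strain)
  lam_range <- range(1 - strain)
  stab <- drucker_stability(fitted_model, lam_range, n_scan = 400)
  structure(list(
    model = fitted_model, objective = obj, residuals = pred - stress,
    fitted = pred, curve = curve, stable = nrow(stab) == 0,
    stability = stab, diagnostics = diag, fit_type = model,
    objective_type = objective),
    class = "material_fit")
}

# Multi-start Levenberg-Marquardt for the 3-term Ogden law.  Starts draw
# alpha log-uniform on [0.5, 8] with random signs on mu, scaled so the
# small-strain uniaxial tangent 3*sum(mu) matches the curve's secant modulus.
fit_ogden3_multistart <- function(strain, stress, objective, keep, seed,
                                  n_starts) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ratio <- stress[keep] / strain[keep]
  sec <- max(ratio[is.finite(ratio)], 1e-3)
  resid_fn <- function(par) {
    m <- tryCatch(ogden_material(par[1:3], par[4:6]), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, sum(keep)))
    pred <- tryCatch(model_curve_stress(m, strain), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e6, sum(keep)))
    if (objective == "relative") (pred[keep] - stress[keep]) / stress[keep]
    else pred[keep] - stress[keep]
  }
  best <- list(par = NULL, objective = Inf, n_converged = 0L)
  for (s in seq_len(n_starts)) {
    alpha <- exp(stats::runif(3, log(0.5), log(8)))
    w <- stats::runif(3, 0.2, 1) * sample(c(-1, 1), 3, replace = TRUE)
    if (abs(sum(w)) < 0.1) w <- abs(w)          # avoid a near-zero modulus sum
    mu <- w * (sec / 3) / sum(w)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(mu, alpha), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(resid_fn(fit$par)^2)
    if (is.finite(obj)) {
      best$n_converged <- best$n_converged + 1L
      if (obj < best$objective) best[c("par", "objective")] <- list(fit$par, obj)
    }
  }
  best
}

#' @export
print.material_fit <- function(x, ...) {
  cat(sprintf("<material fit: %s> objective %.4g (%s), %s\n", x$fit_type,
              x$objective, x$objective_type,
              if (x$stable) "Drucker-stable over the fitted range"
              else "UNSTABLE over the fitted range"))
  print(x$model)
  invisible(x)
}

#' @export
summary.material_fit <- function(object, ...) {
  rmse <- sqrt(mean(object$residuals^2))
  cat(sprintf("Material fit (%s) to specimen %s\n", object$fit_type,
              attr(object$curve, "specimen_id")))
  cat(sprintf("  samples: %d, strain span: %.3f\n", nrow(object$curve),
              diff(range(object$curve$strain))))
  cat(sprintf("  objective: %.6g (%s), stress RMSE: %.4g MPa\n",
              object$objective, object$objective_type, rmse))
  cat(sprintf("  starts: %d, converged: %d\n", object$diagnostics$starts,
              object$diagnostics$converged))
  cat(sprintf("  Drucker stability over fitted range: %s\n",
              if (object$stable) "stable" else "VIOLATED"))
  print(object$model)
  invisible(object)
}

#' @export
coef.material_fit <- function(object, ...) {
  m <- object$model
  if (inherits(m, "elastic_material"))
    c(youngs_modulus = m$youngs_modulus, poisson_ratio = m$poisson_ratio)
  else if (inherits(m, "neo_hookean_material")) c(c10 = m$c10)
  else c(stats::setNames(m$mu, paste0("mu", seq_along(m$mu))),
         stats::setNames(m$alpha, paste0("alpha", seq_along(m$alpha))))
}

#' @export
predict.material_fit <- function(object, newdata = NULL, ...) {
  strain <- if (is.null(newdata)) object$curve$strain
  else if (is.data.frame(newdata)) newdata$strain else newdata
  model_curve_stress(object$model, strain)
}

#' @export
residuals.material_fit <- function(object, ...) object$residuals

#' @export
plot.material_fit <- function(x, ...) {
  plot(x$curve$strain, x$curve$stress, pch = 16, cex = 0.6,
       xlab = "nominal strain (compression +)",
       ylab = "nominal stress (MPa)", ...)
  s <- seq(min(x$curve$strain), max(x$curve$strain), length.out = 200)
  graphics::lines(s, model_curve_stress(x$model, pmax(s, 0)), col = 2, lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("data", paste0("fit (", x$fit_type, ")")),
                   pch = c(16, NA), lty = c(NA, 1), col = c(1, 2))
  invisible(x)
}
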