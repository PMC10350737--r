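# Synthetic specimen cohorts: geometry, quasi-static ramp curves and DMA
# displacement traces with the statistical structure of the physical model
# and validation datasets, so the whole pipeline is testable without any
# experimental download.

#' Ground truth for synthetic cohort generation
#'
#' Parameterises the synthetic data generator: the generating material, the
#' between-specimen thickness distribution (truncated normal), a log-normal
#' multiplicative stiffness heterogeneity applied uniformly to all moduli,
#' additive measurement noise, and an optional loss-tangent phase lag
#' `delta` applied to the cyclic displacement of DMA traces.  The phase lag
#' is a synthetic-only device: the constitutive models in this package are
#' elastic, and `delta` exists so that hysteresis metrics have a non-trivial
#' test surface mirroring experimental loops.
#'
#' @param material Generating `cartilage_material`.
#' @param thickness_mean,thickness_sd Cartilage thickness distribution, mm
#'   (defaults 1.305 and 0.25; draws truncated below at 0.3 mm).
#' @param stiffness_sdlog SD of the log-normal per-specimen stiffness factor
#'   (0 for a homogeneous cohort).
#' @param noise_sd_stress Additive stress noise on ramp curves, MPa.
#' @param noise_sd_um Additive displacement noise on traces/curves, µm.
#' @param delta Loss-tangent phase lag for DMA traces, radians in [0, pi/2).
#' @param seed Base RNG seed (mandatory for reproducibility).
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth <- function(material, thickness_mean = 1.305, thickness_sd = 0.25,
                         stiffness_sdlog = 0, noise_sd_stress = 0,
                         noise_sd_um = 0, delta = 0, seed = 42L) {
  stopifnot(inherits(material, "cartilage_material"),
            thickness_mean > 0, thickness_sd >= 0, stiffness_sdlog >= 0,
            noise_sd_stress >= 0, noise_sd_um >= 0,
            delta >= 0, delta < pi / 2)
  structure(list(material = material, thickness_mean = thickness_mean,
                 thickness_sd = thickness_sd, stiffness_sdlog = stiffness_sdlog,
                 noise_sd_stress = noise_sd_stress, noise_sd_um = noise_sd_um,
                 delta = delta, seed = as.integer(seed)),
            class = "ground_truth")
}

scale_material <- function(material, factor) {
  if (inherits(material, "elastic_material"))
    elastic_material(material$youngs_modulus * factor, material$poisson_ratio)
  else if (inherits(material, "neo_hookean_material"))
    neo_hookean_material(material$c10 * factor, material$convention)
  else ogden_material(material$mu * factor, material$alpha)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic specimen cohort
#'
#' Draws per-specimen geometry and heterogeneity for `n` cartilage discs:
#' 8 mm diameter, thickness from a truncated normal (> 0.3 mm), a log-normal
#' multiplicative stiffness factor (unit mean), and donor metadata (age,
#' sex, weight class) carried for realism but unused in computation.  Fully
#' deterministic for a fixed `truth$seed`.
#'
#' @param n Number of specimens (>= 1).
#' @param cohort `"model"` or `"validation"`.
#' @param truth A [ground_truth()].
#' @return Data frame of class `"specimen_cohort"`: columns `id`,
#'   `diameter_mm`, `thickness_mm`, `cohort`, `stiffness_factor`,
#'   `age`, `sex`, `weight_class`.
#' @examples
#' generate_cohort(6, "validation", default_validation_truth())
#' @export
generate_cohort <- function(n, cohort = c("model", "validation"), truth) {
  cohort <- match.arg(cohort)
  stopifnot(n >= 1, inherits(truth, "ground_truth"))
  with_seed(truth$seed + ifelse(cohort == "model", 0L, 1L) * 1000003L, {
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        t_i <- stats::rnorm(1, truth$thickness_mean, truth$thickness_sd)
        if (t_i > 0.3) break
      }
      th[i] <- t_i
    }
    sf <- if (truth$stiffness_sdlog > 0)
      stats::rlnorm(n, meanlog = -truth$stiffness_sdlog^2 / 2,
                    sdlog = truth$stiffness_sdlog) else rep(1, n)
    structure(data.frame(
      id = sprintf("%s%02d", toupper(substr(cohort, 1, 1)), seq_len(n)),
      diameter_mm = 8, thickness_mm = th, cohort = cohort,
      stiffness_factor = sf,
      age = sample(55:90, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      weight_class = sample(c("NW", "OW"), n, replace = TRUE),
      stringsAsFactors = FALSE),
      truth = truth, class = c("specimen_cohort", "data.frame"))
  })
}

#' Generate a synthetic quasi-static ramp curve for a specimen
#'
#' Emulates the ramp test: force sampled at the given load rate up to the
#' target force, converted to nominal stress on the specimen's face, with
#' strain from the homogeneous uniaxial closed form under the specimen's
#' stiffness-perturbed material, plus additive measurement noise.  With all
#' noise zero the oracle is reproduced exactly.
#'
#' @param specimen One row of a [generate_cohort()] data frame.
#' @param truth The [ground_truth()].
#' @param force_max Peak ramp force, N (default 61.6, giving the mean
#'   physiological pressure on an 8 mm disc).
#' @param load_rate Load rate, N/s (default 3).
#' @param sample_interval Sampling interval, s (default 0.25).
#' @return A [stress_strain_curve()].
#' @export
generate_ramp_curve <- function(specimen, truth, force_max = 61.6,
                                load_rate = 3, sample_interval = 0.25) {
  stopifnot(inherits(truth, "ground_truth"), nrow(specimen) == 1)
  if (!is.finite(specimen$thickness_mm) || specimen$thickness_mm <= 0)
    stop("specimen thickness must be positive")
  force <- seq(0, force_max, by = load_rate * sample_interval)
  if (force[length(force)] < force_max) force <- c(force, force_max)
  stress <- stress_from_force(force, specimen$diameter_mm)
  mat <- scale_material(truth$material, specimen$stiffness_factor)
  strain <- vapply(stress, function(p)
    1 - solve_stretch(mat, p, "uniaxial_free"), numeric(1))
  with_seed(truth$seed + 7L * specimen_index(specimen), {
    if (truth$noise_sd_um > 0)
      strain <- strain + stats::rnorm(length(strain), 0,
                                      truth$noise_sd_um / 1000 / specimen$thickness_mm)
    if (truth$noise_sd_stress > 0)
      stress <- stress + stats::rnorm(length(stress), 0, truth$noise_sd_stress)
  })
  # measurement noise can break strict monotonicity; keep the grid monotone
  o <- order(strain); strain <- strain[o]; stress <- stress[o]
  dup <- c(FALSE, diff(strain) <= 0)
  stress_strain_curve(strain[!dup], stress[!dup], specimen_id = specimen$id)
}

specimen_index <- function(specimen) {
  idx <- suppressWarnings(as.integer(gsub("\\D", "", specimen$id)))
  if (is.na(idx)) 0L else idx
}

#' Generate a synthetic DMA displacement trace for a specimen
#'
#' Displacement from the homogeneous uniaxial closed form under the
#' specimen's stiffness-perturbed material at every protocol sample, with an
#' optional loss-tangent phase lag `truth$delta` applied to the cyclic step
#' (the displacement responds to the pressure a lag `delta/omega` earlier,
#' producing elliptical hysteresis loops like experimental DMA data) and
#' additive displacement noise.
#'
#' @param specimen One row of a [generate_cohort()] data frame.
#' @param truth The [ground_truth()].
#' @param protocol A [loading_protocol()].
#' @return A [solution_trace()].
#' @export
generate_dma_trace <- function(specimen, truth, protocol = loading_protocol()) {
  stopifnot(inherits(truth, "ground_truth"), nrow(specimen) == 1)
  mat <- scale_material(truth$material, specimen$stiffness_factor)
  s <- protocol_samples(protocol)
  t_eff <- s$time_s
  if (truth$delta > 0) {
    lag <- truth$delta / (2 * pi * protocol$frequency)
    cyc <- s$step == "cyclic"
    # displacement follows the pressure from 'lag' seconds earlier, wrapped
    # within the periodic cyclic step
    t0 <- protocol$ramp_duration
    t_eff[cyc] <- t0 + (s$time_s[cyc] - t0 - lag) %% (1 / protocol$frequency)
  }
  p_eff <- pressure_at(t_eff, protocol)
  disp <- vapply(p_eff, function(p)
    specimen$thickness_mm * (1 - solve_stretch(mat, p, "uniaxial_free")) * 1000,
    numeric(1))
  disp <- with_seed(truth$seed + 13L * specimen_index(specimen) + 1L, {
    if (truth$noise_sd_um > 0)
      disp + stats::rnorm(length(disp), 0, truth$noise_sd_um) else disp
  })
  disp[1] <- 0                                 # reference at first contact
  solution_trace(s$time_s, s$pressure_MPa, disp, s$step,
                 thickness_mm = specimen$thickness_mm,
                 frequency_Hz = protocol$frequency,
                 label = paste0("synthetic/", specimen$id))
}

#' Calibrate a synthetic validation-cohort ground truth
#'
#' Solves for a one-term Ogden stand-in material (synthetic; it represents
#' no fitted experimental constants) whose population-mean ramp compression
#' and dynamic amplitude under the default protocol match the given targets,
#' averaging over the thickness and log-normal stiffness distributions by
#' Gauss--Hermite quadrature.  The two free constants are the modulus `mu`
#' (entering linearly at fixed ramp stretch) and the strain-stiffening
#' exponent `alpha` (controlling the tangent-to-secant ratio, hence the
#' dynamic amplitude).
#'
#' @param target_ramp_um,target_dynamp_um Cohort-mean targets, µm.
#' @param protocol A [loading_protocol()].
#' @param thickness_mean,thickness_sd,stiffness_sdlog Cohort distribution
#'   parameters passed through to the returned truth.
#' @param delta,noise_sd_um,noise_sd_stress,seed Passed through.
#' @return A [ground_truth()] whose material hits both targets in the
#'   population mean.
#' @export
calibrate_validation_truth <- function(target_ramp_um = 437,
                                       target_dynamp_um = 41.4,
                                       protocol = loading_protocol(),
                                       thickness_mean = 1.305,
                                       thickness_sd = 0.25,
                                       stiffness_sdlog = 0.15,
                                       delta = 0.12, noise_sd_um = 0.2,
                                       noise_sd_stress = 0, seed = 42L) {
  # Gauss-Hermite nodes for the log-normal stiffness factor
  gh <- gauss_hermite_15()
  sfac <- exp(-stiffness_sdlog^2 / 2 + sqrt(2) * stiffness_sdlog * gh$x)
  wts <- gh$w / sqrt(pi)
  # population-mean thickness of the truncated normal (truncation at 0.3 mm)
  a <- (0.3 - thickness_mean) / max(thickness_sd, 1e-12)
  th_mean <- if (thickness_sd > 0)
    thickness_mean + thickness_sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  else thickness_mean
  p_ramp <- protocol$p_mean
  p_lo <- protocol$p_mean - protocol$amplitude
  p_hi <- protocol$p_mean + protocol$amplitude
  mean_metrics <- function(mu, alpha) {
    mat <- ogden_material(mu, alpha, label = "ogden1_synthetic")
    lam <- vapply(c(p_ramp, p_lo, p_hi), function(p)
      sum(wts * vapply(sfac, function(s)
        solve_stretch(scale_material(mat, s), p, "uniaxial_free"), numeric(1))),
      numeric(1))
    c(ramp = th_mean * (1 - lam[1]) * 1000,
      dynamp = th_mean * (lam[2] - lam[3]) * 1000)
  }
  mu_for_alpha <- function(alpha) {
    # closed-form seed: one-term uniaxial stress at the target ramp stretch
    lam_r <- 1 - target_ramp_um / (th_mean * 1000)
    mu0 <- p_ramp * alpha / (2 * (lam_r^(-alpha / 2 - 1) - lam_r^(alpha - 1)))
    f <- function(mu) mean_metrics(mu, alpha)["ramp"] - target_ramp_um
    stats::uniroot(f, c(mu0 / 5, 5 * mu0), tol = 1e-10)$root
  }
  g <- function(alpha) {
    mu <- mu_for_alpha(alpha)
    mean_metrics(mu, alpha)["dynamp"] - target_dynamp_um
  }
  alpha <- stats::uniroot(g, c(4, 80), tol = 1e-8)$root
  mu <- mu_for_alpha(alpha)
  ground_truth(ogden_material(mu, alpha, label = "ogden1_synthetic"),
               thickness_mean = thickness_mean, thickness_sd = thickness_sd,
               stiffness_sdlog = stiffness_sdlog,
               noise_sd_stress = noise_sd_stress, noise_sd_um = noise_sd_um,
               delta = delta, seed = seed)
}

# 15-point Gauss-Hermite rule (weight exp(-x^2)), computed from the Jacobi
# matrix of the Hermite recurrence.
gauss_hermite_15 <- function() {
  n <- 15
  J <- matrix(0, n, n)
  for (k in seq_len(n - 1)) J[k, k + 1] <- J[k + 1, k] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

.truth_cache <- new.env(parent = emptyenv())

#' Default synthetic validation-cohort ground truth
#'
#' The packaged calibration: a one-term Ogden stand-in with log-normal
#' stiffness heterogeneity, thickness spread and a small loss-tangent lag,
#' calibrated at load time by [calibrate_validation_truth()] so the
#' population-mean ramp compression and dynamic amplitude are 437 µm and
#' 41.4 µm.  Cached after the first call.
#'
#' @return A [ground_truth()].
#' @export
default_validation_truth <- function() {
  if (is.null(.truth_cache$default))
    .truth_cache$default <- calibrate_validation_truth()
  .truth_cache$default
}

#' Write a cohort and its per-specimen files to a directory
#'
#' Writes the cohort manifest (YAML) plus one ramp-curve and one DMA-trace
#' file per specimen, all as delimited text consumable by
#' [read_stress_strain()] and [read_trace()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param protocol A [loading_protocol()] for the DMA traces.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, protocol = loading_protocol()) {
  stopifnot(inherits(cohort, "specimen_cohort"))
  truth <- attr(cohort, "truth")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(cohort = cohort$cohort[1], n = nrow(cohort),
                   material = material_to_config(truth$material),
                   specimens = lapply(seq_len(nrow(cohort)), function(i)
                     as.list(cohort[i, c("id", "diameter_mm", "thickness_mm")])))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (i in seq_len(nrow(cohort))) {
    sp <- cohort[i, ]
    cv <- generate_ramp_curve(sp, truth)
    utils::write.table(
      data.frame(strain = cv$strain, stress_MPa = cv$stress),
      file.path(dir, paste0(sp$id, "_ramp.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    write_trace(generate_dma_trace(sp, truth, protocol),
                file.path(dir, paste0(sp$id, "_dma.tsv")))
  }
  invisible(dir)
}
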