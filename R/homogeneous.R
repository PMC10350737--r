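# Semi-analytic solver for a homogeneous incompressible block under the
# loading protocol: the independent oracle for the finite-element solver and
# the engine behind fast cohort simulation.

#' Axial stretch of a homogeneous block under pressure
#'
#' Solves `P(lambda) = -pressure` for the axial stretch, where `P` is the
#' closed-form nominal stress of the chosen deformation mode
#' ([nominal_stress()]).  Uses a safeguarded Newton iteration (bisection
#' fallback) on the bracket `[0.2, 1]`, tolerance 1e-12 on the stretch, which
#' copes with the stiffly nonlinear Ogden response near instability.
#'
#' @param model A `cartilage_material`.
#' @param pressure Applied compressive pressure, MPa (>= 0).
#' @param mode Deformation mode, see [nominal_stress()].
#' @param bracket Search bracket for the stretch (default `c(0.2, 1)`).
#' @return Axial stretch in (0, 1]; the stress residual satisfies
#'   `|P(lambda) + pressure| <= 1e-9` MPa.
#' @section Stability failures: if the material destabilises (nominal stress
#'   stops decreasing) before the load is reached, a condition of class
#'   `"cartdyn_stability_error"` is signalled carrying the last stable
#'   stretch and the maximum sustainable pressure.
#' @examples
#' solve_stretch(ogden_reference_material(), 1.225, "uniaxial_free")
#' @export
solve_stretch <- function(model, pressure,
                          mode = c("uniaxial_free", "lateral_locked"),
                          bracket = c(0.2, 1)) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(pressure), length(pressure) == 1L, is.finite(pressure))
  if (pressure < 0) stop("'pressure' must be non-negative (compression positive)")
  if (pressure == 0) return(1)
  f <- function(l) nominal_stress(model, l, mode) + pressure
  lo <- min(bracket); hi <- max(bracket)
  if (f(hi) <= 0) stop("upper bracket does not carry positive residual")
  if (f(lo) > 0) {
    # no sign change: the material cannot sustain this pressure on the
    # bracket -- find the last stable (monotone-decreasing stress) stretch
    grid <- seq(hi, lo, length.out = 512)
    P <- nominal_stress(model, grid, mode)
    turn <- which(diff(P) >= 0)            # stress stops decreasing
    lam_stable <- if (length(turn)) grid[turn[1]] else lo
    p_max <- -min(P[seq_len(if (length(turn)) turn[1] else length(P))])
    stop(stability_error(
      sprintf("material destabilises before reaching %.4g MPa (max sustainable %.4g MPa)",
              pressure, p_max),
      last_stable_stretch = lam_stable, max_pressure = p_max))
  }
  # safeguarded Newton with bisection fallback
  lam <- 1 - pressure / max(nominal_tangent(model, 1, mode), 1e-12)
  if (!is.finite(lam) || lam <= lo || lam >= hi) lam <- (lo + hi) / 2
  for (i in 1:200) {
    fl <- f(lam)
    if (fl > 0) hi <- lam else lo <- lam
    step <- fl / nominal_tangent(model, lam, mode)
    lam_new <- lam - step
    if (!is.finite(lam_new) || lam_new <= lo || lam_new >= hi)
      lam_new <- (lo + hi) / 2             # bisection fallback
    if (abs(lam_new - lam) < 1e-12) { lam <- lam_new; break }
    lam <- lam_new
  }
  lam
}

stability_error <- function(msg, last_stable_stretch = NA_real_,
                            max_pressure = NA_real_, time_s = NA_real_) {
  structure(class = c("cartdyn_stability_error", "error", "condition"),
            list(message = msg, call = NULL,
                 last_stable_stretch = last_stable_stretch,
                 max_pressure = max_pressure, time_s = time_s))
}

#' Compressive displacement of a homogeneous specimen under pressure
#'
#' `thickness * (1 - lambda) * 1000` micrometres, exactly linear in
#' thickness.
#'
#' @inheritParams solve_stretch
#' @param thickness Specimen thickness, mm (> 0).
#' @return Displacement, µm (compression positive).
#' @export
displacement_under <- function(model, pressure, thickness = 1.305,
                               mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(thickness), length(thickness) == 1L)
  if (!is.finite(thickness) || thickness <= 0) stop("'thickness' must be positive")
  thickness * (1 - solve_stretch(model, pressure, mode)) * 1000
}

#' Construct a solution trace
#'
#' The common currency between the finite-element solver, the homogeneous
#' oracle, the synthetic generator and the DMA metrics: time / applied
#' pressure / top-surface compressive displacement samples with a step label.
#'
#' @param time_s,pressure_MPa,displacement_um,step Equal-length columns;
#'   `step` in `c("ramp", "cyclic")`; time strictly increasing with
#'   displacement 0 at time 0 when a ramp start is present.
#' @param thickness_mm,frequency_Hz,label Metadata carried as attributes.
#' @return A data frame of class `"solution_trace"`.
#' @export
solution_trace <- function(time_s, pressure_MPa, displacement_um, step,
                           thickness_mm = NA_real_, frequency_Hz = 1,
                           label = NULL) {
  n <- length(time_s)
  stopifnot(length(pressure_MPa) == n, length(displacement_um) == n,
            length(step) == n)
  if (n > 1 && any(diff(time_s) <= 0)) stop("'time_s' must be strictly increasing")
  if (!all(step %in% c("ramp", "cyclic"))) stop("'step' must be 'ramp' or 'cyclic'")
  structure(
    data.frame(time_s = time_s, pressure_MPa = pressure_MPa,
               displacement_um = displacement_um, step = step,
               stringsAsFactors = FALSE),
    thickness_mm = thickness_mm, frequency_Hz = frequency_Hz, label = label,
    class = c("solution_trace", "data.frame"))
}

#' @export
print.solution_trace <- function(x, ...) {
  cat(sprintf("<solution trace> %d samples, t in [%g, %g] s%s\n", nrow(x),
              min(x$time_s), max(x$time_s),
              if (!is.null(attr(x, "label"))) paste0(", ", attr(x, "label")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
plot.solution_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time_s, x$pressure_MPa, type = "l", xlab = "time (s)",
       ylab = "pressure (MPa)", ...)
  plot(x$time_s, x$displacement_um, type = "l", xlab = "time (s)",
       ylab = "compression (um)", ...)
  invisible(x)
}

#' Quasi-static protocol simulation of a homogeneous specimen
#'
#' Solves the homogeneous stretch independently at every protocol sample
#' (the materials are time-independent, so the response is quasi-static) and
#' returns the displacement trace.
#'
#' @param model A `cartilage_material`.
#' @param protocol A [loading_protocol()].
#' @param thickness Specimen thickness, mm.
#' @param mode Deformation mode, see [nominal_stress()].
#' @return A [solution_trace()].  Stability failures are re-signalled with
#'   the protocol time at which they occur.
#' @examples
#' tr <- simulate_protocol(neo_hookean_material(4.89), loading_protocol())
#' ramp_compression(tr)
#' @export
simulate_protocol <- function(model, protocol = loading_protocol(),
                              thickness = 1.305,
                              mode = c("uniaxial_free", "lateral_locked")) {
  mode <- match.arg(mode)
  s <- protocol_samples(protocol)
  disp <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    disp[i] <- tryCatch(
      displacement_under(model, s$pressure_MPa[i], thickness, mode),
      cartdyn_stability_error = function(e) {
        e$time_s <- s$time_s[i]
        e$message <- sprintf("t = %.3f s: %s", s$time_s[i], e$message)
        stop(e)
      })
  }
  solution_trace(s$time_s, s$pressure_MPa, disp, s$step,
                 thickness_mm = thickness, frequency_Hz = protocol$frequency,
                 label = paste0(model$label, "/", mode))
}

#' Write or read a solution trace as delimited text
#'
#' Tab-separated with header columns `time_s`, `pressure_MPa`,
#' `displacement_um`, `step`.
#'
#' @param trace A [solution_trace()].
#' @param file Path.
#' @return `write_trace()` returns `file` invisibly; `read_trace()` returns a
#'   [solution_trace()].
#' @export
write_trace <- function(trace, file) {
  stopifnot(inherits(trace, "solution_trace"))
  utils::write.table(as.data.frame(trace), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("time_s", "pressure_MPa", "displacement_um", "step")
  if (!all(need %in% names(d)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  solution_trace(d$time_s, d$pressure_MPa, d$displacement_um, d$step)
}
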