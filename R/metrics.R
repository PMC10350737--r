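# The study's two headline scalar outputs -- ramp compression and dynamic
# amplitude -- plus normalised-compression and hysteresis diagnostics,
# computed from any solution trace (simulated or synthetic-experimental).

trace_frequency <- function(trace, frequency = NULL) {
  f <- frequency %||% attr(trace, "frequency_Hz") %||% 1
  stopifnot(is.numeric(f), f > 0)
  f
}

final_cycle <- function(trace, frequency = NULL) {
  cyc <- trace[trace$step == "cyclic", , drop = FALSE]
  if (!nrow(cyc)) stop("trace contains no cyclic step")
  f <- trace_frequency(trace, frequency)
  t_end <- max(cyc$time_s)
  dt <- if (nrow(cyc) > 1) stats::median(diff(cyc$time_s)) else Inf
  span <- t_end - min(cyc$time_s) + dt     # first cyclic sample sits one
  if (span < 1 / f - 1e-9)                 # interval after the step start
    stop("cyclic step shorter than one full period; cannot extract a cycle")
  cyc[cyc$time_s >= t_end - 1 / f - 1e-9, , drop = FALSE]
}

#' Ramp compression
#'
#' The initial compression: displacement accumulated going from zero pressure
#' to the mean physiological pressure, read at the final sample of the ramp
#' step.
#'
#' @param trace A [solution_trace()].
#' @return Displacement, µm.
#' @export
ramp_compression <- function(trace) {
  stopifnot(inherits(trace, "solution_trace"))
  rmp <- trace[trace$step == "ramp", , drop = FALSE]
  if (!nrow(rmp)) stop("trace contains no ramp step")
  rmp$displacement_um[nrow(rmp)]
}

#' Dynamic amplitude
#'
#' The change in compression across the physiological pressure range:
#' peak-to-peak (max minus min) displacement over the final complete loading
#' cycle.  Extrema are taken from the samples directly; the default protocol
#' sampling places the cycle extremes exactly on the grid.
#'
#' @param trace A [solution_trace()].
#' @param frequency Cyclic frequency, Hz; defaults to the trace attribute.
#' @return Peak-to-peak displacement, µm.
#' @export
dynamic_amplitude <- function(trace, frequency = NULL) {
  stopifnot(inherits(trace, "solution_trace"))
  win <- final_cycle(trace, frequency)
  max(win$displacement_um) - min(win$displacement_um)
}

#' Normalised compression over the final cycle
#'
#' Per-sample difference between the displacement at a given sample and the
#' displacement at the minimum applied pressure during the full cycle; zero
#' at the minimum-pressure sample, with maximum equal to the dynamic
#' amplitude for any single-valued (elastic) response.
#'
#' @inheritParams dynamic_amplitude
#' @return Data frame with columns `time_s`, `normalised_um`.
#' @export
normalised_compression <- function(trace, frequency = NULL) {
  stopifnot(inherits(trace, "solution_trace"))
  win <- final_cycle(trace, frequency)
  ref <- win$displacement_um[which.min(win$pressure_MPa)]
  data.frame(time_s = win$time_s, normalised_um = win$displacement_um - ref)
}

#' Hysteresis loop area over the final cycle
#'
#' Signed trapezoidal integral of pressure over displacement around the
#' final complete cycle (loop closed through the first sample).  In
#' MPa times µm, which equals J/m^2 of dissipated energy per unit loaded
#' area per cycle; zero (to integration tolerance) for any elastic,
#' single-valued pressure--displacement relation, positive when displacement
#' lags pressure.
#'
#' @inheritParams dynamic_amplitude
#' @return Loop area, J/m^2.
#' @export
hysteresis_area <- function(trace, frequency = NULL) {
  stopifnot(inherits(trace, "solution_trace"))
  win <- final_cycle(trace, frequency)
  p <- c(win$pressure_MPa, win$pressure_MPa[1])
  d <- c(win$displacement_um, win$displacement_um[1])
  sum((p[-1] + p[-length(p)]) / 2 * diff(d))
}

#' Cohort mean and standard deviation
#'
#' Sample statistics (SD with the n-1 denominator) for a per-specimen metric,
#' matching the mean-plus-minus-SD cohort reporting convention.
#'
#' @param values Numeric vector of per-specimen values.
#' @return Named numeric vector `c(mean, sd, n)`; `sd` is 0 for a single
#'   value.
#' @export
cohort_stats <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  s <- if (length(values) > 1) stats::sd(values) else 0
  c(mean = mean(values), sd = s, n = length(values))
}

#' Metrics table for a set of traces
#'
#' Convenience wrapper computing the headline metrics for a list of traces,
#' in the flat delimited-text layout used by study reports.
#'
#' @param traces Named list of [solution_trace()] objects.
#' @param model Optional model label column.
#' @return Data frame with columns `specimen`, `model`, `ramp_um`,
#'   `dynamp_um`, `hysteresis_J_m2`.
#' @export
metrics_table <- function(traces, model = NA_character_) {
  stopifnot(is.list(traces), length(traces) >= 1)
  ids <- names(traces) %||% as.character(seq_along(traces))
  do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(specimen = ids[i], model = model,
               ramp_um = ramp_compression(tr),
               dynamp_um = dynamic_amplitude(tr),
               hysteresis_J_m2 = hysteresis_area(tr),
               stringsAsFactors = FALSE)
  }))
}
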