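# The two-step pressure protocol: quasi-static ramp to the mean physiological
# pressure followed by 1 Hz sinusoidal cycling across the physiological range.

#' Two-step compression loading protocol
#'
#' A linear pressure ramp from zero to `p_mean` over `ramp_duration`, followed
#' by sinusoidal loading `p_mean + amplitude * cos(2*pi*frequency*(t - t0))`
#' for `cyclic_duration`, where `t0` is the end of the ramp.  Under the
#' defaults the cycle spans exactly 0.75--1.7 MPa at 1 Hz, the physiological
#' range during ambulation; the alternative amplitude 0.388 MPa reproduces the
#' narrower printed variant of the same protocol.  Note the protocol jumps
#' from `p_mean` to the cycle peak at `t0` (cos(0) = 1).
#'
#' @param p_mean Mean physiological pressure, MPa (default 1.225).
#' @param amplitude Cyclic amplitude, MPa (default 0.475; alternative 0.388).
#' @param frequency Cyclic frequency, Hz (default 1).
#' @param ramp_duration,cyclic_duration Step durations, s (default 1 each).
#' @param sample_interval Trace sampling interval, s (default 0.005).
#' @return An object of class `"loading_protocol"`.
#' @examples
#' pressure_at(c(0.5, 1, 1.5, 2), loading_protocol())
#' @export
loading_protocol <- function(p_mean = 1.225, amplitude = 0.475, frequency = 1,
                             ramp_duration = 1, cyclic_duration = 1,
                             sample_interval = 0.005) {
  stopifnot(is.numeric(p_mean), is.numeric(amplitude), is.numeric(frequency))
  if (!(p_mean > amplitude && amplitude >= 0))
    stop("protocol requires p_mean > amplitude >= 0")
  if (ramp_duration <= 0 || cyclic_duration <= 0 || sample_interval <= 0)
    stop("durations and sample_interval must be positive")
  structure(list(p_mean = p_mean, amplitude = amplitude, frequency = frequency,
                 ramp_duration = ramp_duration, cyclic_duration = cyclic_duration,
                 sample_interval = sample_interval),
            class = "loading_protocol")
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf(paste0("<loading protocol> ramp 0 -> %.4g MPa over %g s, ",
                     "then %.4g +/- %.4g MPa at %g Hz for %g s\n"),
              x$p_mean, x$ramp_duration, x$p_mean, x$amplitude, x$frequency,
              x$cyclic_duration))
  invisible(x)
}

#' Applied pressure at a protocol time
#'
#' @param t Time(s) in seconds, within `[0, ramp_duration + cyclic_duration]`.
#' @param protocol A [loading_protocol()].
#' @return Pressure, MPa (vectorised over `t`).  Times at exactly
#'   `ramp_duration` report the end-of-ramp pressure `p_mean`.
#' @export
pressure_at <- function(t, protocol = loading_protocol()) {
  stopifnot(inherits(protocol, "loading_protocol"), is.numeric(t))
  t_end <- protocol$ramp_duration + protocol$cyclic_duration
  if (any(t < -1e-12 | t > t_end + 1e-12))
    stop("time outside the protocol window [0, ", t_end, "] s")
  ifelse(t <= protocol$ramp_duration,
         protocol$p_mean * t / protocol$ramp_duration,
         protocol$p_mean + protocol$amplitude *
           cos(2 * pi * protocol$frequency * (t - protocol$ramp_duration)))
}

#' Nominal stress applied by a force on a circular specimen face
#'
#' Converts an axial force to the nominal compressive stress on a disc of the
#' given diameter: `force / (pi * (diameter/2)^2)`.  61.6 N on an 8 mm core
#' gives the protocol's mean physiological pressure of 1.225 MPa (3 s.f.).
#'
#' @param force Axial force, N (>= 0).
#' @param diameter Specimen diameter, mm (> 0).
#' @return Nominal stress, MPa (vectorised).
#' @examples
#' stress_from_force(61.6, 8)
#' @export
stress_from_force <- function(force, diameter) {
  stopifnot(is.numeric(force), is.numeric(diameter))
  if (any(force < 0)) stop("'force' must be non-negative")
  if (any(diameter <= 0)) stop("'diameter' must be positive")
  force / (pi * (diameter / 2)^2)
}

#' Protocol sampling grid
#'
#' Times at which a protocol trace is sampled: the ramp step on
#' `[0, ramp_duration]` and the cyclic step on
#' `(ramp_duration, ramp_duration + cyclic_duration]`, both at
#' `sample_interval` spacing, with a step label per sample.
#'
#' @param protocol A [loading_protocol()].
#' @return Data frame with columns `time_s`, `pressure_MPa`, `step`.
#' @keywords internal
protocol_samples <- function(protocol) {
  dt <- protocol$sample_interval
  t_ramp <- seq(0, protocol$ramp_duration, by = dt)
  if (t_ramp[length(t_ramp)] < protocol$ramp_duration)
    t_ramp <- c(t_ramp, protocol$ramp_duration)
  t_end <- protocol$ramp_duration + protocol$cyclic_duration
  t_cyc <- seq(protocol$ramp_duration + dt, t_end, by = dt)
  if (length(t_cyc) && t_cyc[length(t_cyc)] < t_end - 1e-12)
    t_cyc <- c(t_cyc, t_end)
  data.frame(
    time_s = c(t_ramp, t_cyc),
    pressure_MPa = pressure_at(c(t_ramp, t_cyc), protocol),
    step = rep(c("ramp", "cyclic"), c(length(t_ramp), length(t_cyc))),
    stringsAsFactors = FALSE)
}
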