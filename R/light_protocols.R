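# Synthetic illumination protocols.  All three kinds expose intensity(t) in
# umol photons m^-2 s^-1 and a closed-form total photon dose, so equal-dose
# comparisons across regimes are exact by construction.

new_light_protocol <- function(kind, duration, params) {
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
    duration <= 0) {
    stop_invalid("duration must be a single positive number of seconds")
  }
  structure(
    list(kind = kind, duration = duration, params = params),
    class = "light_protocol"
  )
}

#' Constant (static) illumination
#'
#' @param intensity Photon flux density, umol photons m^-2 s^-1 (>= 0).
#' @param duration Protocol length in seconds.
#' @return A `light_protocol` object.
#' @examples
#' total_dose(light_static(100, 3600)) # 3.6e5
#' @export
light_static <- function(intensity, duration) {
  if (!is.numeric(intensity) || length(intensity) != 1 ||
    !is.finite(intensity) || intensity < 0) {
    stop_invalid("intensity must be a single non-negative number")
  }
  new_light_protocol("static", duration, list(intensity = intensity))
}

#' Sinusoidal illumination starting from its minimum
#'
#' `intensity(t) = mean + amplitude * sin(2 pi t / period - pi / 2)`; the
#' phase offset makes the protocol start at `mean - amplitude`, consistent
#' with simulations that begin in darkness.  Over a whole number of periods
#' the dose equals that of static light at `mean`.
#'
#' @param mean Mean intensity, umol photons m^-2 s^-1.
#' @param amplitude Modulation depth; must satisfy `0 <= amplitude <= mean`.
#' @param period Oscillation period, s.
#' @param duration Protocol length, s.
#' @return A `light_protocol` object.
#' @export
light_sinusoidal <- function(mean, amplitude, period, duration) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) || mean < 0) {
    stop_invalid("mean must be a single non-negative number")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1 || !is.finite(amplitude) ||
    amplitude < 0 || amplitude > mean) {
    stop_invalid("amplitude must satisfy 0 <= amplitude <= mean")
  }
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
    period <= 0) {
    stop_invalid("period must be a single positive number of seconds")
  }
  new_light_protocol(
    "sinusoidal", duration,
    list(mean = mean, amplitude = amplitude, period = period)
  )
}

#' Square-wave (fluctuating) illumination
#'
#' Each period starts in the low phase (simulations begin from darkness) and
#' spends `duty_fraction` of the period at `high`.  The mean intensity is
#' `low + duty_fraction * (high - low)`; over whole periods the dose matches
#' static light at that mean.
#'
#' @param low,high Intensities of the two phases, `0 <= low <= high`.
#' @param period Period, s.
#' @param duty_fraction Fraction of each period spent at `high`, in `[0, 1]`.
#' @param duration Protocol length, s.
#' @return A `light_protocol` object.
#' @export
light_square_wave <- function(low, high, period, duty_fraction, duration) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1 ||
    length(high) != 1 || !is.finite(low) || !is.finite(high) ||
    low < 0 || high < low) {
    stop_invalid("need 0 <= low <= high")
  }
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
    period <= 0) {
    stop_invalid("period must be a single positive number of seconds")
  }
  if (!is.numeric(duty_fraction) || length(duty_fraction) != 1 ||
    is.na(duty_fraction) || duty_fraction < 0 || duty_fraction > 1) {
    stop_invalid("duty_fraction must lie in [0, 1]")
  }
  new_light_protocol(
    "square_wave", duration,
    list(low = low, high = high, period = period, duty_fraction = duty_fraction)
  )
}

#' Evaluate a protocol's intensity at time(s) t
#'
#' @param protocol A `light_protocol`.
#' @param t Numeric vector of times, s.  Square-wave transitions are
#'   right-continuous (the new phase applies at the breakpoint itself).
#' @return Intensities in umol photons m^-2 s^-1, same length as `t`.
#' @export
light_intensity <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"))
  p <- protocol$params
  switch(protocol$kind,
    static = rep(p$intensity, length(t)),
    sinusoidal = p$mean + p$amplitude * sin(2 * pi * t / p$period - pi / 2),
    square_wave = {
      phase <- t %% p$period
      low_len <- (1 - p$duty_fraction) * p$period
      ifelse(phase < low_len, p$low, p$high)
    },
    stop_invalid(paste0("unknown protocol kind: ", protocol$kind))
  )
}

#' Total photon dose of a protocol, in closed form
#'
#' @param protocol A `light_protocol`.
#' @return Integral of intensity over `[0, duration]`, umol photons m^-2.
#' @export
total_dose <- function(protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  p <- protocol$params
  d <- protocol$duration
  switch(protocol$kind,
    static = p$intensity * d,
    sinusoidal = {
      # integral of amp*sin(2 pi t/P - pi/2) over [0, d]
      w <- 2 * pi / p$period
      p$mean * d + p$amplitude / w * (cos(pi / 2) - cos(w * d - pi / 2))
    },
    square_wave = {
      whole <- floor(d / p$period)
      rem <- d - whole * p$period
      low_len <- (1 - p$duty_fraction) * p$period
      per_period <- p$low * low_len + p$high * p$duty_fraction * p$period
      tail_dose <- p$low * min(rem, low_len) + p$high * max(rem - low_len, 0)
      whole * per_period + tail_dose
    }
  )
}

#' Times at which a protocol is discontinuous
#'
#' The integrator restarts at these times so that step-function transitions
#' are never stepped over.  Smooth protocols return `numeric(0)`.
#'
#' @param protocol A `light_protocol`.
#' @return Sorted vector of breakpoint times in `(0, duration)`.
#' @export
light_breakpoints <- function(protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (protocol$kind != "square_wave") {
    return(numeric(0))
  }
  p <- protocol$params
  if (p$low == p$high || p$duty_fraction %in% c(0, 1)) {
    return(numeric(0))
  }
  low_len <- (1 - p$duty_fraction) * p$period
  starts <- seq(0, protocol$duration, by = p$period)
  br <- sort(c(starts, starts + low_len))
  br[br > 0 & br < protocol$duration]
}

#' @export
print.light_protocol <- function(x, ...) {
  cat(sprintf(
    "light_protocol [%s], %.0f s, dose %.3g umol m^-2\n  %s\n",
    x$kind, x$duration, total_dose(x),
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  ))
  invisible(x)
}

# pack for the C++ right-hand side: c(kind_code, p1..p4, duration)
pack_light <- function(protocol) {
  p <- protocol$params
  switch(protocol$kind,
    static = c(0, p$intensity, 0, 0, 0, protocol$duration),
    sinusoidal = c(1, p$mean, p$amplitude, p$period, 0, protocol$duration),
    square_wave = c(
      2, p$low, p$high, p$period, p$duty_fraction,
      protocol$duration
    )
  )
}
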