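#' Unit pulsatile synaptic waveform
#'
#' The standard stimulus shape within one period: a linear rise over
#' `rise` ms, a plateau of `plateau` ms at 1, then an exponential decay
#' with time constant `decay_tau` ms.  The waveform restarts at each
#' period; the decay tail is truncated at the period end (with the default
#' 0.1 ms time constant the carried-over tail is below `exp(-10)` even at
#' 600 Hz).
#'
#' @param t_in_period time since period start (ms); vectorized
#' @param rise rise time (ms)
#' @param plateau plateau duration (ms)
#' @param decay_tau decay time constant (ms)
#' @return dimensionless level in `[0, 1]`
#' @examples
#' pulse_shape(0.025)  # mid-rise: 0.5
#' pulse_shape(0.35)   # one decay time constant past the plateau: exp(-1)
#' @export
pulse_shape <- function(t_in_period, rise = 0.05, plateau = 0.2,
                        decay_tau = 0.1) {
  ifelse(t_in_period < rise, t_in_period / rise,
         ifelse(t_in_period < rise + plateau, 1,
                exp(-(t_in_period - rise - plateau) / decay_tau)))
}

#' Describe a stimulus regime
#'
#' A declarative description of the drive applied to the membrane: a
#' pulsatile synaptic component (`amplitude` at `frequency`), a steady
#' synaptic background (`background`, the 0 Hz component), and/or a
#' current-clamp component built with [current_clamp()].  Synaptic
#' components compose additively: pulses ride atop the background.
#' Combining synaptic drive with current clamp in one regime is unusual
#' and triggers a warning.
#'
#' @param amplitude pulsatile syn_clamp peak amplitude (dimensionless,
#'   `>= 0`; 0 disables the pulsatile component)
#' @param frequency pulse rate (Hz; required when `amplitude > 0`)
#' @param background steady syn_clamp level (dimensionless, `>= 0`)
#' @param clamp optional [current_clamp()] description
#' @param rise,plateau,decay_tau pulse-shape segments (ms), see
#'   [pulse_shape()]
#' @param start stimulus onset (ms)
#' @param duration stimulus duration (ms); `Inf` keeps it on for the whole
#'   simulation
#' @return an object of class `stimulus_regime`
#' @examples
#' stimulus_regime(amplitude = 1, frequency = 200)           # pure pulsatile
#' stimulus_regime(background = 0.05)                        # steady drive
#' stimulus_regime(amplitude = 0.1, frequency = 200, background = 0.00736)
#' @export
stimulus_regime <- function(amplitude = 0, frequency = NULL,
                            background = 0, clamp = NULL,
                            rise = 0.05, plateau = 0.2, decay_tau = 0.1,
                            start = 0, duration = Inf) {
  stopifnot(amplitude >= 0, background >= 0, start >= 0, duration > 0)
  if (amplitude > 0) {
    if (is.null(frequency) || frequency <= 0)
      stop("a pulsatile component needs a positive 'frequency'")
    if (1000 / frequency <= rise + plateau)
      stop("pulse period must exceed rise + plateau")
  }
  has_syn <- amplitude > 0 || background > 0
  if (!has_syn && is.null(clamp))
    stop("regime must contain a synaptic or a current-clamp component")
  if (has_syn && !is.null(clamp))
    warning("combining synaptic and current-clamp drive in one regime")
  if (!is.null(clamp)) stopifnot(inherits(clamp, "current_clamp"))
  structure(list(amplitude = amplitude,
                 frequency = if (amplitude > 0) frequency else 0,
                 background = background, clamp = clamp,
                 rise = rise, plateau = plateau, decay_tau = decay_tau,
                 start = start, duration = duration),
            class = "stimulus_regime")
}

#' Describe a current-clamp drive
#'
#' @param kind `"step"` (constant `amplitude` for `duration`), `"ramp"`
#'   (linear from 0 to `amplitude` over `duration`) or `"pulse-train"`
#'   (rectangular pulses of `width` ms at `frequency` Hz)
#' @param amplitude injected current (nA); for a ramp, the peak reached at
#'   the end of `duration`
#' @param duration drive duration (ms)
#' @param start drive onset (ms)
#' @param width pulse width (ms), pulse-train only
#' @param frequency pulse rate (Hz), pulse-train only
#' @return an object of class `current_clamp`
#' @export
current_clamp <- function(kind = c("step", "ramp", "pulse-train"),
                          amplitude, duration, start = 0,
                          width = NULL, frequency = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(amplitude), duration > 0, start >= 0)
  if (kind == "pulse-train") {
    if (is.null(width) || is.null(frequency) || width <= 0 || frequency <= 0)
      stop("pulse-train clamp needs positive 'width' and 'frequency'")
    if (width >= 1000 / frequency)
      stop("pulse width must be shorter than the pulse period")
  }
  structure(list(kind = kind, amplitude = amplitude, duration = duration,
                 start = start, width = width, frequency = frequency),
            class = "current_clamp")
}

#' Synaptic activation level at a time point
#'
#' Background level plus pulsatile amplitude times the unit waveform,
#' evaluated within the regime's active window.
#'
#' @param t time (ms); vectorized
#' @param regime a [stimulus_regime()]
#' @return dimensionless syn_clamp level
#' @export
syn_level <- function(t, regime) {
  stopifnot(inherits(regime, "stimulus_regime"))
  if (regime$amplitude == 0 && regime$background == 0)
    stop("regime has no synaptic component")
  active <- t >= regime$start & t <= regime$start + regime$duration
  lev <- rep(regime$background, length(t))
  if (regime$amplitude > 0) {
    per <- 1000 / regime$frequency
    lev <- lev + regime$amplitude *
      pulse_shape((t - regime$start) %% per, regime$rise, regime$plateau,
                  regime$decay_tau)
  }
  ifelse(active, lev, 0)
}

#' Injected current at a time point
#'
#' @param t time (ms); vectorized
#' @param drive a [current_clamp()] description
#' @return injected current (nA), positive depolarizing
#' @export
clamp_current <- function(t, drive) {
  stopifnot(inherits(drive, "current_clamp"))
  tr <- t - drive$start
  active <- tr >= 0 & tr <= drive$duration
  val <- switch(drive$kind,
    step  = rep(drive$amplitude, length(t)),
    ramp  = drive$amplitude * tr / drive$duration,
    `pulse-train` = ifelse(tr %% (1000 / drive$frequency) < drive$width,
                           drive$amplitude, 0))
  ifelse(active, val, 0)
}

#' @export
print.stimulus_regime <- function(x, ...) {
  parts <- character()
  if (x$background > 0)
    parts <- c(parts, sprintf("background syn_clamp %g (0 Hz)", x$background))
  if (x$amplitude > 0)
    parts <- c(parts, sprintf("pulses amplitude %g at %g Hz", x$amplitude,
                              x$frequency))
  if (!is.null(x$clamp))
    parts <- c(parts, sprintf("%s I_clamp %g nA for %g ms", x$clamp$kind,
                              x$clamp$amplitude, x$clamp$duration))
  cat("Stimulus regime:", paste(parts, collapse = " + "), "\n")
  invisible(x)
}
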