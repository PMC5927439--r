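#' Voltage-dependent gating rates
#'
#' Forward and backward rate coefficients for one Hodgkin-Huxley gate.  All
#' rates are exponential in voltage, `alpha_j = k exp(eta V)`, except the
#' backward inactivation rate which is sigmoidal,
#' `beta_h = beta_h_max / (exp(-(V - beta_h_vhalf)/beta_h_k) + 1)`, so that
#' the inactivation time constant tends to `1/beta_h_max` = 0.3 ms at
#' strong depolarization.
#'
#' @param v membrane potential (mV); vectorized
#' @param gate one of `"m"` (Na+ activation), `"h"` (Na+ inactivation),
#'   `"n"` (delayed-rectifier activation)
#' @param params an [electrocyte_params()] object
#' @return list with components `alpha` and `beta` (ms^-1)
#' @examples
#' gate_rates(0, "m")$alpha      # prefactor: 8.03 ms^-1
#' gate_rates(100, "h")$beta     # -> beta_h_max = 3.33 ms^-1
#' @export
gate_rates <- function(v, gate = c("m", "h", "n"),
                       params = electrocyte_params()) {
  gate <- match.arg(gate)
  switch(gate,
    m = list(alpha = params$k_alpha_m * exp(params$eta_alpha_m * v),
             beta  = params$k_beta_m * exp(params$eta_beta_m * v)),
    h = list(alpha = params$k_alpha_h * exp(params$eta_alpha_h * v),
             beta  = params$beta_h_max /
                       (exp(-(v - params$beta_h_vhalf) / params$beta_h_k) + 1)),
    n = list(alpha = params$k_alpha_n * exp(params$eta_alpha_n * v),
             beta  = params$k_beta_n * exp(params$eta_beta_n * v))
  )
}

#' Gate equilibrium value and time constant
#'
#' Steady state `x_inf = alpha/(alpha + beta)` and relaxation time
#' `tau = 1/(alpha + beta)` of the first-order gating equation
#' `dj/dt = alpha (1 - j) - beta j`.
#'
#' @inheritParams gate_rates
#' @return list with components `x_inf` (dimensionless) and `tau` (ms)
#' @examples
#' gate_equilibrium(-28, "m")$x_inf^3   # ~0.5: m^3 activation midpoint
#' @export
gate_equilibrium <- function(v, gate = c("m", "h", "n"),
                             params = electrocyte_params()) {
  gate <- match.arg(gate)
  r <- gate_rates(v, gate, params)
  list(x_inf = r$alpha / (r$alpha + r$beta), tau = 1 / (r$alpha + r$beta))
}

#' Midpoint of an activation curve raised to a power
#'
#' Solves `x_inf(v)^k = 1/2` for `v`; used to characterize the `m^3` and
#' `n^4` open-fraction curves.
#'
#' @param gate gate name
#' @param power exponent applied to the gate variable (3 for `m`, 4 for `n`)
#' @param params an [electrocyte_params()] object
#' @param interval voltage bracket (mV) for the root search
#' @return midpoint voltage (mV)
#' @export
activation_midpoint <- function(gate, power, params = electrocyte_params(),
                                interval = c(-80, 40)) {
  stats::uniroot(function(v) gate_equilibrium(v, gate, params)$x_inf^power - 0.5,
                 interval, tol = 1e-10)$root
}
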