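#' Conductance-based membrane currents
#'
#' Evaluates the four conductance currents at a membrane state:
#' transient Na+ `I_NaT = gNa_max m^3 h (1 - gamma) (V - E_Na)`,
#' persistent Na+ `I_NaP = gNa_max m^3 gamma (V - E_Na)`,
#' delayed-rectifier `I_K = gK_max n^4 (V - E_K)` and leak
#' `I_L = gL (V - E_L)`.  With conductances in uS and voltages in mV the
#' currents are in nA, positive outward.
#'
#' @param state named list or vector with components `v` (mV) and gating
#'   variables `m`, `h`, `n`
#' @param params an [electrocyte_params()] object
#' @return named list of currents `i_na_t`, `i_na_p`, `i_k`, `i_leak` (nA)
#' @examples
#' p <- electrocyte_params()
#' conductance_currents(list(v = p$e_na, m = 0.5, h = 1, n = 0.1), p)$i_na_t
#' @export
conductance_currents <- function(state, params = electrocyte_params()) {
  v <- state[["v"]]; m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  g_na <- params$g_na_max * m^3
  list(
    i_na_t = g_na * h * (1 - params$gamma) * (v - params$e_na),
    i_na_p = g_na * params$gamma * (v - params$e_na),
    i_k    = params$g_k_max * n^4 * (v - params$e_k),
    i_leak = params$g_leak * (v - params$e_leak)
  )
}

#' GHK electrodiffusive current through the AChR synapse
#'
#' Single-ion Goldman-Hodgkin-Katz flux,
#' `I = P F z u/(1 - exp(-u)) ([X]_in - [X]_out exp(-u))` with
#' `u = zFV/RT`, scaled by the dimensionless synaptic activation `level`
#' (the "cation permeability clamp").  Computed in SI units (permeability
#' in m^3/s, concentrations in mol/m^3) and returned in nA, positive
#' outward.  The removable singularity at `V = 0` is handled with a
#' four-term Taylor expansion of `u/(1 - exp(-u))` for `|u| < 1e-4`.
#'
#' @param v membrane potential (mV); vectorized
#' @param ion `"Na"` or `"K"`
#' @param level dimensionless synaptic activation, `>= 0`
#' @param params an [electrocyte_params()] object
#' @return current (nA), positive outward
#' @examples
#' ghk_current(-90, "Na")        # large inward Na+ current (negative)
#' ghk_current(achr_reversal(electrocyte_params()), "Na") +
#'   ghk_current(achr_reversal(electrocyte_params()), "K") # ~0
#' @export
ghk_current <- function(v, ion = c("Na", "K"), level = 1,
                        params = electrocyte_params()) {
  ion <- match.arg(ion)
  if (any(level < 0)) stop("synaptic activation 'level' must be >= 0")
  perm_si <- params$p_na * 1e-9          # mm^3/s -> m^3/s
  if (ion == "K") perm_si <- perm_si * params$pk_over_pna
  conc <- if (ion == "Na") c(params$na_in, params$na_out)
          else c(params$k_in, params$k_out)
  u <- v / rtf_mv(params$temperature)
  ufac <- ifelse(abs(u) < 1e-4,
                 1 + u / 2 + u^2 / 12 - u^4 / 720,
                 u / (1 - exp(-u)))
  level * perm_si * .const$faraday * ufac * (conc[1] - conc[2] * exp(-u)) * 1e9
}

#' Total synaptic (AChR) current
#'
#' Sum of the Na+ and K+ GHK components at a given activation level,
#' positive outward; reverses at [achr_reversal()].
#'
#' @inheritParams ghk_current
#' @return current (nA)
#' @export
achr_current <- function(v, level = 1, params = electrocyte_params()) {
  ghk_current(v, "Na", level, params) + ghk_current(v, "K", level, params)
}
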