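#' Physical constants used throughout the model
#'
#' Faraday constant (C/mol), molar gas constant (J/mol/K) and elementary
#' charge (C), CODATA values.
#' @keywords internal
.const <- list(
  faraday = 96485.33212,
  gas     = 8.31446261815324,
  e_charge = 1.602176634e-19
)

#' Nernst equilibrium potential
#'
#' @param c_out extracellular concentration (mM)
#' @param c_in intracellular concentration (mM)
#' @param temperature absolute temperature (K)
#' @return equilibrium potential in mV
#' @examples
#' nernst(2.16, 89, 293.15)   # K+ at the default concentrations, ~ -94 mV
#' @export
nernst <- function(c_out, c_in, temperature = 293.15) {
  stopifnot(all(c_out > 0), all(c_in > 0), temperature > 0)
  rtf_mv(temperature) * log(c_out / c_in)
}

#' RT/F in millivolts
#' @param temperature absolute temperature (K)
#' @return RT/F (mV)
#' @export
rtf_mv <- function(temperature = 293.15) {
  .const$gas * temperature / .const$faraday * 1000
}

#' Parameters of the electrocyte posterior-membrane model
#'
#' Builds the full parameter set of the excitable posterior-membrane model:
#' membrane capacitance, maximal conductances, fixed reversal potentials,
#' Hodgkin-Huxley rate constants for the activation (`m`), inactivation
#' (`h`) and delayed-rectifier (`n`) gates, and the AChR synapse described
#' by GHK electrodiffusion (permeability-area products plus the ion
#' concentrations on both sides of the membrane).
#'
#' Rate laws: `alpha_j(V) = k_alpha_j * exp(eta_alpha_j * V)` for all three
#' gates, and likewise for `beta_m` and `beta_n`.  The backward inactivation
#' rate is sigmoidal, `beta_h(V) = beta_h_max / (exp(-(V - beta_h_vhalf) /
#' beta_h_k) + 1)`, which makes the inactivation time constant settle at
#' `1/beta_h_max` (0.3 ms) under strong depolarization.
#'
#' The fixed reversal potentials `e_na` and `e_k` are used in the
#' conductance currents and are *not* recomputed from the concentrations at
#' each step (the model assumes invariant Na+ and K+ gradients); the
#' concentrations feed only the GHK synaptic currents.  The default
#' intracellular sodium of 13.5 mM is chosen so that its Nernst potential
#' matches `e_na` = 55 mV and the two-ion GHK reversal of the synapse falls
#' at +2.2 mV.
#'
#' @param capacitance membrane capacitance (nF)
#' @param g_na_max maximal Na+ conductance (uS); the one parameter varied
#'   across firing frequencies
#' @param g_k_max maximal delayed-rectifier K+ conductance (uS)
#' @param g_leak leak conductance (uS)
#' @param gamma persistent (non-inactivating) fraction of the Na+
#'   conductance, dimensionless in `[0, 1]`
#' @param e_na,e_k fixed Na+ and K+ reversal potentials (mV)
#' @param e_leak leak reversal potential (mV); equals `e_k` by default
#' @param temperature absolute temperature (K)
#' @param k_alpha_m,eta_alpha_m,k_beta_m,eta_beta_m activation-gate rate
#'   constants (ms^-1, mV^-1)
#' @param k_alpha_h,eta_alpha_h forward (recovery) inactivation rate
#'   constants (ms^-1, mV^-1)
#' @param beta_h_max,beta_h_vhalf,beta_h_k sigmoidal backward inactivation
#'   rate: maximum (ms^-1), half-activation voltage (mV) and slope factor
#'   (mV)
#' @param k_alpha_n,eta_alpha_n,k_beta_n,eta_beta_n delayed-rectifier gate
#'   rate constants (ms^-1, mV^-1)
#' @param p_na AChR Na+ permeability-area product (mm^3/s)
#' @param pk_over_pna AChR permeability ratio P_K/P_Na (dimensionless)
#' @param na_in,na_out,k_in,k_out ion concentrations (mM)
#' @return an object of class `electrocyte_params`
#' @examples
#' p <- electrocyte_params()
#' p$g_na_max
#' nernst(p$k_out, p$k_in, p$temperature)  # consistent with e_k
#' @export
electrocyte_params <- function(capacitance = 50,
                               g_na_max = 700,
                               g_k_max = 2000,
                               g_leak = 5,
                               gamma = 0.02,
                               e_na = 55,
                               e_k = -94,
                               e_leak = e_k,
                               temperature = 293.15,
                               k_alpha_m = 8.03, eta_alpha_m = 0.0037,
                               k_beta_m = 0.2195, eta_beta_m = -0.0763,
                               k_alpha_h = 0.02247, eta_alpha_h = -0.06802,
                               beta_h_max = 3.33, beta_h_vhalf = -30,
                               beta_h_k = 9,
                               k_alpha_n = 2.135, eta_alpha_n = 0.03792,
                               k_beta_n = 0.3524, eta_beta_n = -0.01552,
                               p_na = 0.00016,
                               pk_over_pna = 1.11,
                               na_in = 13.5, na_out = 120,
                               k_in = 89, k_out = 2.16) {
  p <- list(
    capacitance = capacitance, g_na_max = g_na_max, g_k_max = g_k_max,
    g_leak = g_leak, gamma = gamma, e_na = e_na, e_k = e_k,
    e_leak = e_leak, temperature = temperature,
    k_alpha_m = k_alpha_m, eta_alpha_m = eta_alpha_m,
    k_beta_m = k_beta_m, eta_beta_m = eta_beta_m,
    k_alpha_h = k_alpha_h, eta_alpha_h = eta_alpha_h,
    beta_h_max = beta_h_max, beta_h_vhalf = beta_h_vhalf,
    beta_h_k = beta_h_k,
    k_alpha_n = k_alpha_n, eta_alpha_n = eta_alpha_n,
    k_beta_n = k_beta_n, eta_beta_n = eta_beta_n,
    p_na = p_na, pk_over_pna = pk_over_pna,
    na_in = na_in, na_out = na_out, k_in = k_in, k_out = k_out
  )
  class(p) <- "electrocyte_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of capacitance, conductances, rate prefactors,
#' permeabilities and concentrations, that `gamma` lies in `[0, 1]`, and
#' that the fixed K+ reversal is consistent (within 0.5 mV) with the Nernst
#' potential computed from the stated concentrations and temperature.
#'
#' @param p an `electrocyte_params` object
#' @return `p`, invisibly; stops with an itemized message on violation
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "electrocyte_params"))
  errs <- character()
  pos <- c("capacitance", "g_na_max", "g_k_max", "g_leak",
           "k_alpha_m", "k_beta_m", "k_alpha_h", "beta_h_max", "beta_h_k",
           "k_alpha_n", "k_beta_n", "p_na", "pk_over_pna",
           "na_in", "na_out", "k_in", "k_out", "temperature")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      errs <- c(errs, sprintf("'%s' must be a single positive number", f))
  }
  if (!is.numeric(p$gamma) || p$gamma < 0 || p$gamma > 1)
    errs <- c(errs, "'gamma' must lie in [0, 1]")
  if (length(errs) == 0L) {
    ek_nernst <- nernst(p$k_out, p$k_in, p$temperature)
    if (abs(ek_nernst - p$e_k) > 0.5)
      errs <- c(errs, sprintf(
        "fixed e_k (%.2f mV) is inconsistent with Nernst K+ potential (%.2f mV)",
        p$e_k, ek_nernst))
  }
  if (length(errs) > 0L)
    stop("invalid parameter set:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.electrocyte_params <- function(x, ...) {
  cat("Electrocyte posterior-membrane parameters\n")
  cat(sprintf("  C = %g nF, gNa_max = %g uS (gamma = %g), gK_max = %g uS, gL = %g uS\n",
              x$capacitance, x$g_na_max, x$gamma, x$g_k_max, x$g_leak))
  cat(sprintf("  E_Na = %g mV, E_K = %g mV, E_L = %g mV, T = %g K\n",
              x$e_na, x$e_k, x$e_leak, x$temperature))
  cat(sprintf("  AChR: P_Na = %g mm^3/s, P_K/P_Na = %g, V_rev = %.2f mV\n",
              x$p_na, x$pk_over_pna, achr_reversal(x)))
  invisible(x)
}

#' Two-ion GHK reversal potential of the AChR synapse
#'
#' Zero-current potential of the combined Na+/K+ electrodiffusive pathway,
#' `V_rev = (RT/F) log((P_Na [Na]_o + P_K [K]_o) / (P_Na [Na]_i + P_K [K]_i))`.
#'
#' @param params an `electrocyte_params` object
#' @return reversal potential (mV); approximately +2.2 mV at defaults
#' @export
achr_reversal <- function(params) {
  r <- params$pk_over_pna
  rtf_mv(params$temperature) *
    log((params$na_out + r * params$k_out) / (params$na_in + r * params$k_in))
}
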