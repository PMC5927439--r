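#' Right-hand side of the membrane equation
#'
#' Pure-R reference implementation of the model's ordinary differential
#' equations: `C dV/dt = -I_NaT - I_NaP - I_K - I_L + I_stim`, with the
#' gates obeying `dj/dt = alpha_j (1 - j) - beta_j j`.  `I_stim` is the
#' injected clamp current plus the depolarizing synaptic current
#' (`-level * (I_AChR(Na) + I_AChR(K))` in the outward-positive
#' convention).  The compiled integrator uses an equivalent C
#' implementation; this function is the reference for tests and for
#' inspecting instantaneous derivatives.
#'
#' @param t time (ms)
#' @param state named vector or list with `v`, `m`, `h`, `n`
#' @param regime a [stimulus_regime()] (or `NULL` for an unforced membrane)
#' @param params an [electrocyte_params()] object
#' @return named list: `deriv` (named numeric, d(state)/dt in mV/ms and
#'   ms^-1) and `currents` (the full breakdown in nA: `i_na_t`, `i_na_p`,
#'   `i_k`, `i_leak`, `i_achr_na`, `i_achr_k`, `i_clamp`)
#' @export
membrane_rhs <- function(t, state, regime = NULL,
                         params = electrocyte_params()) {
  v <- state[["v"]]
  cc <- conductance_currents(state, params)
  lev <- 0
  i_clamp <- 0
  if (!is.null(regime)) {
    if (regime$amplitude > 0 || regime$background > 0)
      lev <- syn_level(t, regime)
    if (!is.null(regime$clamp)) i_clamp <- clamp_current(t, regime$clamp)
  }
  i_achr_na <- ghk_current(v, "Na", lev, params)
  i_achr_k <- ghk_current(v, "K", lev, params)
  dv <- (-(cc$i_na_t + cc$i_na_p + cc$i_k + cc$i_leak) -
           (i_achr_na + i_achr_k) + i_clamp) / params$capacitance
  dgate <- vapply(c("m", "h", "n"), function(g) {
    r <- gate_rates(v, g, params)
    r$alpha * (1 - state[[g]]) - r$beta * state[[g]]
  }, numeric(1))
  list(deriv = c(v = dv, dgate),
       currents = c(cc, list(i_achr_na = i_achr_na, i_achr_k = i_achr_k,
                             i_clamp = i_clamp)))
}

#' Resting state of the unforced membrane
#'
#' Relaxes the unforced membrane for `relax_ms` and refines the endpoint by
#' root finding on the steady-state current balance (gates held at their
#' voltage equilibria).  At the default parameters the rest potential sits
#' just above E_K, near -93.8 mV, set by the balance of the K+-equal leak
#' against the small depolarizing Na+ window current.
#'
#' @param params an [electrocyte_params()] object
#' @param relax_ms duration of the preliminary unforced relaxation (ms)
#' @return named numeric vector `c(v, m, h, n)`
#' @export
resting_state <- function(params = electrocyte_params(), relax_ms = 200) {
  eq <- function(v) vapply(c("m", "h", "n"), function(g)
    gate_equilibrium(v, g, params)$x_inf, numeric(1))
  # relaxation from a hyperpolarized guess
  v0 <- params$e_k + 2
  y0 <- c(v = v0, eq(v0))
  traj <- .integrate_raw(y0, params, .null_regime(), relax_ms, dt_out = 0.5)
  v_end <- traj[nrow(traj), "v"]
  # refine: steady-state net current must vanish
  balance <- function(v) {
    g <- eq(v)
    cc <- conductance_currents(list(v = v, m = g[["m"]], h = g[["h"]],
                                    n = g[["n"]]), params)
    -(cc$i_na_t + cc$i_na_p + cc$i_k + cc$i_leak)
  }
  span <- 2
  lo <- v_end - span; hi <- v_end + span
  if (lo <= params$e_k) lo <- params$e_k + 1e-6
  root <- tryCatch(stats::uniroot(balance, c(lo, hi), tol = 1e-12)$root,
                   error = function(e)
                     stop("resting-state refinement failed; residual at ",
                          signif(v_end, 6), " mV: ",
                          signif(balance(v_end), 3), " nA", call. = FALSE))
  st <- c(v = root, eq(root))
  d <- membrane_rhs(0, as.list(st), NULL, params)$deriv
  if (max(abs(d)) > 1e-9)
    stop("resting state did not converge; max residual ", signif(max(abs(d)), 3))
  st
}

# regime placeholder for unforced integration (clamp of zero amplitude)
.null_regime <- function() {
  structure(list(amplitude = 0, frequency = 0, background = 0,
                 clamp = NULL, rise = 0.05, plateau = 0.2, decay_tau = 0.1,
                 start = 0, duration = Inf),
            class = "stimulus_regime")
}

# flatten params + regime into the fixed-layout vector expected by the
# compiled right-hand side (see src/membrane.c)
.epm_c_parms <- function(params, regime, duration) {
  cl <- regime$clamp
  ckind <- 0
  if (!is.null(cl))
    ckind <- match(cl$kind, c("step", "ramp", "pulse-train"))
  syn_dur <- min(regime$duration, duration)
  c(params$capacitance, params$g_na_max, params$g_k_max, params$g_leak,
    params$gamma, params$e_na, params$e_k, params$e_leak,
    params$k_alpha_m, params$eta_alpha_m, params$k_beta_m, params$eta_beta_m,
    params$k_alpha_h, params$eta_alpha_h,
    params$beta_h_max, params$beta_h_vhalf, params$beta_h_k,
    params$k_alpha_n, params$eta_alpha_n, params$k_beta_n, params$eta_beta_n,
    params$p_na * 1e-9, params$p_na * params$pk_over_pna * 1e-9,
    params$na_in, params$na_out, params$k_in, params$k_out,
    rtf_mv(params$temperature), .const$faraday,
    regime$background, regime$amplitude, regime$frequency,
    regime$rise, regime$plateau, regime$decay_tau,
    regime$start, syn_dur,
    ckind,
    if (is.null(cl)) 0 else cl$amplitude,
    if (is.null(cl)) 0 else cl$start,
    if (is.null(cl)) 0 else cl$duration,
    if (is.null(cl) || is.null(cl$width)) 0 else cl$width,
    if (is.null(cl) || is.null(cl$frequency)) 0 else cl$frequency)
}

.traj_cols <- c("i_na_t", "i_na_p", "i_k", "i_leak",
                "i_achr_na", "i_achr_k", "i_clamp", "syn")

.integrate_raw <- function(y0, params, regime, duration, dt_out = 0.005,
                           rtol = 1e-8, atol = 1e-8, hmax = 0.01) {
  times <- seq(0, duration, by = dt_out)
  out <- deSolve::ode(y = unname(y0), times = times, func = "epm_derivs",
                      parms = .epm_c_parms(params, regime, duration),
                      dllname = "electrocyte", initfunc = "epm_initmod",
                      nout = 8, outnames = .traj_cols,
                      method = "lsoda", rtol = rtol, atol = atol, hmax = hmax)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed at t = ", utils::tail(out[, 1], 1), " ms",
         call. = FALSE)
  colnames(out) <- c("t", "v", "m", "h", "n", .traj_cols)
  out
}

#' Integrate the membrane model under a stimulus regime
#'
#' Runs the compiled model from the resting state with the `lsoda`
#' stiff-capable adaptive integrator.  Output is sampled on a regular grid
#' (default 0.005 ms, fine enough to resolve the 0.05 ms stimulus rise),
#' and the maximal internal step is capped at `hmax` so that brief
#' synaptic pulses are never stepped over.  Results are deterministic for
#' identical inputs and solver options.
#'
#' @param params an [electrocyte_params()] object
#' @param regime a [stimulus_regime()], or `NULL` for an unforced run
#' @param duration simulated time (ms)
#' @param dt_out output sampling interval (ms)
#' @param rtol,atol relative/absolute solver tolerances
#' @param hmax maximal internal step (ms)
#' @param init optional initial state (named `c(v, m, h, n)`); defaults to
#'   [resting_state()]
#' @return a `membrane_trajectory`: a data frame with time (`t`, ms), the
#'   state (`v`, `m`, `h`, `n`), the current breakdown in nA (`i_na_t`,
#'   `i_na_p`, `i_k`, `i_leak`, `i_achr_na`, `i_achr_k`, `i_clamp`;
#'   positive outward, clamp positive depolarizing) and the instantaneous
#'   syn_clamp level (`syn`), with the regime, parameters and solver
#'   options attached as attributes
#' @examples
#' \donttest{
#' traj <- simulate_membrane(regime = stimulus_regime(amplitude = 1,
#'                                                    frequency = 200),
#'                           duration = 30)
#' range(traj$v)
#' }
#' @export
simulate_membrane <- function(params = electrocyte_params(), regime = NULL,
                              duration, dt_out = 0.005,
                              rtol = 1e-8, atol = 1e-8, hmax = 0.01,
                              init = NULL) {
  if (is.null(regime)) regime <- .null_regime()
  stopifnot(inherits(regime, "stimulus_regime"), duration > 0)
  y0 <- if (is.null(init)) resting_state(params) else init
  out <- .integrate_raw(y0, params, regime, duration, dt_out, rtol, atol,
                        hmax)
  traj <- as.data.frame(out)
  attr(traj, "params") <- params
  attr(traj, "regime") <- regime
  attr(traj, "solver") <- list(dt_out = dt_out, rtol = rtol, atol = atol,
                               hmax = hmax)
  class(traj) <- c("membrane_trajectory", "data.frame")
  traj
}

#' Detect action potentials in a trajectory
#'
#' A spike is an upward crossing of `threshold` followed by a local
#' maximum; the peak voltage is refined by a quadratic fit through the
#' three samples bracketing the maximum.  Crossings within the refractory
#' lockout of the previous spike are ignored.
#'
#' @param traj a `membrane_trajectory` (or any data frame with columns `t`
#'   and `v`)
#' @param threshold detection threshold (mV); well above the model's
#'   apparent firing threshold near -45 mV and below all reported peaks
#' @param refractory minimal accepted inter-spike interval (ms)
#' @return a `spike_train`: data frame with spike times `t_peak` (ms) and
#'   interpolated peak voltages `v_peak` (mV)
#' @export
detect_spikes <- function(traj, threshold = -20, refractory = 0.5) {
  t <- traj$t; v <- traj$v
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  t_peak <- numeric(0); v_peak <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (t[i] - last < refractory) next
    # local maximum after the crossing: first sample where v turns down
    j <- i + 1
    while (j < length(v) && v[j + 1] >= v[j]) j <- j + 1
    if (j <= 1 || j >= length(v)) next
    a <- v[j - 1]; b <- v[j]; cc <- v[j + 1]
    den <- a - 2 * b + cc
    if (den < 0) {
      off <- 0.5 * (a - cc) / den
      t_peak <- c(t_peak, t[j] + off * (t[j + 1] - t[j]))
      v_peak <- c(v_peak, b - (a - cc)^2 / (8 * den))
    } else {
      t_peak <- c(t_peak, t[j]); v_peak <- c(v_peak, b)
    }
    last <- t[j]
  }
  structure(data.frame(t_peak = t_peak, v_peak = v_peak),
            class = c("spike_train", "data.frame"))
}

#' Mean firing frequency of a spike train
#'
#' `1000 / mean(ISI)` over the spikes falling inside the analysis window.
#' Fewer than three spikes in the window is reported as non-firing (0 Hz).
#'
#' @param train a `spike_train` from [detect_spikes()]
#' @param window `c(t_min, t_max)` analysis window (ms); used to exclude
#'   the onset transient
#' @return frequency (Hz)
#' @export
measure_frequency <- function(train, window = c(0, Inf)) {
  st <- train$t_peak[train$t_peak >= window[1] & train$t_peak <= window[2]]
  if (length(st) < 3) return(0)
  1000 / mean(diff(st))
}

#' Charge-to-ion conversion constant
#'
#' Number of elementary charges carried by 1 nA flowing for 1 ms
#' (1 pC), in units of 1e9 ions.
#' @return ions per nA.ms, divided by 1e9
#' @export
ions_per_nAms <- function() 1e-12 / .const$e_charge / 1e9

#' Per-action-potential Na+ entry budget
#'
#' Integrates the inward Na+ charge carried by each pathway (transient
#' Nav, persistent Nav, AChR) over an analysis window aligned with the
#' drive, converts charge to ion counts and divides by the number of
#' action potentials, giving the per-AP Na+-entry budget that proxies
#' Na+/K+-ATPase demand (1 ATP per 3 Na+).  K+ tallies (delayed rectifier,
#' leak and AChR pathways, net outward) are returned alongside.
#'
#' For pulsatile drive the window spans whole stimulus periods, skipping
#' the first `skip_periods`; for steady drive it spans midpoints between
#' spikes, skipping spikes before `transient_ms`.  At least `min_aps`
#' action potentials must remain in the window.
#'
#' @param traj a `membrane_trajectory` from [simulate_membrane()]
#' @param train optional precomputed [detect_spikes()] result
#' @param skip_periods stimulus periods discarded as onset transient
#'   (pulsatile drive)
#' @param transient_ms onset transient discarded for steady drive (ms)
#' @param min_aps minimal number of APs required in the window
#' @return an `entry_tally`: list with per-AP Na+ entries (`na_t`, `na_p`,
#'   `nav` = their sum, `achr`, `total`), per-AP K+ tallies (`k_kv`,
#'   `k_leak`, `k_achr`, net outward), all in units of 1e9 ions, plus
#'   `n_aps` and the analysis window
#' @export
tally_na_entry <- function(traj, train = NULL, skip_periods = 5,
                           transient_ms = 25, min_aps = 15) {
  regime <- attr(traj, "regime")
  if (is.null(train)) train <- detect_spikes(traj)
  t <- traj$t
  pulsatile <- !is.null(regime) && regime$amplitude > 0
  if (pulsatile) {
    per <- 1000 / regime$frequency
    n_per <- floor((max(t) - regime$start) / per)
    if (n_per <= skip_periods)
      stop("trajectory shorter than the transient-exclusion window")
    w0 <- regime$start + skip_periods * per
    w1 <- regime$start + n_per * per
  } else {
    st <- train$t_peak[train$t_peak >= transient_ms]
    if (length(st) < 2)
      stop("too few post-transient APs for a steady-drive tally")
    mid <- (st[-1] + st[-length(st)]) / 2
    w0 <- mid[1]; w1 <- mid[length(mid)]
  }
  n_aps <- sum(train$t_peak >= w0 & train$t_peak <= w1)
  if (n_aps < min_aps)
    stop("only ", n_aps, " APs in the analysis window; need >= ", min_aps)
  sel <- t >= w0 & t <= w1
  trapz <- function(y) {
    x <- t[sel]; y <- y[sel]
    sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  }
  conv <- ions_per_nAms()
  # inward Na+: currents are outward-positive, so entry = -integral
  na_t <- -trapz(traj$i_na_t) / n_aps * conv
  na_p <- -trapz(traj$i_na_p) / n_aps * conv
  achr <- -trapz(traj$i_achr_na) / n_aps * conv
  res <- list(na_t = na_t, na_p = na_p, nav = na_t + na_p, achr = achr,
              total = na_t + na_p + achr,
              k_kv = trapz(traj$i_k) / n_aps * conv,
              k_leak = trapz(traj$i_leak) / n_aps * conv,
              k_achr = trapz(traj$i_achr_k) / n_aps * conv,
              n_aps = n_aps, window = c(w0, w1))
  class(res) <- "entry_tally"
  res
}

#' @export
print.entry_tally <- function(x, ...) {
  cat(sprintf(
    "Na+ entry per AP (x1e9 ions): total %.2f = Nav %.2f (T %.2f + P %.2f) + AChR %.2f  [%d APs]\n",
    x$total, x$nav, x$na_t, x$na_p, x$achr, x$n_aps))
  invisible(x)
}
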