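#' Run a stimulus-driven train and summarize it
#'
#' Convenience wrapper used by the protocol drivers: simulates long enough
#' for `skip_periods + n_aps` stimulus periods (pulsatile drive) or a
#' post-transient train at `expect_hz` (steady drive), detects spikes and
#' reports the post-transient mean peak voltage, the firing frequency and
#' whether the train is 1:1 entrained with the pulsatile drive.
#'
#' @param params an [electrocyte_params()] object
#' @param regime a [stimulus_regime()]
#' @param n_aps number of post-transient APs to cover
#' @param skip_periods onset periods excluded from measurement
#' @param expect_hz rough expected firing rate for steady drive (Hz); sets
#'   the simulated duration
#' @param transient_ms onset transient for steady drive (ms)
#' @param ... passed to [simulate_membrane()]
#' @return list with `traj`, `train`, `v_peak` (mean post-transient),
#'   `v_peak_sd`, `frequency` (Hz), `entrained` (logical or `NA` for
#'   steady drive), `n_aps`
#' @export
run_train <- function(params, regime, n_aps = 20, skip_periods = 5,
                      expect_hz = 200, transient_ms = 25, ...) {
  if (regime$amplitude > 0) {
    per <- 1000 / regime$frequency
    duration <- (skip_periods + n_aps) * per
    w0 <- skip_periods * per
  } else {
    duration <- transient_ms + n_aps * 1000 / expect_hz
    w0 <- transient_ms
  }
  traj <- simulate_membrane(params, regime, duration, ...)
  train <- detect_spikes(traj)
  sel <- train$t_peak >= w0
  vp <- train$v_peak[sel]
  entrained <- NA
  if (regime$amplitude > 0)
    entrained <- sum(sel) == n_aps
  list(traj = traj, train = train,
       v_peak = if (length(vp)) mean(vp) else NA_real_,
       v_peak_sd = if (length(vp) > 1) stats::sd(vp) else NA_real_,
       frequency = measure_frequency(train, c(w0, Inf)),
       entrained = entrained, n_aps = sum(sel))
}

#' Calibrate the maximal Na+ conductance to a target peak voltage
#'
#' Bisects on `g_na_max` until the post-transient mean AP peak equals
#' `target_vpeak` (default 12.86 mV, the standard AP amplitude).  The peak
#' voltage increases monotonically with `g_na_max`, so plain bisection on
#' the bracket suffices.  For pulsatile drive the train must be 1:1
#' entrained at both bracket ends; otherwise the calibration aborts.
#'
#' @param params an [electrocyte_params()] object (its `g_na_max` is
#'   overridden during the search)
#' @param frequency pulse rate (Hz) for pulsatile drive; ignored when
#'   `amplitude = 0`
#' @param amplitude pulsatile syn_clamp amplitude (0 for steady drive)
#' @param background steady syn_clamp background level
#' @param target_vpeak target mean peak voltage (mV)
#' @param bracket search interval for `g_na_max` (uS)
#' @param tol bisection tolerance on `g_na_max` (uS)
#' @param expect_hz expected firing rate for steady drive (Hz)
#' @param ... passed to [run_train()]
#' @return list with `g_na_max` (uS), the verification `run` (a
#'   [run_train()] result at the calibrated conductance) and the achieved
#'   `v_peak`
#' @export
calibrate_gna_max <- function(params = electrocyte_params(), frequency = 200,
                              amplitude = 1, background = 0,
                              target_vpeak = 12.86,
                              bracket = c(300, 2500), tol = 0.5,
                              expect_hz = frequency, ...) {
  regime <- stimulus_regime(amplitude = amplitude,
                            frequency = if (amplitude > 0) frequency else NULL,
                            background = background)
  eval_g <- function(g) {
    p <- params; p$g_na_max <- g
    run_train(p, regime, expect_hz = expect_hz, ...)
  }
  lo <- bracket[1]; hi <- bracket[2]
  ok <- function(r) is.na(r$entrained) || isTRUE(r$entrained)
  # below target: insufficient conductance, including failure to entrain
  below <- function(r) !ok(r) || is.na(r$v_peak) || r$v_peak < target_vpeak
  r_lo <- eval_g(lo); r_hi <- eval_g(hi)
  if (!ok(r_hi))
    stop("calibration bracket failure: drive does not entrain 1:1 even at ",
         hi, " uS", call. = FALSE)
  if (!below(r_lo) || below(r_hi))
    stop("calibration bracket failure: target peak ", target_vpeak,
         " mV not spanned by [", lo, ", ", hi, "] uS", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (below(eval_g(mid))) lo <- mid else hi <- mid
  }
  g <- (lo + hi) / 2
  run <- eval_g(g)
  list(g_na_max = g, run = run, v_peak = run$v_peak)
}

#' Threshold level for sustained firing under steady synaptic drive
#'
#' Bisects on the constant (0 Hz) syn_clamp level for the smallest value
#' producing sustained repetitive firing.  Firing onset here is a
#' saddle-node-on-invariant-circle bifurcation (class 1 excitability), so
#' the inter-spike interval diverges at threshold; the detection window
#' must be long enough that slow near-threshold firing still counts
#' (default 2000 ms, requiring at least `min_spikes` post-transient
#' spikes).
#'
#' @param params an [electrocyte_params()] object
#' @param bracket `c(lo, hi)` syn_clamp levels spanning non-firing and
#'   firing
#' @param tol absolute bisection tolerance on the level
#' @param window detection window (ms)
#' @param transient_ms spikes before this time are ignored
#' @param min_spikes spikes required to call the membrane firing
#' @param ... passed to [simulate_membrane()]
#' @return the threshold syn_clamp level (dimensionless)
#' @export
steady_threshold <- function(params = electrocyte_params(),
                             bracket = c(0.002, 0.05), tol = 1e-4,
                             window = 2000, transient_ms = 25,
                             min_spikes = 3, ...) {
  fires <- function(level) {
    traj <- simulate_membrane(params,
                              stimulus_regime(background = level),
                              duration = window, ...)
    train <- detect_spikes(traj)
    sum(train$t_peak >= transient_ms) >= min_spikes
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo) || !fires(hi))
    stop("threshold bracket failure: need non-firing at ", lo,
         " and firing at ", hi, call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Frequency-intensity curve
#'
#' Firing frequency and mean peak voltage as a function of stimulus
#' intensity, for a family of steady syn_clamp levels or of current-clamp
#' step amplitudes.  Non-firing points are reported as 0 Hz.  The model
#' shows class 1 excitability: frequency rises continuously from zero as
#' the intensity crosses threshold.
#'
#' @param params an [electrocyte_params()] object
#' @param levels sorted steady syn_clamp levels (used when
#'   `drive = "syn"`)
#' @param currents sorted step amplitudes in nA (used when
#'   `drive = "clamp"`)
#' @param drive `"syn"` or `"clamp"`
#' @param duration simulated time per point (ms)
#' @param transient_ms onset transient excluded from measurement (ms)
#' @param step_ms duration of the current step (ms, clamp drive)
#' @param ... passed to [simulate_membrane()]
#' @return data frame with columns `intensity`, `frequency` (Hz),
#'   `v_peak` (mV, `NA` when not firing)
#' @export
frequency_curve <- function(params = electrocyte_params(), levels = NULL,
                            currents = NULL, drive = c("syn", "clamp"),
                            duration = 400, transient_ms = 100,
                            step_ms = 40, ...) {
  drive <- match.arg(drive)
  grid <- if (drive == "syn") levels else currents
  stopifnot(!is.null(grid), !is.unsorted(grid))
  res <- lapply(grid, function(x) {
    regime <- if (drive == "syn") stimulus_regime(background = x)
      else stimulus_regime(clamp = current_clamp("step", x, step_ms))
    dur <- if (drive == "syn") duration else step_ms
    tr0 <- if (drive == "syn") transient_ms else 0
    traj <- simulate_membrane(params, regime, dur, ...)
    train <- detect_spikes(traj)
    sel <- train$t_peak >= tr0
    data.frame(intensity = x,
               frequency = measure_frequency(train, c(tr0, Inf)),
               v_peak = if (any(sel)) mean(train$v_peak[sel]) else NA_real_)
  })
  do.call(rbind, res)
}

#' Devil's-staircase entrainment scan
#'
#' Scans the pulsatile amplitude atop a fixed subthreshold background and
#' records the output firing frequency, exposing the rational locking
#' plateaus (1:1, 1:2, 1:3, ...) of the periodically forced membrane.  A
#' grid point is locked at ratio `1/k` when its output frequency is within
#' `lock_tol` (relative) of `frequency/k`; plateaus are locked ratios held
#' over at least two consecutive grid points.  The critical amplitude is
#' the smallest grid amplitude from which 1:1 locking is sustained through
#' the top of the grid.
#'
#' @param params an [electrocyte_params()] object
#' @param background subthreshold steady syn_clamp level
#' @param frequency pulse rate (Hz)
#' @param amplitudes amplitude grid (sorted)
#' @param duration simulated time per point (ms)
#' @param transient_ms onset transient excluded from measurement (ms)
#' @param lock_tol relative frequency tolerance for calling a point locked
#' @param max_ratio largest `k` in the `1/k` locking ratios searched
#' @param ... passed to [simulate_membrane()]
#' @return list of class `staircase_result`: `curve` (data frame
#'   `amplitude`, `frequency`), `plateaus` (data frame `ratio`,
#'   `frequency`, `amp_lo`, `amp_hi`, `n_points`), `critical_amplitude`
#'   (smallest amplitude with sustained 1:1 locking, `NA` if never
#'   reached), and the drive description
#' @export
devil_staircase <- function(params = electrocyte_params(),
                            background = 0.00736, frequency = 200,
                            amplitudes = seq(0, 0.5, by = 0.005),
                            duration = 300, transient_ms = 100,
                            lock_tol = 0.01, max_ratio = 6, ...) {
  stopifnot(!is.unsorted(amplitudes))
  f_out <- vapply(amplitudes, function(a) {
    regime <- if (a > 0)
      stimulus_regime(amplitude = a, frequency = frequency,
                      background = background)
    else stimulus_regime(background = background)
    traj <- simulate_membrane(params, regime, duration, ...)
    measure_frequency(detect_spikes(traj), c(transient_ms, Inf))
  }, numeric(1))
  curve <- data.frame(amplitude = amplitudes, frequency = f_out)
  # classify each point by locking ratio
  ratio <- rep(NA_integer_, length(amplitudes))
  for (k in seq_len(max_ratio)) {
    tgt <- frequency / k
    hit <- abs(f_out - tgt) <= lock_tol * tgt & is.na(ratio)
    ratio[hit] <- k
  }
  plateaus <- data.frame(ratio = integer(), frequency = numeric(),
                         amp_lo = numeric(), amp_hi = numeric(),
                         n_points = integer())
  r <- rle(ifelse(is.na(ratio), 0L, ratio))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] > 0 && r$lengths[i] >= 2) {
      plateaus <- rbind(plateaus, data.frame(
        ratio = r$values[i], frequency = frequency / r$values[i],
        amp_lo = amplitudes[starts[i]], amp_hi = amplitudes[ends[i]],
        n_points = r$lengths[i]))
    }
  }
  one2one <- !is.na(ratio) & ratio == 1L
  crit <- NA_real_
  if (any(one2one)) {
    idx <- which(one2one)
    # sustained: locked from this point to the top of the grid
    sustained <- idx[vapply(idx, function(i) all(one2one[i:length(one2one)]),
                            logical(1))]
    if (length(sustained)) crit <- amplitudes[min(sustained)]
  }
  structure(list(curve = curve, plateaus = plateaus,
                 critical_amplitude = crit, background = background,
                 frequency = frequency),
            class = "staircase_result")
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "Devil's staircase: %g Hz pulses atop background %g; critical 1:1 amplitude %s\n",
    x$frequency, x$background,
    ifelse(is.na(x$critical_amplitude), "not reached",
           format(x$critical_amplitude))))
  if (nrow(x$plateaus)) {
    cat("Plateaus:\n")
    print(x$plateaus, row.names = FALSE)
  }
  invisible(x)
}

#' Stimulus regimes of the cost table
#'
#' The 18 synaptic stimulation regimes explored for the per-AP Na+-entry
#' cost table: for each target frequency (200, 500, 600 Hz) a pure
#' pulsatile drive, pulses atop a subthreshold background (80% of the 0 Hz
#' firing threshold) at full and at reduced amplitude, pulses atop a
#' suprathreshold background (one that free-runs at roughly 70% of the
#' target frequency) at full and reduced amplitude, and a pure steady
#' drive firing at the target frequency.
#'
#' @return data frame with columns `row`, `target_hz`, `background`,
#'   `amplitude`
#' @export
cost_table_regimes <- function() {
  data.frame(
    row = 1:18,
    target_hz = rep(c(200, 500, 600), each = 6),
    background = c(0,      0.0074, 0.0074, 0.03, 0.03, 0.048,
                   0,      0.0064, 0.0064, 0.12, 0.12, 0.28,
                   0,      0.0054, 0.0054, 0.18, 0.18, 0.47),
    amplitude  = c(1, 1, 0.34, 1, 0.16, 0,
                   1, 1, 0.68, 1, 0.45, 0,
                   1, 1, 0.85, 1, 0.70, 0)
  )
}

#' Per-regime Na+ entry cost table
#'
#' For each stimulus regime, calibrates `g_na_max` to the standard peak
#' voltage and tallies the pathway-resolved Na+ entry per AP.  A failed
#' calibration is recorded as an `NA` row rather than aborting the table.
#'
#' @param params an [electrocyte_params()] object
#' @param regimes data frame as returned by [cost_table_regimes()] (or a
#'   subset of its rows)
#' @param target_vpeak calibration target (mV)
#' @param bracket `g_na_max` search interval (uS)
#' @param ... passed to [calibrate_gna_max()]
#' @return data frame with one row per regime: the regime description,
#'   calibrated `g_na_max` (uS) and per-AP entries `total`, `nav`, `achr`
#'   (x1e9 ions)
#' @export
cost_matrix <- function(params = electrocyte_params(),
                        regimes = cost_table_regimes(),
                        target_vpeak = 12.86, bracket = c(300, 2500), ...) {
  res <- lapply(seq_len(nrow(regimes)), function(i) {
    rg <- regimes[i, ]
    out <- data.frame(rg, g_na_max = NA_real_, total = NA_real_,
                      nav = NA_real_, achr = NA_real_)
    cal <- tryCatch(
      calibrate_gna_max(params, frequency = rg$target_hz,
                        amplitude = rg$amplitude,
                        background = rg$background,
                        target_vpeak = target_vpeak, bracket = bracket,
                        expect_hz = rg$target_hz, ...),
      error = function(e) {
        warning("row ", rg$row, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(cal)) {
      tl <- tally_na_entry(cal$run$traj, cal$run$train)
      out$g_na_max <- cal$g_na_max
      out$total <- tl$total; out$nav <- tl$nav; out$achr <- tl$achr
    }
    out
  })
  do.call(rbind, res)
}

#' Calibrated pure-pulsatile Na+ entries across frequencies
#'
#' Calibrates `g_na_max` at each frequency for the standard pulsatile
#' drive (amplitude 1) and tallies the per-AP Na+ entry; the substrate for
#' the cost-versus-frequency fit.
#'
#' @param params an [electrocyte_params()] object
#' @param frequencies pulse rates (Hz)
#' @param ... passed to [calibrate_gna_max()]
#' @return data frame with `frequency`, `g_na_max`, `total`, `nav`, `achr`
#' @export
pulsatile_entries <- function(params = electrocyte_params(),
                              frequencies = c(300, 400, 500), ...) {
  res <- lapply(frequencies, function(f) {
    cal <- calibrate_gna_max(params, frequency = f, ...)
    tl <- tally_na_entry(cal$run$traj, cal$run$train)
    data.frame(frequency = f, g_na_max = cal$g_na_max, total = tl$total,
               nav = tl$nav, achr = tl$achr)
  })
  do.call(rbind, res)
}

#' Exponential fold change of per-AP cost with frequency
#'
#' Fits `entry = A exp(b f)` to (frequency, entry) points by unweighted
#' least squares in log space and returns the fitted ratio between
#' `f_hi` and `f_lo` (`exp(b (f_hi - f_lo))`).
#'
#' @param frequencies frequencies (Hz)
#' @param entries per-AP total Na+ entries (positive, any consistent unit)
#' @param f_lo,f_hi frequencies whose fitted ratio is reported (Hz)
#' @return the fold change (dimensionless)
#' @examples
#' cost_fold_change(c(300, 400, 500), 60 * exp(0.0008 * c(300, 400, 500)))
#' @export
cost_fold_change <- function(frequencies, entries, f_lo = 300, f_hi = 500) {
  stopifnot(length(frequencies) == length(entries), length(entries) >= 2)
  if (any(entries <= 0)) stop("entries must be positive")
  b <- stats::coef(stats::lm(log(entries) ~ frequencies))[["frequencies"]]
  exp(b * (f_hi - f_lo))
}

#' Peak-voltage sweep across nearby frequencies (jamming avoidance)
#'
#' Holds `g_na_max` fixed and measures the mean AP peak for standard
#' pulsatile drive at frequencies around a center, emulating the transient
#' ~10 Hz discharge-frequency excursions of the jamming avoidance
#' response.  With the conductance calibrated for the center frequency the
#' peak declines only slightly over a +10 Hz excursion.
#'
#' @param params an [electrocyte_params()] object
#' @param center center frequency (Hz)
#' @param g_na_max fixed maximal Na+ conductance (uS)
#' @param deltas frequency offsets from the center (Hz)
#' @param amplitude pulsatile amplitude
#' @param ... passed to [run_train()]
#' @return data frame with `frequency`, `v_peak`, and `delta_v_peak`
#'   relative to the center frequency
#' @export
jar_sweep <- function(params = electrocyte_params(), center = 400,
                      g_na_max = 783, deltas = seq(-10, 10, by = 5),
                      amplitude = 1, ...) {
  p <- params; p$g_na_max <- g_na_max
  freqs <- center + deltas
  vp <- vapply(freqs, function(f) {
    run_train(p, stimulus_regime(amplitude = amplitude, frequency = f),
              ...)$v_peak
  }, numeric(1))
  data.frame(frequency = freqs, v_peak = vp,
             delta_v_peak = vp - vp[which(freqs == center)[1]])
}

#' Effect of pulsatile stimulus amplitude on peaks and Na+ budgets
#'
#' At fixed `g_na_max`, sweeps the pulsatile amplitude and reports the AP
#' peak and the pathway-resolved Na+ entry.  Larger stimuli push far more
#' Na+ through the AChR pathway, yet the total entry is almost unchanged
#' because the early AChR influx displaces Nav influx; at very large
#' amplitudes the peak declines.
#'
#' @param params an [electrocyte_params()] object
#' @param frequency pulse rate (Hz)
#' @param amplitudes sorted pulsatile amplitudes
#' @param g_na_max fixed maximal Na+ conductance (uS)
#' @param ... passed to [run_train()]
#' @return data frame with `amplitude`, `v_peak`, `total`, `nav`, `achr`
#' @export
pulse_amplitude_scan <- function(params = electrocyte_params(),
                                 frequency = 200,
                                 amplitudes = c(0.5, 1, 2, 3, 5),
                                 g_na_max = 700, ...) {
  stopifnot(!is.unsorted(amplitudes))
  p <- params; p$g_na_max <- g_na_max
  res <- lapply(amplitudes, function(a) {
    run <- run_train(p, stimulus_regime(amplitude = a,
                                        frequency = frequency), ...)
    tl <- tally_na_entry(run$traj, run$train)
    data.frame(amplitude = a, v_peak = run$v_peak, total = tl$total,
               nav = tl$nav, achr = tl$achr)
  })
  do.call(rbind, res)
}
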