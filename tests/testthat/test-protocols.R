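test_that("exponential cost fit recovers planted parameters", {
  f <- c(300, 400, 500)
  # synthetic exact-exponential entries: fold must come back exactly
  planted <- 52 * exp(0.00079 * f)
  expect_equal(cost_fold_change(f, planted), exp(0.00079 * 200),
               tolerance = 1e-12)
  # flat data: fold change of 1
  expect_equal(cost_fold_change(f, rep(63.1, 3)), 1)
  expect_error(cost_fold_change(f, c(1, -2, 3)), "positive")
})

test_that("threshold search demands a valid bracket", {
  expect_error(steady_threshold(default_params, bracket = c(0.05, 0.1),
                                window = 200),
               "bracket")
})

test_that("firing frequency rises continuously with steady drive intensity", {
  # class 1 excitability: non-decreasing f-I curve through threshold
  fc <- frequency_curve(default_params,
                        levels = c(0.005, 0.0095, 0.012, 0.05),
                        duration = 600, transient_ms = 100)
  expect_equal(fc$frequency[1], 0)            # below threshold: silent
  expect_true(all(diff(fc$frequency) >= 0))
  expect_gt(fc$frequency[4], 150)
  # well above threshold the firing is fast; just past it, much slower
  expect_lt(fc$frequency[3], fc$frequency[4] / 2)
})

test_that("current-clamp steps drive repetitive firing", {
  fc <- frequency_curve(default_params, currents = c(500, 1500),
                        drive = "clamp", step_ms = 40)
  expect_true(all(fc$frequency > 50))
  expect_true(all(diff(fc$frequency) >= 0))
})

test_that("calibration hits the target peak and reports the verification run", {
  cal <- calibrate_gna_max(default_params, frequency = 200,
                           bracket = c(500, 1000))
  expect_equal(cal$v_peak, 12.86, tolerance = 2e-3)
  expect_true(cal$run$entrained)
  expect_equal(cal$g_na_max, 700, tolerance = 0.02)
  # an unreachable target errors out rather than returning an endpoint
  expect_error(calibrate_gna_max(default_params, frequency = 200,
                                 target_vpeak = 40,
                                 bracket = c(500, 1000)),
               "bracket")
})

test_that("jar sweep is anchored at zero and declines with frequency", {
  js <- jar_sweep(default_params, center = 400, g_na_max = 783,
                  deltas = c(-10, 0, 10))
  expect_equal(js$delta_v_peak[js$frequency == 400], 0)
  expect_true(all(diff(js$v_peak) < 0))   # monotone decline 390 -> 410
})

test_that("background-fraction choice barely affects peaks and budgets", {
  # subthreshold background at 75%/80%/85% of the 0 Hz firing threshold
  thr <- 0.00927
  res <- lapply(thr * c(0.75, 0.80, 0.85), function(bg) {
    run <- run_train(default_params,
                     stimulus_regime(amplitude = 1, frequency = 200,
                                     background = bg))
    list(v = run$v_peak, tot = tally_na_entry(run$traj, run$train)$total)
  })
  v <- vapply(res, `[[`, numeric(1), "v")
  tot <- vapply(res, `[[`, numeric(1), "tot")
  expect_lt(max(v) - min(v), 0.01)                   # <= 0.01 mV
  expect_lt((max(tot) - min(tot)) / tot[2], 0.002)   # <= 0.2 %
})

test_that("cost table rows carry calibrated conductance and additive budgets", {
  cm <- cost_matrix(default_params, cost_table_regimes()[c(1, 6, 7, 12), ])
  expect_false(any(is.na(cm$g_na_max)))
  expect_equal(cm$total, cm$nav + cm$achr, tolerance = 1e-9)
  # pure pulsatile is the cheapest regime at each frequency
  expect_gt(cm$total[2], cm$total[1])   # 200 Hz: steady > pulsatile
  expect_gt(cm$total[4], cm$total[3])   # 500 Hz: steady > pulsatile
  # pure pulsatile at 200 Hz: the defining standard conductance
  expect_equal(cm$g_na_max[1], 700, tolerance = 0.02)
})

test_that("staircase machinery identifies rational locking plateaus", {
  # coarse grid around the known plateaus keeps this check fast
  st <- devil_staircase(default_params, amplitudes = seq(0.08, 0.2, 0.01),
                        duration = 300, transient_ms = 100)
  expect_true(any(st$plateaus$ratio == 4))   # 50 Hz
  expect_true(any(st$plateaus$ratio == 3))   # 66.7 Hz
  expect_true(is.na(st$critical_amplitude))  # 1:1 not reached on this grid
  f_01 <- st$curve$frequency[abs(st$curve$amplitude - 0.1) < 1e-9]
  expect_equal(f_01, 50, tolerance = 0.01)
})
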