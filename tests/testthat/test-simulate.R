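test_that("resting state is a stable fixed point just above E_K", {
  p <- default_params
  rs <- resting_state(p)
  expect_gt(rs[["v"]], p$e_k)
  expect_lt(rs[["v"]], -85)
  # gates sit at their voltage equilibria
  for (g in c("m", "h", "n"))
    expect_equal(rs[[g]], gate_equilibrium(rs[["v"]], g, p)$x_inf,
                 tolerance = 1e-9)
  # all four derivatives vanish
  d <- membrane_rhs(0, as.list(rs), NULL, p)$deriv
  expect_lt(max(abs(d)), 1e-9)
  # perturbing the potential and relaxing returns to the same state
  pert <- rs; pert[["v"]] <- rs[["v"]] + 1
  traj <- simulate_membrane(p, NULL, duration = 150, init = pert,
                            dt_out = 0.05)
  expect_equal(unname(unlist(traj[nrow(traj), c("v", "m", "h", "n")])),
               unname(rs), tolerance = 1e-5)
})

test_that("unforced membrane stays at rest", {
  traj <- simulate_membrane(default_params, duration = 100, dt_out = 0.05)
  rs <- resting_state(default_params)
  expect_lt(max(abs(traj$v - rs[["v"]])), 0.01)
  expect_equal(nrow(detect_spikes(traj)), 0)
})

test_that("hyperpolarized start drifts depolarizing toward rest", {
  # at E_K with gates equilibrated the Na window/leak balance pulls V up
  p <- default_params
  st <- list(v = p$e_k,
             m = gate_equilibrium(p$e_k, "m", p)$x_inf,
             h = gate_equilibrium(p$e_k, "h", p)$x_inf,
             n = gate_equilibrium(p$e_k, "n", p)$x_inf)
  expect_gt(membrane_rhs(0, st, NULL, p)$deriv[["v"]], 0)
})

test_that("compiled and reference right-hand sides agree along a trajectory", {
  p <- default_params
  rg <- stimulus_regime(amplitude = 1, frequency = 200)
  traj <- simulate_membrane(p, rg, duration = 10)
  idx <- seq(1, nrow(traj), by = 40)
  for (i in idx) {
    ref <- membrane_rhs(traj$t[i], as.list(traj[i, c("v", "m", "h", "n")]),
                        rg, p)
    # current breakdown recorded by the compiled solver matches R
    expect_equal(traj$i_na_t[i], ref$currents$i_na_t, tolerance = 1e-10)
    expect_equal(traj$i_k[i], ref$currents$i_k, tolerance = 1e-10)
    expect_equal(traj$i_achr_na[i], ref$currents$i_achr_na,
                 tolerance = 1e-10)
    expect_equal(traj$i_achr_k[i], ref$currents$i_achr_k, tolerance = 1e-10)
    # bookkeeping: -C dV/dt equals the signed sum of the breakdown
    lhs <- -p$capacitance * ref$deriv[["v"]]
    rhs <- with(traj[i, ], i_na_t + i_na_p + i_k + i_leak +
                  i_achr_na + i_achr_k - i_clamp)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("finite differences of V are consistent with the reported rhs", {
  p <- default_params
  rg <- stimulus_regime(background = 0.05)
  traj <- simulate_membrane(p, rg, duration = 30)
  i <- which(traj$t > 20)[seq(1, 1500, by = 250)]
  dt <- traj$t[2] - traj$t[1]
  fd <- (traj$v[i + 1] - traj$v[i - 1]) / (2 * dt)
  an <- vapply(i, function(k)
    membrane_rhs(traj$t[k], as.list(traj[k, c("v", "m", "h", "n")]),
                 rg, p)$deriv[["v"]], numeric(1))
  # central differences agree to O(dt^2) relative to the fastest slopes
  expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-2)
})

test_that("gating variables stay within [0, 1] along driven trajectories", {
  for (rg in list(stimulus_regime(amplitude = 1, frequency = 600),
                  stimulus_regime(background = 0.4))) {
    traj <- simulate_membrane(default_params, rg, duration = 40)
    for (g in c("m", "h", "n")) {
      expect_gte(min(traj[[g]]), 0)
      expect_lte(max(traj[[g]]), 1)
    }
  }
})

test_that("standard 200 Hz drive yields one 13 mV-class AP per pulse", {
  run <- standard_run_200()
  expect_true(run$entrained)
  expect_equal(run$frequency, 200, tolerance = 1e-4)
  expect_equal(run$v_peak, 12.86, tolerance = 0.02)
  # depolarization accelerates near the apparent threshold region (-45 mV)
  traj <- run$traj
  expect_gt(max(traj$v), 10)
  expect_lt(min(traj$v), -90)
})

test_that("spike detection counts threshold crossings of a synthetic wave", {
  t <- seq(0, 100, by = 0.01)
  k <- 7
  v <- -40 + 30 * sin(2 * pi * k * t / 100)   # crosses -20 mV k times
  fake <- data.frame(t = t, v = v)
  train <- detect_spikes(fake)
  expect_equal(nrow(train), k)
  expect_equal(train$v_peak, rep(-10, k), tolerance = 1e-5)
  # subthreshold wave: no spikes
  expect_equal(nrow(detect_spikes(data.frame(t = t, v = v - 25))), 0)
})

test_that("frequency measurement averages inter-spike intervals", {
  train <- structure(data.frame(t_peak = seq(10, 100, by = 5),
                                v_peak = 12),
                     class = c("spike_train", "data.frame"))
  expect_equal(measure_frequency(train), 200)
  few <- structure(data.frame(t_peak = c(10, 20), v_peak = 12),
                   class = c("spike_train", "data.frame"))
  expect_equal(measure_frequency(few), 0)   # non-firing
})

test_that("halving solver tolerances leaves V_peak unchanged to 0.01 mV", {
  rg <- stimulus_regime(amplitude = 1, frequency = 200)
  a <- simulate_membrane(default_params, rg, duration = 30)
  b <- simulate_membrane(default_params, rg, duration = 30,
                         rtol = 5e-9, atol = 5e-9, hmax = 0.005)
  pa <- detect_spikes(a)$v_peak
  pb <- detect_spikes(b)$v_peak
  expect_equal(length(pa), length(pb))
  expect_lt(max(abs(pa - pb)), 0.01)
})

test_that("Na entry tally is additive, stationary and window-robust", {
  run <- standard_run_200(n_aps = 40)
  tl <- tally_na_entry(run$traj, run$train)
  expect_equal(tl$total, tl$na_t + tl$na_p + tl$achr)
  expect_equal(tl$nav, tl$na_t + tl$na_p)
  expect_true(all(c(tl$na_t, tl$na_p, tl$achr) >= 0))
  # doubling the analysed train barely moves the per-AP values
  half <- run_train(default_params,
                    stimulus_regime(amplitude = 1, frequency = 200),
                    n_aps = 20)
  tl2 <- tally_na_entry(half$traj, half$train)
  expect_equal(tl$total, tl2$total, tolerance = 0.005)
  # per-period stationarity: successive periods agree within 1%
  conv <- ions_per_nAms()
  traj <- run$traj
  per_entry <- vapply(30:38, function(k) {
    sel <- traj$t >= k * 5 & traj$t <= (k + 1) * 5
    x <- traj$t[sel]
    y <- -(traj$i_na_t + traj$i_na_p + traj$i_achr_na)[sel]
    sum(diff(x) * (y[-length(y)] + y[-1]) / 2) * conv
  }, numeric(1))
  expect_lt(diff(range(per_entry)) / mean(per_entry), 0.01)
})

test_that("the charge-to-ion conversion constant is exact", {
  # 1 nA.ms = 1e-12 C; divided by the elementary charge, in units of 1e9
  expect_equal(ions_per_nAms(), 1e-12 / 1.602176634e-19 / 1e9)
  expect_equal(ions_per_nAms() * 1e9, 6.2415e6, tolerance = 1e-4)
})

test_that("tally demands a long enough post-transient train", {
  short <- run_train(default_params,
                     stimulus_regime(amplitude = 1, frequency = 200),
                     n_aps = 6)
  expect_error(tally_na_entry(short$traj, short$train), "APs")
})
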