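test_that("conductance currents match hand-evaluated values", {
  p <- electrocyte_params(g_na_max = 700, g_k_max = 2000, g_leak = 5,
                          gamma = 0.02, e_na = 55, e_k = -94)
  cc <- conductance_currents(list(v = -50, m = 0.5, h = 1, n = 0.1), p)
  # oracle: scalar arithmetic, 700 * 0.125 * 1 * 0.98 * (-105) etc.
  expect_equal(cc$i_na_t, -9003.75)
  expect_equal(cc$i_na_p, -183.75)
  expect_equal(cc$i_k, 8.8)
  expect_equal(cc$i_leak, 220)
})

test_that("driving-force and inactivation zeros behave as the equations say", {
  p <- default_params
  cc <- conductance_currents(list(v = p$e_na, m = 0.5, h = 0.7, n = 0.1), p)
  expect_equal(cc$i_na_t, 0)
  expect_equal(cc$i_na_p, 0)
  # persistent current has no h dependence
  a <- conductance_currents(list(v = -40, m = 0.3, h = 0, n = 0.1), p)
  b <- conductance_currents(list(v = -40, m = 0.3, h = 1, n = 0.1), p)
  expect_equal(a$i_na_t, 0)
  expect_equal(a$i_na_p, b$i_na_p)
})

test_that("GHK current matches a frozen direct evaluation and scales in level", {
  # frozen from a direct high-precision evaluation of the flux equation at
  # V = -90 mV, P_Na = 0.00016 mm^3/s, [Na] 13.5/120 mM, T = 293.15 K
  expect_equal(ghk_current(-90, "Na"), -6770.953627457866, tolerance = 1e-12)
  expect_equal(ghk_current(-90, "K"), 22.88466569441314, tolerance = 1e-12)
  expect_equal(ghk_current(-90, "Na", level = 0.25),
               0.25 * ghk_current(-90, "Na"))
  expect_error(ghk_current(-50, "Na", level = -1), "level")
})

test_that("the V = 0 singularity is removable and the series branch agrees", {
  p <- default_params
  rtf <- rtf_mv(p$temperature)
  # analytic limit: u/(1-exp(-u)) -> 1
  lim <- p$p_na * 1e-9 * 96485.33212 * (p$na_in - p$na_out) * 1e9
  expect_equal(ghk_current(0, "Na", 1, p), lim)
  expect_equal(ghk_current(1e-3, "Na"), ghk_current(0, "Na"),
               tolerance = 1e-4)
  # series branch vs direct formula across the matching region
  direct <- function(v, cin, cout, perm) {
    u <- v / rtf
    perm * 96485.33212 * u / (1 - exp(-u)) * (cin - cout * exp(-u)) * 1e9
  }
  for (u in c(-0.1, -0.01, -1e-3, 1e-3, 0.01, 0.1)) {
    v <- u * rtf
    expect_equal(ghk_current(v, "Na"),
                 direct(v, p$na_in, p$na_out, p$p_na * 1e-9),
                 tolerance = 1e-12)
    # the truncated series itself stays accurate well past its switch point
    series <- 1 + u / 2 + u^2 / 12 - u^4 / 720
    expect_equal(series, u / (1 - exp(-u)), tolerance = 1e-9)
  }
})

test_that("each single-ion GHK current is strictly increasing in voltage", {
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(ghk_current(v, "Na")) > 0))
  expect_true(all(diff(ghk_current(v, "K")) > 0))
})

test_that("the synaptic pathway reverses once, near +2.2 mV", {
  p <- default_params
  v <- seq(-100, 60, by = 0.5)
  tot <- achr_current(v, 1, p)
  expect_equal(sum(diff(sign(tot)) != 0), 1)   # exactly one zero
  vrev <- stats::uniroot(function(x) achr_current(x, 1, p), c(-20, 20),
                         tol = 1e-10)$root
  expect_equal(vrev, 2.2, tolerance = 0.02)
  expect_equal(vrev, achr_reversal(p), tolerance = 1e-6)
})

test_that("Nernst potentials reproduce the fixed reversals", {
  p <- default_params
  expect_equal(nernst(p$k_out, p$k_in, p$temperature), -94, tolerance = 0.001)
  expect_equal(nernst(p$na_out, p$na_in, p$temperature), 55, tolerance = 0.004)
  expect_equal(nernst(5, 5), 0)
})
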