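test_that("lambert_w satisfies its defining equation on both branches", {
  set.seed(5)
  z <- complex(real = stats::runif(25, -5, 5), imaginary = stats::runif(25, -5, 5))
  z <- c(z, -1 / exp(1), -0.1, -0.5, 0.5, 3, -50, -1e6)
  w0 <- lambert_w(z, branch = 0L)
  expect_lt(max(abs(w0 * exp(w0) - z) / pmax(1, abs(z))), 1e-10)
  expect_equal(lambert_w(0), 0 + 0i)
  expect_equal(lambert_w(-1 / exp(1)), complex(real = -1), tolerance = 1e-5)

  zn <- c(-0.3, -0.05, -1 / exp(1) + 1e-4)
  wm1 <- lambert_w(zn, branch = -1L)
  expect_lt(max(abs(wm1 * exp(wm1) - zn)), 1e-10)
  expect_true(all(Re(wm1) <= -1))

  # agrees with the real principal branch where one exists
  zr <- c(-0.3, -0.1, 0.2, 1, 10)
  expect_equal(Re(lambert_w(zr)), pracma::lambertWp(zr), tolerance = 1e-10)
})

test_that("eigenvalues satisfy the characteristic equation and dominate a spectral oracle", {
  set.seed(9)
  # brute-force oracle: Newton iteration on lambda + a + b e^(-lambda tau)
  # from a grid of complex starting points, keep the rightmost converged root
  spectral_oracle <- function(a, b, tau) {
    f <- function(l) l + a + b * exp(-l * tau)
    fp <- function(l) 1 - b * tau * exp(-l * tau)
    best <- NULL
    for (re in seq(-a - 2, 1, length.out = 14)) {
      for (im in seq(0.01, 2.5 * pi / tau, length.out = 14)) {
        l <- complex(real = re, imaginary = im)
        for (k in 1:100) {
          step <- f(l) / fp(l)
          l <- l - step
          if (abs(step) < 1e-13) break
        }
        if (abs(f(l)) < 1e-9 && (is.null(best) || Re(l) > Re(best))) best <- l
      }
    }
    best
  }
  for (i in 1:12) {
    p <- toy_params(tau1 = stats::runif(1, 15, 50),
                    c1 = stats::runif(1, 5, 30),
                    r_ikk = stats::runif(1, 0.04, 0.2))
    K <- stats::runif(1, 0.4, 2)
    lin <- dominant_eigenvalue(p, K)
    resid <- abs(lin$lambda + lin$a + lin$b * exp(-lin$lambda * p$tau1))
    expect_lt(resid, 1e-9)
    if (lin$oscillatory) {
      orc <- spectral_oracle(lin$a, lin$b, p$tau1)
      expect_equal(Re(lin$lambda), Re(orc), tolerance = 1e-6)
      expect_equal(abs(Im(lin$lambda)), abs(Im(orc)), tolerance = 1e-6)
    }
  }
})

test_that("degenerate linearizations reduce to closed forms", {
  p <- toy_params(c1 = 0)   # no delayed term after simplification: b = 0
  lin <- dominant_eigenvalue(p, K = 1)
  expect_equal(lin$b, 0)
  expect_equal(lin$lambda, complex(real = -lin$a))
  expect_false(lin$oscillatory)
  expect_true(is.na(lin$period))
})

test_that("analytic period and decay match the simulated model", {
  # underdamped sample, simulated near the fixed point where the
  # linearization applies: inter-peak interval within 5%, decay within 15%
  set.seed(21)
  cases <- 0
  cfg <- integrator_config(rel_tol = 1e-9, abs_tol = 1e-11, max_step = 1,
                           dt_out = 0.25)
  for (i in 1:25) {
    if (cases >= 10) break
    p <- toy_params(tau1 = stats::runif(1, 25, 45),
                    c1 = stats::runif(1, 8, 20),
                    r_ikk = stats::runif(1, 0.05, 0.12))
    lin <- dominant_eigenvalue(p, K = 1)
    if (!lin$oscillatory || lin$decay_rate < 5e-4 || lin$decay_rate > 0.05)
      next
    ys <- fixed_point(p, 1)
    tr <- integrate_dde("single", p, input_signal(amplitude = 1, t_on = -1e6),
                        t_end = 900, history = 1.03 * ys, config = cfg)
    osc <- measure_oscillations(tr, t_cut = 0,
                                prominence = 1e-5 * p$nf_tot)
    if (length(osc$peak_times) < 3 || is.na(osc$decay_estimate)) next
    cases <- cases + 1
    expect_lt(abs(osc$period_estimate - lin$period) / lin$period, 0.05)
    expect_lt(abs(osc$decay_estimate - lin$decay_rate) / lin$decay_rate,
              0.15)
  }
  expect_gte(cases, 5)
})

test_that("period is delay-dominated and input-insensitive", {
  p <- reference_params()
  K0 <- reference_K()
  tab <- period_sensitivity(p, K_grid = c(K0, 4 * K0),
                            tau_grid = c(p$tau1, 2 * p$tau1))
  base <- tab$period_min[tab$tau_min == p$tau1 & tab$k == K0]
  doubled <- tab$period_min[tab$tau_min == 2 * p$tau1 & tab$k == K0]
  expect_gt(doubled, 1.5 * base)

  k_quad <- tab$period_min[tab$tau_min == p$tau1 & tab$k == 4 * K0]
  expect_lt(abs(k_quad - base) / base, 0.10)

  # decay rate at fixed tau is monotone in K but only weakly sensitive:
  # the instantaneous coefficient a = rho r K grows linearly, and the
  # Re W(-b tau e^{a tau}) / tau term cancels most of that growth, so the
  # net decay increases sublinearly (the input "only negligibly affects
  # ... the oscillation decay")
  kg <- K0 * seq(2, 8, by = 0.5)
  dec <- vapply(kg, function(K) dominant_eigenvalue(p, K)$decay_rate, 0)
  expect_true(all(diff(dec) > 0))
  # quadrupling the input from 2 K0 changes the decay by well under 4x
  expect_lt(dec[kg == 8 * K0] / dec[kg == 2 * K0], 2)
})

test_that("explicit large-input fixed point matches the full root", {
  p <- toy_params(kc = 1e-4)  # nf_tot >> kc
  for (K in c(1, 2, 4)) {
    y_simpl <- fixed_point(p, K, simplified = TRUE)
    y_full <- fixed_point(p, K)
    expect_lt(abs(y_simpl - y_full) / y_full, 0.02)
  }
  # stationary total IkBa decreases with stronger input
  ys <- vapply(c(0.5, 1, 2, 4), function(K) fixed_point(p, K), 0)
  expect_true(all(diff(ys) < 0))
})

test_that("oscillation measurement recovers constructed signals", {
  tt <- seq(0, 600, by = 0.25)
  x <- 100 * exp(-tt / 200) * (1 + 0.5 * cos(2 * pi * tt / 90))
  traj <- data.frame(time_min = tt, x_nM = x)
  osc <- measure_oscillations(traj, t_cut = 360, prominence = 1)
  expect_equal(osc$period_estimate, 90, tolerance = 1 / 90)
  expect_equal(osc$decay_estimate, 1 / 200, tolerance = 0.1)

  flat <- data.frame(time_min = tt, x_nM = rep(50, length(tt)))
  osc0 <- measure_oscillations(flat, t_cut = 360, prominence = 1)
  expect_length(osc0$peak_times, 0)
  expect_identical(osc0$max_peak_trough_after, 0)
  expect_true(is.na(osc0$period_estimate))
})
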