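test_that("promoter occupancy follows the hyperbolic binding law", {
  occ <- promoter_occupancy(0, kp = 30)
  expect_equal(occ$p_free, 1)
  expect_equal(occ$p_bound, 0)
  expect_equal(promoter_occupancy(30, 30)$p_bound, 0.5)
  expect_equal(promoter_occupancy(9 * 30, 30)$p_bound, 0.9)

  x <- seq(0, 500, length.out = 40)
  occ <- promoter_occupancy(x, kp = 75)
  expect_equal(occ$p_free + occ$p_bound, rep(1, length(x)))
  expect_true(all(diff(occ$p_bound) > 0))

  expect_error(promoter_occupancy(-1, 30), "nonnegative")
  expect_error(promoter_occupancy(1, 0), "positive")
})

test_that("free NF-kB solver matches a damped fixed-point iteration oracle", {
  p <- toy_params()
  expect_equal(solve_free_nfkb(0, 0, p), p$nf_tot)

  # sequestration limit: x -> 0 monotonically as inhibitor grows
  y <- 10^seq(0, 6, length.out = 30)
  x <- solve_free_nfkb(y, 0, p)
  expect_true(all(diff(x) < 0))
  expect_lt(x[30], 1e-3)

  # independent brute-force oracle: bisection on the monotone conservation
  # residual x + (ya + ye) x / (kc + x) - nf_tot
  oracle <- function(ya, ye, p) {
    g <- function(x) x + (ya + ye) * x / (p$kc + x) - p$nf_tot
    lo <- 0; hi <- p$nf_tot
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  set.seed(42)
  for (i in 1:20) {
    ya <- stats::runif(1, 0, 2 * p$nf_tot)
    ye <- stats::runif(1, 0, 0.5 * p$nf_tot)
    expect_equal(solve_free_nfkb(ya, ye, p), oracle(ya, ye, p),
                 tolerance = 1e-10)
  }

  # strict monotonicity in each inhibitor argument on randomized grids
  set.seed(7)
  ya <- sort(stats::runif(15, 0, 150))
  ye0 <- stats::runif(1, 0, 30)
  expect_true(all(diff(solve_free_nfkb(ya, ye0, p)) < 0))
  ye <- sort(stats::runif(15, 0, 150))
  expect_true(all(diff(solve_free_nfkb(ye0, ye, p)) < 0))

  expect_error(solve_free_nfkb(-1, 0, p), "nonnegative")
})

test_that("single-loop right-hand side vanishes at fixed points", {
  p <- toy_params()
  for (K in c(0, 0.5, 1)) {
    ys <- fixed_point(p, K)
    expect_lt(abs(rhs_single(ys, ys, K, p)), 1e-10)
  }
})

test_that("dual right-hand side reduces exactly to the single model", {
  p <- toy_params(eps = 0)
  set.seed(11)
  for (i in 1:10) {
    y <- stats::runif(1, 0, 150)
    yd <- stats::runif(1, 0, 150)
    K <- stats::runif(1, 0, 2)
    d <- rhs_dual(c(y, 0), c(yd, 0), c(stats::runif(1, 0, 150), 0), K, p)
    expect_identical(d[1], rhs_single(y, yd, K, p))
  }
})

test_that("dual right-hand side vanishes at the dual fixed point", {
  p <- toy_params()
  ss <- steady_state("dual", p, K = 0.8)
  d <- rhs_dual(c(ss$y_a, ss$y_e), c(ss$y_a, ss$y_e), c(ss$y_a, ss$y_e),
                0.8, p)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("reduced model matches the full mass-action system at quasi-equilibrium", {
  # the independently coded mass-action ODE (explicit binding, fast rates)
  # must reproduce the reduced drift of the isoform totals
  p <- toy_params()
  set.seed(3)
  for (i in 1:8) {
    ya <- stats::runif(1, 5, 150)
    ye <- stats::runif(1, 0, 60)
    yad <- stats::runif(1, 5, 150)
    yed <- stats::runif(1, 0, 60)
    K <- stats::runif(1, 0, 1.5)
    x <- solve_free_nfkb(ya, ye, p)
    pa <- partition_ikb <- function(yt) {
      b <- yt * x / (p$kc + x); c(yt - b, b)
    }
    st <- c(pa(ya), pa(ye))
    x1 <- solve_free_nfkb(yad, yed, p)
    x2 <- solve_free_nfkb(stats::runif(1, 5, 150), yed, p)
    ma <- mass_action_drift(st, x1, x2, K, p)
    # reduced drift of totals with the same delayed nuclear NF-kB values
    occ1 <- promoter_occupancy(x1, p$kp)
    occ2 <- promoter_occupancy(x2, p$kp)
    red_a <- p$c0 * occ1$p_free + p$c1 * occ1$p_bound -
      p$deg_a * st[1] - p$r_ikk * K * (st[1] + p$rho * st[2])
    red_e <- p$eps * (p$c0_e * occ2$p_free + p$c1 * occ2$p_bound) -
      p$deg_e * st[3] - p$r_ikk * K * (st[3] + p$rho * st[4])
    expect_equal(ma[1] + ma[2], red_a, tolerance = 1e-8)
    expect_equal(ma[3] + ma[4], red_e, tolerance = 1e-8)
  }
})

test_that("NF-kB is conserved along integrated trajectories", {
  p <- toy_params()
  tr <- integrate_dde("dual", p, input_signal(amplitude = 1), t_end = 240,
                      config = fast_cfg())
  x <- tr$x_nM
  seq_a <- tr$y_alpha_nM * x / (p$kc + x)
  seq_e <- tr$y_eps_nM * x / (p$kc + x)
  expect_lt(max(abs(x + seq_a + seq_e - p$nf_tot)) / p$nf_tot, 1e-8)
})

test_that("feedback-free variant is non-oscillatory and attenuates faster with higher synthesis", {
  p <- toy_params()
  v <- no_feedback_variant(p)
  expect_identical(v$c1, 0)
  expect_true(v$constitutive_only)

  tr <- integrate_dde("none", v, input_signal(amplitude = 1), t_end = 480,
                      config = fast_cfg())
  osc <- measure_oscillations(tr, t_cut = 0, prominence = 0.01 * p$nf_tot)
  expect_lte(length(osc$peak_times), 1)

  pulse <- input_signal(amplitude = 1, duration = 15)
  slow <- integrate_dde("none", no_feedback_variant(p, c0 = 0.00185), pulse,
                        t_end = 2000, config = fast_cfg(dt = 1))
  fast <- integrate_dde("none", no_feedback_variant(p, c0 = 0.3), pulse,
                        t_end = 2000, config = fast_cfg(dt = 1))
  thr <- 0.2 * p$nf_tot
  t_fall <- function(tr) {
    i <- which(tr$x_nM > thr)
    if (!length(i)) return(0)
    tr$time_min[max(i)]
  }
  expect_lt(t_fall(fast), t_fall(slow))
})
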