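# a hand-built minimal network exercises the raw engine against analytic laws
birth_death_network <- function(k = 50, gamma = 1, delay = 0) {
  net <- list(architecture = "custom", species = "Y",
              init = c(Y = 0L),
              reactions = list(
                list(rate = k, order = 0, s1 = 0, s2 = 0, scales_k = 0,
                     delay = delay, change = c(Y = 1)),
                list(rate = gamma, order = 1, s1 = 1, s2 = 0, scales_k = 0,
                     delay = 0, change = c(Y = -1))),
              omega = 1, n_nfkb_total = NA, params = NULL)
  class(net) <- "nfkb_network"
  net
}

test_that("non-delayed birth-death matches the analytic stationary law", {
  net <- birth_death_network(k = 50, gamma = 1)
  finals <- vapply(1:200, function(s) {
    tr <- ssa_simulate(net, input_signal(amplitude = 0), t_end = 12, dt = 1,
                       seed = s)
    tr$Y[nrow(tr)]                      # t = 12 >> 1/gamma: stationary
  }, 0)
  se <- sqrt(50) / sqrt(200)            # Poisson stationary: var = mean = 50
  expect_lt(abs(mean(finals) - 50), 3 * se)
  # distribution consistent with Poisson(50)
  expect_gt(stats::chisq.test(table(cut(finals, c(-Inf, 44, 50, 56, Inf))),
                              p = diff(stats::ppois(c(-Inf, 44, 50, 56, Inf),
                                                    50)))$p.value, 0.01)
})

test_that("delayed births produce nothing strictly before the delay elapses", {
  net <- birth_death_network(k = 100, gamma = 0, delay = 7)
  tr <- ssa_simulate(net, input_signal(amplitude = 0), t_end = 20, dt = 0.25,
                     seed = 4, prewarm = FALSE)
  expect_true(all(tr$Y[tr$time_min < 7] == 0))
  expect_gt(tr$Y[nrow(tr)], 0)
})

test_that("queue prewarming supplies in-flight completions at the basal rate", {
  # pure accumulation: prewarmed births arrive during [0, delay) as a
  # Poisson(k * t) count, exactly as if the process had been running
  net <- birth_death_network(k = 100, gamma = 0, delay = 7)
  n3 <- vapply(1:80, function(s) {
    tr <- ssa_simulate(net, input_signal(amplitude = 0), t_end = 3.5, dt = 3.5,
                       seed = s, prewarm = TRUE)
    tr$Y[nrow(tr)]
  }, 0)
  expect_lt(abs(mean(n3) - 350), 3 * sqrt(350 / 80))
})

test_that("identical seeds give bit-identical trajectories", {
  p <- toy_params()
  net <- build_network("single", p, 500)
  a <- ssa_simulate(net, input_signal(amplitude = 1), t_end = 90, dt = 1,
                    seed = 42)
  b <- ssa_simulate(net, input_signal(amplitude = 1), t_end = 90, dt = 1,
                    seed = 42)
  expect_identical(a, b)
})

test_that("NF-kB conservation is exact at every sampled time", {
  p <- toy_params()
  for (arch in c("single", "dual")) {
    net <- build_network(arch, p, 800)
    tr <- ssa_simulate(net, input_signal(amplitude = 1), t_end = 120, dt = 1,
                       seed = 11)
    held <- tr$N + tr$C + tr$Pb
    if (arch == "dual") held <- held + tr$D + tr$Qb
    expect_true(all(held == 800))
  }
})

test_that("generated propensities reproduce the reduced rate equations", {
  # rate-equation limit: summed drift of the isoform totals at a
  # quasi-equilibrated state equals the reduced right-hand side
  p <- toy_params()
  net <- build_network("dual", p, 1000)
  set.seed(8)
  for (i in 1:6) {
    ya <- stats::runif(1, 5, 120)
    ye <- stats::runif(1, 0, 60)
    yad <- stats::runif(1, 5, 120)
    yed <- stats::runif(1, 0, 60)
    K <- stats::runif(1, 0, 1.5)
    x <- solve_free_nfkb(ya, ye, p)
    xd1 <- solve_free_nfkb(yad, yed, p)
    xd2 <- xd1
    occ <- promoter_occupancy(x, p$kp)
    occ_d <- promoter_occupancy(xd1, p$kp)
    pa <- partition_ikb(ya, x, p$kc)
    pe <- partition_ikb(ye, x, p$kc)
    conc <- c(N = x, Yf = pa$free, C = pa$bound,
              Pf = occ_d$p_free, Pb = occ_d$p_bound,
              Zf = pe$free, D = pe$bound,
              Qf = occ_d$p_free, Qb = occ_d$p_bound)
    drift <- network_drift(net, conc, K = K)
    red <- rhs_dual(c(ya, ye), c(yad, yed), c(yad, yed), K, p)
    expect_equal(unname(drift["Yf"] + drift["C"]), red[1], tolerance = 1e-8)
    expect_equal(unname(drift["Zf"] + drift["D"]), red[2], tolerance = 1e-8)
  }
})

test_that("dual network with eps = 0 never synthesizes IkBe", {
  p <- toy_params(eps = 0)
  net <- build_network("dual", p, 500)
  tr <- ssa_simulate(net, input_signal(amplitude = 1), t_end = 240, dt = 1,
                     seed = 2)
  expect_true(all(tr$Zf + tr$D <= tr$Zf[1] + tr$D[1]))
  ini0 <- replace(net$init, c("Zf", "D"), c(0L, 0L))
  ini0["N"] <- net$n_nfkb_total - ini0["C"] - ini0["Pb"]
  tr2 <- ssa_simulate(net, input_signal(amplitude = 1), t_end = 240, dt = 1,
                      init = ini0, seed = 3)
  expect_true(all(tr2$Zf == 0 & tr2$D == 0))
})

test_that("no-feedback network has constitutive synthesis only", {
  p <- toy_params()
  net <- build_network("none", p, 500)
  expect_false(any(c("Pf", "Pb") %in% net$species))
  ord <- vapply(net$reactions, `[[`, 0, "order")
  dly <- vapply(net$reactions, `[[`, 0, "delay")
  expect_true(any(ord == 0 & dly == p$tau1))   # delayed zeroth-order birth
})

test_that("ensemble summary and peak/late CV behave on constructed families", {
  # family of damped cosines with amplitude scatter and common phase:
  # peak CV equals the amplitude coefficient of variation
  tt <- seq(0, 300, by = 1)
  shape <- function(t) 40 * exp(-t / 150) * cos(2 * pi * (t - 20) / 90)
  set.seed(31)
  amp <- 1 + 0.1 * stats::rnorm(60)
  runs <- t(vapply(amp, function(a) 50 + a * shape(tt), tt))
  mu <- colMeans(runs)
  sdv <- apply(runs, 2, stats::sd)
  ens <- data.frame(time_min = tt, mean = mu, sd = sdv, cv = sdv / mu)
  res <- cv_peak_and_late(ens)
  expect_equal(res$t_peak, 20, tolerance = 3)
  # per-run value at the peak is 50 + a * shape(t_peak): the CV equals the
  # amplitude-scatter CV scaled by the shape factor
  f <- shape(res$t_peak)
  expect_equal(res$cv_peak, abs(f) * stats::sd(amp) / (50 + f * mean(amp)),
               tolerance = 0.02)

  # noiseless identical family
  runs0 <- matrix(rep(50 + shape(tt), 3), nrow = 3, byrow = TRUE)
  mu0 <- colMeans(runs0)
  ens0 <- data.frame(time_min = tt, mean = mu0, sd = 0, cv = 0)
  res0 <- cv_peak_and_late(ens0)
  expect_equal(res0$cv_peak, 0)
  expect_equal(res0$cv_late, 0)
})
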