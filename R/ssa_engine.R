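#' Build a discrete stochastic reaction network
#'
#' Translates the deterministic rate constants into stochastic propensities
#' via the volume factor `omega = n_nfkb_total / nf_tot` (molecules per nM)
#' and assembles one of four architectures:
#' * `"none"` -- constitutive (delayed) IkBa synthesis, no promoter species;
#' * `"single"` -- the 9-reaction IkBa negative feedback loop (one binary
#'   promoter, delayed synthesis, explicit complex association/dissociation,
#'   constitutive and IKK-mediated degradation);
#' * `"dual"` -- the 18-reaction network adding the IkBe loop;
#' * `"autorepressor"` -- a 4-reaction transcriptional auto-repressor used as
#'   the contrast architecture (signal-activated delayed synthesis of a
#'   repressor that binds its own promoter).
#'
#' Binding and dissociation are simulated explicitly; dissociation rate
#' constants (`k_off_complex`, `k_off_promoter`) set the quasi-equilibration
#' speed and the association constants follow from `kc` and `kp`.
#'
#' @param architecture One of `"none"`, `"single"`, `"dual"`,
#'   `"autorepressor"`.
#' @param params An `nfkb_params` object.
#' @param n_nfkb_total Total NF-kB copy number (>= 10); conservation of
#'   NF-kB (free + complexed + promoter-bound) is structural.
#' @param k_off_complex IkB--NF-kB dissociation rate (1/min).
#' @param k_off_promoter Promoter unbinding rate (1/min).
#' @param autorep Named list of auto-repressor constants
#'   (`synth` nM/min at K = 1, `deg` 1/min, `k_rep` nM dissociation constant,
#'   `delay` min); defaults are chosen so the deterministic peak matches the
#'   NF-kB networks' peak copy number.
#' @return An object of class `nfkb_network`.
#' @export
build_network <- function(architecture = c("single", "dual", "none",
                                           "autorepressor"),
                          params, n_nfkb_total = 1000,
                          k_off_complex = 6, k_off_promoter = 6,
                          autorep = list(synth = 7.4, deg = 0.014,
                                         k_rep = 10, delay = NULL)) {
  architecture <- match.arg(architecture)
  if (n_nfkb_total < 10) stop("n_nfkb_total must be >= 10", call. = FALSE)
  omega <- n_nfkb_total / params$nf_tot
  kon_c <- k_off_complex / params$kc / omega
  kon_p <- k_off_promoter / params$kp / omega

  rx <- list()
  add <- function(rate, order, s1 = 0, s2 = 0, scales_k = 0, delay = 0,
                  change) {
    rx[[length(rx) + 1L]] <<- list(rate = rate, order = order, s1 = s1,
                                   s2 = s2, scales_k = scales_k,
                                   delay = delay, change = change)
  }

  if (architecture == "autorepressor") {
    species <- c("R", "Pf", "Pb")
    ch <- function(...) { v <- c(...); stats::setNames(v, species) }
    delay <- if (is.null(autorep$delay)) params$tau1 else autorep$delay
    add(k_off_promoter / autorep$k_rep / omega, 2, 1, 2,
        change = ch(-1, -1, 1))                       # R + Pf -> Pb
    add(k_off_promoter, 1, 3, change = ch(1, 1, -1))  # Pb -> Pf + R
    add(autorep$deg, 1, 1, change = ch(-1, 0, 0))     # R -> 0
    add(autorep$synth * omega, 1, 2, scales_k = 1, delay = delay,
        change = ch(1, 0, 0))                         # Pf -> Pf + R (delayed)
    init <- stats::setNames(c(0L, 1L, 0L), species)
  } else {
    species <- c("N", "Yf", "C")
    if (architecture != "none") species <- c(species, "Pf", "Pb")
    if (architecture == "dual") species <- c(species, "Zf", "D", "Qf", "Qb")
    ns <- length(species)
    ch <- function(...) {
      v <- numeric(ns)
      args <- list(...)
      v[match(names(args), species)] <- unlist(args)
      v
    }
    i <- function(nm) match(nm, species)

    # IkBa complex and degradation reactions (shared by all variants)
    add(kon_c, 2, i("N"), i("Yf"), change = ch(N = -1, Yf = -1, C = 1))
    add(k_off_complex, 1, i("C"), change = ch(N = 1, Yf = 1, C = -1))
    add(params$deg_a, 1, i("Yf"), change = ch(Yf = -1))
    add(params$r_ikk, 1, i("Yf"), scales_k = 1, change = ch(Yf = -1))
    add(params$rho * params$r_ikk, 1, i("C"), scales_k = 1,
        change = ch(C = -1, N = 1))

    if (architecture == "none") {
      add(params$c0 * omega, 0, delay = params$tau1, change = ch(Yf = 1))
    } else {
      add(kon_p, 2, i("N"), i("Pf"), change = ch(N = -1, Pf = -1, Pb = 1))
      add(k_off_promoter, 1, i("Pb"), change = ch(N = 1, Pf = 1, Pb = -1))
      add(params$c0 * omega, 1, i("Pf"), delay = params$tau1,
          change = ch(Yf = 1))
      add(params$c1 * omega, 1, i("Pb"), delay = params$tau1,
          change = ch(Yf = 1))
    }
    if (architecture == "dual") {
      add(kon_c, 2, i("N"), i("Zf"), change = ch(N = -1, Zf = -1, D = 1))
      add(k_off_complex, 1, i("D"), change = ch(N = 1, Zf = 1, D = -1))
      add(params$deg_e, 1, i("Zf"), change = ch(Zf = -1))
      add(params$r_ikk, 1, i("Zf"), scales_k = 1, change = ch(Zf = -1))
      add(params$rho * params$r_ikk, 1, i("D"), scales_k = 1,
          change = ch(D = -1, N = 1))
      add(kon_p, 2, i("N"), i("Qf"), change = ch(N = -1, Qf = -1, Qb = 1))
      add(k_off_promoter, 1, i("Qb"), change = ch(N = 1, Qf = 1, Qb = -1))
      add(params$eps * params$c0_e * omega, 1, i("Qf"), delay = params$tau2,
          change = ch(Zf = 1))
      add(params$eps * params$c1 * omega, 1, i("Qb"), delay = params$tau2,
          change = ch(Zf = 1))
    }

    # initial state: basal deterministic steady state, rounded, with free
    # NF-kB absorbing the rounding so conservation is exact
    variant <- switch(architecture, none = "none", single = "single",
                      dual = "dual")
    basal <- steady_state(variant, params, K = 0)
    xa <- partition_ikb(basal$y_a, basal$x, params$kc)
    init <- stats::setNames(integer(length(species)), species)
    init["C"] <- round(xa$bound * omega)
    init["Yf"] <- round(xa$free * omega)
    if (architecture != "none") init["Pf"] <- 1L
    if (architecture == "dual") {
      xe <- partition_ikb(basal$y_e, basal$x, params$kc)
      init["D"] <- round(xe$bound * omega)
      init["Zf"] <- round(xe$free * omega)
      init["Qf"] <- 1L
    }
    held <- init["C"] + if (architecture == "dual") init["D"] else 0L
    if (held > n_nfkb_total)
      stop("basal complexes exceed total NF-kB copy number", call. = FALSE)
    init["N"] <- n_nfkb_total - held
  }

  net <- list(architecture = architecture, species = species, init = init,
              reactions = rx, omega = omega, n_nfkb_total = n_nfkb_total,
              params = params)
  class(net) <- "nfkb_network"
  net
}

# raw stochastic propensities at a copy-number state (mirrors the C++ engine,
# including the same-species combinatorial factor)
.propensities <- function(tb, x, K) {
  a <- tb$rate
  for (j in seq_along(a)) {
    if (tb$order[j] >= 1) a[j] <- a[j] * x[tb$s1[j]]
    if (tb$order[j] == 2) {
      a[j] <- a[j] * if (tb$s2[j] == tb$s1[j]) (x[tb$s1[j]] - 1) / 2
                     else x[tb$s2[j]]
    }
    if (tb$scales_k[j]) a[j] <- a[j] * K
  }
  pmax(a, 0)
}

.network_tables <- function(net) {
  rx <- net$reactions
  list(rate = vapply(rx, `[[`, 0, "rate"),
       order = as.integer(vapply(rx, `[[`, 0, "order")),
       s1 = as.integer(vapply(rx, `[[`, 0, "s1")),
       s2 = as.integer(vapply(rx, `[[`, 0, "s2")),
       scales_k = as.integer(vapply(rx, `[[`, 0, "scales_k")),
       delay = vapply(rx, `[[`, 0, "delay"),
       stoich = do.call(rbind, lapply(rx, function(r) as.integer(r$change))))
}

#' Deterministic propensity-derived rates (rate-equation limit)
#'
#' Sums `stoich * propensity / omega` over reactions at a concentration state,
#' giving the macroscopic rate of change implied by the stochastic network.
#' Used to verify that the generated networks reproduce the reduced model's
#' right-hand side (with quasi-equilibrated binding).
#'
#' @param net An `nfkb_network`.
#' @param conc Named concentrations (nM) for every species (promoters as
#'   occupancy probabilities).
#' @param K IKK activity.
#' @return Named rate of change per species (nM/min, promoters 1/min).
#' @export
network_drift <- function(net, conc, K = 0) {
  tb <- .network_tables(net)
  promoter <- net$species %in% c("Pf", "Pb", "Qf", "Qb")
  x <- conc[net$species] * ifelse(promoter, 1, net$omega)
  prop <- tb$rate
  for (j in seq_along(prop)) {
    if (tb$order[j] >= 1) prop[j] <- prop[j] * x[tb$s1[j]]
    if (tb$order[j] == 2) prop[j] <- prop[j] * x[tb$s2[j]]
    if (tb$scales_k[j]) prop[j] <- prop[j] * K
  }
  drift <- as.numeric(t(tb$stoich) %*% prop) / net$omega
  stats::setNames(drift, net$species)
}

#' Simulate one stochastic realization
#'
#' Exact delayed-SSA realization of a network under a piecewise-constant
#' input, sampled on a uniform grid (last-value interpolation of the jump
#' process).  Identical `seed` and configuration give a bit-identical
#' trajectory.
#'
#' @param net An `nfkb_network`.
#' @param signal An `nfkb_signal`.
#' @param t_end End time (min).
#' @param dt Sampling grid spacing (min).
#' @param seed Integer seed.
#' @param init Optional replacement initial copy numbers.
#' @param prewarm If `TRUE` (default), the delayed-completion queue is seeded
#'   at t = 0 with in-flight syntheses: for each delayed channel, a Poisson
#'   number (mean propensity x delay, evaluated at the initial state under the
#'   pre-stimulus baseline input) of completions at uniform times within one
#'   delay.  This is the stochastic analogue of the deterministic solver's
#'   constant pre-stimulus history; `FALSE` starts with an empty queue.
#' @return A data frame: `time_min` plus one column per species (integer copy
#'   numbers sampled on the grid), with the network as attribute.
#' @export
ssa_simulate <- function(net, signal = input_signal(), t_end = 360, dt = 1,
                         seed = 1L, init = NULL, prewarm = TRUE) {
  if (is.null(init)) init <- net$init
  tb <- .network_tables(net)
  grid <- seq(0, t_end, by = dt)
  sw <- signal_switch_times(net_signal <- signal)
  k_times <- sort(unique(c(0, sw[sw > 0 & sw < t_end])))
  k_values <- signal_value(signal, k_times)
  set.seed(seed)
  q_times <- numeric(0)
  q_rx <- integer(0)
  if (isTRUE(prewarm)) {
    a0 <- .propensities(tb, as.numeric(init), signal$baseline)
    for (j in which(tb$delay > 0 & a0 > 0)) {
      n <- stats::rpois(1L, a0[j] * tb$delay[j])
      if (n > 0) {
        q_times <- c(q_times, stats::runif(n, 0, tb$delay[j]))
        q_rx <- c(q_rx, rep.int(j, n))
      }
    }
  }
  m <- .ssa_run(as.integer(init), tb$rate, tb$order, tb$s1, tb$s2,
                tb$scales_k, tb$delay, tb$stoich, k_times, k_values, grid,
                q_times, q_rx - 1L)
  colnames(m) <- net$species
  out <- data.frame(time_min = grid, m, check.names = FALSE)
  attr(out, "network") <- net
  attr(out, "seed") <- seed
  class(out) <- c("nfkb_ssa_trajectory", "data.frame")
  out
}

#' Ensemble of stochastic runs
#'
#' Runs `n_runs` independent realizations (seeds `seed, seed + 1, ...`) and
#' summarizes a readout species per grid time: ensemble mean, standard
#' deviation and coefficient of variation.
#'
#' @param net An `nfkb_network`.
#' @param n_runs Number of runs (>= 2).
#' @param signal An `nfkb_signal`.
#' @param t_end,dt Grid definition (min).
#' @param seed Base seed; run i uses `seed + i - 1`.
#' @param species Readout species (default free/nuclear NF-kB `"N"`, or the
#'   repressor `"R"` for the auto-repressor network).  A character vector sums
#'   the named species per run; e.g. `c("N", "Pb")` gives the NF-kB pool not
#'   sequestered by IkB, which is the observable the reduced model's free
#'   NF-kB `x` stands for (the reduction neglects promoter-bound NF-kB).
#' @param keep_runs If `TRUE`, attach the runs matrix (runs x times).
#' @return A data frame of class `nfkb_ensemble` with columns `time_min`,
#'   `mean`, `sd`, `cv` (`NA` where the mean is 0) and attributes `n_runs`,
#'   `species`.
#' @export
ssa_ensemble <- function(net, n_runs = 200, signal = input_signal(),
                         t_end = 360, dt = 1, seed = 1L, species = NULL,
                         keep_runs = FALSE) {
  stopifnot(n_runs >= 2)
  if (is.null(species))
    species <- if (net$architecture == "autorepressor") "R" else "N"
  grid <- seq(0, t_end, by = dt)
  runs <- matrix(NA_real_, nrow = n_runs, ncol = length(grid))
  bad <- setdiff(species, net$species)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_len(n_runs)) {
    tr <- ssa_simulate(net, signal, t_end, dt, seed = seed + i - 1L)
    runs[i, ] <- if (length(species) == 1L) tr[[species]] else
      rowSums(as.matrix(tr[species]))
  }
  mu <- colMeans(runs)
  sdv <- apply(runs, 2, stats::sd)
  out <- data.frame(time_min = grid, mean = mu, sd = sdv,
                    cv = ifelse(mu > 0, sdv / mu, NA_real_))
  attr(out, "n_runs") <- n_runs
  attr(out, "species") <- species
  attr(out, "network") <- net
  if (keep_runs) attr(out, "runs") <- runs
  class(out) <- c("nfkb_ensemble", "data.frame")
  out
}

#' Peak and late-phase coefficients of variation
#'
#' The peak CV is the ensemble CV evaluated at the time of the mean
#' trajectory's first peak; the late-phase CV is the time-average of the CV
#' over the window from the first trough after that peak to the end of the
#' record (the late-phase response is the level following the trough after
#' the first peak).
#'
#' @param ens An `nfkb_ensemble` (or data frame with `time_min`, `mean`,
#'   `cv`).
#' @param prominence Minimum swing for peak detection on the mean trajectory;
#'   defaults to 5% of the mean trajectory's range.
#' @return A list with `cv_peak`, `cv_late`, `t_peak`, `t_trough`.
#' @export
cv_peak_and_late <- function(ens, prominence = NULL) {
  v <- ens$mean
  tt <- ens$time_min
  if (is.null(prominence)) prominence <- 0.05 * diff(range(v))
  ex <- .local_extrema(v)
  pruned <- .prune_extrema(v, ex$idx, ex$kind, prominence)
  pk <- pruned$idx[pruned$kind == "peak"]
  if (!length(pk)) stop("mean trajectory has no identifiable first peak",
                        call. = FALSE)
  ipk <- pk[1]
  tr <- pruned$idx[pruned$kind == "trough"]
  itr <- tr[tr > ipk]
  itr <- if (length(itr)) itr[1] else which.min(v[ipk:length(v)]) + ipk - 1L
  late <- ens$cv[itr:length(v)]
  list(cv_peak = ens$cv[ipk],
       cv_late = mean(late, na.rm = TRUE),
       t_peak = tt[ipk], t_trough = tt[itr])
}
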