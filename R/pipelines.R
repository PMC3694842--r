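#' Damping optimization scan over the secondary-loop parameters
#'
#' For each grid point (tau2, eps), integrates the dual-feedback model under
#' persistent stimulation and evaluates the persistence-of-oscillations
#' metric: the maximum peak-trough difference of nuclear NF-kB after `t_cut`
#' (6 h by default).  "Optimal damping" minimizes this metric.  The `eps = 0`
#' column reproduces the single-feedback model for every tau2.
#'
#' @param params An `nfkb_params` object (tau2/eps fields are overridden by
#'   the grids).
#' @param K Persistent IKK activity.
#' @param tau2_grid Secondary synthesis delays (min).
#' @param eps_grid Secondary feedback-strength scalings.
#' @param t_cut Metric cutoff (min).
#' @param t_end Integration horizon (min).
#' @param config Integrator configuration.
#' @return A list of class `nfkb_scan`: `tau2_grid`, `eps_grid`, `metric`
#'   (matrix tau2 x eps, nM; `NA` where integration failed), and `argmin`
#'   (named vector with the minimizing `tau2`, `eps` and metric value).
#' @export
damping_scan <- function(params, K = 1, tau2_grid = seq(0, 90, by = 7.5),
                         eps_grid = params$eps, t_cut = 360, t_end = 720,
                         config = integrator_config(rel_tol = 1e-7,
                                                    abs_tol = 1e-9,
                                                    dt_out = 0.5)) {
  metric <- matrix(NA_real_, length(tau2_grid), length(eps_grid),
                   dimnames = list(tau2 = tau2_grid, eps = eps_grid))
  sig <- input_signal(amplitude = K)
  for (i in seq_along(tau2_grid)) for (j in seq_along(eps_grid)) {
    p <- update_params(params, tau2 = tau2_grid[i], eps = eps_grid[j])
    tr <- try(integrate_dde("dual", p, sig, t_end = t_end, config = config),
              silent = TRUE)
    if (!inherits(tr, "try-error"))
      metric[i, j] <- measure_oscillations(tr, t_cut = t_cut)$max_peak_trough_after
  }
  if (all(is.na(metric))) stop("all scan points failed", call. = FALSE)
  am <- arrayInd(which.min(metric), dim(metric))
  res <- list(tau2_grid = tau2_grid, eps_grid = eps_grid, metric = metric,
              argmin = c(tau2 = tau2_grid[am[1]], eps = eps_grid[am[2]],
                         metric = min(metric, na.rm = TRUE)),
              t_cut = t_cut, K = K)
  class(res) <- "nfkb_scan"
  res
}

#' Response duration versus stimulus duration
#'
#' Integrates the chosen model variant for input pulses starting at t = 0
#' from basal history and measures the response duration: the total time
#' nuclear NF-kB exceeds a threshold, with crossing times refined by
#' root-bracketed linear interpolation on the dense trajectory.
#'
#' @param variant `"none"`, `"single"` or `"dual"`.
#' @param params An `nfkb_params` object.
#' @param K Pulse amplitude.
#' @param pulse_durations Input durations (min); `Inf` allowed.
#' @param threshold Nuclear NF-kB threshold (nM; default 50).
#' @param t_end Integration horizon (min).
#' @param config Integrator configuration.
#' @return A data frame of class `nfkb_duration_curve` with columns
#'   `input_duration_min` and `response_duration_min`.
#' @export
duration_response <- function(variant, params, K = 1,
                              pulse_durations = c(15, 30, 45, 60, 90, 120),
                              threshold = 50, t_end = 480,
                              config = integrator_config(rel_tol = 1e-7,
                                                         abs_tol = 1e-9,
                                                         dt_out = 0.25)) {
  stopifnot(threshold > 0)
  resp <- vapply(pulse_durations, function(d) {
    tr <- integrate_dde(variant, params,
                        input_signal(amplitude = K, t_on = 0, duration = d),
                        t_end = t_end, config = config)
    time_above_threshold(tr, threshold)
  }, 0)
  out <- data.frame(input_duration_min = pulse_durations,
                    response_duration_min = resp)
  attr(out, "threshold") <- threshold
  class(out) <- c("nfkb_duration_curve", "data.frame")
  out
}

#' Total time a trajectory spends above a threshold
#'
#' @param traj An `nfkb_trajectory` (or data frame with `time_min` and the
#'   column in `what`).
#' @param threshold Threshold level.
#' @param what Column to threshold.
#' @return Total time above threshold (min); 0 if never exceeded.
#' @export
time_above_threshold <- function(traj, threshold, what = "x_nM") {
  tt <- traj$time_min
  v <- traj[[what]] - threshold
  above <- v > 0
  total <- 0
  for (i in seq_len(length(tt) - 1)) {
    if (above[i] && above[i + 1]) {
      total <- total + (tt[i + 1] - tt[i])
    } else if (xor(above[i], above[i + 1]) && v[i + 1] != v[i]) {
      tc <- tt[i] + (tt[i + 1] - tt[i]) * v[i] / (v[i] - v[i + 1])
      total <- total + if (above[i]) tc - tt[i] else tt[i + 1] - tc
    }
  }
  total
}

#' Extrinsic-noise scan over a deterministic parameter family
#'
#' Emulates cell-to-cell variability in total NF-kB or in the IKK input by
#' integrating a deterministic family of trajectories with the varied
#' quantity at `base * (1 - f)`, `base`, and `base * (1 + f)` (optionally a
#' finer sampled family), then summarizing the spread at the peak and in the
#' late phase with the half-range coefficient of variation
#' `(max - min) / (max + min)` (an sd/mean alternative is available).
#'
#' The peak statistic uses each family member's first-peak height of nuclear
#' NF-kB; the late statistic uses each member's time-averaged level from its
#' first trough to `t_end`.
#'
#' @param params An `nfkb_params` object.
#' @param vary `"nf_tot"` or `"K"`.
#' @param K Nominal IKK activity.
#' @param fraction Fractional variation f (default 0.25, the measurement
#'   error scale of the abundance data this emulates).
#' @param n_family Family size (>= 3, odd recommended).
#' @param variant Model variant.
#' @param t_end Horizon (min).
#' @param cv_mode `"halfrange"` (default) or `"sd"`.
#' @param config Integrator configuration.
#' @return A list of class `nfkb_extrinsic`: `cv_peak`, `cv_late`, plus the
#'   per-member `peaks` and `late_levels`.
#' @export
extrinsic_scan <- function(params, vary = c("nf_tot", "K"), K = 1,
                           fraction = 0.25, n_family = 3,
                           variant = "dual", t_end = 480,
                           cv_mode = c("halfrange", "sd"),
                           config = integrator_config(rel_tol = 1e-7,
                                                      abs_tol = 1e-9,
                                                      dt_out = 0.5)) {
  vary <- match.arg(vary)
  cv_mode <- match.arg(cv_mode)
  stopifnot(fraction >= 0, n_family >= 3)
  scale <- seq(1 - fraction, 1 + fraction, length.out = n_family)
  peaks <- late <- numeric(n_family)
  for (i in seq_along(scale)) {
    p <- params
    Ki <- K
    if (vary == "nf_tot") p <- update_params(p, nf_tot = params$nf_tot * scale[i])
    else Ki <- K * scale[i]
    tr <- integrate_dde(variant, p, input_signal(amplitude = Ki),
                        t_end = t_end, config = config)
    osc <- measure_oscillations(tr, t_cut = 0,
                                prominence = 0.01 * p$nf_tot)
    if (length(osc$peak_times)) {
      peaks[i] <- osc$peak_values[1]
      t0 <- osc$trough_times[osc$trough_times > osc$peak_times[1]]
      t0 <- if (length(t0)) t0[1] else osc$peak_times[1]
    } else {
      peaks[i] <- max(tr$x_nM)
      t0 <- tr$time_min[which.max(tr$x_nM)]
    }
    sel <- tr$time_min >= t0
    late[i] <- mean(tr$x_nM[sel])
  }
  cv <- function(v) {
    if (cv_mode == "halfrange") (max(v) - min(v)) / (max(v) + min(v))
    else stats::sd(v) / mean(v)
  }
  res <- list(cv_peak = cv(peaks), cv_late = cv(late),
              peaks = peaks, late_levels = late, scale = scale, vary = vary,
              fraction = fraction)
  class(res) <- "nfkb_extrinsic"
  res
}

#' Single-cell versus population damping metrics
#'
#' Two measures of late oscillatory variability on a family of trajectories
#' sharing a time grid: the mean single-cell magnitude (maximum peak-trough
#' difference after `t_after`, computed per trajectory, then averaged) and
#' the population magnitude (the same metric computed on the pointwise-mean
#' trajectory).  For identical trajectories the two agree; for
#' phase-desynchronized families the population metric is smaller.
#'
#' @param times Shared time grid (min).
#' @param traj_matrix Matrix of trajectories (rows = trajectories, columns =
#'   grid times).
#' @param t_after Metric cutoff (min; default 300, i.e. 5 h).
#' @return A list with `a_single` and `a_population` (same units as the
#'   trajectories).
#' @export
damping_metrics <- function(times, traj_matrix, t_after = 300) {
  stopifnot(is.matrix(traj_matrix), nrow(traj_matrix) >= 2,
            ncol(traj_matrix) == length(times))
  metric1 <- function(v) {
    df <- data.frame(time_min = times, x_nM = v)
    measure_oscillations(df, t_cut = t_after,
                         prominence = 0.01 * diff(range(v)))$max_peak_trough_after
  }
  a_single <- mean(apply(traj_matrix, 1, metric1))
  a_population <- metric1(colMeans(traj_matrix))
  list(a_single = a_single, a_population = a_population, t_after = t_after)
}
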