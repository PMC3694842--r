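#' Generate a surrogate mRNA induction time course
#'
#' Emulates a quantitated RNase-protection time course: a sigmoidal rise from
#' a basal to a peak level that crosses its half-maximum at `true_delay`, with
#' multiplicative lognormal measurement noise of a given coefficient of
#' variation.  Band intensities are positive, hence the multiplicative noise
#' model; an additive-Gaussian mode is available.
#'
#' @param true_delay Time of half-maximal induction (min).
#' @param rise_sharpness Logistic steepness (1/min).
#' @param basal,peak Basal and peak expression levels (arbitrary units,
#'   `basal < peak`).
#' @param sample_times Sampling times (min, strictly increasing).
#' @param noise_cv Measurement coefficient of variation (>= 0).
#' @param seed Integer seed (reproducible).
#' @param noise One of `"lognormal"`, `"gaussian"`.
#' @return A data frame of class `nfkb_timecourse` with columns `time_min`,
#'   `value`.
#' @export
gen_mrna_course <- function(true_delay, rise_sharpness = 0.15, basal = 5,
                            peak = 100, sample_times = seq(0, 180, by = 15),
                            noise_cv = 0, seed = 1L,
                            noise = c("lognormal", "gaussian")) {
  noise <- match.arg(noise)
  stopifnot(basal < peak, noise_cv >= 0, all(diff(sample_times) > 0))
  mu <- basal + (peak - basal) /
    (1 + exp(-rise_sharpness * (sample_times - true_delay)))
  set.seed(seed)
  v <- if (noise_cv == 0) {
    mu
  } else if (noise == "lognormal") {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(0, mu + stats::rnorm(length(mu), sd = noise_cv * mu))
  }
  out <- data.frame(time_min = sample_times, value = v)
  attr(out, "true_delay") <- true_delay
  attr(out, "seed") <- seed
  class(out) <- c("nfkb_timecourse", "data.frame")
  out
}

#' Estimate a synthesis delay from half-maximal induction
#'
#' Normalizes a sampled induction curve to 100% at its maximum (the first
#' sample is the basal reference) and returns the first time the linearly
#' interpolated curve crosses 50% of the basal-to-peak range.
#'
#' @param sample A data frame with `time_min` and `value` columns (e.g. from
#'   [gen_mrna_course()] or a two-column CSV).
#' @return Estimated delay (min).
#' @export
estimate_half_max_delay <- function(sample) {
  tt <- sample$time_min
  v <- sample$value
  basal <- v[1]
  pk <- max(v)
  if (pk <= basal) stop("curve has no induction above the basal level",
                        call. = FALSE)
  half <- basal + 0.5 * (pk - basal)
  d <- v - half
  cross <- which(d[-1] >= 0 & d[-length(d)] < 0)
  if (!length(cross))
    stop("activation curve never crosses the 50% level", call. = FALSE)
  i <- cross[1]
  tt[i] + (tt[i + 1] - tt[i]) * (half - v[i]) / (v[i + 1] - v[i])
}

#' Peak IkBa : IkBe ratio
#'
#' Integrates the dual-feedback model under persistent stimulation from basal
#' history and returns the ratio of the global maxima of total IkBa and total
#' IkBe over the response window.  With `eps = 1` (equal inducible synthesis
#' rates) this is the model statistic that maps measured isoform abundance
#' ratios onto the feedback-strength scale.
#'
#' @param params An `nfkb_params` object; `eps` is overridden by the `eps`
#'   argument.
#' @param eps Feedback-strength scaling at which to evaluate (default 1).
#' @param K Persistent IKK activity.
#' @param t_end Response window (min).
#' @param config Integrator configuration.
#' @return Peak ratio (dimensionless).
#' @export
peak_ratio <- function(params, eps = 1, K = 1, t_end = 480,
                       config = integrator_config(rel_tol = 1e-7,
                                                  abs_tol = 1e-9,
                                                  dt_out = 0.5)) {
  p <- update_params(params, eps = eps)
  tr <- integrate_dde("dual", p, input_signal(amplitude = K), t_end = t_end,
                      config = config)
  max(tr$y_alpha_nM) / max(tr$y_eps_nM)
}

# anchor evaluators used by calibrate_parameters; each returns one number
.anchor_fns <- list(
  period = function(p, K, config) {
    tr <- integrate_dde("single", p, input_signal(amplitude = K),
                        t_end = 480, config = config)
    measure_oscillations(tr, t_cut = 360)$period_estimate
  },
  peak_ratio = function(p, K, config) peak_ratio(p, K = K, config = config),
  peak_x = function(p, K, config) {
    tr <- integrate_dde("single", p, input_signal(amplitude = K),
                        t_end = 480, config = config)
    max(tr$x_nM)
  },
  duration = function(p, K, config) {
    duration_response("dual", p, K = K, pulse_durations = 15,
                      config = config)$response_duration_min
  }
)

#' Calibrate model parameters to target observables
#'
#' Bounded derivative-free least squares on normalized anchor residuals.
#' Anchors are named targets among `period` (min, single-loop persistent
#' stimulation), `peak_ratio` (dual model at eps = 1), `peak_x` (nM,
#' single-loop peak nuclear NF-kB) and `duration` (min, dual model, 15-min
#' pulse, 50 nM threshold).  The optimizer is deterministic given the start
#' and bounds (Nelder-Mead on a box-transformed scale).
#'
#' @param start An `nfkb_params` object: the documented starting point.
#' @param anchors Named numeric vector of targets, e.g.
#'   `c(period = 90, peak_ratio = 3.9)`.
#' @param free Character vector of parameter names to vary (subset of the
#'   `nfkb_params` fields); may be empty, in which case `start` is returned
#'   with residuals reported.
#' @param lower,upper Named bounds for the free parameters.
#' @param K IKK activity used in the anchor simulations.
#' @param tol Relative residual at which an anchor counts as satisfied.
#' @param maxit Optimizer iteration cap.
#' @param config Integrator configuration (defaults favor speed).
#' @return A list of class `nfkb_calibration`: `params` (calibrated),
#'   `achieved` (anchor values), `residuals` (relative), `converged`
#'   (all residuals below `tol`), `worst` (name of the largest residual).
#' @export
calibrate_parameters <- function(start, anchors, free = character(),
                                 lower = NULL, upper = NULL, K = 1,
                                 tol = 0.1, maxit = 200,
                                 config = integrator_config(rel_tol = 1e-6,
                                                            abs_tol = 1e-8,
                                                            dt_out = 0.5)) {
  stopifnot(length(anchors) >= 1, !is.null(names(anchors)))
  bad <- setdiff(names(anchors), names(.anchor_fns))
  if (length(bad)) stop("unknown anchor(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  evaluate <- function(p) vapply(names(anchors),
                                 function(a) .anchor_fns[[a]](p, K, config), 0)
  residual <- function(vals) abs(vals - anchors) / abs(anchors)

  if (length(free)) {
    stopifnot(all(free %in% names(start)), !is.null(lower), !is.null(upper),
              all(free %in% names(lower)), all(free %in% names(upper)))
    lo <- unlist(lower[free]); hi <- unlist(upper[free])
    # box transform: unconstrained z <-> bounded theta
    to_theta <- function(z) lo + (hi - lo) / (1 + exp(-z))
    to_z <- function(th) stats::qlogis(pmin(pmax((th - lo) / (hi - lo),
                                                 1e-6), 1 - 1e-6))
    obj <- function(z) {
      th <- to_theta(z)
      p <- do.call(update_params, c(list(start),
                                    stats::setNames(as.list(th), free)))
      vals <- try(suppressWarnings(evaluate(p)), silent = TRUE)
      if (inherits(vals, "try-error") || anyNA(vals)) return(1e4)
      sum(residual(vals)^2)
    }
    z0 <- to_z(unlist(start[free]))
    opt <- if (length(free) == 1L) {
      stats::optim(z0, obj, method = "Brent", lower = to_z(lo + 1e-9),
                   upper = to_z(hi - 1e-9),
                   control = list(maxit = maxit))
    } else {
      stats::optim(z0, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-6))
    }
    th <- to_theta(opt$par)
    params <- do.call(update_params, c(list(start),
                                       stats::setNames(as.list(th), free)))
  } else {
    params <- start
  }
  achieved <- evaluate(params)
  res <- residual(achieved)
  out <- list(params = params, achieved = achieved, residuals = res,
              converged = all(res <= tol),
              worst = names(anchors)[which.max(res)])
  class(out) <- "nfkb_calibration"
  if (!out$converged)
    warning("calibration residual above tolerance for anchor `", out$worst,
            "` (", signif(max(res), 3), ")", call. = FALSE)
  out
}
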