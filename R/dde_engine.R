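#' Integrator configuration
#'
#' @param rel_tol,abs_tol Relative and absolute tolerances for the adaptive
#'   solver.
#' @param max_step Maximum internal step (min).
#' @param dt_out Output grid spacing (min); the dense-evaluation contract is
#'   fulfilled by interpolation on this grid.
#' @return A list of class `nfkb_integrator_config`.
#' @export
integrator_config <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_step = 1,
                              dt_out = 0.25) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_step > 0, dt_out > 0)
  cfg <- list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
              dt_out = dt_out)
  class(cfg) <- "nfkb_integrator_config"
  cfg
}

#' Integrate a delayed-feedback model
#'
#' Integrates the chosen model variant with a piecewise-constant IKK input and
#' a constant pre-stimulus history, using an adaptive method-of-steps scheme
#' ([deSolve::dede()]) whose delayed lookups interpolate already-computed
#' segments.  Input switch times are inserted into the output grid so the
#' induced derivative discontinuities are resolved.
#'
#' @param variant One of `"none"`, `"single"`, `"dual"`.
#' @param params An `nfkb_params` object.
#' @param signal An `nfkb_signal` object.
#' @param t_end End time (min), > 0.
#' @param history Constant pre-stimulus state: for `"dual"` a vector
#'   `c(y_a, y_e)`, otherwise a single `y_a` value.  Defaults to the basal
#'   steady state at `K = signal$baseline` (resting cells).
#' @param config An `nfkb_integrator_config`.
#' @return An `nfkb_trajectory`: a data frame with columns `time_min`,
#'   `y_alpha_nM`, `y_eps_nM`, `x_nM` plus metadata attributes.  Nuclear NF-kB
#'   `x` is derived from the inhibitor totals via [solve_free_nfkb()].
#' @export
integrate_dde <- function(variant = c("single", "dual", "none"), params,
                          signal = input_signal(), t_end = 480,
                          history = NULL, config = integrator_config()) {
  variant <- match.arg(variant)
  stopifnot(t_end > 0)
  if (is.null(history)) {
    ss <- steady_state(variant, params, K = signal$baseline)
    history <- if (variant == "dual") c(ss$y_a, ss$y_e) else ss$y_a
  }
  if (any(history < 0) || !all(is.finite(history)))
    stop("history must be a nonnegative constant state", call. = FALSE)
  nstate <- if (variant == "dual") 2L else 1L
  if (length(history) != nstate)
    stop("history must have length ", nstate, " for variant ", variant,
         call. = FALSE)

  lag_state <- function(t, tau) {
    if (t - tau <= 0) history else deSolve::lagvalue(t - tau)
  }
  deriv <- if (variant == "dual") {
    function(t, y, parms) {
      y <- pmax(y, 0)
      d1 <- pmax(lag_state(t, params$tau1), 0)
      d2 <- pmax(lag_state(t, params$tau2), 0)
      list(rhs_dual(y, d1, d2, signal_value(signal, t), params))
    }
  } else {
    function(t, y, parms) {
      y <- pmax(y, 0)
      yd <- pmax(lag_state(t, params$tau1), 0)
      list(rhs_single(y, yd, signal_value(signal, t), params))
    }
  }

  times <- seq(0, t_end, by = config$dt_out)
  sw <- signal_switch_times(signal)
  sw <- sw[sw > 0 & sw < t_end]
  times <- sort(unique(c(times, sw, t_end)))
  sol <- deSolve::dede(y = history, times = times, func = deriv, parms = NULL,
                       rtol = config$rel_tol, atol = config$abs_tol,
                       hmax = config$max_step)
  if (attr(sol, "istate")[1] < 0)
    stop("DDE integration failed at t = ", max(sol[, 1]), " min",
         call. = FALSE)
  y_a <- pmax(sol[, 2], 0)
  y_e <- if (variant == "dual") pmax(sol[, 3], 0) else rep(0, nrow(sol))
  traj <- data.frame(time_min = sol[, 1], y_alpha_nM = y_a, y_eps_nM = y_e,
                     x_nM = solve_free_nfkb(y_a, y_e, params))
  attr(traj, "variant") <- variant
  attr(traj, "params") <- params
  attr(traj, "signal") <- signal
  class(traj) <- c("nfkb_trajectory", "data.frame")
  traj
}

#' Evaluate a trajectory at arbitrary times
#'
#' Linear interpolation on the dense output grid, consistent with the
#' integrator's dense-evaluation contract.
#'
#' @param traj An `nfkb_trajectory`.
#' @param t Times (min) within the trajectory span.
#' @param what Column to evaluate (default nuclear NF-kB).
#' @return Interpolated values.
#' @export
trajectory_at <- function(traj, t, what = "x_nM") {
  if (any(t < min(traj$time_min) | t > max(traj$time_min)))
    stop("evaluation times outside trajectory span", call. = FALSE)
  stats::approx(traj$time_min, traj[[what]], xout = t)$y
}
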