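#' Lambert W function for complex arguments
#'
#' Solves `W exp(W) = z` by Halley iteration from an asymptotic starting
#' point.  For real `z >= -1/e` the principal branch (`branch = 0`) is real;
#' for real `z < -1/e` it returns the complex value with positive imaginary
#' part (the representative of the conjugate pair relevant to scalar DDE
#' spectra).
#'
#' @param z Complex (or real) argument; vectorized.
#' @param branch Integer branch index (0 = principal, -1, 1, ...).
#' @param tol Convergence tolerance on `|W exp(W) - z|`.
#' @return Complex W values satisfying `W exp(W) = z` to `tol`.
#' @export
lambert_w <- function(z, branch = 0L, tol = 1e-12) {
  z <- as.complex(z)
  vapply(z, function(zz) .lambert_w1(zz, branch, tol), complex(1))
}

.lambert_w1 <- function(z, branch, tol) {
  if (z == 0) {
    if (branch == 0L) return(0 + 0i) else return(complex(real = -Inf))
  }
  # starting point
  if (branch == 0L && abs(z + exp(-1)) < 0.3) {
    p <- sqrt(2 * (exp(1) * z + 1))          # principal sqrt: Im >= 0
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  } else if (branch == -1L && abs(z + exp(-1)) < 0.3 && Im(z) == 0) {
    p <- -sqrt(2 * (exp(1) * z + 1))
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  } else if (branch == 0L && abs(z) <= 1.5) {
    w <- z                # W ~ z near 0; Halley converges from here up to ~e
  } else {
    l <- log(z) + 2i * pi * branch
    w <- l - log(l)       # asymptotic seed; |l| bounded away from 0 here
  }
  for (i in 1:100) {
    ew <- exp(w)
    f <- w * ew - z
    if (abs(f) < tol * max(1, abs(z))) break
    wp1 <- w + 1
    w <- w - f / (ew * wp1 - (w + 2) * f / (2 * wp1))
  }
  if (abs(w * exp(w) - z) > 1e-8 * max(1, abs(z)))
    stop("lambert_w failed to converge for z = ", format(z), call. = FALSE)
  w
}

#' Fixed point of the single-loop model under constant input
#'
#' Root of the closed-form right-hand side of the scalar delay equation with
#' the delayed argument set equal to the instantaneous one.  By default the
#' full form (constitutive synthesis and degradation included) is solved
#' numerically; `simplified = TRUE` uses the large-input approximation (basal
#' terms neglected, `nf_tot >> kc`) whose stationary level solves a quadratic
#' explicitly.
#'
#' @param params An `nfkb_params` object.
#' @param K Constant IKK activity, >= 0.
#' @param simplified Use the explicit large-input form.
#' @return Stationary total IkBa `y_star` (nM).
#' @export
fixed_point <- function(params, K, simplified = FALSE) {
  stopifnot(K >= 0)
  if (simplified) {
    beta <- params$rho * params$r_ikk * K
    if (beta <= 0)
      stop("simplified fixed point requires K > 0 (large-input regime)",
           call. = FALSE)
    n <- params$nf_tot
    # beta y (kp + n - y) = c1 (n - y)  ->  beta y^2 - (beta(kp+n)+c1) y + c1 n = 0
    b <- beta * (params$kp + n) + params$c1
    disc <- b * b - 4 * beta * params$c1 * n
    if (disc < 0) stop("no real fixed point in simplified form", call. = FALSE)
    return((b - sqrt(disc)) / (2 * beta))   # smaller root lies in (0, n)
  }
  f <- function(y) rhs_single(y, y, K, params)
  hi <- params$nf_tot
  while (f(hi) > 0 && hi < 1e9) hi <- hi * 2
  if (f(hi) > 0)
    stop("fixed-point bracketing failed on [0, ", hi, "]", call. = FALSE)
  stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Dominant eigenvalue of the linearized single-loop model
#'
#' Linearizes the scalar delay equation about its fixed point,
#' `d(dy)/dt = -a dy - b dy_tau`, and returns the dominant eigenvalue from the
#' principal branch of the Lambert W function,
#' `lambda = -a + W(-b tau exp(a tau)) / tau`.  In the underdamped regime
#' (W argument below -1/e) the representative with positive imaginary part is
#' returned; `2*pi / Im(lambda)` is the oscillation period and `-Re(lambda)`
#' the decay rate.
#'
#' By default the coefficients use the simplified large-input
#' form: `a = rho * r_ikk * K` and `b = c1 * kp / (kp + nf_tot - y*)^2` at the
#' explicit fixed point.  With `simplified = FALSE` both coefficients are
#' computed by numerical differentiation of the full right-hand side at the
#' full fixed point.
#'
#' @param params An `nfkb_params` object.
#' @param K Constant IKK activity.
#' @param simplified Use the large-input linearization (default `TRUE`).
#' @return A list of class `nfkb_linearization` with `y_star`, `lambda`
#'   (complex), `period` (min, `NA` if overdamped), `decay_rate` (1/min),
#'   `a`, `b`, and `oscillatory` (logical).
#' @export
dominant_eigenvalue <- function(params, K, simplified = TRUE) {
  tau <- params$tau1
  if (simplified) {
    y_star <- fixed_point(params, K, simplified = TRUE)
    a <- params$rho * params$r_ikk * K
    b <- params$c1 * params$kp / (params$kp + params$nf_tot - y_star)^2
  } else {
    y_star <- fixed_point(params, K)
    h <- max(1e-6, 1e-7 * y_star)
    a <- -(rhs_single(y_star + h, y_star, K, params) -
             rhs_single(y_star - h, y_star, K, params)) / (2 * h)
    b <- -(rhs_single(y_star, y_star + h, K, params) -
             rhs_single(y_star, y_star - h, K, params)) / (2 * h)
  }
  if (b == 0) {
    lambda <- complex(real = -a)             # no delayed term: lambda = -a
  } else if (tau <= 0) {
    lambda <- complex(real = -a - b)         # degenerate non-delayed limit
  } else {
    arg <- -b * tau * exp(a * tau)
    lambda <- -a + lambert_w(arg) / tau
  }
  oscillatory <- Im(lambda) > 1e-12
  res <- list(y_star = y_star, lambda = lambda,
              period = if (oscillatory) 2 * pi / Im(lambda) else NA_real_,
              decay_rate = -Re(lambda), a = a, b = b,
              oscillatory = oscillatory)
  resid <- abs(lambda + a + b * exp(-lambda * tau))
  if (is.finite(resid) && resid > 1e-9 * max(1, abs(lambda)))
    stop("characteristic-equation residual too large: ", format(resid),
         call. = FALSE)
  class(res) <- "nfkb_linearization"
  res
}

#' Analytic period and decay over input and delay grids
#'
#' Applies [dominant_eigenvalue()] across a grid of IKK inputs and synthesis
#' delays.  The period depends strongly on the delay but only weakly on the
#' input, while the decay rate grows with the input.
#'
#' @param params An `nfkb_params` object.
#' @param K_grid Vector of IKK activities.
#' @param tau_grid Vector of delays (min).
#' @param simplified Passed to [dominant_eigenvalue()].
#' @return A data frame with columns `tau_min`, `k`, `period_min`,
#'   `decay_per_min`.
#' @export
period_sensitivity <- function(params, K_grid, tau_grid, simplified = TRUE) {
  stopifnot(length(K_grid) > 0, length(tau_grid) > 0)
  grid <- expand.grid(tau_min = tau_grid, k = K_grid)
  res <- t(apply(grid, 1, function(r) {
    p <- update_params(params, tau1 = r[["tau_min"]])
    lin <- dominant_eigenvalue(p, r[["k"]], simplified = simplified)
    c(lin$period, lin$decay_rate)
  }))
  grid$period_min <- res[, 1]
  grid$decay_per_min <- res[, 2]
  grid
}

# alternating local extrema of a sampled series; returns indices and kinds
.local_extrema <- function(v) {
  d <- diff(v)
  # collapse exact plateaus by keeping the first point of each run
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(idx = integer(0), kind = character(0)))
  idx <- integer(0); kind <- character(0)
  prev <- s[nz[1]]
  for (i in nz[-1]) {
    if (s[i] != prev) {
      idx <- c(idx, i)
      kind <- c(kind, if (prev > 0) "peak" else "trough")
      prev <- s[i]
    }
  }
  list(idx = idx, kind = kind)
}

# prune an alternating extrema sequence until every adjacent swing >= prom
.prune_extrema <- function(values, idx, kind, prom) {
  while (length(idx) >= 2) {
    swings <- abs(diff(values[idx]))
    m <- which.min(swings)
    if (swings[m] >= prom) break
    keep <- setdiff(seq_along(idx), c(m, m + 1))
    idx <- idx[keep]; kind <- kind[keep]
  }
  list(idx = idx, kind = kind)
}

#' Measure oscillation features of a trajectory
#'
#' Peak/trough detection on the nuclear NF-kB time course with a minimum
#' prominence, plus the damping metric used throughout the analyses: the
#' maximum peak-trough difference among extrema occurring after a cutoff time.
#'
#' @param traj An `nfkb_trajectory` (or any data frame with `time_min` and the
#'   column named in `what`).
#' @param t_cut Cutoff (min) for the late-oscillation damping metric.
#' @param prominence Minimum swing (nM) for an extremum to count as a peak or
#'   trough; defaults to 1% of total NF-kB when available, else 1% of the
#'   signal range.
#' @param what Column to analyze.
#' @return A list of class `nfkb_oscillations`: `peak_times`, `peak_values`,
#'   `trough_times`, `trough_values`, `period_estimate` (mean inter-peak
#'   spacing, `NA` with fewer than 2 peaks), `decay_estimate` (1/min, from a
#'   log-linear fit to successive peak-trough amplitudes, `NA` with fewer than
#'   2 cycles), and `max_peak_trough_after` (nM; 0 if no extrema after
#'   `t_cut`).
#' @export
measure_oscillations <- function(traj, t_cut = 360, prominence = NULL,
                                 what = "x_nM") {
  tt <- traj$time_min
  v <- traj[[what]]
  if (max(tt) < t_cut)
    stop("trajectory must span beyond t_cut", call. = FALSE)
  if (is.null(prominence)) {
    p <- attr(traj, "params")
    prominence <- if (!is.null(p)) 0.01 * p$nf_tot else 0.01 * diff(range(v))
  }
  ex <- .local_extrema(v)
  pruned <- .prune_extrema(v, ex$idx, ex$kind, prominence)
  pk <- pruned$idx[pruned$kind == "peak"]
  tr <- pruned$idx[pruned$kind == "trough"]

  period <- if (length(pk) >= 2) mean(diff(tt[pk])) else NA_real_
  # amplitude decay from successive peak -> following-trough differences
  decay <- NA_real_
  amps <- numeric(0); amp_t <- numeric(0)
  for (i in pk) {
    nxt <- tr[tr > i]
    if (length(nxt)) {
      amps <- c(amps, v[i] - v[nxt[1]])
      amp_t <- c(amp_t, tt[i])
    }
  }
  ok <- amps > 0
  if (sum(ok) >= 2)
    decay <- -stats::coef(stats::lm(log(amps[ok]) ~ amp_t[ok]))[[2]]

  # damping metric on the raw alternating extrema (no prominence pruning):
  # the largest swing between adjacent extrema whose leading extremum falls
  # at or after t_cut
  metric <- 0
  if (length(ex$idx) >= 2) {
    lead <- ex$idx[-length(ex$idx)]
    swing <- abs(diff(v[ex$idx]))
    late <- tt[lead] >= t_cut
    if (any(late)) metric <- max(swing[late])
  }
  res <- list(peak_times = tt[pk], peak_values = v[pk],
              trough_times = tt[tr], trough_values = v[tr],
              period_estimate = period, decay_estimate = decay,
              max_peak_trough_after = metric, t_cut = t_cut)
  class(res) <- "nfkb_oscillations"
  res
}
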