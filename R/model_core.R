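#' Promoter occupancy probabilities
#'
#' Quasi-equilibrium probabilities for an IkB promoter to be free of, or bound
#' by, nuclear NF-kB.  DNA binding is fast relative to synthesis and
#' degradation, so the promoter state tracks the instantaneous nuclear NF-kB
#' level x through the dissociation constant `kp`.
#'
#' @param x Nuclear NF-kB concentration (nM); vectorized.
#' @param kp Promoter dissociation constant (nM).
#' @return A list with components `p_free` and `p_bound`; the two sum to 1 and
#'   `p_bound = x / (kp + x)` increases monotonically in `x`.
#' @export
promoter_occupancy <- function(x, kp) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("x must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(kp) || length(kp) != 1L || kp <= 0)
    stop("kp must be a single positive number", call. = FALSE)
  pb <- x / (kp + x)
  list(p_free = 1 - pb, p_bound = pb)
}

#' Free nuclear NF-kB from total inhibitor levels
#'
#' Solves the conservation + quasi-equilibrium system for free (nuclear) NF-kB
#' given the total concentrations of the two IkB isoforms.  Total NF-kB is
#' partitioned between the free pool and the complexes with each isoform
#' (promoter-bound NF-kB is negligible); complex binding is at quasi-
#' equilibrium with dissociation constant `kc`, which yields the quadratic
#' \deqn{x^2 + (k_c + y_a + y_e - N) x - N k_c = 0}
#' whose unique nonnegative root is returned (N = total NF-kB).
#'
#' @param y_a Total IkBa (nM); vectorized.
#' @param y_e Total IkBe (nM); vectorized (0 for the single-loop model).
#' @param params An `nfkb_params` object.
#' @return Free nuclear NF-kB x (nM), strictly decreasing in both inhibitor
#'   arguments, with `0 <= x <= nf_tot`.
#' @export
solve_free_nfkb <- function(y_a, y_e = 0, params) {
  if (any(y_a < 0) || any(y_e < 0))
    stop("inhibitor concentrations must be nonnegative", call. = FALSE)
  n <- params$nf_tot
  kc <- params$kc
  b <- kc + y_a + y_e - n
  disc <- sqrt(b * b + 4 * n * kc)
  # numerically stable positive quadratic root for either sign of b
  x <- ifelse(b <= 0, (disc - b) / 2, 2 * n * kc / (disc + b))
  pmin(x, n)
}

# quasi-equilibrium partition of a total-isoform level into free and
# NF-kB-bound parts, given free nuclear NF-kB x
partition_ikb <- function(y_tot, x, kc) {
  bound <- y_tot * x / (kc + x)
  list(free = y_tot - bound, bound = bound)
}

# synthesis rate of an isoform given delayed nuclear NF-kB x_tau
synthesis_rate <- function(x_tau, c_const, c_ind, kp, constitutive_only) {
  if (constitutive_only) return(c_const + 0 * x_tau)
  occ <- promoter_occupancy(x_tau, kp)
  c_const * occ$p_free + c_ind * occ$p_bound
}

#' Right-hand side of the single-feedback delay-differential equation
#'
#' Rate of change of total IkBa: delayed synthesis (constitutive from the free
#' promoter, induced from the NF-kB-bound promoter, both read at the delayed
#' nuclear NF-kB level), constitutive degradation of the free protein, and
#' IKK-induced degradation of free and complexed IkBa.
#'
#' @param y_now Total IkBa at time t (nM).
#' @param y_delayed Total IkBa at time t - tau1 (nM).
#' @param k_now IKK activity K(t) (dimensionless).
#' @param params An `nfkb_params` object.
#' @return dy/dt (nM/min).
#' @export
rhs_single <- function(y_now, y_delayed, k_now, params) {
  if (any(c(y_now, y_delayed, k_now) < 0))
    stop("rhs_single inputs must be nonnegative", call. = FALSE)
  x_tau <- solve_free_nfkb(y_delayed, 0, params)
  x_now <- solve_free_nfkb(y_now, 0, params)
  part <- partition_ikb(y_now, x_now, params$kc)
  synthesis_rate(x_tau, params$c0, params$c1, params$kp,
                 params$constitutive_only) -
    params$deg_a * part$free -
    params$r_ikk * k_now * (part$free + params$rho * part$bound)
}

#' Right-hand side of the dual-feedback delay-differential system
#'
#' Coupled rates of change of total IkBa and total IkBe.  Each isoform's
#' synthesis reads nuclear NF-kB at its own delay (tau1 for IkBa, tau2 for
#' IkBe), computed from the full delayed state (both isoforms); degradation
#' acts on the instantaneous quasi-equilibrium partition.  IkBe synthesis
#' (both constitutive and induced) is scaled by `eps`; with `eps = 0` and
#' `y_e = 0` the IkBa component reproduces [rhs_single()] exactly.
#'
#' @param state Numeric vector `c(y_a, y_e)` at time t (nM).
#' @param delayed1 State `c(y_a, y_e)` at time t - tau1 (nM).
#' @param delayed2 State `c(y_a, y_e)` at time t - tau2 (nM).
#' @param k_now IKK activity K(t).
#' @param params An `nfkb_params` object.
#' @return Numeric vector `c(dy_a/dt, dy_e/dt)` (nM/min).
#' @export
rhs_dual <- function(state, delayed1, delayed2, k_now, params) {
  if (any(c(state, delayed1, delayed2, k_now) < 0))
    stop("rhs_dual inputs must be nonnegative", call. = FALSE)
  x_t1 <- solve_free_nfkb(delayed1[1], delayed1[2], params)
  x_t2 <- solve_free_nfkb(delayed2[1], delayed2[2], params)
  x_now <- solve_free_nfkb(state[1], state[2], params)
  pa <- partition_ikb(state[1], x_now, params$kc)
  pe <- partition_ikb(state[2], x_now, params$kc)
  dya <- synthesis_rate(x_t1, params$c0, params$c1, params$kp,
                        params$constitutive_only) -
    params$deg_a * pa$free -
    params$r_ikk * k_now * (pa$free + params$rho * pa$bound)
  dye <- params$eps * synthesis_rate(x_t2, params$c0_e, params$c1, params$kp,
                                     params$constitutive_only) -
    params$deg_e * pe$free -
    params$r_ikk * k_now * (pe$free + params$rho * pe$bound)
  c(dya, dye)
}

#' Steady state under constant IKK activity
#'
#' Finds the stationary state of the chosen model variant for a constant input
#' K by reducing the stationarity conditions to a single equation in the free
#' nuclear NF-kB level x: at steady state each total-isoform level follows
#' from balancing delayed synthesis (evaluated at x) against degradation, and
#' x must reproduce itself through [solve_free_nfkb()].
#'
#' @param variant One of `"none"`, `"single"`, `"dual"`.
#' @param params An `nfkb_params` object.
#' @param K Constant IKK activity.
#' @return A list with `x`, `y_a`, `y_e` (nM).
#' @export
steady_state <- function(variant = c("single", "dual", "none"), params, K = 0) {
  variant <- match.arg(variant)
  kc <- params$kc
  y_of_x <- function(x, c_const, c_ind, deg, scale = 1) {
    syn <- scale * synthesis_rate(x, c_const, c_ind, params$kp,
                                  params$constitutive_only)
    # deg * free + r K (free + rho bound) with free/bound partition of y:
    # y * [deg * kc + r K (kc + rho x)] / (kc + x)
    syn * (kc + x) / (deg * kc + params$r_ikk * K * (kc + params$rho * x))
  }
  ya_fun <- function(x) y_of_x(x, params$c0, params$c1, params$deg_a)
  ye_fun <- function(x) {
    if (variant == "dual")
      y_of_x(x, params$c0_e, params$c1, params$deg_e, scale = params$eps)
    else 0
  }
  g <- function(x) solve_free_nfkb(ya_fun(x), ye_fun(x), params) - x
  lo <- params$nf_tot * 1e-12
  hi <- params$nf_tot
  if (g(hi) > 0) {          # inhibitor never accumulates: all NF-kB free
    x <- hi
  } else {
    x <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  list(x = x, y_a = ya_fun(x), y_e = ye_fun(x))
}
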