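#' Kinetic parameters of the reduced IkB--NF-kB models
#'
#' Builds and validates the parameter set shared by the no-feedback,
#' single-feedback and dual-feedback delay-differential models.  Concentrations
#' are in nM, time in minutes, and the IKK input K is dimensionless.
#'
#' @param nf_tot Total NF-kB concentration (nM); conserved.
#' @param c0 Constitutive IkBa synthesis rate from the unbound promoter
#'   (nM/min).
#' @param c1 Induced synthesis rate from the NF-kB-bound promoter (nM/min).
#' @param deg_a Constitutive degradation rate of free IkBa (1/min).
#' @param r_ikk IKK-mediated degradation rate coefficient per unit K (1/min).
#' @param rho Ratio of IKK-mediated degradation of the NF-kB-bound complex to
#'   that of free IkB (dimensionless, order 1).
#' @param kp Promoter-binding dissociation constant of NF-kB (nM).
#' @param kc IkB--NF-kB complex dissociation constant (nM).
#' @param tau1 IkBa synthesis delay (min).
#' @param tau2 IkBe synthesis delay (min).
#' @param eps IkBe feedback-strength scaling factor (dimensionless); scales
#'   both constitutive and induced IkBe synthesis.  `eps = 0` removes the
#'   secondary loop and reduces the dual model exactly to the single-feedback
#'   model.
#' @param c0_e Constitutive IkBe synthesis rate (nM/min).
#' @param deg_e Constitutive degradation rate of free IkBe (1/min).
#' @param constitutive_only If `TRUE`, IkBa synthesis is a flat `c0`
#'   independent of promoter occupancy (the no-feedback variant).
#'
#' @return An object of class `nfkb_params` (a named list).
#' @export
model_params <- function(nf_tot = 250, c0 = 0.00185, c1 = 61, deg_a = 0.07,
                         r_ikk = 0.14, rho = 2, kp = 600, kc = 5e-7,
                         tau1 = 45, tau2 = 45, eps = 0.7,
                         c0_e = 2e-4, deg_e = 0.25,
                         constitutive_only = FALSE) {
  p <- list(nf_tot = nf_tot, c0 = c0, c1 = c1, deg_a = deg_a, r_ikk = r_ikk,
            rho = rho, kp = kp, kc = kc, tau1 = tau1, tau2 = tau2, eps = eps,
            c0_e = c0_e, deg_e = deg_e,
            constitutive_only = isTRUE(constitutive_only))
  validate_params(p)
  class(p) <- "nfkb_params"
  p
}

validate_params <- function(p) {
  num <- c("nf_tot", "c0", "c1", "deg_a", "r_ikk", "rho", "kp", "kc",
           "tau1", "tau2", "eps", "c0_e", "deg_e")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter `", f, "` must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter `", f, "` must be nonnegative", call. = FALSE)
  }
  for (f in c("nf_tot", "kp", "kc"))
    if (p[[f]] <= 0)
      stop("parameter `", f, "` must be strictly positive", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' @param params An `nfkb_params` object.
#' @param ... Named fields to replace.
#' @return A new validated `nfkb_params` object.
#' @export
update_params <- function(params, ...) {
  mods <- list(...)
  bad <- setdiff(names(mods), names(params))
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params[names(mods)] <- mods
  validate_params(params)
  class(params) <- "nfkb_params"
  params
}

#' No-feedback model variant
#'
#' Returns a parameter set in which induced IkBa synthesis is disabled
#' (`c1 = 0`) and synthesis no longer depends on promoter occupancy, so IkBa is
#' produced constitutively at rate `c0`.  Raising `c0` (the published variant
#' uses 0.3 nM/min instead of 0.00185 nM/min) speeds post-pulse attenuation at
#' the cost of responsiveness.
#'
#' @param params An `nfkb_params` object.
#' @param c0 Optional replacement constitutive synthesis rate (nM/min).
#' @return An `nfkb_params` object for the feedback-free system.
#' @export
no_feedback_variant <- function(params, c0 = NULL) {
  params$c1 <- 0
  params$eps <- 0
  params$constitutive_only <- TRUE
  if (!is.null(c0)) params$c0 <- c0
  validate_params(params)
  params
}

#' Piecewise-constant IKK input signal
#'
#' K(t) equals `baseline` before `t_on` and from `t_on + duration` onwards, and
#' `amplitude` on `[t_on, t_on + duration)`.
#'
#' @param amplitude Stimulated IKK activity (dimensionless).
#' @param t_on Onset time (min).
#' @param duration Pulse duration (min); `Inf` for persistent stimulation.
#' @param baseline Pre/post-stimulus activity (default 0).
#' @return An object of class `nfkb_signal`.
#' @export
input_signal <- function(amplitude = 1, t_on = 0, duration = Inf,
                         baseline = 0) {
  stopifnot(is.numeric(amplitude), amplitude >= 0,
            is.numeric(t_on), is.finite(t_on),
            is.numeric(duration), duration > 0,
            is.numeric(baseline), baseline >= 0)
  s <- list(amplitude = amplitude, t_on = t_on, duration = duration,
            baseline = baseline)
  class(s) <- "nfkb_signal"
  s
}

#' Evaluate an input signal
#'
#' @param signal An `nfkb_signal` object.
#' @param t Time or vector of times (min).
#' @return K(t), vectorized over `t`.
#' @export
signal_value <- function(signal, t) {
  on <- t >= signal$t_on & t < signal$t_on + signal$duration
  ifelse(on, signal$amplitude, signal$baseline)
}

# times at which K(t) jumps (finite ones only)
signal_switch_times <- function(signal) {
  s <- signal$t_on
  if (is.finite(signal$duration)) s <- c(s, signal$t_on + signal$duration)
  s
}

#' Reference parameter configuration
#'
#' The calibrated parameter set shipped with the package.  It is seeded from
#' literature-scale biochemical measurements (total NF-kB 100 nM, constitutive
#' IkBa synthesis 0.00185 nM/min, tight IkB--NF-kB binding) and calibrated so
#' that the single-loop model oscillates with a period of about 90 min under
#' persistent stimulation and the dual model with `eps = 1` gives a peak
#' IkBa:IkBe ratio of 3.9 (see the methods vignette).
#'
#' @return An `nfkb_params` object.
#' @export
reference_params <- function() {
  do.call(model_params, .reference_config$params)
}

#' Reference stimulated IKK activity
#'
#' The dimensionless IKK amplitude used for the stimulated analyses with the
#' reference configuration.
#'
#' @return A single number.
#' @export
reference_K <- function() .reference_config$K
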