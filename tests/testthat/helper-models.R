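# shared fixtures: a fast integrator and a small, oscillation-prone parameter
# set used where the exact reference configuration is not the point
fast_cfg <- function(dt = 0.5) {
  integrator_config(rel_tol = 1e-7, abs_tol = 1e-9, dt_out = dt)
}

toy_params <- function(...) {
  update_params(model_params(nf_tot = 100, c1 = 12, r_ikk = 0.1, rho = 1,
                             tau1 = 37, kp = 30, kc = 0.0067, deg_a = 0.07,
                             deg_e = 0.18, c0_e = 1e-4, tau2 = 45, eps = 0.35),
                ...)
}

# independent full mass-action ODE oracle for the dual model: explicit free
# and bound species with fast binding, delays inserted in the synthesis
# terms.  Used to cross-check the reduced quasi-equilibrium right-hand side.
mass_action_drift <- function(state, delayed_x1, delayed_x2, K, params,
                              kon = 1e5) {
  # state: yaf, yab, zef, zeb; x = nf_tot - yab - zeb
  x <- params$nf_tot - state[2] - state[4]
  koff <- kon * params$kc
  occ1 <- promoter_occupancy(delayed_x1, params$kp)
  occ2 <- promoter_occupancy(delayed_x2, params$kp)
  dyaf <- params$c0 * occ1$p_free + params$c1 * occ1$p_bound -
    params$deg_a * state[1] - params$r_ikk * K * state[1] -
    kon * x * state[1] + koff * state[2]
  dyab <- kon * x * state[1] - koff * state[2] -
    params$rho * params$r_ikk * K * state[2]
  dzef <- params$eps * (params$c0_e * occ2$p_free + params$c1 * occ2$p_bound) -
    params$deg_e * state[3] - params$r_ikk * K * state[3] -
    kon * x * state[3] + koff * state[4]
  dzeb <- kon * x * state[3] - koff * state[4] -
    params$rho * params$r_ikk * K * state[4]
  c(dyaf, dyab, dzef, dzeb)
}
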