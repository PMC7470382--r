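# shared fixtures, all built in code

cq_form <- drug_formulation("chloroquine")
hcq_form <- drug_formulation("hydroxychloroquine")

# fast-kinetics parameter set for tests that must approach steady state or
# integrate most of the AUC inside a short grid (not a drug-like fixture)
fast_pk <- pk_parameters(cl_f = 20, vc_f = 100, q_f = 15, vp_f = 300,
                         ka = 0.8, tlag = 0.5, renal_fraction = 0.5,
                         mw_base = 319.87, drug = "test")

# numerical ODE solution of the same depot + mammillary system, with a
# cumulative-elimination state so mass balance is checkable; independent
# oracle for the analytic profile
ode_profile <- function(params, schedule, time_grid, rtol = 1e-10) {
  np <- length(params$q_f)
  k10 <- params$cl_f / params$vc_f
  k1p <- params$q_f / params$vc_f
  kp1 <- params$q_f / params$vp_f
  deriv <- function(t, y, p) {
    depot <- y[1]; cen <- y[2]; per <- y[3:(2 + np)]
    dd <- -params$ka * depot
    dc <- params$ka * depot - (k10 + sum(k1p)) * cen + sum(kp1 * per)
    dp <- k1p * cen - kp1 * per
    delim <- k10 * cen
    list(c(dd, dc, dp, delim))
  }
  events <- data.frame(var = 1, time = schedule$time_h + params$tlag,
                       value = schedule$amount_mg_base * params$f_rel,
                       method = "add")
  times <- sort(unique(c(time_grid, events$time)))
  y0 <- c(depot = 0, central = 0, per = rep(0, np), elim = 0)
  sol <- deSolve::lsoda(y0, times, deriv, NULL, rtol = rtol, atol = 1e-12,
                        events = list(data = events))
  amt <- stats::approx(sol[, 1], sol[, 3], xout = time_grid)$y
  list(conc_um = amt / params$vc_f * 1000 / params$mw_base, raw = sol)
}
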