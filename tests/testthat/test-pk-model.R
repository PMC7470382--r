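test_that("allometric scaling uses 0.75/1.0 exponents about 62 kg", {
  pk <- make_fixture_pk_set("chloroquine")
  expect_equal(allometric_scale(pk, 62), pk)
  up <- allometric_scale(pk, 124)
  expect_equal(up$cl_f, pk$cl_f * 2^0.75)
  expect_equal(up$q_f, pk$q_f * 2^0.75)
  expect_equal(up$vc_f, pk$vc_f * 2)
  half <- allometric_scale(pk, 31)
  expect_equal(half$vc_f, pk$vc_f / 2)
  expect_equal(half$ka, pk$ka) # absorption not weight-scaled
  expect_error(allometric_scale(pk, -1), "positive")
})

test_that("exponential variability recovers log-normal median and CV", {
  pk <- make_fixture_pk_set("chloroquine")
  expect_equal(sample_individual(pk, 0), pk)
  set.seed(101)
  n <- 1e5
  cl <- vapply(seq_len(n), function(i) sample_individual(pk, 0.30)$cl_f,
               numeric(1))
  expect_lt(abs(median(cl) / pk$cl_f - 1), 0.01)
  gcv <- sqrt(exp(stats::sd(log(cl))^2) - 1)
  expect_lt(abs(gcv - 0.30), 0.01)
})

test_that("renal impairment reduces only total clearance, by the right factor", {
  pk <- make_fixture_pk_set("chloroquine") # renal fraction 0.5
  imp <- apply_renal_impairment(pk, 0.9)
  expect_equal(imp$cl_f / pk$cl_f, 0.55) # 45% reduction
  expect_equal(imp[setdiff(names(imp), "cl_f")],
               pk[setdiff(names(pk), "cl_f")])
  expect_equal(apply_renal_impairment(pk, 0), pk)
  pk$renal_fraction <- 0.2
  expect_equal(apply_renal_impairment(pk, 1)$cl_f, pk$cl_f * 0.8)
  expect_error(apply_renal_impairment(pk, 1.2), "\\[0, 1\\]")
})

test_that("terminal half-life matches limits and the simulated tail slope", {
  # one-compartment limit: q -> 0
  p1 <- pk_parameters(cl_f = 10, vc_f = 100, q_f = 1e-9, vp_f = 1e-9,
                      ka = 1, drug = "test")
  expect_equal(terminal_half_life(p1), log(2) * 100 / 10, tolerance = 1e-5)
  # two-compartment half-life >= the pooled one-compartment half-life
  pk <- make_fixture_pk_set("chloroquine")
  expect_gte(terminal_half_life(pk),
             log(2) * (pk$vc_f + sum(pk$vp_f)) / pk$cl_f)
  # and equals the log-slope of the simulated terminal tail
  sched <- build_treatment_schedule("flat", 62, cq_form)
  tail_grid <- seq(5000, 8000, by = 100)
  prof <- simulate_profile(pk, sched, tail_grid)
  slope <- unname(coef(lm(log(prof$conc_um) ~ prof$time_h))[2])
  expect_equal(log(2) / -slope, terminal_half_life(pk), tolerance = 1e-3)
})

test_that("fixture parameter sets satisfy the qualitative PK constraints", {
  for (drug in c("chloroquine", "hydroxychloroquine")) {
    pk <- make_fixture_pk_set(drug)
    expect_gt(terminal_half_life(pk), 672) # > 28 days
    expect_gt((pk$vc_f + sum(pk$vp_f)) / 62, 100) # > 100 L/kg at 62 kg
  }
  expect_equal(make_fixture_pk_set("chloroquine")$mw_base, 319.87)
  expect_error(make_fixture_pk_set("quinine"))
})

test_that("analytic profile matches the numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  grid <- seq(0, 96, by = 2)
  sched <- build_treatment_schedule("flat", 62, cq_form)
  for (params in list(fast_pk, make_fixture_pk_set("chloroquine"))) {
    a <- simulate_profile(params, sched, grid)$conc_um
    o <- ode_profile(params, sched, grid)$conc_um
    nz <- o > 0
    expect_lt(max(abs(a[nz] - o[nz]) / o[nz]), 1e-6)
  }
  # three-compartment variant (two peripheral compartments)
  p3 <- pk_parameters(cl_f = 20, vc_f = 100, q_f = c(15, 3),
                      vp_f = c(300, 2000), ka = 0.8, tlag = 0.5,
                      drug = "test3")
  a <- simulate_profile(p3, sched, grid)$conc_um
  o <- ode_profile(p3, sched, grid)$conc_um
  nz <- o > 0
  expect_lt(max(abs(a[nz] - o[nz]) / o[nz]), 1e-6)
})

test_that("ODE oracle conserves mass", {
  skip_if_not_installed("deSolve")
  sched <- build_treatment_schedule("flat", 62, cq_form)
  sol <- ode_profile(fast_pk, sched, seq(0, 96, by = 1))$raw
  # evaluate at observation times only: rows at the exact event times hold
  # the pre-event state
  sol <- sol[sol[, 1] %in% seq(0, 96, by = 1), ]
  dosed <- vapply(sol[, 1], function(t)
    sum(sched$amount_mg_base[sched$time_h + fast_pk$tlag <= t + 1e-9]),
    numeric(1))
  in_system <- rowSums(sol[, -1, drop = FALSE]) # depot+cpts+eliminated
  err <- abs(in_system - dosed) / max(dosed)
  expect_lt(max(err), 1e-8)
})

test_that("profiles are linear in dose and superpose over dose events", {
  grid <- seq(0, 200, by = 1)
  sched <- build_treatment_schedule("flat", 62, cq_form)
  base <- simulate_profile(fast_pk, sched, grid)$conc_um
  double <- sched; double$amount_mg_base <- 2 * double$amount_mg_base
  expect_equal(simulate_profile(fast_pk, double, grid)$conc_um, 2 * base,
               tolerance = 1e-12)
  # sum of per-dose profiles equals the multi-dose profile
  per_dose <- rowSums(vapply(seq_len(nrow(sched)), function(i)
    simulate_profile(fast_pk, sched[i, ], grid)$conc_um,
    numeric(length(grid))))
  expect_equal(per_dose, base, tolerance = 1e-12)
  # time invariance: shifting the schedule shifts the profile
  shifted <- sched; shifted$time_h <- shifted$time_h + 24
  s1 <- simulate_profile(fast_pk, shifted, grid)$conc_um
  expect_equal(s1[grid >= 24], base[seq_len(sum(grid >= 24))],
               tolerance = 1e-12)
})

test_that("profile contract: zero before lag, empty schedule, bad grids", {
  grid <- seq(0, 48, by = 0.25)
  one <- build_treatment_schedule("flat", 62, cq_form)[1, ]
  prof <- simulate_profile(fast_pk, one, grid)
  expect_true(all(prof$conc_um[grid <= fast_pk$tlag] == 0))
  expect_true(all(prof$conc_um[grid > fast_pk$tlag] > 0))
  empty <- one[0, ]
  expect_true(all(simulate_profile(fast_pk, empty, grid)$conc_um == 0))
  expect_error(simulate_profile(fast_pk, one, c(-1, 0, 1)), "negative")
  expect_error(simulate_profile(fast_pk, one, c(0, 2, 1)), "increasing")
})

test_that("troughs accumulate toward steady state; renal impairment raises it", {
  # repeated identical doses: troughs non-decreasing toward steady state
  ident <- data.frame(time_h = seq(0, 59) * 24, amount_mg_base = 155,
                      tablets = 1, role = "maintenance")
  troughs_at <- ident$time_h[-1] - 1e-6
  pk <- make_fixture_pk_set("chloroquine")
  tr <- simulate_profile(pk, ident, troughs_at)$conc_um
  expect_true(all(diff(tr) > -1e-12))
  # steady-state average concentration scales as 1/CL: fast kinetics so the
  # last dosing interval is effectively at steady state
  daily <- data.frame(time_h = seq(0, 29) * 24,
                      amount_mg_base = 155, tablets = 1,
                      role = "maintenance")
  grid <- seq(0, 30 * 24, by = 0.5)
  avg_last <- function(p) {
    prof <- simulate_profile(p, daily, grid)
    (auc_to_horizon(prof, 720) - auc_to_horizon(prof, 696)) / 24
  }
  ratio <- avg_last(apply_renal_impairment(fast_pk, 0.9)) / avg_last(fast_pk)
  expect_equal(ratio, 1 / 0.55, tolerance = 0.02)
})

test_that("population simulation is seeded, reproducible, and degenerates correctly", {
  sched <- build_treatment_schedule("flat", 62, cq_form)
  grid <- seq(0, 168, by = 4)
  pk <- make_fixture_pk_set("chloroquine")
  spec <- population_spec(n_subjects = 8, omega = 0.3, seed = 11,
                          weights = c(50, 70))
  pop1 <- simulate_population(pk, sched, spec, grid)
  pop2 <- simulate_population(pk, sched, spec, grid)
  expect_identical(pop1$conc_um, pop2$conc_um)
  # omega = 0 at reference weight: every profile is the typical profile
  spec0 <- population_spec(n_subjects = 4, omega = 0, seed = 1, weights = 62)
  pop0 <- simulate_population(pk, sched, spec0, grid)
  typ <- simulate_profile(pk, sched, grid)$conc_um
  for (i in 1:4) expect_equal(pop0$conc_um[i, ], typ)
  # log-normal mean above median: population mean Cmax > typical Cmax
  specv <- population_spec(n_subjects = 2000, omega = 0.3, seed = 3,
                           weights = 62)
  popv <- simulate_population(pk, sched, specv, time_grid = grid)
  expect_gt(mean(apply(popv$conc_um, 1, max)), max(typ))
})
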