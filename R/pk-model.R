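#' Apparent oral pharmacokinetic parameters
#'
#' Parameter set for a linear mammillary disposition model (one central and
#' one or two peripheral compartments) with first-order oral absorption and
#' an absorption lag. All clearances and volumes are apparent (divided by
#' oral bioavailability F). Concentrations are modelled directly in whole
#' blood; `blood_plasma_ratio` is carried only for scaling plasma-referenced
#' EC50 values, never for profile conversion.
#'
#' @param cl_f apparent elimination clearance CL/F (L/h).
#' @param vc_f apparent central volume Vc/F (L).
#' @param q_f apparent intercompartmental clearance(s) Q/F (L/h); a vector
#'   of length 1 or 2 (one entry per peripheral compartment).
#' @param vp_f apparent peripheral volume(s) Vp/F (L); same length as `q_f`.
#' @param ka first-order absorption rate constant (1/h).
#' @param tlag absorption lag time (h).
#' @param f_rel relative oral bioavailability in (0, 1].
#' @param renal_fraction fraction of CL/F that is renal (reported range
#'   0.20--0.55; the worst-case renal scenario uses 0.5).
#' @param blood_plasma_ratio whole-blood to plasma concentration ratio.
#' @param mw_base molecular weight of the base (g/mol), for mg -> uM.
#' @param drug drug label carried in output metadata.
#' @return An object of class `"pk_parameters"`.
#' @seealso [make_fixture_pk_set()] for illustrative CQ/HCQ sets.
#' @export
pk_parameters <- function(cl_f, vc_f, q_f, vp_f, ka, tlag = 0, f_rel = 1,
                          renal_fraction = 0.5, blood_plasma_ratio = 1,
                          mw_base = 319.87, drug = "chloroquine") {
  stopifnot(length(q_f) == length(vp_f), length(q_f) %in% 1:2,
            cl_f > 0, vc_f > 0, all(q_f > 0), all(vp_f > 0), ka > 0,
            tlag >= 0, f_rel > 0, f_rel <= 1,
            renal_fraction >= 0, renal_fraction <= 1,
            blood_plasma_ratio > 0, mw_base > 0)
  structure(list(cl_f = cl_f, vc_f = vc_f, q_f = q_f, vp_f = vp_f,
                 ka = ka, tlag = tlag, f_rel = f_rel,
                 renal_fraction = renal_fraction,
                 blood_plasma_ratio = blood_plasma_ratio,
                 mw_base = mw_base, drug = drug),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("PK parameters (%s, %d peripheral cpt):\n", x$drug,
              length(x$q_f)))
  cat(sprintf("  CL/F %.3g L/h  Vc/F %.4g L  Q/F %s L/h  Vp/F %s L\n",
              x$cl_f, x$vc_f, paste(signif(x$q_f, 3), collapse = "+"),
              paste(signif(x$vp_f, 4), collapse = "+")))
  cat(sprintf("  ka %.3g /h  tlag %.3g h  F %.3g  renal fraction %.2g\n",
              x$ka, x$tlag, x$f_rel, x$renal_fraction))
  cat(sprintf("  terminal half-life %.1f days\n",
              terminal_half_life(x) / 24))
  invisible(x)
}

#' Virtual-population specification
#'
#' How many subjects to simulate, the between-patient variability magnitude
#' (standard deviation of the log-normal parameter deviations; 0.30
#' approximates the 30% variability added exponentially to all parameters),
#' the subject weights, and the allometric scaling convention (exponent 0.75
#' on clearances, 1.0 on volumes, reference weight 62 kg).
#'
#' @param n_subjects number of virtual subjects (simulations use 1,000).
#' @param omega log-scale SD of between-patient variability (>= 0).
#' @param seed integer seed; every simulation drawing from this spec is
#'   reproducible given the seed.
#' @param weights vector of body weights (kg), recycled to `n_subjects`.
#' @param ref_weight allometric reference weight (kg).
#' @param exp_clearance,exp_volume allometric exponents.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(n_subjects = 1000, omega = 0.30, seed = 1L,
                            weights = 62, ref_weight = 62,
                            exp_clearance = 0.75, exp_volume = 1) {
  stopifnot(n_subjects >= 1, omega >= 0, all(weights > 0), ref_weight > 0)
  structure(list(n_subjects = as.integer(n_subjects), omega = omega,
                 seed = as.integer(seed),
                 weights = rep_len(weights, n_subjects),
                 ref_weight = ref_weight, exp_clearance = exp_clearance,
                 exp_volume = exp_volume),
            class = "population_spec")
}

# parameters that receive between-patient variability / allometry
.clearance_fields <- c("cl_f", "q_f")
.volume_fields <- c("vc_f", "vp_f")

#' Allometric scaling of PK parameters by body weight
#'
#' Clearances are multiplied by `(weight / ref_weight)^0.75` and volumes by
#' `(weight / ref_weight)^1`, the standard pharmacometric convention; all
#' other fields are unchanged.
#'
#' @param params a [pk_parameters()] set (typical values).
#' @param weight subject body weight (kg, > 0).
#' @param ref_weight reference weight (kg); 62 kg is the standard patient.
#' @param exp_clearance,exp_volume allometric exponents.
#' @return Scaled [pk_parameters()].
#' @export
allometric_scale <- function(params, weight, ref_weight = 62,
                             exp_clearance = 0.75, exp_volume = 1) {
  stopifnot(inherits(params, "pk_parameters"))
  if (weight <= 0) stop("weight must be positive")
  r <- weight / ref_weight
  for (f in .clearance_fields) params[[f]] <- params[[f]] * r^exp_clearance
  for (f in .volume_fields) params[[f]] <- params[[f]] * r^exp_volume
  params
}

#' Draw an individual parameter set with exponential variability
#'
#' Each structural parameter (CL/F, Vc/F, Q/F, Vp/F, ka, tlag) is multiplied
#' by `exp(eta)` with independent `eta ~ N(0, omega^2)`, so individual
#' parameters are log-normal with median equal to the typical value and
#' geometric CV `sqrt(exp(omega^2) - 1)` (~30.4% at omega 0.30). Uses the
#' current R random-number stream.
#'
#' @param params typical [pk_parameters()].
#' @param omega log-scale SD (>= 0).
#' @return Individual [pk_parameters()].
#' @export
sample_individual <- function(params, omega) {
  stopifnot(inherits(params, "pk_parameters"), omega >= 0)
  fields <- c("cl_f", "vc_f", "q_f", "vp_f", "ka", "tlag")
  for (f in fields) {
    eta <- stats::rnorm(length(params[[f]]), 0, omega)
    params[[f]] <- params[[f]] * exp(eta)
  }
  params
}

#' Renal-impairment clearance adjustment
#'
#' Reduces total apparent clearance by `renal_fraction * impairment_fraction`
#' with no compensatory increase in hepatic clearance. The worst-case
#' scenario (renal fraction 0.5, 90% impairment) reduces total body
#' clearance by 45%.
#'
#' @param params a [pk_parameters()] set.
#' @param impairment_fraction fraction of renal clearance lost, in \[0, 1\]
#'   (severe impairment: 0.9, i.e. 10% of renal function remaining).
#' @return Adjusted [pk_parameters()].
#' @export
apply_renal_impairment <- function(params, impairment_fraction = 0.9) {
  stopifnot(inherits(params, "pk_parameters"))
  if (impairment_fraction < 0 || impairment_fraction > 1)
    stop("impairment_fraction must be in [0, 1]")
  params$cl_f <- params$cl_f *
    (1 - params$renal_fraction * impairment_fraction)
  params
}

# disposition matrix (central + peripherals), first-order rate constants
.disposition_matrix <- function(params) {
  np <- length(params$q_f)
  k10 <- params$cl_f / params$vc_f
  k1p <- params$q_f / params$vc_f
  kp1 <- params$q_f / params$vp_f
  M <- matrix(0, np + 1, np + 1)
  M[1, 1] <- -(k10 + sum(k1p))
  for (i in seq_len(np)) {
    M[1, 1 + i] <- kp1[i]
    M[1 + i, 1] <- k1p[i]
    M[1 + i, 1 + i] <- -kp1[i]
  }
  M
}

#' Terminal elimination half-life
#'
#' `log(2)` divided by the smallest-magnitude disposition exponent of the
#' compartment system. For chloroquine and hydroxychloroquine the deep
#' peripheral compartment makes this very long (reported averages about
#' 38 and 54 days).
#'
#' @param params a [pk_parameters()] set.
#' @return Half-life in hours.
#' @export
terminal_half_life <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  lam <- eigen(.disposition_matrix(params), only.values = TRUE)$values
  log(2) / min(abs(Re(lam)))
}

# exponential-mode decomposition of the full depot+disposition system for
# a unit amount in the depot: central amount(t) = sum(w * exp(lambda * t)).
# ka coinciding with a disposition eigenvalue (measure-zero) is broken by a
# tiny perturbation so the eigenbasis stays well conditioned.
.profile_modes <- function(params) {
  M <- .disposition_matrix(params)
  lam_disp <- eigen(M, only.values = TRUE)$values
  ka <- params$ka
  if (any(abs(ka - abs(Re(lam_disp))) < 1e-9)) ka <- ka * (1 + 1e-7)
  n <- nrow(M) + 1L
  A <- matrix(0, n, n)
  A[1, 1] <- -ka
  A[2, 1] <- ka
  A[2:n, 2:n] <- M
  e <- eigen(A)
  y0 <- c(1, rep(0, n - 1))
  w <- e$vectors[2, ] * solve(e$vectors, y0)
  list(lambda = Re(e$values), w = Re(w))
}

#' Simulate a whole-blood concentration-time profile
#'
#' Analytic (exponential-mode) solution of the linear oral absorption +
#' mammillary disposition model, superposed over all dose events of a
#' schedule. Each dose contributes nothing before `dose time + tlag`;
#' amounts in mg base are converted to micromolar whole-blood
#' concentrations via `mg / Vc * 1000 / mw_base`. The profile is
#' deterministic given the parameter set.
#'
#' @param params an individual [pk_parameters()] set.
#' @param schedule a `dose_schedule` (may be empty: all-zero profile).
#' @param time_grid strictly increasing non-negative times (h); defaults to
#'   [default_time_grid()] of the schedule.
#' @return A `concentration_profile`: data frame with `time_h` and
#'   `conc_um`.
#' @examples
#' pk <- make_fixture_pk_set("chloroquine")
#' sched <- build_treatment_schedule("flat", 62, drug_formulation(), days = 7)
#' prof <- simulate_profile(pk, sched)
#' cmax(prof)
#' @export
simulate_profile <- function(params, schedule, time_grid = NULL) {
  stopifnot(inherits(params, "pk_parameters"))
  if (is.null(time_grid)) time_grid <- default_time_grid(schedule)
  if (any(time_grid < 0)) stop("negative times in grid")
  if (is.unsorted(time_grid, strictly = TRUE))
    stop("time grid must be strictly increasing")
  conc <- numeric(length(time_grid))
  if (NROW(schedule) > 0) {
    modes <- .profile_modes(params)
    scale <- params$f_rel / params$vc_f * 1000 / params$mw_base
    for (d in seq_len(NROW(schedule))) {
      tp <- time_grid - schedule$time_h[d] - params$tlag
      on <- tp > 0
      if (!any(on)) next
      contrib <- colSums(modes$w * exp(outer(modes$lambda, tp[on])))
      conc[on] <- conc[on] + schedule$amount_mg_base[d] * scale * contrib
    }
    conc[conc < 0] <- 0 # clip floating-point negatives near the lag
  }
  structure(data.frame(time_h = time_grid, conc_um = conc),
            class = c("concentration_profile", "data.frame"))
}

#' Default observation grid for a schedule
#'
#' 1-hour steps over the dosing period, then 24-hour steps out to one month
#' (720 h) past the last dose.
#'
#' @param schedule a `dose_schedule` (or any data frame with `time_h`).
#' @return Numeric vector of times (h).
#' @export
default_time_grid <- function(schedule) {
  last <- if (NROW(schedule) > 0) max(schedule$time_h) else 0
  unique(c(seq(0, last + 24, by = 1), seq(last + 24, last + 720, by = 24)))
}

#' Simulate a virtual population of concentration profiles
#'
#' For each subject: allometric scaling of the typical parameters to the
#' subject's weight, a log-normal individual draw with SD `omega`, then the
#' deterministic profile. The whole run is reproducible under the spec's
#' seed.
#'
#' @param params typical [pk_parameters()].
#' @param schedule a `dose_schedule`.
#' @param spec a [population_spec()].
#' @param time_grid observation grid (h); default [default_time_grid()].
#' @return A `pk_population`: list with `time_h`, a subjects-by-times
#'   concentration matrix `conc_um`, the subject table, schedule and spec.
#' @export
simulate_population <- function(params, schedule, spec, time_grid = NULL) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(spec, "population_spec"))
  if (is.null(time_grid)) time_grid <- default_time_grid(schedule)
  set.seed(spec$seed)
  conc <- matrix(0, spec$n_subjects, length(time_grid))
  subjects <- data.frame(subject_id = seq_len(spec$n_subjects),
                         weight_kg = spec$weights)
  for (i in seq_len(spec$n_subjects)) {
    ind <- allometric_scale(params, spec$weights[i], spec$ref_weight,
                            spec$exp_clearance, spec$exp_volume)
    ind <- sample_individual(ind, spec$omega)
    conc[i, ] <- simulate_profile(ind, schedule, time_grid)$conc_um
  }
  structure(list(time_h = time_grid, conc_um = conc, subjects = subjects,
                 schedule = schedule, spec = spec, params = params),
            class = "pk_population")
}

#' @export
print.pk_population <- function(x, ...) {
  cat(sprintf("Simulated population: %d subjects x %d time points (seed %d)\n",
              nrow(x$conc_um), ncol(x$conc_um), x$spec$seed))
  cat(sprintf("  drug %s, omega %.2f, weights %g-%g kg\n", x$params$drug,
              x$spec$omega, min(x$spec$weights), max(x$spec$weights)))
  invisible(x)
}

#' @export
plot.pk_population <- function(x, level = 0.95, ec50 = NULL, ...) {
  s <- summarize_population(x, level = level)
  graphics::plot(x$time_h / 24, s$mean_profile, type = "n",
                 ylim = c(0, max(s$pi_high)),
                 xlab = "Time (days)",
                 ylab = expression("Whole-blood concentration (" * mu * "M)"),
                 ...)
  graphics::polygon(c(x$time_h, rev(x$time_h)) / 24,
                    c(s$pi_low, rev(s$pi_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$time_h / 24, s$mean_profile, lwd = 2)
  if (!is.null(ec50))
    graphics::abline(h = ec50, col = "red", lty = 2)
  invisible(s)
}

#' @export
plot.concentration_profile <- function(x, ...) {
  graphics::plot(x$time_h / 24, x$conc_um, type = "l",
                 xlab = "Time (days)",
                 ylab = expression("Whole-blood concentration (" * mu * "M)"),
                 ...)
  invisible(x)
}
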