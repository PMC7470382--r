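#' Peak concentration of a profile
#'
#' @param profile a `concentration_profile` (or data frame with `time_h`,
#'   `conc_um`).
#' @return List with `cmax` (uM) and `tmax` (h, first time attaining it).
#' @export
cmax <- function(profile) {
  if (NROW(profile) == 0) stop("empty profile")
  i <- which.max(profile$conc_um)
  list(cmax = profile$conc_um[i], tmax = profile$time_h[i])
}

#' Area under the concentration-time curve to a horizon
#'
#' Trapezoidal integral of the profile from time zero to `horizon`; the
#' exposure summaries use a horizon of one month (720 h) after the last
#' dose. A horizon between grid points is handled by linear interpolation;
#' a horizon beyond the grid is an error.
#'
#' @param profile a `concentration_profile`.
#' @param horizon upper limit (h); default is the last grid time.
#' @return AUC in uM*h.
#' @export
auc_to_horizon <- function(profile, horizon = max(profile$time_h)) {
  if (NROW(profile) == 0) stop("empty profile")
  t <- profile$time_h; c0 <- profile$conc_um
  if (horizon > max(t) + 1e-9) stop("horizon beyond time grid")
  if (horizon < max(t)) {
    keep <- t <= horizon
    ch <- stats::approx(t, c0, xout = horizon)$y
    t <- c(t[keep], horizon); c0 <- c(c0[keep], ch)
  }
  sum(diff(t) * (utils::head(c0, -1) + utils::tail(c0, -1)) / 2)
}

#' Exposure summary of a simulated population
#'
#' Pointwise arithmetic mean and empirical 95% prediction interval
#' (2.5th/97.5th percentiles across subjects, linear interpolation between
#' order statistics), plus per-subject Cmax and AUC (to one month past the
#' last dose) with population quantiles.
#'
#' @param pop a `pk_population` from [simulate_population()].
#' @param level prediction-interval level (default 0.95).
#' @param auc_horizon AUC upper limit (h); default last dose + 720 h.
#' @return An `exposure_summary` list: `time_h`, `mean_profile`, `pi_low`,
#'   `pi_high`, per-subject `cmax`/`tmax`/`auc`, and their quantiles.
#' @export
summarize_population <- function(pop, level = 0.95, auc_horizon = NULL) {
  stopifnot(inherits(pop, "pk_population") || is.list(pop))
  conc <- pop$conc_um
  if (NROW(conc) < 1) stop("no profiles to summarise")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (is.null(auc_horizon)) {
    last <- if (NROW(pop$schedule) > 0) max(pop$schedule$time_h) else 0
    auc_horizon <- min(last + 720, max(pop$time_h))
  }
  cm <- apply(conc, 1, max)
  tm <- pop$time_h[apply(conc, 1, which.max)]
  auc <- apply(conc, 1, function(y)
    auc_to_horizon(data.frame(time_h = pop$time_h, conc_um = y),
                   auc_horizon))
  structure(list(
    time_h = pop$time_h,
    mean_profile = colMeans(conc),
    pi_low = apply(conc, 2, stats::quantile, probs[1]),
    pi_high = apply(conc, 2, stats::quantile, probs[2]),
    level = level,
    cmax = cm, tmax = tm, auc = auc, auc_horizon = auc_horizon,
    cmax_quantiles = stats::quantile(cm, c(probs[1], 0.5, probs[2])),
    auc_quantiles = stats::quantile(auc, c(probs[1], 0.5, probs[2]))),
    class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Exposure summary (%d subjects, %g%% prediction interval)\n",
              length(x$cmax), 100 * x$level))
  cat(sprintf("  Cmax (uM): median %.3g [%.3g, %.3g]\n",
              x$cmax_quantiles[2], x$cmax_quantiles[1], x$cmax_quantiles[3]))
  cat(sprintf("  AUC 0-%g h (uM*h): median %.4g [%.4g, %.4g]\n",
              x$auc_horizon, x$auc_quantiles[2], x$auc_quantiles[1],
              x$auc_quantiles[3]))
  invisible(x)
}

#' Scale an in vitro EC50 to whole blood
#'
#' In vitro SARS-CoV-2 inhibition EC50 values are assumed to correspond to
#' total plasma concentrations and are scaled to whole blood by the
#' blood:plasma concentration ratio: 1.13 uM x 3 = 3.39 uM for chloroquine,
#' 0.72 uM x 4 = 2.88 uM for hydroxychloroquine. These are approximate
#' indicators only, never effect predictions.
#'
#' @param ec50_invitro in vitro EC50 (uM, plasma-referenced, > 0).
#' @param blood_plasma_ratio whole-blood:plasma ratio (> 0).
#' @return EC50 in uM whole blood.
#' @examples
#' scale_ec50_to_blood(1.13, 3) # 3.39
#' scale_ec50_to_blood(0.72, 4) # 2.88
#' @export
scale_ec50_to_blood <- function(ec50_invitro, blood_plasma_ratio) {
  if (any(ec50_invitro <= 0)) stop("EC50 must be positive")
  if (any(blood_plasma_ratio <= 0)) stop("blood:plasma ratio must be positive")
  ec50_invitro * blood_plasma_ratio
}

#' Fraction of subjects whose Cmax exceeds a threshold
#'
#' The whole-blood safety bound suggested by the self-poisoning analysis is
#' 10 uM (3.2 ug/mL) for peak chloroquine concentrations.
#'
#' @param pop a `pk_population` (or an `exposure_summary`).
#' @param threshold uM whole blood (>= 0).
#' @return Proportion in \[0, 1\].
#' @export
fraction_exceeding <- function(pop, threshold) {
  stopifnot(threshold >= 0)
  cm <- if (inherits(pop, "exposure_summary")) pop$cmax
        else apply(pop$conc_um, 1, max)
  mean(cm > threshold)
}

#' Molar / mass concentration conversion
#'
#' `um_to_ug_per_ml()` converts micromolar to ug/mL (`conc * mw / 1000`);
#' 10 uM chloroquine (MW 319.87) is 3.2 ug/mL. `ug_per_ml_to_um()` inverts.
#'
#' @param conc concentration (uM or ug/mL; non-negative, vectorised).
#' @param mw molecular weight (g/mol).
#' @return Converted concentration.
#' @examples
#' um_to_ug_per_ml(10, 319.87) # 3.1987
#' @export
um_to_ug_per_ml <- function(conc, mw) {
  stopifnot(all(conc >= 0), mw > 0)
  conc * mw / 1000
}

#' @rdname um_to_ug_per_ml
#' @export
ug_per_ml_to_um <- function(conc, mw) {
  stopifnot(all(conc >= 0), mw > 0)
  conc * 1000 / mw
}

#' Threshold-exceedance report across weights
#'
#' Runs [fraction_exceeding()] per weight group of a population and returns
#' the per-weight breakdown plus the overall fraction.
#'
#' @param pop a `pk_population`.
#' @param threshold uM whole blood (default 10, the safety bound).
#' @return A `threshold_report` data frame (`weight_kg`, `n`, `n_exceeding`,
#'   `fraction`) with the overall fraction as attribute `overall`.
#' @export
threshold_report <- function(pop, threshold = 10) {
  cm <- apply(pop$conc_um, 1, max)
  w <- pop$subjects$weight_kg
  by_w <- lapply(split(cm, w), function(v)
    c(n = length(v), n_exceeding = sum(v > threshold), fraction = mean(v > threshold)))
  out <- data.frame(weight_kg = as.numeric(names(by_w)),
                    do.call(rbind, by_w), row.names = NULL)
  structure(out, class = c("threshold_report", "data.frame"),
            threshold = threshold, overall = mean(cm > threshold))
}
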