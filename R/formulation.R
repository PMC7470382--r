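#' Drug formulation: salt stoichiometry and tablet strength
#'
#' Describes a marketed tablet formulation of a 4-aminoquinoline: the salt
#' form, the tablet salt mass, and the molecular weights needed for
#' salt/base arithmetic. Dosing recommendations for these drugs are given
#' in base equivalents because different salts carry different base
#' fractions; the two most widely available forms, chloroquine diphosphate
#' 250 mg and hydroxychloroquine sulphate 200 mg, both contain 155 mg base.
#'
#' The nominal tablet base mass is the rounded 155 mg unit in which the
#' simulated regimens are expressed; it must agree with the molecular-weight
#' quotient `tablet_salt_mg * mw_base / mw_salt` to within 1 mg.
#'
#' @param drug `"chloroquine"` or `"hydroxychloroquine"`, or pass all fields
#'   explicitly for a custom formulation.
#' @param salt_name salt label.
#' @param tablet_salt_mg salt mass per tablet (mg).
#' @param tablet_base_mg nominal base mass per tablet (mg).
#' @param mw_base,mw_salt molecular weights (g/mol); `mw_salt > mw_base`.
#' @return An object of class `"drug_formulation"`.
#' @examples
#' cq <- drug_formulation("chloroquine")
#' salt_to_base(250, cq, round = TRUE) # 155
#' @export
drug_formulation <- function(drug = c("chloroquine", "hydroxychloroquine"),
                             salt_name = NULL, tablet_salt_mg = NULL,
                             tablet_base_mg = NULL, mw_base = NULL,
                             mw_salt = NULL) {
  if (is.null(salt_name)) {
    drug <- match.arg(drug)
    def <- switch(drug,
      chloroquine = list(salt_name = "diphosphate", tablet_salt_mg = 250,
                         tablet_base_mg = 155, mw_base = 319.87,
                         mw_salt = 515.86),
      hydroxychloroquine = list(salt_name = "sulphate", tablet_salt_mg = 200,
                                tablet_base_mg = 155, mw_base = 335.87,
                                mw_salt = 433.95))
    salt_name <- def$salt_name; tablet_salt_mg <- def$tablet_salt_mg
    tablet_base_mg <- def$tablet_base_mg
    mw_base <- def$mw_base; mw_salt <- def$mw_salt
  } else {
    drug <- if (length(drug) == 1L) drug else "custom"
  }
  stopifnot(is.numeric(mw_base), is.numeric(mw_salt),
            mw_salt > mw_base, mw_base > 0,
            tablet_salt_mg > 0, tablet_base_mg > 0)
  implied <- tablet_salt_mg * mw_base / mw_salt
  if (abs(implied - tablet_base_mg) > 1)
    stop("tablet_base_mg (", tablet_base_mg,
         ") disagrees with salt stoichiometry (", round(implied, 2),
         " mg) by more than 1 mg")
  structure(list(drug = drug, salt_name = salt_name,
                 tablet_salt_mg = tablet_salt_mg,
                 tablet_base_mg = tablet_base_mg,
                 mw_base = mw_base, mw_salt = mw_salt),
            class = "drug_formulation")
}

#' @export
print.drug_formulation <- function(x, ...) {
  cat(sprintf("%s %s: %g mg salt/tablet = %g mg base (MW %g / %g g/mol)\n",
              x$drug, x$salt_name, x$tablet_salt_mg, x$tablet_base_mg,
              x$mw_base, x$mw_salt))
  invisible(x)
}

#' Convert salt mass to base equivalent (and back)
#'
#' `salt_to_base()` converts a salt dose to the active-moiety (base)
#' equivalent by the molecular-weight ratio; `base_to_salt()` is its exact
#' inverse. Dosing by base avoids the salt-form confusion that has caused
#' dosing errors with these drugs.
#'
#' @param mass_salt,mass_base dose in mg (non-negative, vectorised).
#' @param formulation a [drug_formulation()].
#' @param round round the result to the nearest mg.
#' @return Dose in mg.
#' @examples
#' salt_to_base(250, drug_formulation("chloroquine"), round = TRUE) # 155
#' salt_to_base(200, drug_formulation("hydroxychloroquine"), round = TRUE)
#' @export
salt_to_base <- function(mass_salt, formulation, round = FALSE) {
  stopifnot(inherits(formulation, "drug_formulation"))
  if (any(mass_salt < 0)) stop("salt mass must be non-negative")
  out <- mass_salt * formulation$mw_base / formulation$mw_salt
  if (round) round(out) else out
}

#' @rdname salt_to_base
#' @export
base_to_salt <- function(mass_base, formulation, round = FALSE) {
  stopifnot(inherits(formulation, "drug_formulation"))
  if (any(mass_base < 0)) stop("base mass must be non-negative")
  out <- mass_base * formulation$mw_salt / formulation$mw_base
  if (round) round(out) else out
}

#' Whole-tablet quantisation of a target base dose
#'
#' Returns the tablet count within `bounds` whose total base mass is closest
#' to the target (e.g. "three to five tablets to achieve doses as close as
#' possible to 10 mg base/kg"). Ties are broken toward fewer tablets, the
#' safety-conservative choice.
#'
#' @param target_mg target dose in mg base (>= 0).
#' @param formulation a [drug_formulation()].
#' @param bounds integer vector `c(min, max)` of admissible tablet counts.
#' @return Integer tablet count.
#' @examples
#' cq <- drug_formulation("chloroquine")
#' tablets_for_target(620, cq, c(3, 5)) # 4 (62-kg patient at 10 mg/kg)
#' tablets_for_target(400, cq, c(3, 5)) # 3 (40-kg patient)
#' @export
tablets_for_target <- function(target_mg, formulation, bounds) {
  stopifnot(inherits(formulation, "drug_formulation"), target_mg >= 0)
  if (length(bounds) != 2L || bounds[2] < bounds[1])
    stop("bounds must be a non-empty integer interval c(min, max)")
  n <- seq.int(bounds[1], bounds[2])
  err <- abs(n * formulation$tablet_base_mg - target_mg)
  # which.min returns the first (smallest n) among ties
  n[which.min(err)]
}

new_dose_schedule <- function(time_h, tablets, role, formulation, strategy,
                              duration_days) {
  stopifnot(all(diff(time_h) > 0), time_h[1] == 0)
  events <- data.frame(time_h = time_h,
                       amount_mg_base = tablets * formulation$tablet_base_mg,
                       tablets = tablets, role = role)
  structure(events, class = c("dose_schedule", "data.frame"),
            formulation = formulation, strategy = strategy,
            duration_days = duration_days)
}

#' Build a COVID-19 treatment dose schedule
#'
#' Constructs the simulated treatment regimens: a loading dose at 0 and
#' 6 hours followed by maintenance doses every 12 hours (starting 12 hours
#' after the first dose) up to, but not including, `days * 24` hours. Three
#' strategies are supported:
#' \describe{
#'   \item{`"flat"`}{four tablets per loading dose, two tablets per
#'     maintenance dose, regardless of weight (the RECOVERY/SOLIDARITY
#'     regimen; 7 or 10 days).}
#'   \item{`"weight_loading"`}{loading quantised to 3--5 tablets targeting
#'     10 mg base/kg per administration; flat two-tablet maintenance.}
#'   \item{`"weight_both"`}{weight-based loading as above plus maintenance
#'     quantised to 1--3 tablets targeting 5 mg base/kg per 12 h.}
#' }
#' A 7-day flat schedule has 2 loading + 13 maintenance doses (last at
#' 156 h); 10 days gives 19 maintenance doses (last at 228 h).
#'
#' @param strategy `"flat"`, `"weight_loading"` or `"weight_both"`.
#' @param weight body weight in kg; weights outside the simulated 40--90 kg
#'   range trigger a warning, not an error.
#' @param formulation a [drug_formulation()].
#' @param days treatment duration, 7 or 10.
#' @param loading_target,maintenance_target mg base/kg targets for the
#'   weight-based strategies.
#' @param loading_bounds,maintenance_bounds admissible tablet-count
#'   intervals for quantisation.
#' @return A `dose_schedule`: a data frame of dose events (`time_h`,
#'   `amount_mg_base`, `tablets`, `role`) with the formulation, strategy and
#'   duration as attributes.
#' @examples
#' cq <- drug_formulation("chloroquine")
#' sched <- build_treatment_schedule("flat", 62, cq, days = 7)
#' head(sched, 3)           # 620, 620, 310 mg at 0, 6, 12 h
#' sum(sched$amount_mg_base) # 5270 mg base over 7 days
#' @export
build_treatment_schedule <- function(strategy = c("flat", "weight_loading",
                                                  "weight_both"),
                                     weight, formulation, days = 7,
                                     loading_target = 10,
                                     maintenance_target = 5,
                                     loading_bounds = c(3, 5),
                                     maintenance_bounds = c(1, 3)) {
  strategy <- match.arg(strategy)
  stopifnot(days %in% c(7, 10), weight > 0)
  if (weight < 40 || weight > 90)
    warning("weight ", weight, " kg is outside the simulated 40-90 kg range")
  load_tab <- if (strategy == "flat") 4L
              else tablets_for_target(loading_target * weight, formulation,
                                      loading_bounds)
  maint_tab <- if (strategy == "weight_both")
                 tablets_for_target(maintenance_target * weight, formulation,
                                    maintenance_bounds)
               else 2L
  maint_times <- seq(12, days * 24 - 12, by = 12)
  new_dose_schedule(
    time_h = c(0, 6, maint_times),
    tablets = c(load_tab, load_tab, rep(maint_tab, length(maint_times))),
    role = c("loading", "loading", rep("maintenance", length(maint_times))),
    formulation = formulation, strategy = strategy, duration_days = days)
}

#' Build a prophylaxis dose schedule
#'
#' A single weight-based loading dose (3--5 tablets targeting 10 mg base/kg)
#' at time 0, followed by one tablet daily from 24 h up to, but not
#' including, `months * 30 * 24` hours. At 62 kg the one-tablet maintenance
#' equals 2.5 mg base/kg/day. `months = 0` yields a loading-only schedule.
#'
#' @inheritParams build_treatment_schedule
#' @param months prophylaxis duration in 30-day months (>= 0).
#' @return A `dose_schedule`.
#' @examples
#' cq <- drug_formulation("chloroquine")
#' p <- build_prophylaxis_schedule(62, cq, months = 3)
#' p$amount_mg_base[1:2] # 620 loading, then 155 daily
#' @export
build_prophylaxis_schedule <- function(weight, formulation, months = 3,
                                       loading_target = 10,
                                       loading_bounds = c(3, 5)) {
  stopifnot(weight > 0, months >= 0)
  if (weight < 40 || weight > 90)
    warning("weight ", weight, " kg is outside the simulated 40-90 kg range")
  load_tab <- tablets_for_target(loading_target * weight, formulation,
                                 loading_bounds)
  maint_times <- if (months > 0) seq(24, months * 30 * 24 - 24, by = 24)
                 else numeric(0)
  new_dose_schedule(
    time_h = c(0, maint_times),
    tablets = c(load_tab, rep(1L, length(maint_times))),
    role = c("loading", rep("maintenance", length(maint_times))),
    formulation = formulation, strategy = "prophylaxis",
    duration_days = months * 30)
}

#' Halve the maintenance doses of a schedule
#'
#' Renal-impairment alternative dosing: maintenance doses are halved while
#' loading doses are unchanged (half-tablet maintenance is permitted here).
#'
#' @param schedule a `dose_schedule`.
#' @return The modified `dose_schedule`.
#' @export
halve_maintenance <- function(schedule) {
  stopifnot(inherits(schedule, "dose_schedule"))
  m <- schedule$role == "maintenance"
  schedule$tablets[m] <- schedule$tablets[m] / 2
  schedule$amount_mg_base[m] <- schedule$amount_mg_base[m] / 2
  schedule
}

#' Per-event dose in mg base/kg
#'
#' @param schedule a `dose_schedule`.
#' @param weight body weight in kg (> 0).
#' @return Numeric vector, one value per dose event.
#' @examples
#' cq <- drug_formulation("chloroquine")
#' s <- build_treatment_schedule("flat", 62, cq)
#' schedule_mg_per_kg(s, 62)[1:3] # 10, 10, 5
#' @export
schedule_mg_per_kg <- function(schedule, weight) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (weight <= 0) stop("weight must be positive")
  schedule$amount_mg_base / weight
}

#' @export
print.dose_schedule <- function(x, n = 6L, ...) {
  f <- attr(x, "formulation")
  cat(sprintf("Dose schedule (%s, %s): %d events over %g days, %g mg base total\n",
              f$drug, attr(x, "strategy"), nrow(x), attr(x, "duration_days"),
              sum(x$amount_mg_base)))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more events\n", sep = "")
  invisible(x)
}

#' Write / read a dose schedule as CSV
#'
#' CSV layout: `time_h,amount_mg_base,tablets`.
#'
#' @param schedule a `dose_schedule`.
#' @param path file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "dose_schedule"))
  utils::write.csv(schedule[c("time_h", "amount_mg_base", "tablets")], path,
                   row.names = FALSE)
  invisible(path)
}
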