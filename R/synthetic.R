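#' Generating truth for a synthetic self-poisoning cohort
#'
#' Defines the statistical law a synthetic cohort is drawn from: admission
#' concentrations follow a truncated log-normal (log-median `log_median`,
#' log-SD `log_sd`, truncated to `trunc_um`), and death is Bernoulli with a
#' logistic probability in concentration, `plogis((conc - c50) / steepness)`.
#' The defaults emulate the qualitative structure of the pooled overdose
#' data — near-zero mortality below 15 uM rising steeply above 20 uM — and
#' are deliberately not fitted to any real cohort.
#'
#' @param n cohort size (default 258, the pooled-cohort size).
#' @param log_median log of the median concentration (default `log(9)` uM).
#' @param log_sd log-scale SD (default 0.6).
#' @param trunc_um truncation bounds in uM, positive and ordered
#'   (default `c(1, 85)`).
#' @param c50 concentration of 50% death probability (uM, default 30).
#' @param steepness logistic scale (uM per logit, > 0; default 2).
#' @param seed integer seed.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(n = 258, log_median = log(9), log_sd = 0.6,
                         trunc_um = c(1, 85), c50 = 30, steepness = 2,
                         seed = 1L) {
  stopifnot(n >= 1, log_sd > 0, length(trunc_um) == 2,
            trunc_um[1] > 0, trunc_um[1] < trunc_um[2], steepness > 0)
  structure(list(n = as.integer(n), log_median = log_median,
                 log_sd = log_sd, trunc_um = trunc_um, c50 = c50,
                 steepness = steepness, seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Generate a synthetic self-poisoning cohort
#'
#' Draws concentrations from the truncated log-normal by inverse-CDF
#' sampling and outcomes from the logistic mortality law; deterministic
#' under the truth's seed. The generating truth is echoed as an attribute
#' so recovery tests can compare estimate to truth.
#'
#' @param truth a [cohort_truth()].
#' @return A `poisoning_cohort` (study_id `"synthetic"`) with attribute
#'   `truth`.
#' @examples
#' coh <- generate_poisoning_cohort(cohort_truth(seed = 7))
#' summary(coh)
#' @export
generate_poisoning_cohort <- function(truth = cohort_truth()) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(truth$seed)
  plo <- stats::plnorm(truth$trunc_um[1], truth$log_median, truth$log_sd)
  phi <- stats::plnorm(truth$trunc_um[2], truth$log_median, truth$log_sd)
  u <- stats::runif(truth$n, plo, phi)
  conc <- stats::qlnorm(u, truth$log_median, truth$log_sd)
  p <- stats::plogis((conc - truth$c50) / truth$steepness)
  died <- stats::rbinom(truth$n, 1L, p)
  coh <- load_cohort(data.frame(study_id = "synthetic", conc_um = conc,
                                died = died))
  attr(coh, "truth") <- truth
  coh
}

#' Generate uniform integer body weights
#'
#' Uniform integer weights over the simulated 40--90 kg adult range.
#'
#' @param n number of weights (>= 0).
#' @param low,high inclusive bounds (kg), `low < high`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Integer vector of weights (kg).
#' @export
generate_weights <- function(n, low = 40, high = 90, seed = NULL) {
  stopifnot(n >= 0, low < high)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(integer(0))
  sample(seq.int(low, high), n, replace = TRUE)
}

#' Illustrative PK parameter fixtures for chloroquine / hydroxychloroquine
#'
#' Returns a documented, ILLUSTRATIVE parameter set — not the published
#' model estimates, which are not reproduced here — constructed to satisfy
#' the drugs' qualitative pharmacokinetic constraints: terminal elimination
#' half-life longer than 28 days and total apparent distribution volume
#' above 100 L/kg for a 62-kg adult, with absorption and distribution rates
#' in the range reported for 4-aminoquinolines. Simulated concentration
#' bands therefore have realistic shape but should not be read as
#' reproductions of any published profile.
#'
#' @param drug `"chloroquine"` or `"hydroxychloroquine"`.
#' @return A [pk_parameters()] set (attribute `provenance = "illustrative"`).
#' @examples
#' terminal_half_life(make_fixture_pk_set("chloroquine")) / 24 # > 28 days
#' @export
make_fixture_pk_set <- function(drug = c("chloroquine",
                                         "hydroxychloroquine")) {
  drug <- match.arg(drug)
  p <- switch(drug,
    chloroquine = pk_parameters(
      cl_f = 6, vc_f = 300, q_f = 35, vp_f = 9000, ka = 0.4, tlag = 0.5,
      f_rel = 1, renal_fraction = 0.5, blood_plasma_ratio = 3,
      mw_base = 319.87, drug = "chloroquine"),
    hydroxychloroquine = pk_parameters(
      cl_f = 10, vc_f = 500, q_f = 45, vp_f = 12000, ka = 0.5, tlag = 0.5,
      f_rel = 1, renal_fraction = 0.5, blood_plasma_ratio = 4,
      mw_base = 335.87, drug = "hydroxychloroquine"))
  attr(p, "provenance") <- "illustrative"
  p
}

#' Write a self-contained synthetic study bundle
#'
#' Emits, into `dir`, everything the pipeline consumes: a synthetic
#' poisoning cohort CSV, a PK parameter config (YAML), a regimen config,
#' and a truth echo JSON. Two runs with the same seed produce byte-identical
#' bundles.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed driving all randomness in the bundle.
#' @return Invisibly, the named list of file paths written.
#' @export
simulate_study_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohort_truth(seed = seed)
  coh <- generate_poisoning_cohort(truth)
  paths <- list(
    cohort = file.path(dir, "cohort_synthetic.csv"),
    pk_config = file.path(dir, "pk_chloroquine_illustrative.yml"),
    regimen = file.path(dir, "regimen_treatment_7d.yml"),
    truth = file.path(dir, "cohort_truth.json"))
  utils::write.csv(as.data.frame(coh), paths$cohort, row.names = FALSE)
  pk <- make_fixture_pk_set("chloroquine")
  yaml::write_yaml(list(
    drug = pk$drug, provenance = "illustrative",
    cl_f_l_per_h = pk$cl_f, vc_f_l = pk$vc_f, q_f_l_per_h = pk$q_f,
    vp_f_l = pk$vp_f, ka_per_h = pk$ka, tlag_h = pk$tlag,
    f_rel = pk$f_rel, renal_fraction = pk$renal_fraction,
    blood_plasma_ratio = pk$blood_plasma_ratio, mw_base = pk$mw_base),
    paths$pk_config)
  yaml::write_yaml(list(
    scenario = "treatment-7d", drug = "chloroquine", strategy = "flat",
    weight_kg = 62, days = 7, n_subjects = 50, omega = 0.3,
    seed = seed, pk_config = basename(paths$pk_config)),
    paths$regimen)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a PK parameter config file
#'
#' Inverse of the bundle's PK YAML layout (units stated in the field
#' names).
#'
#' @param path YAML file as written by [simulate_study_bundle()].
#' @return A [pk_parameters()] set.
#' @export
read_pk_config <- function(path) {
  y <- yaml::read_yaml(path)
  pk_parameters(cl_f = y$cl_f_l_per_h, vc_f = y$vc_f_l,
                q_f = unlist(y$q_f_l_per_h), vp_f = unlist(y$vp_f_l),
                ka = y$ka_per_h, tlag = y$tlag_h, f_rel = y$f_rel,
                renal_fraction = y$renal_fraction,
                blood_plasma_ratio = y$blood_plasma_ratio,
                mw_base = y$mw_base, drug = y$drug)
}
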