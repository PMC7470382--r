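#' Load a self-poisoning cohort table
#'
#' Reads and validates a pooled self-poisoning cohort: one row per overdose
#' patient with the study label, admission whole-blood chloroquine +
#' desethyl-metabolite concentration (uM, as measured by legacy
#' UV-spectrophotometry, which does not separate parent from metabolite)
#' and the vital outcome coded 0 (survived) / 1 (died). Invalid rows are
#' rejected with their row index rather than coerced.
#'
#' @param path CSV path with header `study_id,conc_um,died`, or a data
#'   frame already in memory.
#' @param col_map named character vector mapping the expected names to the
#'   file's actual column names, e.g.
#'   `c(study_id = "study", conc_um = "cq_um", died = "outcome")`.
#' @return A `poisoning_cohort` data frame with attributes `n`, `n_deaths`,
#'   `conc_range` and per-study counts; `summary()` prints them.
#' @export
load_cohort <- function(path, col_map = NULL) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      if (!col_map[[want]] %in% names(df))
        stop("mapped column '", col_map[[want]], "' not found")
      names(df)[names(df) == col_map[[want]]] <- want
    }
  }
  need <- c("study_id", "conc_um", "died")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("empty cohort table")
  conc <- suppressWarnings(as.numeric(df$conc_um))
  bad <- which(is.na(conc) | conc <= 0)
  if (length(bad))
    stop("non-positive or non-numeric concentration at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$died %in% c(0, 1))
  if (length(bad))
    stop("outcome not coded 0/1 at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- data.frame(study_id = as.character(df$study_id), conc_um = conc,
                    died = as.integer(df$died))
  structure(out, class = c("poisoning_cohort", "data.frame"),
            n = nrow(out), n_deaths = sum(out$died),
            conc_range = range(conc),
            per_study = table(out$study_id))
}

#' @export
summary.poisoning_cohort <- function(object, ...) {
  r <- attr(object, "conc_range")
  cat(sprintf("Pooled self-poisoning cohort: n = %d, deaths = %d (%.1f%%)\n",
              attr(object, "n"), attr(object, "n_deaths"),
              100 * attr(object, "n_deaths") / attr(object, "n")))
  cat(sprintf("  admission concentrations %.3g-%.3g uM (CQ + desethyl)\n",
              r[1], r[2]))
  print(attr(object, "per_study"))
  invisible(list(n = attr(object, "n"), n_deaths = attr(object, "n_deaths"),
                 conc_range = r, per_study = attr(object, "per_study")))
}

#' Default concentration bin edges (uM)
#'
#' Half-open, left-closed bins aligned with the 15, 20 and 25 uM thresholds
#' the mortality analysis quotes.
#' @return Numeric vector of edges.
#' @export
default_bin_edges <- function() c(0, 5, 10, 15, 20, 25, 30, 40, 55, 85)

#' Binned concentration-mortality with bootstrap confidence intervals
#'
#' The core of the pooled self-poisoning analysis: patients are grouped in
#' half-open concentration bins `[lower, upper)`, per-bin mortality is the
#' death proportion, and its 95% CI is the percentile nonparametric
#' bootstrap obtained by resampling patients with replacement within each
#' bin. Empty bins are reported with `NA` mortality, not dropped.
#'
#' @param cohort a `poisoning_cohort` (or data frame with `conc_um`,
#'   `died`).
#' @param edges strictly increasing bin edges (uM) covering the data range.
#' @param n_boot bootstrap replicates per bin (>= 1000; default 2000).
#' @param seed integer seed making the CIs reproducible.
#' @param level confidence level (default 0.95).
#' @return A `mortality_bins` data frame: `lower`, `upper`, `n`, `deaths`,
#'   `mortality`, `ci_low`, `ci_high`.
#' @examples
#' coh <- generate_poisoning_cohort(cohort_truth(seed = 42))
#' binned_mortality(coh, seed = 1)
#' @export
binned_mortality <- function(cohort, edges = default_bin_edges(),
                             n_boot = 2000, seed = 1L, level = 0.95) {
  stopifnot(is.unsorted(edges, strictly = TRUE) == FALSE,
            length(edges) >= 2, n_boot >= 1)
  conc <- cohort$conc_um; died <- cohort$died
  if (min(conc) < edges[1] || max(conc) >= edges[length(edges)] + 1e-9)
    stop("edges do not cover the data range")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  set.seed(seed)
  nb <- length(edges) - 1L
  idx <- findInterval(conc, edges, rightmost.closed = TRUE)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    n = 0L, deaths = 0L, mortality = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_)
  for (b in seq_len(nb)) {
    d <- died[idx == b]
    out$n[b] <- length(d)
    if (length(d) == 0) next # empty bin: mortality stays NA by design
    out$deaths[b] <- sum(d)
    out$mortality[b] <- mean(d)
    res <- matrix(sample(d, length(d) * n_boot, replace = TRUE),
                  nrow = n_boot)
    props <- rowMeans(res)
    ci <- stats::quantile(props, probs, names = FALSE)
    out$ci_low[b] <- min(ci[1], out$mortality[b])
    out$ci_high[b] <- max(ci[2], out$mortality[b])
  }
  structure(out, class = c("mortality_bins", "data.frame"),
            n_boot = n_boot, seed = seed, level = level)
}

#' @export
print.mortality_bins <- function(x, ...) {
  cat(sprintf("Binned mortality (%d bins, %d bootstrap replicates, %g%% CI)\n",
              nrow(x), attr(x, "n_boot"), 100 * attr(x, "level")))
  print.data.frame(cbind(x[1:4], round(x[5:7], 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.mortality_bins <- function(x, ...) {
  mid <- (x$lower + x$upper) / 2
  graphics::plot(mid, 100 * x$mortality, pch = 16, ylim = c(0, 100),
                 xlab = expression("Admission concentration (" * mu * "M)"),
                 ylab = "Mortality (%)", ...)
  graphics::segments(mid, 100 * x$ci_low, mid, 100 * x$ci_high)
  invisible(x)
}

#' Mortality above a concentration cutoff
#'
#' Deaths, patients and death proportion among records with admission
#' concentration strictly above `cutoff` (e.g. greater than 5% mortality
#' above 20 uM).
#'
#' @param cohort a `poisoning_cohort`.
#' @param cutoff uM.
#' @return List with `deaths`, `n`, `proportion`.
#' @export
mortality_above <- function(cohort, cutoff) {
  sel <- cohort$conc_um > cutoff
  if (!any(sel)) stop("no records above cutoff; proportion undefined")
  list(deaths = sum(cohort$died[sel]), n = sum(sel),
       proportion = mean(cohort$died[sel]))
}

#' Largest grid threshold with no deaths below it
#'
#' Returns the largest grid value `t` such that no patient with admission
#' concentration below `t` died; if even the smallest grid value has deaths
#' below it, that smallest value is returned with attribute
#' `qualifies = FALSE`. On the pooled data, no deaths occurred below 15 uM.
#'
#' @param cohort a `poisoning_cohort`.
#' @param grid increasing concentration grid (uM).
#' @return Grid value (uM) with logical attribute `qualifies`.
#' @export
zero_death_threshold <- function(cohort, grid = c(5, 10, 15, 20, 25)) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  ok <- vapply(grid, function(t) !any(cohort$died[cohort$conc_um < t] == 1),
               logical(1))
  if (!any(ok))
    return(structure(grid[1], qualifies = FALSE))
  structure(max(grid[ok]), qualifies = TRUE)
}

#' Correct a total (parent + metabolite) concentration to parent equivalent
#'
#' Legacy UV-spectrophotometric assays co-measure desethylchloroquine;
#' assuming about 30% of the measured concentration is metabolite, the
#' parent-equivalent concentration is `total * (1 - metabolite_fraction)`.
#' This is how the 15 uM no-death bound maps to the approximately 10 uM
#' whole-blood parent safety bound.
#'
#' @param conc_total measured total concentration (uM, vectorised).
#' @param metabolite_fraction fraction attributable to metabolite, in
#'   \[0, 1).
#' @return Parent-equivalent concentration (uM).
#' @examples
#' parent_fraction_correction(15) # 10.5
#' @export
parent_fraction_correction <- function(conc_total, metabolite_fraction = 0.30) {
  if (metabolite_fraction < 0 || metabolite_fraction >= 1)
    stop("metabolite_fraction must be in [0, 1)")
  conc_total * (1 - metabolite_fraction)
}

#' Two-group mortality contingency summary
#'
#' Per-group mortality percentages, risk ratio and odds ratio of group b
#' versus group a; with a zero cell, both the unadjusted and the
#' Haldane-Anscombe-corrected (add 0.5 to every cell) odds ratios are
#' reported. The historical Paris series contrasts 1/106 deaths below a
#' 25 uM peak with 13/61 (21%) above it.
#'
#' @param deaths_a,n_a,deaths_b,n_b integer counts, `deaths <= n`, `n > 0`.
#' @param digits rounding of the reported percentages; the default `NULL`
#'   follows the usual quoting convention (integers, except one decimal
#'   below 1%, so 1/106 reads 0.9% and 13/61 reads 21%).
#' @return List: `pct_a`, `pct_b` (rounded %), `risk_ratio`, `odds_ratio`,
#'   `odds_ratio_haldane`.
#' @examples
#' contingency_mortality(1, 106, 13, 61)$pct_b # 21
#' @export
contingency_mortality <- function(deaths_a, n_a, deaths_b, n_b,
                                  digits = NULL) {
  stopifnot(deaths_a >= 0, deaths_b >= 0, n_a > 0, n_b > 0,
            deaths_a <= n_a, deaths_b <= n_b)
  pa <- deaths_a / n_a; pb <- deaths_b / n_b
  rnd <- function(pct) {
    d <- if (!is.null(digits)) digits else if (pct < 1) 1 else 0
    round(pct, d)
  }
  or <- (deaths_b / (n_b - deaths_b)) / (deaths_a / (n_a - deaths_a))
  orh <- ((deaths_b + 0.5) / (n_b - deaths_b + 0.5)) /
         ((deaths_a + 0.5) / (n_a - deaths_a + 0.5))
  list(pct_a = rnd(100 * pa), pct_b = rnd(100 * pb),
       risk_ratio = pb / pa, odds_ratio = or, odds_ratio_haldane = orh)
}
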