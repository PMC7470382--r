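synth_cohort <- function(seed = 5) generate_poisoning_cohort(cohort_truth(seed = seed))

test_that("cohort loader validates structure and reports row indices", {
  coh <- synth_cohort()
  expect_s3_class(coh, "poisoning_cohort")
  expect_equal(attr(coh, "n"), 258)
  df <- as.data.frame(coh)
  expect_error(load_cohort(df[0, ]), "empty")
  expect_error(load_cohort(df[c("study_id", "died")]), "conc_um")
  bad <- df; bad$conc_um[3] <- -1
  expect_error(load_cohort(bad), "row.*3")
  bad <- df; bad$died[7] <- 2
  expect_error(load_cohort(bad), "row.*7")
  # column mapping accommodates alternative headers
  alt <- df; names(alt) <- c("study", "cq_um", "outcome")
  remap <- load_cohort(alt, col_map = c(study_id = "study",
                                        conc_um = "cq_um",
                                        died = "outcome"))
  expect_equal(remap$conc_um, coh$conc_um)
})

test_that("binned mortality conserves patients and is order/seed invariant", {
  coh <- synth_cohort()
  bins <- binned_mortality(coh, seed = 1)
  expect_equal(sum(bins$n), attr(coh, "n"))
  expect_equal(sum(bins$deaths), attr(coh, "n_deaths"))
  nonempty <- !is.na(bins$mortality)
  expect_true(all(bins$ci_low[nonempty] <= bins$mortality[nonempty] &
                    bins$mortality[nonempty] <= bins$ci_high[nonempty]))
  # point estimates invariant to record order and bootstrap seed
  shuf <- coh[sample(nrow(coh)), ]
  bins2 <- binned_mortality(shuf, seed = 99)
  expect_equal(bins2$mortality, bins$mortality)
  expect_equal(bins2$n, bins$n)
  # CI reproducible given the seed
  expect_equal(binned_mortality(coh, seed = 1), bins)
  # an all-survivor bin has CI [0, 0]
  surv <- which(bins$deaths == 0 & bins$n > 0)
  expect_true(all(bins$ci_low[surv] == 0 & bins$ci_high[surv] == 0))
  expect_error(binned_mortality(coh, edges = c(0, 10)), "cover")
})

test_that("bootstrap CI stabilises as replicates grow", {
  coh <- synth_cohort()
  b2k <- binned_mortality(coh, n_boot = 2000, seed = 1)
  b20k <- binned_mortality(coh, n_boot = 20000, seed = 1)
  ok <- !is.na(b2k$mortality)
  expect_lt(max(abs(b2k$ci_low[ok] - b20k$ci_low[ok])), 0.01)
  expect_lt(max(abs(b2k$ci_high[ok] - b20k$ci_high[ok])), 0.01)
})

test_that("bootstrap CI matches exhaustive enumeration on a 4-patient bin", {
  # 2 deaths among 4 patients: all 4^4 equally likely resamples
  d <- c(1, 1, 0, 0)
  grids <- expand.grid(rep(list(1:4), 4))
  props <- apply(grids, 1, function(i) mean(d[i]))
  exact <- quantile(props, c(0.025, 0.975), names = FALSE)
  coh <- load_cohort(data.frame(study_id = "x", conc_um = c(21, 22, 23, 24),
                                died = d))
  bins <- binned_mortality(coh, edges = c(20, 25), n_boot = 50000, seed = 2)
  expect_equal(bins$mortality, 0.5)
  expect_lt(abs(bins$ci_low - exact[1]), 0.01)
  expect_lt(abs(bins$ci_high - exact[2]), 0.01)
})

test_that("threshold statistics agree with brute-force filters", {
  coh <- synth_cohort()
  m <- mortality_above(coh, 20)
  sel <- coh$conc_um > 20
  expect_equal(m$n, sum(sel))
  expect_equal(m$deaths, sum(coh$died[sel]))
  expect_equal(m$proportion, mean(coh$died[sel]))
  expect_equal(mortality_above(coh, 0)$proportion, mean(coh$died))
  expect_error(mortality_above(coh, 100), "above cutoff")

  grid <- c(5, 10, 15, 20, 25)
  zdt <- zero_death_threshold(coh, grid)
  brute <- max(c(-Inf, grid[vapply(grid, function(t)
    sum(coh$died[coh$conc_um < t]) == 0, logical(1))]))
  expect_equal(as.numeric(zdt), brute)
  # zero-death cohort: max of grid; deaths-everywhere cohort: flagged floor
  none <- load_cohort(data.frame(study_id = "x", conc_um = c(2, 30),
                                 died = c(0, 0)))
  expect_equal(as.numeric(zero_death_threshold(none, grid)), 25)
  all_die <- load_cohort(data.frame(study_id = "x", conc_um = c(2, 30),
                                    died = c(1, 1)))
  z <- zero_death_threshold(all_die, grid)
  expect_equal(as.numeric(z), 5)
  expect_false(attr(z, "qualifies"))
})

test_that("metabolite correction maps the 15 uM bound near 10 uM parent", {
  expect_equal(parent_fraction_correction(15), 10.5)
  expect_equal(parent_fraction_correction(81), 56.7)
  expect_equal(parent_fraction_correction(c(15, 81), 0), c(15, 81))
  expect_error(parent_fraction_correction(15, 1), "\\[0, 1\\)")
})

test_that("contingency summary reproduces quoted percentages and odds", {
  ct <- contingency_mortality(1, 106, 13, 61)
  expect_equal(ct$pct_a, 0.9)
  expect_equal(ct$pct_b, 21)
  expect_equal(ct$risk_ratio, (13 / 61) / (1 / 106))
  expect_equal(ct$odds_ratio, (13 * 105) / (48 * 1)) # cross-product
  eq <- contingency_mortality(5, 50, 5, 50)
  expect_equal(eq$risk_ratio, 1)
  zero <- contingency_mortality(0, 10, 3, 10)
  expect_true(is.infinite(zero$odds_ratio))
  expect_equal(zero$odds_ratio_haldane, (3.5 / 7.5) / (0.5 / 10.5))
})

test_that("monotone mortality laws yield (noise-tolerant) monotone bin estimates", {
  truth <- cohort_truth(n = 50000, seed = 31)
  coh <- generate_poisoning_cohort(truth)
  bins <- binned_mortality(coh, n_boot = 1000, seed = 1)
  ok <- !is.na(bins$mortality) & bins$n >= 30
  m <- bins$mortality[ok]
  # allow 3 binomial SDs of slack per adjacent pair
  sds <- sqrt(pmax(m * (1 - m), 1e-6) / bins$n[ok])
  expect_true(all(diff(m) > -3 * (utils::head(sds, -1) + utils::tail(sds, -1))))
})
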