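test_that("replicate aggregation computes unbiased variance per level", {
  recs <- tibble::tibble(s_mM = c(0.1, 0.1, 0.1, 0.05, 0.05, 0.05),
                         rate_U_per_mg = c(0.4, 0.5, 0.6, 0.3, 0.3, 0.3))
  agg <- aggregate_replicates(recs)
  expect_equal(agg$s_mM, c(0.05, 0.1))  # sorted by substrate
  expect_equal(agg$mean_rate, c(0.3, 0.5))
  expect_equal(agg$rate_variance, c(0, 0.01))
  expect_equal(agg$n_replicates, c(3L, 3L))
  expect_error(
    aggregate_replicates(tibble::tibble(s_mM = 0.1, rate_U_per_mg = NaN)),
    class = "ppasekin_validation_error")
})

test_that("zero-variance levels fall back to the smallest positive variance with a warning", {
  s <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  d <- tibble::tibble(s_mM = s, mean_rate = mm_rate(s, 1, 0.2),
                      rate_variance = c(0, 1e-4, 2e-4, 1e-4, 3e-4),
                      n_replicates = 3L)
  expect_warning(fit <- fit_model(d, "mm"),
                 class = "ppasekin_zero_variance_warning")
  expect_true(fit$converged)
})

test_that("single-replicate levels are never silently weighted", {
  s <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  d <- tibble::tibble(s_mM = s, mean_rate = mm_rate(s, 1, 0.2),
                      rate_variance = c(NA, 1e-4, 2e-4, 1e-4, 3e-4),
                      n_replicates = c(1L, 3L, 3L, 3L, 3L))
  expect_error(fit_model(d, "mm"), class = "ppasekin_validation_error")
  expect_silent(fit_model(d, "mm", weights = "unit"))
})

test_that("substrate-inhibition truncation keeps the expected points and is recorded", {
  d <- tibble::tibble(s_mM = c(0.05, 0.1, 0.2, 0.25, 0.5),
                      mean_rate = c(0.2, 0.35, 0.45, 0.4, 0.3),
                      rate_variance = 1e-4, n_replicates = 3L)
  kept <- truncate_for_substrate_inhibition(d, 0.2)
  expect_equal(nrow(kept), 3L)
  expect_equal(attr(kept, "truncation_max_s"), 0.2)
  expect_equal(truncate_for_substrate_inhibition(d, 1)$s_mM, d$s_mM)
  expect_error(truncate_for_substrate_inhibition(d, 0.01),
               class = "ppasekin_underdetermined_error")
  # via fit_model a three-parameter law needs four points after truncation
  expect_error(fit_model(d, "hill", weights = "unit", truncate_max_s = 0.2),
               class = "ppasekin_underdetermined_error")
})

test_that("noiseless data are recovered exactly for all three laws", {
  set.seed(301)
  for (i in 1:20) {
    truth_h <- random_hill_params()
    fit_h <- fit_model(noiseless_dataset(truth_h), "hill", weights = "unit")
    expect_lt(rel_err(coef(fit_h)[["vm"]], truth_h$vm), 1e-6)
    expect_lt(rel_err(coef(fit_h)[["k_half_mM"]], truth_h$k_half), 1e-6)
    expect_lt(rel_err(coef(fit_h)[["n_h"]], truth_h$n_h), 1e-6)
    expect_lt(fit_h$wrss, 1e-12)

    truth_m <- random_mwc_params()
    fit_m <- fit_model(noiseless_dataset(truth_m), "mwc", weights = "unit")
    expect_lt(rel_err(coef(fit_m)[["vm"]], truth_m$vm), 1e-6)
    expect_lt(rel_err(coef(fit_m)[["l"]], truth_m$l), 1e-4)
    expect_lt(rel_err(coef(fit_m)[["k_r_uM"]], truth_m$k_r), 1e-6)
  }
  truth_mm <- list(vm = 0.8, km = 0.15)
  d <- tibble::tibble(s_mM = c(0.025, 0.05, 0.1, 0.2, 0.4, 0.8),
                      mean_rate = mm_rate(c(0.025, 0.05, 0.1, 0.2, 0.4, 0.8),
                                          0.8, 0.15),
                      rate_variance = NA_real_, n_replicates = 1L)
  fit_mm <- fit_model(d, "mm", weights = "unit")
  expect_lt(rel_err(coef(fit_mm)[["vm"]], 0.8), 1e-6)
  expect_lt(rel_err(coef(fit_mm)[["km_mM"]], 0.15), 1e-6)
})

test_that("published-scale allosteric parameters are recovered from noiseless data", {
  s_uM <- seq(10, 500, length.out = 10)
  truth <- mwc_params(vm = 0.51, l = 17, k_r = 84)
  d <- tibble::tibble(s_mM = s_uM / 1000, mean_rate = mwc_rate(s_uM / 1000, truth),
                      rate_variance = NA_real_, n_replicates = 1L)
  fit <- fit_model(d, "mwc", weights = "unit")
  expect_lt(rel_err(coef(fit)[["vm"]], 0.51), 1e-4)
  expect_lt(rel_err(coef(fit)[["l"]], 17), 1e-4)
  expect_lt(rel_err(coef(fit)[["k_r_uM"]], 84), 1e-4)
})

test_that("fitted weighted SSE never exceeds the brute-force grid optimum", {
  set.seed(55)
  for (i in 1:4) {
    truth <- random_hill_params()
    s <- c(0.025, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8)
    v <- hill_rate(s, truth) * (1 + rnorm(length(s), 0, 0.08))
    d <- tibble::tibble(s_mM = s, mean_rate = pmax(v, 0),
                        rate_variance = (0.08 * pmax(hill_rate(s, truth), 0.05))^2,
                        n_replicates = 4L)
    w <- 1 / d$rate_variance
    fit <- fit_model(d, "hill")
    expect_lte(fit$wrss, oracle_grid_sse(d, "hill", w) + 1e-9)
    fitm <- fit_model(d, "mwc")
    expect_lte(fitm$wrss, oracle_grid_sse(d, "mwc", w) + 1e-9)
  }
})

test_that("point estimates are invariant to rescaling all variances", {
  set.seed(77)
  s <- c(0.025, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8)
  v <- hill_rate(s, hill_params(1, 0.1, 2)) * (1 + rnorm(8, 0, 0.05))
  base <- tibble::tibble(s_mM = s, mean_rate = pmax(v, 0),
                         rate_variance = runif(8, 1e-5, 1e-3),
                         n_replicates = 4L)
  scaled <- dplyr::mutate(base, rate_variance = rate_variance * 37.5)
  f1 <- fit_model(base, "hill")
  f2 <- fit_model(scaled, "hill")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  # SEs follow cov = s^2 (J'WJ)^-1 with s^2 = WRSS/(N-p), so they are
  # invariant too: the variance scale cancels
  expect_equal(f1$std_errors, f2$std_errors, tolerance = 1e-6)
})

test_that("tidy and glance expose estimates, errors and fit diagnostics", {
  s <- c(0.025, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8)
  d <- tibble::tibble(s_mM = s, mean_rate = hill_rate(s, hill_params(1, 0.1, 2)),
                      rate_variance = 1e-5, n_replicates = 4L)
  fit <- fit_model(d, "hill")
  td <- tidy(fit)
  expect_equal(td$term, c("vm", "k_half_mM", "n_h"))
  expect_true(all(td$std.error >= 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$points_used, 8L)
  expect_true(gl$converged)
  expect_equal(gl$df.residual, 5L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("underdetermined fits and impossible weights raise typed errors", {
  d <- tibble::tibble(s_mM = c(0.1, 0.2, 0.3), mean_rate = c(0.2, 0.3, 0.35),
                      rate_variance = 1e-4, n_replicates = 3L)
  expect_error(fit_model(d, "hill"), class = "ppasekin_underdetermined_error")
  d4 <- tibble::tibble(s_mM = c(0.1, 0.2, 0.3, 0.4),
                       mean_rate = c(0.2, 0.3, 0.35, 0.38),
                       rate_variance = 0, n_replicates = 3L)
  expect_error(suppressWarnings(fit_model(d4, "hill")),
               class = "ppasekin_validation_error")
})
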