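#' Aggregate replicate assay rates into weighted mean points
#'
#' Collapses replicate rate measurements to one point per substrate level:
#' the mean rate, the unbiased sample variance of the replicates (n - 1
#' denominator) and the replicate count. Points are sorted by substrate
#' concentration within each group. The variance feeds the 1/variance
#' weights used by [fit_model()].
#'
#' @param records a data frame of replicate records with a substrate column
#'   and a rate column.
#' @param s_col name of the substrate-concentration column (mM).
#' @param rate_col name of the rate column (U/mg).
#' @param by optional character vector of grouping columns (e.g. enzyme and
#'   salt level) carried through to the output.
#' @return A tibble with columns `by...`, `s_mM`, `mean_rate`,
#'   `rate_variance` (`NA` for single-replicate levels), `n_replicates`.
#' @export
#' @examples
#' recs <- tibble::tibble(s_mM = rep(c(0.05, 0.1), each = 3),
#'                        rate = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9))
#' aggregate_replicates(recs, rate_col = "rate")
aggregate_replicates <- function(records, s_col = "s_mM",
                                 rate_col = "rate_U_per_mg",
                                 by = character()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty data frame.")
  }
  for (col in c(s_col, rate_col, by)) {
    if (!col %in% names(records)) {
      abort_validation(sprintf("`records` has no column `%s`.", col))
    }
  }
  rates <- records[[rate_col]]
  if (!is.numeric(rates) || anyNA(rates) || any(!is.finite(rates))) {
    abort_validation("All replicate rates must be finite numbers.")
  }
  check_number(records[[s_col]], s_col, lower = 0)

  records %>%
    dplyr::rename(s_mM = all_of(s_col)) %>%
    group_by(across(all_of(c(by, "s_mM")))) %>%
    summarise(
      mean_rate = mean(.data[[rate_col]]),
      rate_variance = if (dplyr::n() > 1) stats::var(.data[[rate_col]]) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(across(all_of(c(by, "s_mM"))))
}

#' Drop substrate-inhibited points before fitting
#'
#' Saturation laws cannot describe inhibition by excess substrate, so
#' points above a chosen concentration are excluded before fitting and the
#' threshold is recorded on the result (and in the downstream fit).
#'
#' @param dataset an aggregated dataset from [aggregate_replicates()].
#' @param max_s retain only points with `s_mM <= max_s` (mM).
#' @param min_points minimum points that must remain (default 2;
#'   [fit_model()] tightens this to one more than the model's parameter
#'   count when it applies the truncation itself).
#' @return The filtered dataset with attribute `truncation_max_s`.
#' @export
truncate_for_substrate_inhibition <- function(dataset, max_s, min_points = 2L) {
  check_scalar(max_s, "max_s", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(dataset) || !"s_mM" %in% names(dataset)) {
    abort_validation("`dataset` must contain an `s_mM` column.")
  }
  out <- dplyr::filter(dataset, .data$s_mM <= max_s)
  if (nrow(out) < min_points) {
    abort(sprintf(paste0("Truncation at %g mM leaves %d point(s); at least %d ",
                         "are needed for an identifiable fit."),
                  max_s, nrow(out), min_points),
          class = "ppasekin_underdetermined_error")
  }
  attr(out, "truncation_max_s") <- max_s
  out
}

# model plumbing: parameter order, evaluation, starts and bounds
model_info <- function(model, dataset) {
  vmax <- max(dataset$mean_rate)
  smax <- max(dataset$s_mM)
  # data-driven centres: vm0 = max mean rate, k0 = s at half-max
  above <- dataset$s_mM[dataset$mean_rate >= vmax / 2]
  k0 <- if (length(above) > 0) min(above) else smax / 2
  k0 <- max(k0, 1e-6)
  switch(model,
    hill = list(
      par_names = c("vm", "k_half_mM", "n_h"),
      fn = function(s, par) {
        sn <- s^par[3]
        par[1] * sn / (par[2]^par[3] + sn)
      },
      starts = lapply(c(1, 2, 3, 5), function(nh) c(vmax, k0, nh)),
      lower = c(1e-12, 1e-12, 0.5),
      upper = c(10 * vmax, 10 * smax, 8)
    ),
    mwc = list(
      par_names = c("vm", "l", "k_r_mM"),
      fn = function(s, par) {
        u <- 1 + s / par[3]
        par[1] * (u^4 - u^3) / (u^4 + par[2])
      },
      starts = lapply(c(0, 10, 1e3, 1e5), function(l) c(vmax, l, k0)),
      lower = c(1e-12, 0, 1e-12),
      upper = c(10 * vmax, 1e7, 10 * smax)
    ),
    mm = list(
      par_names = c("vm", "km_mM"),
      fn = function(s, par) par[1] * s / (par[2] + s),
      starts = list(c(vmax, k0)),
      lower = c(1e-12, 1e-12),
      upper = c(10 * vmax, 10 * smax)
    ),
    abort_validation(sprintf("Unknown model `%s`.", model))
  )
}

resolve_weights <- function(dataset, weights) {
  v <- dataset$rate_variance
  n <- dataset$n_replicates
  if (weights == "unit") return(rep(1, nrow(dataset)))
  if (anyNA(v)) {
    abort(paste0("Single-replicate levels have no variance; aggregate with ",
                 "more replicates, use `weights = \"unit\"`, or pool first."),
          class = "ppasekin_validation_error")
  }
  if (any(v == 0)) {
    vmin <- min(v[v > 0])
    if (!is.finite(vmin)) {
      abort("All replicate variances are zero; 1/variance weights are undefined.",
            class = "ppasekin_validation_error")
    }
    warn(sprintf(paste0("%d level(s) with zero replicate variance; substituting ",
                        "the smallest positive variance (%g) for weighting."),
                 sum(v == 0), vmin), class = "ppasekin_zero_variance_warning")
    v[v == 0] <- vmin
  }
  switch(weights,
    "replicate-variance" = 1 / v,
    "sem" = n / v,  # 1 / (variance of the mean)
    abort_validation(sprintf("Unknown weights mode `%s`.", weights))
  )
}

#' Fit a rate law to aggregated assay data by weighted least squares
#'
#' Minimises the weighted residual sum of squares
#' \deqn{\sum_i w_i (\bar v_i - f(s_i; \theta))^2}
#' over the model parameters, with `w_i = 1/variance_i` by default (the
#' replicate sample variance; `weights = "sem"` uses the variance of the
#' mean instead, `"unit"` ignores precision). Optimisation uses bounded
#' Levenberg-Marquardt least squares restarted from a small data-driven
#' grid of initial values (`n_h` in 1/2/3/5 for the Hill law, `l` in
#' 0/10/1e3/1e5 for the allosteric law); the best converged start wins,
#' ties going to the earlier start. Standard errors follow the usual
#' nonlinear-regression convention `cov = s^2 (J^T W J)^{-1}` with
#' `s^2 = WRSS / (N - p)` and a finite-difference Jacobian at the optimum.
#'
#' @param dataset an aggregated dataset from [aggregate_replicates()] with
#'   columns `s_mM`, `mean_rate`, `rate_variance`, `n_replicates`.
#' @param model `"hill"`, `"mwc"` or `"mm"`.
#' @param weights `"replicate-variance"` (default), `"sem"`, or `"unit"`.
#' @param truncate_max_s optional threshold (mM) passed to
#'   [truncate_for_substrate_inhibition()] before fitting.
#' @param control list overriding optimiser settings `maxiter` (500) and
#'   `ftol` (1e-10).
#' @return An object of class `kin_fit`: point estimates (with `k_r`
#'   reported in uM for the allosteric law), standard errors, the weighted
#'   residual sum of squares, convergence flag, points used, and the
#'   truncation applied. Supports [coef()], [predict()], [tidy()],
#'   [glance()], [autoplot()] and [print()].
#' @export
#' @examples
#' s <- c(0.025, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8)
#' d <- tibble::tibble(s_mM = s,
#'                     mean_rate = hill_rate(s, hill_params(1, 0.1, 2)),
#'                     rate_variance = 1e-4, n_replicates = 4)
#' fit <- fit_model(d, "hill")
#' tidy(fit)
fit_model <- function(dataset, model = c("hill", "mwc", "mm"),
                      weights = c("replicate-variance", "sem", "unit"),
                      truncate_max_s = NULL, control = list()) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  ctrl <- modifyList(list(maxiter = 500L, ftol = 1e-10), control)

  if (!is.data.frame(dataset) ||
      !all(c("s_mM", "mean_rate") %in% names(dataset))) {
    abort_validation("`dataset` needs columns `s_mM` and `mean_rate` (see aggregate_replicates()).")
  }
  if (!"rate_variance" %in% names(dataset)) dataset$rate_variance <- NA_real_
  if (!"n_replicates" %in% names(dataset)) dataset$n_replicates <- 1L

  info0 <- model_info(model, dataset)
  p <- length(info0$par_names)
  if (!is.null(truncate_max_s)) {
    dataset <- truncate_for_substrate_inhibition(dataset, truncate_max_s,
                                                 min_points = p + 1L)
  }
  if (nrow(dataset) < p + 1L) {
    abort(sprintf("Fit of `%s` needs at least %d points; got %d.",
                  model, p + 1L, nrow(dataset)),
          class = "ppasekin_underdetermined_error")
  }
  w <- resolve_weights(dataset, weights)
  if (all(w == 0) || any(!is.finite(w))) {
    abort_validation("Weights are all zero or not finite.")
  }

  info <- model_info(model, dataset)
  s <- dataset$s_mM
  y <- dataset$mean_rate
  sw <- sqrt(w)
  resid_fn <- function(par) sw * (y - info$fn(s, par))

  best <- NULL
  for (start in info$starts) {
    start <- pmin(pmax(start, info$lower), info$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = info$lower, upper = info$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = min(ctrl$maxiter, 1024L),
                           ftol = ctrl$ftol, ptol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res) || !(res$info %in% 1:4)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    abort(sprintf("No start of the `%s` fit converged.", model),
          class = "ppasekin_convergence_error")
  }

  est <- setNames(as.numeric(best$par), info$par_names)
  wrss <- best$deviance
  nobs <- length(y)
  se <- fit_standard_errors(info$fn, est, s, w, wrss, nobs)

  # report k_r on the uM scale customary for R-state constants
  if (model == "mwc") {
    est["k_r_mM"] <- est["k_r_mM"] * 1000
    se["k_r_mM"] <- se["k_r_mM"] * 1000
    names(est)[names(est) == "k_r_mM"] <- "k_r_uM"
    names(se)[names(se) == "k_r_mM"] <- "k_r_uM"
  }

  structure(list(
    model = model,
    estimates = est,
    std_errors = se,
    wrss = wrss,
    sigma2 = if (nobs > length(est)) wrss / (nobs - length(est)) else NA_real_,
    converged = TRUE,
    points_used = nobs,
    truncation_max_s = attr(dataset, "truncation_max_s") %||% NA_real_,
    weights_mode = weights,
    data = as_tibble(dataset[c("s_mM", "mean_rate", "rate_variance", "n_replicates")]),
    weights = w
  ), class = "kin_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_standard_errors <- function(fn, par, s, w, wrss, nobs) {
  p <- length(par)
  if (nobs <= p) return(setNames(rep(NA_real_, p), names(par)))
  jac <- matrix(0, nobs, p)
  for (j in seq_len(p)) {
    h <- max(1e-7 * abs(par[j]), 1e-10)
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- par[j] - h
    jac[, j] <- (fn(s, up) - fn(s, dn)) / (2 * h)
  }
  a <- crossprod(jac, w * jac)  # J^T W J
  s2 <- wrss / (nobs - p)
  se <- tryCatch(sqrt(pmax(diag(s2 * solve(a)), 0)),
                 error = function(e) rep(NA_real_, p))
  setNames(se, names(par))
}

#' @export
coef.kin_fit <- function(object, ...) object$estimates

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("Weighted %s fit (%d points%s)\n", x$model, x$points_used,
              if (is.na(x$truncation_max_s)) ""
              else sprintf(", truncated at %g mM", x$truncation_max_s)))
  est <- x$estimates
  se <- x$std_errors
  for (nm in names(est)) {
    cat(sprintf("  %-10s %s\n", nm, format_pm(est[[nm]], se[[nm]])))
  }
  cat(sprintf("  weighted RSS: %.4g\n", x$wrss))
  invisible(x)
}

#' @export
predict.kin_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$s_mM else newdata$s_mM
  par <- object$estimates
  switch(object$model,
    hill = hill_rate(s, hill_params(par[["vm"]], par[["k_half_mM"]], par[["n_h"]])),
    mwc = mwc_rate(s, mwc_params(par[["vm"]], par[["l"]], par[["k_r_uM"]])),
    mm = mm_rate(s, par[["vm"]], par[["km_mM"]])
  )
}

#' Tidy a fitted rate law
#'
#' @param x a `kin_fit` object.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per parameter (`term`,
#'   `estimate`, `std.error`); `glance()`: a one-row fit summary.
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = as.numeric(x$estimates),
         std.error = as.numeric(x$std_errors))
}

#' @rdname tidy.kin_fit
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble(model = x$model, wrss = x$wrss,
         sigma = sqrt(x$sigma2),
         df.residual = x$points_used - length(x$estimates),
         points_used = x$points_used,
         truncation_max_s = x$truncation_max_s,
         converged = x$converged)
}

# "0.47 ± 0.01": SE to 2 significant figures, estimate to the same decimals
format_pm <- function(est, se) {
  if (is.na(se) || se <= 0) return(sprintf("%.4g", est))
  digits <- max(0, 1 - floor(log10(signif(se, 2))))
  sprintf("%.*f ± %.*f", digits, est, digits, signif(se, 2))
}
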