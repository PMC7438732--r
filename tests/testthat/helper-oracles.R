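# Independent oracles used by the tests. These re-derive expected values by
# brute force (nested bisection, dense grids) without touching the package's
# solver or optimiser internals.

# Nested-bisection speciation oracle over (free PPi, free Mg). Species are
# computed straight from the mass-action relations [M][L]/[ML] = Kd.
oracle_speciate <- function(total_ppi, total_mg, total_k, total_na, ph,
                            constants, tol = 1e-12, iters = 70) {
  kd <- stats::setNames(constants$kd_mM, constants$species)
  get_kd <- function(sp) if (sp %in% names(kd)) kd[[sp]] else Inf
  h <- 10^(3 - ph)

  species_of <- function(p, m) {
    hppi <- h * p / get_kd("HPPi")
    list(
      hppi = hppi,
      h2ppi = h * hppi / get_kd("H2PPi"),
      mgppi = m * p / get_kd("MgPPi"),
      mg2ppi = m * (m * p / get_kd("MgPPi")) / get_kd("Mg2PPi"),
      kppi = total_k * p / get_kd("KPPi"),
      nappi = total_na * p / get_kd("NaPPi"),
      mghppi = m * hppi / get_kd("MgHPPi")
    )
  }
  ppi_total_of <- function(p, m) {
    sp <- species_of(p, m)
    p + sp$hppi + sp$h2ppi + sp$mgppi + sp$mg2ppi + sp$kppi + sp$nappi + sp$mghppi
  }
  mg_total_of <- function(p, m) {
    sp <- species_of(p, m)
    m + sp$mgppi + 2 * sp$mg2ppi + sp$mghppi
  }
  p_given_m <- function(m) {
    lo <- 0; hi <- total_ppi
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (ppi_total_of(mid, m) > total_ppi) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- 0; hi <- total_mg
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mg_total_of(p_given_m(mid), mid) > total_mg) hi <- mid else lo <- mid
  }
  m <- (lo + hi) / 2
  p <- p_given_m(m)
  c(free_ppi = p, free_mg = m,
    s_mg2ppi = species_of(p, m)$mg2ppi)
}

# Dense-grid quantile oracle for the effective Hill coefficient: locate the
# 10% and 90% saturation points by interpolation on a fine logarithmic grid.
oracle_effective_hill <- function(k_r_mM, l, n_grid = 200000) {
  s <- exp(seq(log(k_r_mM * 1e-5), log(k_r_mM * 1e7), length.out = n_grid))
  u <- 1 + s / k_r_mM
  y <- (u^4 - u^3) / (u^4 + l)
  s_at <- function(target) {
    i <- which(y >= target)[1]
    # linear interpolation between bracketing grid points
    s[i - 1] + (target - y[i - 1]) * (s[i] - s[i - 1]) / (y[i] - y[i - 1])
  }
  log(81) / log(s_at(0.9) / s_at(0.1))
}

# Exhaustive grid search over the fit bounds: the minimum weighted SSE over
# a 20^3 lattice, used to bound the optimiser's achieved cost from above.
oracle_grid_sse <- function(dataset, model, w) {
  s <- dataset$s_mM
  y <- dataset$mean_rate
  vmax <- max(y); smax <- max(s)
  axis <- function(lo, hi, log_scale = FALSE, n = 20) {
    if (log_scale) exp(seq(log(lo), log(hi), length.out = n))
    else seq(lo, hi, length.out = n)
  }
  if (model == "hill") {
    grids <- expand.grid(a = axis(vmax / 10, 10 * vmax),
                         b = axis(smax / 100, 10 * smax, log_scale = TRUE),
                         c = axis(0.5, 8))
  } else if (model == "mwc") {
    grids <- expand.grid(a = axis(vmax / 10, 10 * vmax),
                         b = c(0, axis(1, 1e7, log_scale = TRUE, n = 19)),
                         c = axis(smax / 100, 10 * smax, log_scale = TRUE))
  } else stop("unsupported model in oracle")
  best <- Inf
  for (i in seq_len(nrow(grids))) {
    g <- grids[i, ]
    pred <- if (model == "hill") {
      g$a * s^g$c / (g$b^g$c + s^g$c)
    } else {
      u <- 1 + s / g$c
      g$a * (u^4 - u^3) / (u^4 + g$b)
    }
    sse <- sum(w * (y - pred)^2)
    if (sse < best) best <- sse
  }
  best
}

# Random generating parameters within the fitter's bounds
random_hill_params <- function() {
  hill_params(vm = runif(1, 0.2, 2), k_half = runif(1, 0.05, 0.4),
              n_h = runif(1, 1, 5))
}
random_mwc_params <- function() {
  mwc_params(vm = runif(1, 0.2, 2), l = 10^runif(1, 0, 3),
             k_r = runif(1, 30, 200))
}

noiseless_dataset <- function(truth, s = c(0.025, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8)) {
  rate <- if (inherits(truth, "hill_params")) hill_rate(s, truth) else mwc_rate(s, truth)
  tibble::tibble(s_mM = s, mean_rate = rate, rate_variance = NA_real_,
                 n_replicates = 1L)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
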