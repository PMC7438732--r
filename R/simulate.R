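#' Build an assay design
#'
#' Expands a substrate-titration design into fully specified ionic
#' conditions, one row per (added NaCl level, total PPi) point. Two modes
#' mirror the two experimental layouts used for membrane-bound
#' pyrophosphatases:
#'
#' * `matched_mg`: total MgCl2 tracks total PPi as `mg = 2 * ppi`, so that
#'   the substrate species Mg2PPi dominates the titration.
#' * `fixed_mg`: MgCl2 is held at `fixed_mgcl2` for every point, giving
#'   excess free Mg2+ over the PPi titration.
#'
#' Because PPi is supplied as its tetrasodium salt, every point carries a
#' basal sodium contribution of four times the total PPi on top of the
#' added NaCl: `total_na_mM = nacl + 4 * ppi`. K+ (as KCl, default 100 mM)
#' is present throughout since both enzyme families require it for full
#' activity; the assay is buffered at pH 7.2.
#'
#' @param mode `"matched_mg"` or `"fixed_mg"`.
#' @param ppi_totals strictly increasing grid of total PPi (mM). Defaults:
#'   a matched-Mg grid of 8 points (0.1-1.25 mM) whose speciated substrate
#'   spans roughly 0.01-0.55 mM under the default constants, or a fixed-Mg
#'   grid of 8 points up to 0.25 mM.
#' @param fixed_mgcl2 total MgCl2 (mM), required in `fixed_mg` mode.
#' @param kcl KCl concentration (mM), default 100.
#' @param nacl_levels added NaCl levels (mM), default `c(0, 50, 100)`.
#' @param ph assay pH, default 7.2.
#' @return A tibble with one row per design point: `mode`, `nacl_mM`
#'   (added NaCl), `kcl_mM`, `mgcl2_mM`, `ppi_total_mM`, `ph`, plus the
#'   ionic totals `total_ppi_mM`, `total_mg_mM`, `total_k_mM`,
#'   `total_na_mM` consumed by [speciate()].
#' @export
#' @examples
#' make_design("matched_mg", ppi_totals = c(0.05, 0.1), nacl_levels = 0)
make_design <- function(mode = c("matched_mg", "fixed_mg"),
                        ppi_totals = NULL, fixed_mgcl2 = NULL,
                        kcl = 100, nacl_levels = c(0, 50, 100), ph = 7.2) {
  mode <- match.arg(mode)
  if (is.null(ppi_totals)) {
    ppi_totals <- if (mode == "matched_mg") {
      c(0.1, 0.2, 0.3, 0.45, 0.6, 0.8, 1.0, 1.25)
    } else {
      c(0.025, 0.05, 0.075, 0.1, 0.125, 0.15, 0.2, 0.25)
    }
  }
  if (length(ppi_totals) == 0) abort_validation("`ppi_totals` must be non-empty.")
  check_number(ppi_totals, "ppi_totals", lower = 0, strict_lower = TRUE)
  if (is.unsorted(ppi_totals, strictly = TRUE)) {
    abort_validation("`ppi_totals` must be strictly increasing.")
  }
  if (length(nacl_levels) == 0) abort_validation("`nacl_levels` must be non-empty.")
  check_number(nacl_levels, "nacl_levels", lower = 0)
  check_scalar(kcl, "kcl", lower = 0)
  check_scalar(ph, "ph", lower = 2, upper = 12)
  if (mode == "fixed_mg") {
    if (is.null(fixed_mgcl2)) {
      abort_validation("`fixed_mg` mode requires `fixed_mgcl2`.")
    }
    check_scalar(fixed_mgcl2, "fixed_mgcl2", lower = 0, strict_lower = TRUE)
  }

  design_mode <- mode
  grid <- tidyr::expand_grid(nacl_mM = nacl_levels, ppi_total_mM = ppi_totals)
  grid %>%
    mutate(
      mode = design_mode,
      kcl_mM = kcl,
      mgcl2_mM = if (design_mode == "matched_mg") 2 * .data$ppi_total_mM else fixed_mgcl2,
      ph = ph,
      total_ppi_mM = .data$ppi_total_mM,
      total_mg_mM = .data$mgcl2_mM,
      total_k_mM = .data$kcl_mM,
      total_na_mM = .data$nacl_mM + 4 * .data$ppi_total_mM
    ) %>%
    select(all_of(c("mode", "nacl_mM", "kcl_mM", "mgcl2_mM", "ppi_total_mM",
                    "ph", "total_ppi_mM", "total_mg_mM", "total_k_mM",
                    "total_na_mM")))
}

#' Configuration for the synthetic assay generator
#'
#' Bundles the generating rate law per salt level, the replicate count and
#' the noise model used by [simulate_assay()]. Replicate noise is Gaussian
#' with standard deviation `cv * true_rate + sd_floor`; negative draws are
#' redrawn rather than clipped so the noise mean stays at the true rate
#' (at the cost of a slight variance shrinkage when the true rate is within
#' a few SD of zero).
#'
#' @param models named list mapping each added-NaCl level (as a name, e.g.
#'   `"0"`, `"50"`, `"100"`) to an [mwc_params()] or [hill_params()] object.
#' @param enzyme enzyme label carried into the records (default `"ENZ"`).
#' @param n_replicates replicates per point; the experiments emulated here
#'   used 3-5 (default 4). Larger values are allowed for calibration runs.
#' @param cv multiplicative noise, as a coefficient of variation (default
#'   0.08, i.e. 8%, matching figure-scale error bars).
#' @param sd_floor additive SD floor in U/mg (default 0.005).
#' @param seed integer seed; identical seeds give bit-identical records.
#' @param abscissa `"speciated"` to evaluate the generating law on the
#'   speciated substrate Mg2PPi (the matched-Mg convention) or `"total"`
#'   to evaluate it on total PPi.
#' @param constants dissociation constants used when `abscissa = "speciated"`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(models, enzyme = "ENZ", n_replicates = 4L,
                             cv = 0.08, sd_floor = 0.005, seed = 1L,
                             abscissa = c("speciated", "total"),
                             constants = ppi_constants()) {
  abscissa <- match.arg(abscissa)
  if (!is.list(models) || length(models) == 0 || is.null(names(models)) ||
      any(names(models) == "")) {
    abort_validation("`models` must be a named list keyed by added-NaCl level.")
  }
  ok <- vapply(models, function(m) inherits(m, c("hill_params", "mwc_params")),
               logical(1))
  if (!all(ok)) {
    abort_validation("Each entry of `models` must be hill_params() or mwc_params().")
  }
  check_scalar(n_replicates, "n_replicates", lower = 1)
  check_scalar(cv, "cv", lower = 0)
  check_scalar(sd_floor, "sd_floor", lower = 0)
  check_scalar(seed, "seed")
  validate_constants(constants)
  structure(list(models = models, enzyme = enzyme,
                 n_replicates = as.integer(n_replicates), cv = cv,
                 sd_floor = sd_floor, seed = as.integer(seed),
                 abscissa = abscissa, constants = constants),
            class = "synthetic_config")
}

true_rate_for <- function(params, s) {
  if (inherits(params, "mwc_params")) mwc_rate(s, params) else hill_rate(s, params)
}

# Deterministic 31-bit substream seed from the point's identity (not its row
# index), so subsetting a design leaves shared points unchanged.
substream_seed <- function(seed, key) {
  bytes <- utf8ToInt(key)
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer((h + (seed %% m) * 48271) %% m)
}

#' Simulate replicate assay records over a design
#'
#' For each design point, evaluates the generating rate law for that salt
#' level on the configured abscissa and draws `n_replicates` noisy rates
#' (Gaussian, SD = `cv * rate + sd_floor`, negative draws redrawn). Each
#' (point, replicate) uses a substream seeded deterministically from the
#' point's ionic identity and the replicate index, so runs are bit-identical
#' under the same seed and subsetting a design does not change shared
#' points.
#'
#' @param design a design tibble from [make_design()].
#' @param config a [synthetic_config()].
#' @return A tibble of replicate records in the pipeline input schema:
#'   `enzyme`, `mode`, `nacl_mM`, `kcl_mM`, `mgcl2_mM`, `ppi_total_mM`,
#'   `ph`, `replicate_id`, `rate_U_per_mg`.
#' @export
#' @examples
#' des <- make_design("matched_mg", ppi_totals = c(0.1, 0.3), nacl_levels = 0)
#' cfg <- synthetic_config(list(`0` = mwc_params(0.5, 17, 84)), seed = 42)
#' simulate_assay(des, cfg)
simulate_assay <- function(design, config) {
  if (!inherits(config, "synthetic_config")) {
    abort_validation("`config` must come from synthetic_config().")
  }
  if (!is.data.frame(design) || nrow(design) == 0) {
    abort_validation("`design` must be a non-empty data frame.")
  }
  missing_lv <- setdiff(unique(as.character(design$nacl_mM)), names(config$models))
  if (length(missing_lv) > 0) {
    abort_validation(sprintf("No generating model for NaCl level(s): %s",
                             paste(missing_lv, collapse = ", ")))
  }

  s_abs <- if (config$abscissa == "speciated") {
    substrate_grid(design, constants = config$constants)$s_mg2ppi_mM
  } else {
    design$ppi_total_mM
  }

  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    pt <- design[i, ]
    params <- config$models[[as.character(pt$nacl_mM)]]
    truth <- true_rate_for(params, s_abs[i])
    sd_i <- config$cv * truth + config$sd_floor
    key_base <- sprintf("%s|%.10g|%.10g|%.10g|%.10g|%.10g",
                        pt$mode, pt$nacl_mM, pt$kcl_mM, pt$mgcl2_mM,
                        pt$ppi_total_mM, pt$ph)
    rate <- vapply(seq_len(config$n_replicates), function(r) {
      draw_nonneg(truth, sd_i, substream_seed(config$seed,
                                              paste0(key_base, "|", r)))
    }, numeric(1))
    tibble(enzyme = config$enzyme, mode = pt$mode, nacl_mM = pt$nacl_mM,
           kcl_mM = pt$kcl_mM, mgcl2_mM = pt$mgcl2_mM,
           ppi_total_mM = pt$ppi_total_mM, ph = pt$ph,
           replicate_id = seq_len(config$n_replicates),
           rate_U_per_mg = rate)
  })
  dplyr::bind_rows(rows)
}

draw_nonneg <- function(mean, sd, seed) {
  if (sd == 0) return(mean)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= 0) return(x)
  }
  abort("Could not draw a non-negative rate in 1000 attempts.",
        class = "ppasekin_numeric_error")
}
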