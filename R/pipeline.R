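assay_required_cols <- c("enzyme", "mode", "nacl_mM", "kcl_mM", "mgcl2_mM",
                         "ppi_total_mM", "ph", "replicate_id", "rate_U_per_mg")
assay_optional_cols <- c("s_mM")

#' Read a replicate assay table from delimited text
#'
#' Reads, types and validates a table of replicate assay records. The
#' required columns (any order) are `enzyme`, `mode` (`matched_mg` or
#' `fixed_mg`), `nacl_mM`, `kcl_mM`, `mgcl2_mM`, `ppi_total_mM`, `ph`,
#' `replicate_id`, `rate_U_per_mg`; `s_mM` (a precomputed substrate
#' abscissa) is optional. Parse problems are reported with row numbers.
#'
#' @param path path to a tab-delimited text file (use `delim` for other
#'   separators).
#' @param delim field delimiter, default tab.
#' @return A validated tibble of replicate records.
#' @export
read_assay_table <- function(path, delim = "\t") {
  if (!file.exists(path)) abort_validation(sprintf("Assay table not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(assay_required_cols, names(raw))
  if (length(missing) > 0) {
    abort_validation(sprintf("Assay table is missing required column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), c(assay_required_cols, assay_optional_cols))
  if (length(extra) > 0) {
    abort_validation(sprintf("Assay table has unrecognised column(s): %s",
                             paste(extra, collapse = ", ")))
  }
  num_cols <- setdiff(names(raw), c("enzyme", "mode"))
  out <- raw
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort_validation(sprintf("Non-numeric `%s` at row(s): %s", col,
                               paste(head(bad, 5), collapse = ", ")))
    }
    out[[col]] <- vals
  }
  validate_assay_records(out)
}

validate_assay_records <- function(records) {
  if (nrow(records) == 0) abort_validation("Assay table has no rows.")
  nonneg <- c("nacl_mM", "kcl_mM", "mgcl2_mM", "ppi_total_mM", "rate_U_per_mg")
  for (col in nonneg) {
    bad <- which(is.na(records[[col]]) | records[[col]] < 0)
    if (length(bad) > 0) {
      abort_validation(sprintf("Negative or missing `%s` at row(s): %s", col,
                               paste(head(bad, 5), collapse = ", ")))
    }
  }
  bad_ph <- which(is.na(records$ph) | records$ph < 2 | records$ph > 12)
  if (length(bad_ph) > 0) {
    abort_validation(sprintf("pH outside [2, 12] at row(s): %s",
                             paste(head(bad_ph, 5), collapse = ", ")))
  }
  bad_mode <- which(!records$mode %in% c("matched_mg", "fixed_mg"))
  if (length(bad_mode) > 0) {
    abort_validation(sprintf("Unknown `mode` at row(s): %s",
                             paste(head(bad_mode, 5), collapse = ", ")))
  }
  as_tibble(records)
}

#' Write a table to tab-delimited text at full precision
#'
#' @param x a data frame.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_assay_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Percent decrease and fold change relative to a reference
#'
#' The conventions used for salt-sensitivity summaries:
#' `percent_decrease = 100 * (1 - treated / reference)` and
#' `fold_change = treated / reference` (so a 6-fold activation by K+ has
#' `fold_change = 6`).
#'
#' @param reference reference value(s) (e.g. Vm at 0 mM NaCl); positive.
#' @param treated treated value(s), same units; non-negative.
#' @return A tibble with columns `percent_decrease` and `fold_change`.
#' @export
#' @examples
#' relative_change(0.47, 0.23)  # about a 51% decrease
relative_change <- function(reference, treated) {
  check_number(reference, "reference", lower = 0, strict_lower = TRUE)
  check_number(treated, "treated", lower = 0)
  tibble(percent_decrease = 100 * (1 - treated / reference),
         fold_change = treated / reference)
}

#' Salt-sensitivity summary from a parameter table
#'
#' For each enzyme (and Mg level, in fixed-Mg designs), compares a chosen
#' parameter at every non-zero added-NaCl level against the 0 mM NaCl
#' reference, reporting the raw percent decrease, the same value rounded to
#' the nearest ten percentage points (the granularity at which such
#' sensitivities are usually quoted), and the fold change.
#'
#' @param parameter_table a tibble as produced by [run_analysis()] (or
#'   hand-built) with columns `enzyme`, `nacl_mM`, `model`, and the
#'   parameter column named in `parameter`; `mode` and `mgcl2_mM` are used
#'   for grouping when present.
#' @param model which fitted model's rows to summarise (default `"hill"`).
#' @param parameter which parameter to compare (default `"vm"`).
#' @return A tibble with one row per (enzyme group, non-reference NaCl
#'   level): `percent_decrease`, `percent_decrease_rounded`, `fold_change`.
#'   Zero rows when only the reference level is present.
#' @export
salt_sensitivity_summary <- function(parameter_table, model = "hill",
                                     parameter = "vm") {
  req <- c("enzyme", "nacl_mM", "model", parameter)
  missing <- setdiff(req, names(parameter_table))
  if (length(missing) > 0) {
    abort_validation(sprintf("Parameter table is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  tbl <- dplyr::filter(parameter_table, .data$model == !!model)
  if (nrow(tbl) == 0) {
    abort_validation(sprintf("Parameter table has no rows for model `%s`.", model))
  }
  group_cols <- intersect(c("enzyme", "mode", "mgcl2_mM"), names(tbl))
  groups <- dplyr::distinct(tbl, across(all_of(group_cols)))

  out <- purrr::map(seq_len(nrow(groups)), function(i) {
    g <- dplyr::semi_join(tbl, groups[i, ], by = group_cols)
    ref <- dplyr::filter(g, .data$nacl_mM == 0)
    if (nrow(ref) != 1) {
      abort(sprintf("No unique 0 mM NaCl reference row for %s (model %s).",
                    paste(unlist(groups[i, ]), collapse = "/"), model),
            class = "ppasekin_validation_error")
    }
    treated <- dplyr::filter(g, .data$nacl_mM != 0)
    if (nrow(treated) == 0) return(NULL)
    rc <- relative_change(ref[[parameter]], treated[[parameter]])
    dplyr::bind_cols(
      treated[c(group_cols, "nacl_mM", "model")],
      tibble(parameter = parameter,
             reference_value = ref[[parameter]],
             treated_value = treated[[parameter]],
             percent_decrease = rc$percent_decrease,
             percent_decrease_rounded = round_to_nearest(rc$percent_decrease, 10),
             fold_change = rc$fold_change)
    )
  })
  dplyr::bind_rows(out)
}

#' Configuration for a full kinetic analysis run
#'
#' @param models models to fit per condition; any of `"hill"`, `"mwc"`,
#'   `"mm"` (default fits both the Hill and the allosteric law).
#' @param abscissa `"auto"` (matched-Mg conditions use the speciated
#'   substrate Mg2PPi, fixed-Mg conditions use total PPi), `"speciated"`,
#'   or `"total"`.
#' @param truncate_max_s optional truncation threshold(s) in mM to exclude
#'   substrate-inhibited points: a single number applied to every enzyme,
#'   or a named numeric vector keyed by enzyme label.
#' @param weights weighting mode passed to [fit_model()].
#' @param constants dissociation constants used for speciation.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(models = c("hill", "mwc"),
                            abscissa = c("auto", "speciated", "total"),
                            truncate_max_s = NULL,
                            weights = c("replicate-variance", "sem", "unit"),
                            constants = ppi_constants()) {
  abscissa <- match.arg(abscissa)
  weights <- match.arg(weights)
  models <- match.arg(models, c("hill", "mwc", "mm"), several.ok = TRUE)
  if (!is.null(truncate_max_s)) {
    check_number(truncate_max_s, "truncate_max_s", lower = 0, strict_lower = TRUE)
  }
  validate_constants(constants)
  structure(list(models = models, abscissa = abscissa,
                 truncate_max_s = truncate_max_s, weights = weights,
                 constants = constants),
            class = "analysis_config")
}

truncation_for <- function(config, enzyme) {
  tm <- config$truncate_max_s
  if (is.null(tm)) return(NULL)
  if (!is.null(names(tm))) {
    if (enzyme %in% names(tm)) return(unname(tm[[enzyme]])) else return(NULL)
  }
  unname(tm[1])
}

empty_param_row <- function() {
  tibble(vm = NA_real_, vm_se = NA_real_,
         k_half_mM = NA_real_, k_half_mM_se = NA_real_,
         n_h = NA_real_, n_h_se = NA_real_,
         l = NA_real_, l_se = NA_real_,
         k_r_uM = NA_real_, k_r_uM_se = NA_real_,
         km_mM = NA_real_, km_mM_se = NA_real_)
}

fit_to_row <- function(fit) {
  row <- empty_param_row()
  for (nm in names(fit$estimates)) {
    row[[nm]] <- fit$estimates[[nm]]
    row[[paste0(nm, "_se")]] <- fit$std_errors[[nm]]
  }
  row$wrss <- fit$wrss
  row$points_used <- fit$points_used
  row$truncation_max_s <- fit$truncation_max_s
  row$converged <- fit$converged
  row
}

#' Run the full kinetic analysis pipeline
#'
#' Orchestrates, per experimental condition (enzyme, design mode, MgCl2
#' level, added NaCl): computation of the substrate abscissa (equilibrium
#' speciation when requested), aggregation of replicates into weighted mean
#' points, optional truncation of substrate-inhibited points, and weighted
#' nonlinear fits of the requested rate laws; then derives the
#' salt-sensitivity summary of Vm. Conditions whose fit fails are flagged
#' (`converged = FALSE`) and the run continues; every fallback and failure
#' is recorded in the returned log.
#'
#' @param records replicate assay records (see [read_assay_table()] for the
#'   schema), e.g. from [simulate_assay()].
#' @param config an [analysis_config()].
#' @return An object of class `ppase_analysis`: a list with
#'   `parameter_table` (one row per condition and model),
#'   `sensitivity` (Vm percent decreases vs the 0 mM NaCl reference),
#'   `fits` (named list of `kin_fit` objects), and `log` (character).
#' @export
run_analysis <- function(records, config = analysis_config()) {
  if (!inherits(config, "analysis_config")) {
    abort_validation("`config` must come from analysis_config().")
  }
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty table of replicate assay records.")
  }
  records <- validate_assay_records(records)
  log <- character()
  note <- function(msg) {
    log <<- c(log, msg)
    inform(msg)
  }

  # substrate abscissa per record
  use_speciated <- switch(config$abscissa,
    auto = records$mode == "matched_mg",
    speciated = rep(TRUE, nrow(records)),
    total = rep(FALSE, nrow(records))
  )
  records$s_mM <- records$ppi_total_mM
  if (any(use_speciated)) {
    conds <- records[use_speciated, ] %>%
      mutate(total_ppi_mM = .data$ppi_total_mM, total_mg_mM = .data$mgcl2_mM,
             total_k_mM = .data$kcl_mM,
             total_na_mM = .data$nacl_mM + 4 * .data$ppi_total_mM) %>%
      distinct(.data$total_ppi_mM, .data$total_mg_mM, .data$total_k_mM,
               .data$total_na_mM, .data$ph)
    spec <- speciate(conds, constants = config$constants)
    key <- function(p, m, k, na, ph) sprintf("%.12g|%.12g|%.12g|%.12g|%.12g",
                                             p, m, k, na, ph)
    s_map <- setNames(spec$s_mg2ppi_mM,
                      key(spec$total_ppi_mM, spec$total_mg_mM, spec$total_k_mM,
                          spec$total_na_mM, spec$ph))
    idx <- which(use_speciated)
    records$s_mM[idx] <- s_map[key(records$ppi_total_mM[idx],
                                   records$mgcl2_mM[idx], records$kcl_mM[idx],
                                   records$nacl_mM[idx] + 4 * records$ppi_total_mM[idx],
                                   records$ph[idx])]
  }

  # MgCl2 identifies a condition only in fixed-Mg mode (it tracks PPi otherwise)
  records$mgcl2_level <- ifelse(records$mode == "fixed_mg",
                                records$mgcl2_mM, NA_real_)
  conditions <- distinct(records, .data$enzyme, .data$mode, .data$mgcl2_level,
                         .data$nacl_mM)
  rows <- list()
  fits <- list()
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    sub <- dplyr::semi_join(records, cond,
                            by = c("enzyme", "mode", "mgcl2_level", "nacl_mM"))
    label <- sprintf("%s/%s/NaCl %g", cond$enzyme, cond$mode, cond$nacl_mM)
    dataset <- aggregate_replicates(sub, s_col = "s_mM",
                                    rate_col = "rate_U_per_mg")
    tmax <- truncation_for(config, cond$enzyme)
    for (model in config$models) {
      fit <- withCallingHandlers(
        tryCatch(
          fit_model(dataset, model = model, weights = config$weights,
                    truncate_max_s = tmax),
          error = function(e) {
            note(sprintf("[%s, %s] fit failed: %s", label, model,
                         conditionMessage(e)))
            NULL
          }
        ),
        warning = function(w) {
          note(sprintf("[%s, %s] %s", label, model, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      row <- if (is.null(fit)) {
        r <- empty_param_row()
        r$wrss <- NA_real_
        r$points_used <- NA_integer_
        r$truncation_max_s <- if (is.null(tmax)) NA_real_ else tmax
        r$converged <- FALSE
        r
      } else {
        fits[[paste(label, model, sep = ", ")]] <- fit
        fit_to_row(fit)
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(enzyme = cond$enzyme, mode = cond$mode,
               mgcl2_mM = if (cond$mode == "fixed_mg") cond$mgcl2_level else NA_real_,
               nacl_mM = cond$nacl_mM, model = model),
        row
      )
    }
  }
  parameter_table <- dplyr::bind_rows(rows)

  sens_model <- if ("hill" %in% config$models) "hill" else config$models[1]
  sensitivity <- tryCatch(
    salt_sensitivity_summary(
      dplyr::filter(parameter_table, .data$converged), model = sens_model),
    error = function(e) {
      note(sprintf("Salt-sensitivity summary unavailable: %s",
                   conditionMessage(e)))
      NULL
    }
  )

  structure(list(parameter_table = parameter_table, sensitivity = sensitivity,
                 fits = fits, log = log,
                 manifest = list(models = config$models,
                                 abscissa = config$abscissa,
                                 weights = config$weights,
                                 truncate_max_s = config$truncate_max_s,
                                 constants = config$constants)),
            class = "ppase_analysis")
}

#' @export
print.ppase_analysis <- function(x, ...) {
  cat(sprintf("Kinetic analysis: %d fitted condition/model rows\n",
              nrow(x$parameter_table)))
  print(format_parameter_table(x$parameter_table))
  if (!is.null(x$sensitivity) && nrow(x$sensitivity) > 0) {
    cat("\nVm salt sensitivity vs 0 mM NaCl:\n")
    print(x$sensitivity)
  }
  invisible(x)
}

#' Human-readable parameter table
#'
#' Formats each parameter as `estimate ± SE`, with the SE shown to two
#' significant figures and the estimate rounded to the same decimal place
#' (machine-precision values stay in the unformatted table).
#'
#' @param parameter_table the `parameter_table` of a [run_analysis()] result.
#' @return A tibble of display strings.
#' @export
format_parameter_table <- function(parameter_table) {
  param_cols <- c(vm = "vm", k_half_mM = "k_half_mM", n_h = "n_h",
                  l = "l", k_r_uM = "k_r_uM", km_mM = "km_mM")
  keep <- intersect(c("enzyme", "mode", "mgcl2_mM", "nacl_mM", "model",
                      "points_used", "converged"), names(parameter_table))
  out <- parameter_table[keep]
  for (pc in param_cols) {
    if (!pc %in% names(parameter_table)) next
    se_col <- paste0(pc, "_se")
    vals <- purrr::map2_chr(parameter_table[[pc]], parameter_table[[se_col]],
                            function(e, s) {
                              if (is.na(e)) NA_character_ else format_pm(e, s)
                            })
    if (all(is.na(vals))) next
    out[[pc]] <- vals
  }
  out
}
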