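#' Equilibrium speciation of pyrophosphate and the substrate [Mg2PPi]
#'
#' Partitions the total concentrations of pyrophosphate (PPi) and magnesium
#' among free ions and the complexes present in the constants table, at
#' fixed pH, and returns the concentration of the doubly magnesium-complexed
#' species Mg2PPi, taken as the true substrate of membrane-bound
#' pyrophosphatases.
#'
#' The assay is buffered, so `[H+]` is a constant input (`10^(3 - ph)` mM).
#' K+ and Na+ are in large excess over PPi in these assays, so their free
#' concentrations are taken equal to their totals (no monovalent mass
#' balance). The two remaining unknowns, free PPi and free Mg2+, satisfy the
#' PPi and Mg mass balances; free PPi is available in closed form given free
#' Mg, and the Mg balance is a strictly increasing one-dimensional equation
#' in free Mg solved by safeguarded Newton iteration with bisection
#' fallback. Both balances are verified to `tol` on return.
#'
#' @param conditions a data frame with one row per assay point and columns
#'   `total_ppi_mM`, `total_mg_mM`, `total_k_mM`, `total_na_mM`, `ph`.
#' @param constants dissociation-constant table as returned by
#'   [ppi_constants()] or [read_constants()]. Must contain `MgPPi` and
#'   `Mg2PPi`.
#' @param tol relative tolerance on the mass balances (default `1e-10`).
#' @param max_iter maximum solver iterations per condition (default 200).
#' @return The input tibble with added columns `free_ppi_mM`, `free_mg_mM`,
#'   one concentration column per complex in `constants` (e.g. `mg2ppi_mM`),
#'   and `s_mg2ppi_mM`, the substrate concentration (equal to `mg2ppi_mM`).
#' @export
#' @examples
#' conds <- tibble::tibble(total_ppi_mM = 0.1, total_mg_mM = 0.2,
#'                         total_k_mM = 100, total_na_mM = 0.4, ph = 7.2)
#' speciate(conds)
speciate <- function(conditions, constants = ppi_constants(),
                     tol = 1e-10, max_iter = 200L) {
  conditions <- validate_conditions(conditions)
  kd <- constants_vector(constants)
  if (is.na(kd[["MgPPi"]]) || is.na(kd[["Mg2PPi"]])) {
    abort_validation("Substrate computation requires `MgPPi` and `Mg2PPi` constants.")
  }
  check_scalar(tol, "tol", lower = 0, strict_lower = TRUE)

  states <- purrr::pmap(
    conditions[c("total_ppi_mM", "total_mg_mM", "total_k_mM", "total_na_mM", "ph")],
    function(total_ppi_mM, total_mg_mM, total_k_mM, total_na_mM, ph) {
      solve_speciation(total_ppi_mM, total_mg_mM, total_k_mM, total_na_mM,
                       ph, kd, tol, max_iter)
    }
  )
  dplyr::bind_cols(as_tibble(conditions), dplyr::bind_rows(states))
}

validate_conditions <- function(conditions) {
  req <- c("total_ppi_mM", "total_mg_mM", "total_k_mM", "total_na_mM", "ph")
  if (!is.data.frame(conditions)) abort_validation("`conditions` must be a data frame.")
  missing <- setdiff(req, names(conditions))
  if (length(missing) > 0) {
    abort_validation(sprintf("`conditions` is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  for (col in setdiff(req, "ph")) check_number(conditions[[col]], col, lower = 0)
  check_number(conditions$ph, "ph", lower = 2, upper = 12)
  conditions
}

# Solve one condition. Unknowns: p = free PPi, m = free Mg (mM).
# With h = [H+] (mM) fixed and monovalents free = total, every complex is
# proportional to p:
#   alpha(m) = 1 + h/K_H1 + h^2/(K_H1 K_H2) + k/K_K + na/K_Na
#            + m/K_Mg1 + m^2/(K_Mg1 K_Mg2) + m h/(K_H1 K_MgH)
# so p(m) = total_ppi / alpha(m), and the Mg balance
#   g(m) = m + p(m) * (m/K_Mg1 + 2 m^2/(K_Mg1 K_Mg2) + m h/(K_H1 K_MgH))
# is strictly increasing on [0, total_mg] with g(0) = 0 <= total_mg.
solve_speciation <- function(total_ppi, total_mg, total_k, total_na,
                             ph, kd, tol, max_iter) {
  h <- 10^(3 - ph)  # mM

  # per-species binding coefficients c_x such that [X] = c_x(m) * p
  c_h1 <- if (!is.na(kd[["HPPi"]])) h / kd[["HPPi"]] else 0
  c_h2 <- if (!is.na(kd[["H2PPi"]])) c_h1 * h / kd[["H2PPi"]] else 0
  c_k  <- if (!is.na(kd[["KPPi"]])) total_k / kd[["KPPi"]] else 0
  c_na <- if (!is.na(kd[["NaPPi"]])) total_na / kd[["NaPPi"]] else 0
  b_mg1 <- 1 / kd[["MgPPi"]]                      # coeff of m
  b_mg2 <- b_mg1 / kd[["Mg2PPi"]]                 # coeff of m^2
  b_mgh <- if (!is.na(kd[["MgHPPi"]])) c_h1 / kd[["MgHPPi"]] else 0

  alpha0 <- 1 + c_h1 + c_h2 + c_k + c_na
  alpha <- function(m) alpha0 + b_mg1 * m + b_mg2 * m^2 + b_mgh * m
  p_of <- function(m) total_ppi / alpha(m)
  bound_mg <- function(m, p) p * (b_mg1 * m + 2 * b_mg2 * m^2 + b_mgh * m)
  g <- function(m) m + bound_mg(m, p_of(m)) - total_mg

  if (total_mg == 0 || total_ppi == 0) {
    m <- total_mg
    p <- if (total_ppi == 0) 0 else p_of(0)
  } else {
    lo <- 0
    hi <- total_mg
    m <- total_mg / 2
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      gm <- g(m)
      if (abs(gm) <= tol * max(total_mg, total_ppi)) { converged <- TRUE; break }
      if (gm > 0) hi <- m else lo <- m
      # Newton step with numerical derivative, safeguarded by the bracket
      dm <- max(1e-9 * max(m, total_mg), 1e-15)
      dg <- (g(m + dm) - gm) / dm
      m_new <- if (is.finite(dg) && dg > 0) m - gm / dg else NA_real_
      if (!is.finite(m_new) || m_new <= lo || m_new >= hi) m_new <- (lo + hi) / 2
      m <- m_new
    }
    if (!converged) {
      abort(sprintf(paste0("Speciation solver did not converge in %d iterations ",
                           "for condition (PPi = %g, Mg = %g, K = %g, Na = %g mM, pH %g)."),
                    max_iter, total_ppi, total_mg, total_k, total_na, ph),
            class = "ppasekin_solver_error")
    }
    p <- p_of(m)
  }

  species <- tibble(
    free_ppi_mM = p,
    free_mg_mM = m
  )
  add <- function(tbl, nm, value) { tbl[[nm]] <- value; tbl }
  if (!is.na(kd[["HPPi"]]))   species <- add(species, "hppi_mM",  c_h1 * p)
  if (!is.na(kd[["H2PPi"]]))  species <- add(species, "h2ppi_mM", c_h2 * p)
  species <- add(species, "mgppi_mM",  b_mg1 * m * p)
  species <- add(species, "mg2ppi_mM", b_mg2 * m^2 * p)
  if (!is.na(kd[["KPPi"]]))   species <- add(species, "kppi_mM",  c_k * p)
  if (!is.na(kd[["NaPPi"]]))  species <- add(species, "nappi_mM", c_na * p)
  if (!is.na(kd[["MgHPPi"]])) species <- add(species, "mghppi_mM", b_mgh * m * p)
  species$s_mg2ppi_mM <- species$mg2ppi_mM

  # verify both mass balances
  ppi_sum <- p * alpha(m)
  mg_sum <- m + bound_mg(m, p)
  scale_p <- max(total_ppi, 1e-300)
  scale_m <- max(total_mg, 1e-300)
  bal_tol <- max(tol, 1e-10) * 100  # allow for roundoff in the verification sums
  if (total_ppi > 0 && abs(ppi_sum - total_ppi) / scale_p > bal_tol ||
      total_mg > 0 && abs(mg_sum - total_mg) / scale_m > bal_tol) {
    abort("Speciation solution violates a mass balance.",
          class = "ppasekin_solver_error")
  }
  species
}

#' Substrate concentrations over an assay design
#'
#' Vectorizes [speciate()] over the points of an assay design (see
#' [make_design()]), preserving row order, and returns the design with the
#' substrate concentration `s_mg2ppi_mM` attached.
#'
#' @param design an assay-design tibble with the ionic-total columns used by
#'   [speciate()] (as produced by [make_design()]).
#' @inheritParams speciate
#' @return The design tibble with speciation columns appended.
#' @export
substrate_grid <- function(design, constants = ppi_constants(),
                           tol = 1e-10, max_iter = 200L) {
  if (!is.data.frame(design) || nrow(design) == 0) {
    abort_validation("`design` must be a non-empty data frame.")
  }
  speciate(design, constants = constants, tol = tol, max_iter = max_iter)
}
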