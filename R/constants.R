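#' Stepwise dissociation constants for pyrophosphate complexes
#'
#' Default table of conditional stepwise dissociation constants (mM) for the
#' complexes of pyrophosphate (PPi) with H+, Mg2+, K+ and Na+ used by
#' [speciate()]. Each constant describes one dissociation step:
#'
#' * `HPPi`:   \eqn{HPPi \rightleftharpoons H^+ + PPi}
#' * `H2PPi`:  \eqn{H_2PPi \rightleftharpoons H^+ + HPPi}
#' * `MgPPi`:  \eqn{MgPPi \rightleftharpoons Mg^{2+} + PPi}
#' * `Mg2PPi`: \eqn{Mg_2PPi \rightleftharpoons Mg^{2+} + MgPPi}
#' * `KPPi`:   \eqn{KPPi \rightleftharpoons K^+ + PPi}
#' * `NaPPi`:  \eqn{NaPPi \rightleftharpoons Na^+ + PPi}
#' * `MgHPPi`: \eqn{MgHPPi \rightleftharpoons Mg^{2+} + HPPi} (optional)
#'
#' The shipped values are a stand-in compiled from standard conditional
#' constants for pyrophosphate complexation near neutral pH and
#' physiological ionic strength; they are *conditional* constants (no
#' activity-coefficient correction) and every analysis report records the
#' constants actually used. Override any value by passing your own table.
#'
#' @param include_mghppi include the ternary MgHPPi complex (default `TRUE`).
#' @return A tibble with columns `species` and `kd_mM`.
#' @seealso [read_constants()] to load a user table from delimited text.
#' @export
#' @examples
#' ppi_constants()
ppi_constants <- function(include_mghppi = TRUE) {
  tbl <- tibble(
    species = c("HPPi", "H2PPi", "MgPPi", "Mg2PPi", "KPPi", "NaPPi", "MgHPPi"),
    kd_mM = c(
      10^(3 - 8.94),   # pKa1 of HPPi
      10^(3 - 6.13),   # pKa2 (H2PPi)
      0.004,           # Mg2+ + PPi
      0.60,            # Mg2+ + MgPPi
      63,              # K+ + PPi
      83,              # Na+ + PPi
      0.75             # Mg2+ + HPPi
    )
  )
  if (!include_mghppi) tbl <- tbl[tbl$species != "MgHPPi", ]
  tbl
}

ppi_species <- c("HPPi", "H2PPi", "MgPPi", "Mg2PPi", "KPPi", "NaPPi", "MgHPPi")

#' Read a dissociation-constant table from delimited text
#'
#' The file must have a `species` column and either a `kd_mM` column
#' (dissociation constant in mM) or, for protonation steps, a `pka` column.
#' A `pka` entry is converted as `kd_mM = 10^(3 - pka)` (the dissociation
#' constant in mol/L is `10^-pka`; the factor `10^3` converts to mM).
#' When both are present for a row, `kd_mM` wins.
#'
#' @param path path to a tab- or comma-delimited text file.
#' @return A tibble with columns `species` and `kd_mM`.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("Constants file not found: %s", path))
  tbl <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!"species" %in% names(tbl)) {
    abort_validation("Constants file must have a `species` column.")
  }
  if (!any(c("kd_mM", "pka") %in% names(tbl))) {
    abort_validation("Constants file must have a `kd_mM` or `pka` column.")
  }
  kd <- if ("kd_mM" %in% names(tbl)) as.numeric(tbl$kd_mM) else rep(NA_real_, nrow(tbl))
  if ("pka" %in% names(tbl)) {
    use_pka <- is.na(kd) & !is.na(tbl$pka)
    kd[use_pka] <- 10^(3 - as.numeric(tbl$pka[use_pka]))
  }
  out <- tibble(species = as.character(tbl$species), kd_mM = kd)
  validate_constants(out)
  out
}

validate_constants <- function(constants) {
  if (!is.data.frame(constants) ||
      !all(c("species", "kd_mM") %in% names(constants))) {
    abort_validation("`constants` must be a data frame with columns `species` and `kd_mM`.")
  }
  unknown <- setdiff(constants$species, ppi_species)
  if (length(unknown) > 0) {
    abort_validation(sprintf("Unknown species in constants table: %s",
                             paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(constants$species)) {
    abort_validation("Duplicated species in constants table.")
  }
  if (anyNA(constants$kd_mM) || any(constants$kd_mM <= 0)) {
    abort_validation("Every dissociation constant must be a positive number (mM).")
  }
  invisible(constants)
}

# named numeric vector of kd (mM), NA for excluded species
constants_vector <- function(constants) {
  validate_constants(constants)
  kd <- setNames(rep(NA_real_, length(ppi_species)), ppi_species)
  kd[constants$species] <- constants$kd_mM
  kd
}
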