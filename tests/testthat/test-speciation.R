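cond_tbl <- function(ppi, mg, k = 100, na = 0.4, ph = 7.2) {
  tibble::tibble(total_ppi_mM = ppi, total_mg_mM = mg, total_k_mM = k,
                 total_na_mM = na, ph = ph)
}

no_binding_constants <- function() {
  tibble::tibble(species = c("HPPi", "H2PPi", "MgPPi", "Mg2PPi", "KPPi", "NaPPi"),
                 kd_mM = rep(1e12, 6))
}

test_that("with effectively no binding, free ions equal totals and S is zero", {
  st <- speciate(cond_tbl(0.1, 0.2), constants = no_binding_constants())
  expect_equal(st$free_ppi_mM, 0.1, tolerance = 1e-9)
  expect_equal(st$free_mg_mM, 0.2, tolerance = 1e-9)
  expect_lt(st$s_mg2ppi_mM, 1e-12)
})

test_that("zero total PPi leaves magnesium entirely free", {
  st <- speciate(cond_tbl(0, 0.2))
  expect_equal(st$free_mg_mM, 0.2)
  expect_equal(st$free_ppi_mM, 0)
  expect_equal(st$mgppi_mM, 0)
  expect_equal(st$s_mg2ppi_mM, 0)
})

test_that("single-equilibrium case matches the closed-form quadratic", {
  # only MgPPi effectively binds (Kd = 0.01 mM); totals 0.1 / 0.2 mM give
  # x^2 - 0.31 x + 0.02 = 0, x = (0.31 - sqrt(0.0161)) / 2
  consts <- tibble::tibble(species = c("MgPPi", "Mg2PPi"), kd_mM = c(0.01, 1e12))
  x <- (0.31 - sqrt(0.31^2 - 4 * 0.02)) / 2
  st <- speciate(cond_tbl(0.1, 0.2, k = 0, na = 0), constants = consts)
  expect_equal(st$mgppi_mM, x, tolerance = 1e-6)
  expect_equal(st$free_ppi_mM, 0.1 - x, tolerance = 1e-6)
  expect_equal(st$free_mg_mM, 0.2 - x, tolerance = 1e-6)
  expect_equal(x, 0.0915574, tolerance = 1e-5)
})

test_that("solver agrees with the nested-bisection oracle on random instances", {
  set.seed(421)
  consts <- ppi_constants()
  for (i in 1:50) {
    ppi <- runif(1, 0.01, 2)
    mg <- runif(1, 0.01, 5)
    k <- runif(1, 0, 150)
    na <- runif(1, 0, 150)
    ph <- runif(1, 6, 8.5)
    st <- speciate(cond_tbl(ppi, mg, k, na, ph), constants = consts)
    orc <- oracle_speciate(ppi, mg, k, na, ph, consts)
    expect_equal(st$free_ppi_mM, unname(orc["free_ppi"]), tolerance = 1e-6)
    expect_equal(st$free_mg_mM, unname(orc["free_mg"]), tolerance = 1e-6)
    expect_equal(st$s_mg2ppi_mM, unname(orc["s_mg2ppi"]), tolerance = 1e-6)
  }
})

test_that("mass balances hold to 1e-8 relative on randomized inputs", {
  set.seed(99)
  consts <- ppi_constants()
  kd <- setNames(consts$kd_mM, consts$species)
  for (i in 1:40) {
    ppi <- runif(1, 1e-3, 3)
    mg <- runif(1, 1e-3, 6)
    k <- runif(1, 0, 200)
    na <- runif(1, 0, 200)
    ph <- runif(1, 5, 9)
    st <- speciate(cond_tbl(ppi, mg, k, na, ph), constants = consts)
    ppi_sum <- st$free_ppi_mM + st$hppi_mM + st$h2ppi_mM + st$mgppi_mM +
      st$mg2ppi_mM + st$kppi_mM + st$nappi_mM + st$mghppi_mM
    mg_sum <- st$free_mg_mM + st$mgppi_mM + 2 * st$mg2ppi_mM + st$mghppi_mM
    expect_lt(abs(ppi_sum - ppi) / ppi, 1e-8)
    expect_lt(abs(mg_sum - mg) / mg, 1e-8)
    # every mass-action relation is satisfied
    expect_equal(st$free_mg_mM * st$free_ppi_mM / st$mgppi_mM,
                 kd[["MgPPi"]], tolerance = 1e-8)
    expect_equal(st$free_mg_mM * st$mgppi_mM / st$mg2ppi_mM,
                 kd[["Mg2PPi"]], tolerance = 1e-8)
  }
})

test_that("substrate is monotone in the ionic totals", {
  mg_grid <- seq(0.05, 5, length.out = 25)
  s_mg <- vapply(mg_grid, function(mg) speciate(cond_tbl(0.2, mg))$s_mg2ppi_mM,
                 numeric(1))
  expect_true(all(diff(s_mg) >= -1e-12))

  # monotone in total PPi while Mg2+ stays in excess; once PPi depletes the
  # magnesium pool, excess ligand chelates Mg and [Mg2PPi] falls again
  ppi_grid <- seq(0.01, 1.5, length.out = 25)
  s_ppi <- vapply(ppi_grid,
                  function(p) speciate(cond_tbl(p, 10))$s_mg2ppi_mM, numeric(1))
  expect_true(all(diff(s_ppi) >= -1e-12))

  na_grid <- seq(0, 200, length.out = 21)
  s_na <- vapply(na_grid,
                 function(na) speciate(cond_tbl(0.2, 0.4, na = na))$s_mg2ppi_mM,
                 numeric(1))
  expect_true(all(diff(s_na) <= 1e-12))
})

test_that("invalid conditions and constants are rejected", {
  expect_error(speciate(cond_tbl(-0.1, 0.2)), class = "ppasekin_validation_error")
  expect_error(speciate(cond_tbl(0.1, 0.2, ph = 1)),
               class = "ppasekin_validation_error")
  expect_error(
    speciate(cond_tbl(0.1, 0.2),
             constants = tibble::tibble(species = "MgPPi", kd_mM = 0.01)),
    class = "ppasekin_validation_error")  # Mg2PPi required for substrate
  expect_error(
    speciate(cond_tbl(0.1, 0.2),
             constants = tibble::tibble(species = "MgPPi", kd_mM = -1)),
    class = "ppasekin_validation_error")
})

test_that("substrate_grid preserves order and bounds S by total PPi", {
  des <- make_design("matched_mg", ppi_totals = c(0.05, 0.1), nacl_levels = 0)
  out <- substrate_grid(des)
  expect_equal(out$ppi_total_mM, c(0.05, 0.1))
  expect_true(all(out$s_mg2ppi_mM <= out$ppi_total_mM))
  out0 <- substrate_grid(des, constants = no_binding_constants())
  expect_true(all(out0$s_mg2ppi_mM < 1e-12))
  expect_error(substrate_grid(des[0, ]), class = "ppasekin_validation_error")
})

test_that("constants round-trip through the delimited-text reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(species = c("MgPPi", "Mg2PPi"),
                                  kd_mM = c(0.004, 0.6)), path)
  expect_equal(read_constants(path)$kd_mM, c(0.004, 0.6))

  # pKa entries convert as kd_mM = 10^(3 - pka)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tkd_mM\tpka", "HPPi\t\t8.94", "MgPPi\t0.004\t",
               "Mg2PPi\t0.6\t"), path2)
  tbl <- read_constants(path2)
  expect_equal(tbl$kd_mM[tbl$species == "HPPi"], 10^(3 - 8.94))

  shipped <- system.file("extdata", "ppi_complex_constants.tsv",
                         package = "ppasekin")
  expect_equal(read_constants(shipped)$kd_mM, ppi_constants()$kd_mM,
               tolerance = 1e-12)
})
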