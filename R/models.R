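#' Rate-law parameter sets
#'
#' Constructors for the two parameterizations used throughout the package:
#' the empirical Hill equation and the two-state concerted (MWC-type)
#' allosteric rate law.
#'
#' `hill_params()` holds the maximal rate `vm` (U/mg, where 1 U = 1 umol PPi
#' hydrolysed per min), the half-saturation substrate concentration `k_half`
#' (mM) and the Hill coefficient `n_h`.
#'
#' `mwc_params()` holds `vm` (U/mg), the allosteric constant `l = [T]/[R]`
#' (dimensionless ratio of inactive to active conformers) and `k_r`, the
#' dissociation constant of substrate toward the active R state, in uM to
#' match the scale on which such constants are usually reported. Substrate
#' concentrations are handled in mM everywhere else; the uM/mM conversion
#' happens inside [mwc_rate()].
#'
#' @param vm maximal rate, U/mg; must be positive.
#' @param k_half half-saturation substrate concentration, mM; positive.
#' @param n_h Hill coefficient; positive.
#' @param l allosteric constant `[T]/[R]`; non-negative.
#' @param k_r substrate dissociation constant toward the R state, uM; positive.
#' @return A list of class `hill_params` or `mwc_params`.
#' @export
#' @examples
#' hill_params(vm = 0.41, k_half = 0.27, n_h = 3.74)
#' mwc_params(vm = 0.51, l = 17, k_r = 84)
hill_params <- function(vm, k_half, n_h) {
  check_scalar(vm, "vm", lower = 0, strict_lower = TRUE)
  check_scalar(k_half, "k_half", lower = 0, strict_lower = TRUE)
  check_scalar(n_h, "n_h", lower = 0, strict_lower = TRUE)
  structure(list(vm = vm, k_half = k_half, n_h = n_h), class = "hill_params")
}

#' @rdname hill_params
#' @export
mwc_params <- function(vm, l, k_r) {
  check_scalar(vm, "vm", lower = 0, strict_lower = TRUE)
  check_scalar(l, "l", lower = 0)
  check_scalar(k_r, "k_r", lower = 0, strict_lower = TRUE)
  structure(list(vm = vm, l = l, k_r = k_r), class = "mwc_params")
}

#' Saturation function of the two-state allosteric model
#'
#' Fractional saturation of a homodimeric enzyme that exists in an active R
#' and an inactive T conformation in equilibrium `l = [T]/[R]`, with
#' exclusive substrate binding to R (dissociation constant `k_r`) at two
#' catalytic sites, and with substrate also displacing the R/T equilibrium
#' toward R (the `l / (1 + s/k_r)^2` factor). In terms of `u = 1 + s/k_r`:
#' \deqn{\hat{Y} = \frac{u^4 - u^3}{u^4 + L}}
#' which equals the textbook form
#' \eqn{(s/K_R)(1+s/K_R) / [(1+s/K_R)^2 + L/(1+s/K_R)^2]} but is evaluated
#' without the nested quotient. `l = 0` reduces to the Michaelis-Menten
#' hyperbola with `Km = k_r`.
#'
#' @param s substrate concentration(s), same units as `k_r`; non-negative.
#' @param k_r R-state dissociation constant, same units as `s`; positive.
#' @param l allosteric constant; non-negative.
#' @return Saturation fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' mwc_saturation(s = 1, k_r = 1, l = 4)  # u = 2: (16 - 8)/(16 + 4) = 0.4
mwc_saturation <- function(s, k_r, l) {
  check_number(s, "s", lower = 0)
  check_scalar(k_r, "k_r", lower = 0, strict_lower = TRUE)
  check_scalar(l, "l", lower = 0)
  u <- 1 + s / k_r
  (u^4 - u^3) / (u^4 + l)
}

#' Evaluate the allosteric rate law
#'
#' Rate `v = vm * Yhat(s)`, with the proportionality constant between
#' `v/vm` and the saturation function fixed at 1 so that `vm` is the true
#' asymptotic rate. `s` is in mM; the `k_r` stored in `params` (uM) is
#' converted internally.
#'
#' @param s substrate concentration(s), mM; non-negative.
#' @param params an [mwc_params()] object.
#' @return Rate(s) in U/mg.
#' @export
mwc_rate <- function(s, params) {
  stopifnot(inherits(params, "mwc_params"))
  params$vm * mwc_saturation(s, params$k_r / 1000, params$l)
}

#' Evaluate the empirical Hill equation
#'
#' `v = vm * s^n_h / (k_half^n_h + s^n_h)`; `n_h = 1` is the
#' Michaelis-Menten hyperbola.
#'
#' @param s substrate concentration(s), mM; non-negative.
#' @param params a [hill_params()] object.
#' @return Rate(s) in U/mg.
#' @export
hill_rate <- function(s, params) {
  stopifnot(inherits(params, "hill_params"))
  check_number(s, "s", lower = 0)
  sn <- s^params$n_h
  out <- params$vm * sn / (params$k_half^params$n_h + sn)
  out[s == 0] <- 0
  out
}

#' Michaelis-Menten rate
#'
#' Limiting hyperbolic law used as a reference model and as the `l = 0` /
#' `n_h = 1` reduction of the other two.
#'
#' @param s substrate concentration(s), mM; non-negative.
#' @param vm maximal rate, U/mg; positive.
#' @param km Michaelis constant, mM; positive.
#' @return Rate(s) in U/mg.
#' @export
mm_rate <- function(s, vm, km) {
  check_number(s, "s", lower = 0)
  check_scalar(vm, "vm", lower = 0, strict_lower = TRUE)
  check_scalar(km, "km", lower = 0, strict_lower = TRUE)
  vm * s / (km + s)
}

#' Effective Hill coefficient of the allosteric model
#'
#' Apparent cooperativity of the saturation curve, computed from its
#' 10-90% saturation span:
#' \deqn{n_{eff} = \log(81) / \log(S_{90}/S_{10})}
#' where `S_10` and `S_90` are the substrate concentrations at 10% and 90%
#' saturation, located by root-finding on the (strictly increasing)
#' saturation function. For `l = 0` the curve is hyperbolic and
#' `n_eff = 1`; `n_eff` grows with `l` at fixed `k_r`.
#'
#' @param params an [mwc_params()] object.
#' @return The effective Hill coefficient (dimensionless).
#' @export
effective_hill <- function(params) {
  stopifnot(inherits(params, "mwc_params"))
  k_r <- params$k_r / 1000  # mM
  l <- params$l
  s_at <- function(y) {
    upper <- k_r
    while (mwc_saturation(upper, k_r, l) < y) {
      upper <- upper * 4
      if (upper > 1e12 * k_r) {
        abort("Root-finding for the saturation quantile failed to bracket.",
              class = "ppasekin_numeric_error")
      }
    }
    uniroot(function(s) mwc_saturation(s, k_r, l) - y,
            lower = 0, upper = upper, tol = 1e-14)$root
  }
  s10 <- s_at(0.1)
  s90 <- s_at(0.9)
  log(81) / log(s90 / s10)
}
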