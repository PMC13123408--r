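# Solomon-Bloembergen forward model for the paramagnetic relaxation
# enhancement (PRE) induced by a dissolved paramagnetic dopant such as a
# Gd3+ chelate. Gamma1/Gamma2 are the longitudinal/transverse PRE rates for
# a nucleus at distance r from the unpaired electron(s).

#' Define a paramagnetic electron-nucleus spin system
#'
#' Collects the parameters of the dipolar electron-nucleus relaxation
#' mechanism: the electron spin quantum number `S` (7/2 for Gd3+), the
#' electron g value, the rotational correlation time of the dopant, the
#' observed nucleus and the static field.
#'
#' @param S Electron spin quantum number; half-integer, `S >= 1/2`.
#'   Default 7/2 (Gd3+).
#' @param ge Electron g value. Default 2.00232.
#' @param tau_c Rotational correlation time in seconds. There is no universal
#'   value for a small Gd3+ chelate in a crystallisation buffer; the default
#'   of 100 ps is a plausible order of magnitude for qualitative work and
#'   should be overridden for quantitative predictions.
#' @param nucleus Observed nucleus, one of `"1H"`, `"19F"`, `"13C"`.
#' @param B0 Static magnetic field in tesla. Default 14.09 T (600 MHz 1H).
#' @return An object of class `paramagnetic_system`: a list with the input
#'   fields plus the derived Larmor frequencies `omega_I` (nuclear) and
#'   `omega_e` (electron), both in rad/s.
#' @export
#' @examples
#' sys <- paramagnetic_system(tau_c = 100e-12, nucleus = "19F")
#' pre_gamma1(sys, r = 10)
paramagnetic_system <- function(S = 7 / 2, ge = .pre_const$ge_default,
                                tau_c = 100e-12, nucleus = "19F",
                                B0 = 14.09) {
  if (!(S >= 1 / 2) || abs(2 * S - round(2 * S)) > 1e-9) {
    stop("S must be a half-integer >= 1/2", call. = FALSE)
  }
  if (!is.finite(tau_c) || tau_c <= 0) stop("tau_c must be > 0", call. = FALSE)
  if (!is.finite(B0) || B0 <= 0) stop("B0 must be > 0", call. = FALSE)
  gI <- gyromagnetic_ratio(nucleus)
  sys <- list(
    S = S, ge = ge, tau_c = tau_c, nucleus = nucleus, B0 = B0,
    omega_I = gI * B0,
    omega_e = ge * .pre_const$muB * B0 / .pre_const$hbar
  )
  class(sys) <- "paramagnetic_system"
  sys
}

#' @export
print.paramagnetic_system <- function(x, ...) {
  cat(sprintf(
    "<paramagnetic_system> S=%g ge=%.5f tau_c=%.3g s nucleus=%s B0=%.2f T\n",
    x$S, x$ge, x$tau_c, x$nucleus, x$B0))
  cat(sprintf("  omega_I=%.4g rad/s  omega_e=%.4g rad/s\n",
              x$omega_I, x$omega_e))
  invisible(x)
}

#' Lorentzian spectral density
#'
#' The motif `tau_c / (1 + omega^2 tau_c^2)` that appears in both PRE
#' expressions. Bounded above by `tau_c` (its zero-frequency value).
#'
#' @param omega Angular frequency in rad/s, `omega >= 0`. Vectorised.
#' @param tau_c Correlation time in seconds, `> 0`.
#' @return Spectral density in seconds.
#' @export
spectral_density <- function(omega, tau_c) {
  if (!is.numeric(tau_c) || any(!is.finite(tau_c)) || any(tau_c <= 0)) {
    stop("tau_c must be > 0", call. = FALSE)
  }
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  tau_c / (1 + omega^2 * tau_c^2)
}

# shared dipolar prefactor K = (mu0/4pi)^2 gI^2 ge^2 muB^2 S(S+1) / r^6
.sbm_prefactor <- function(sys, r_m) {
  cst <- .pre_const
  gI <- gyromagnetic_ratio(sys$nucleus)
  (cst$mu0 / (4 * pi))^2 * gI^2 * sys$ge^2 * cst$muB^2 *
    sys$S * (sys$S + 1) / r_m^6
}

.check_r <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("electron-nucleus distance r must be > 0", call. = FALSE)
  }
}

#' Longitudinal PRE rate (Solomon-Bloembergen)
#'
#' \deqn{\Gamma_1 = \frac{2}{15}\left(\frac{\mu_0}{4\pi}\right)^2
#'   \gamma_I^2 g_e^2 \mu_B^2 \frac{S(S+1)}{r^6}
#'   \left[\frac{3\tau_c}{1+\omega_I^2\tau_c^2} +
#'         \frac{7\tau_c}{1+\omega_e^2\tau_c^2}\right]}
#'
#' @param sys A [paramagnetic_system()].
#' @param r Electron-nucleus distance in angstrom, `> 0`. Vectorised.
#' @return Longitudinal PRE rate in s^-1.
#' @export
pre_gamma1 <- function(sys, r) {
  stopifnot(inherits(sys, "paramagnetic_system"))
  .check_r(r)
  r_m <- r * 1e-10
  K <- .sbm_prefactor(sys, r_m)
  (2 / 15) * K * (3 * spectral_density(sys$omega_I, sys$tau_c) +
                  7 * spectral_density(sys$omega_e, sys$tau_c))
}

#' Transverse PRE rate (Solomon-Bloembergen)
#'
#' \deqn{\Gamma_2 = \frac{1}{15}\left(\frac{\mu_0}{4\pi}\right)^2
#'   \gamma_I^2 g_e^2 \mu_B^2 \frac{S(S+1)}{r^6}
#'   \left[4\tau_c + \frac{3\tau_c}{1+\omega_I^2\tau_c^2} +
#'         \frac{13\tau_c}{1+\omega_e^2\tau_c^2}\right]}
#'
#' Always `>= pre_gamma1()` for the same system, since every spectral
#' density is bounded by `tau_c`.
#'
#' @inheritParams pre_gamma1
#' @return Transverse PRE rate in s^-1.
#' @export
pre_gamma2 <- function(sys, r) {
  stopifnot(inherits(sys, "paramagnetic_system"))
  .check_r(r)
  r_m <- r * 1e-10
  K <- .sbm_prefactor(sys, r_m)
  (1 / 15) * K * (4 * sys$tau_c +
                  3 * spectral_density(sys$omega_I, sys$tau_c) +
                  13 * spectral_density(sys$omega_e, sys$tau_c))
}

#' PRE prediction for a distance sweep
#'
#' Convenience wrapper evaluating both PRE rates over a vector of distances.
#'
#' @inheritParams pre_gamma1
#' @return A data.frame with columns `r_A`, `gamma1_s1`, `gamma2_s1`.
#' @export
pre_predict <- function(sys, r) {
  data.frame(r_A = r, gamma1_s1 = pre_gamma1(sys, r),
             gamma2_s1 = pre_gamma2(sys, r))
}

#' PRE ratio between two nuclei
#'
#' Ratio of the PRE for nucleus `nucleus_a` to nucleus `nucleus_b` at
#' identical distance, correlation time and field. In the regime
#' `omega_I tau_c << 1` for both nuclei this reduces to the squared ratio of
#' gyromagnetic ratios, which is why 13C PREs are much weaker than 19F PREs.
#'
#' @param nucleus_a,nucleus_b Nucleus names from the gamma table.
#' @param which `"gamma1"` or `"gamma2"`.
#' @param tau_c,B0,S,ge Spin-system parameters, as in
#'   [paramagnetic_system()].
#' @return Dimensionless ratio `Gamma(a) / Gamma(b)`.
#' @export
nucleus_scaling_ratio <- function(nucleus_a, nucleus_b, which = "gamma1",
                                  tau_c = 100e-12, B0 = 14.09,
                                  S = 7 / 2, ge = .pre_const$ge_default) {
  f <- switch(match.arg(which, c("gamma1", "gamma2")),
              gamma1 = pre_gamma1, gamma2 = pre_gamma2)
  sa <- paramagnetic_system(S = S, ge = ge, tau_c = tau_c,
                            nucleus = nucleus_a, B0 = B0)
  sb <- paramagnetic_system(S = S, ge = ge, tau_c = tau_c,
                            nucleus = nucleus_b, B0 = B0)
  f(sa, 10) / f(sb, 10)  # r cancels in the ratio
}
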