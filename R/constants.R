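# CODATA physical constants (SI units throughout the internal layer).
.pre_const <- list(
  mu0  = 4 * pi * 1e-7,          # vacuum permeability, T m / A
  muB  = 9.2740100783e-24,       # Bohr magneton, J / T
  hbar = 1.054571817e-34,        # reduced Planck constant, J s
  ge_default = 2.00232,          # free-electron g value
  gamma = c(                     # gyromagnetic ratios, rad s^-1 T^-1
    "1H"  = 2.6752218744e8,
    "19F" = 2.51815e8,
    "13C" = 6.728284e7
  )
)

#' Physical constants used by the PRE forward model
#'
#' Returns the CODATA constants the package uses internally: vacuum
#' permeability, Bohr magneton, reduced Planck constant, the free-electron g
#' value and a table of nuclear gyromagnetic ratios.
#'
#' @return A named list with elements `mu0` (T m/A), `muB` (J/T), `hbar`
#'   (J s), `ge_default` (dimensionless) and `gamma` (named numeric vector,
#'   rad s^-1 T^-1, for `"1H"`, `"19F"`, `"13C"`).
#' @export
#' @examples
#' physical_constants()$gamma[["19F"]]
physical_constants <- function() .pre_const

#' Gyromagnetic ratio of a nucleus
#'
#' @param nucleus Nucleus name: one of `"1H"`, `"19F"`, `"13C"`.
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
gyromagnetic_ratio <- function(nucleus) {
  g <- .pre_const$gamma
  if (!nucleus %in% names(g)) {
    stop("unknown nucleus '", nucleus, "'; known: ",
         paste(names(g), collapse = ", "), call. = FALSE)
  }
  unname(g[[nucleus]])
}
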