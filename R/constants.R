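# Unit system: energies and frequencies are carried in wavenumbers (cm^-1),
# time in picoseconds. With hbar = 1, a wavenumber enters dynamical phases as
# an angular frequency, so every E[cm^-1] is converted once via
# omega = 2*pi*c*E with c in cm/ps. Rates then come out directly in ps^-1.

#' Physical constants used throughout the package
#'
#' A small table of constants fixing the unit system: all user-facing energies
#' are in cm^-1, times in ps, temperatures in K.
#'
#' @return Named list with elements
#'   \item{c_cm_ps}{speed of light in cm/ps}
#'   \item{cm1_to_radps}{angular frequency (rad/ps) of a 1 cm^-1 quantum}
#'   \item{kB_cm1}{Boltzmann constant in cm^-1/K}
#' @export
#' @examples
#' lh2_constants()$kB_cm1 * 300  # thermal energy at 300 K in cm^-1
lh2_constants <- function() {
  c_cm_ps <- 2.99792458e-2  # 2.99792458e10 cm/s * 1e-12 s/ps
  list(
    c_cm_ps = c_cm_ps,
    cm1_to_radps = 2 * pi * c_cm_ps,      # 0.188365...
    kB_cm1 = 0.695034800                  # k_B / (h c), cm^-1 per K
  )
}

# internal shorthands
.cm2rad <- function() 2 * pi * 2.99792458e-2
.kB <- function() 0.695034800

# inverse temperature in ps/rad for energies expressed in rad/ps
.beta_ang <- function(T) 1 / (.cm2rad() * .kB() * T)
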