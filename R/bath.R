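# Drude-Lorentz bath model and its exponential-series machinery.
#
# Public quantities are in spectroscopic units: lambda, gamma, omega and the
# expansion rates nu_k in cm^-1, coefficients c_k in cm^-2, temperature in K.
# Time-domain evaluations take t in ps and convert wavenumbers to angular
# frequencies internally (1 cm^-1 -> 2*pi*c rad/ps), so that the
# line-broadening function g(t) is a dimensionless complex phase.

#' Drude-Lorentz bath
#'
#' Overdamped-Brownian-oscillator description of the phonon environment of one
#' chromophore: spectral density J(w) = 2*lambda*gamma*w / (w^2 + gamma^2).
#'
#' @param lambda reorganization energy, cm^-1 (>= 0)
#' @param gamma cutoff frequency (inverse bath relaxation time), cm^-1 (> 0)
#' @param T temperature, K (> 0)
#' @return object of class `lh2_bath`
#' @export
drude_lorentz_bath <- function(lambda, gamma, T = 300) {
  stopifnot(is.numeric(lambda), is.numeric(gamma), is.numeric(T))
  if (lambda < 0) stop("reorganization energy must be non-negative")
  if (gamma <= 0) stop("cutoff frequency must be positive")
  if (T <= 0) stop("temperature must be positive")
  structure(list(lambda = lambda, gamma = gamma, T = T), class = "lh2_bath")
}

#' Drude-Lorentz spectral density
#'
#' @param bath an `lh2_bath`
#' @param omega frequency grid, cm^-1 (may be negative; J is odd)
#' @return J(omega) in cm^-1
#' @export
spectral_density <- function(bath, omega) {
  stopifnot(inherits(bath, "lh2_bath"))
  2 * bath$lambda * bath$gamma * omega / (omega^2 + bath$gamma^2)
}

#' Matsubara expansion of the bath correlation function
#'
#' Expands C(t) = sum_k c_k exp(-nu_k t) for a Drude-Lorentz bath:
#' c_0 = lambda*gamma*(cot(beta*gamma/2) - i), nu_0 = gamma, and for k >= 1
#' c_k = (4*lambda*gamma/beta) * nu_k/(nu_k^2 - gamma^2) with Matsubara
#' frequencies nu_k = 2*pi*k/beta.
#'
#' @param bath an `lh2_bath`
#' @param K number of Matsubara terms retained (>= 0)
#' @return object of class `lh2_bath_expansion` with complex `c` (cm^-2),
#'   real `nu` (cm^-1), `K`, and the originating `bath`
#' @export
matsubara_expansion <- function(bath, K = 1) {
  stopifnot(inherits(bath, "lh2_bath"), K >= 0)
  kBT <- .kB() * bath$T                 # cm^-1
  beta <- 1 / kBT                      # cm
  lam <- bath$lambda; gam <- bath$gamma
  bg2 <- beta * gam / 2
  c0 <- lam * gam * (1 / tan(bg2) - 1i)
  nu <- gam
  cc <- c0
  if (K >= 1) {
    k <- seq_len(K)
    nuk <- 2 * pi * k / beta
    if (any(abs(nuk - gam) < 1e-8 * gam))
      stop("Matsubara frequency coincides with the Drude pole (nu_k = gamma); ",
           "perturb gamma by a tiny amount (e.g. 1e-6) to lift the degeneracy")
    ck <- 4 * lam * gam / beta * nuk / (nuk^2 - gam^2)
    cc <- c(cc, ck + 0i)
    nu <- c(nu, nuk)
  }
  structure(list(c = cc, nu = nu, K = K, bath = bath),
            class = "lh2_bath_expansion")
}

#' Bath correlation function from its exponential expansion
#'
#' @param expansion an `lh2_bath_expansion`
#' @param t time grid, ps (t >= 0)
#' @return complex C(t) in cm^-2
#' @export
correlation_function <- function(expansion, t) {
  stopifnot(inherits(expansion, "lh2_bath_expansion"), all(t >= 0))
  nu_ang <- expansion$nu * .cm2rad()
  drop(exp(outer(t, -nu_ang)) %*% expansion$c)
}

#' Line-broadening function g(t) and its derivatives
#'
#' Doubly integrated bath correlation function in closed form,
#' g(t) = sum_k (c_k/nu_k^2) (exp(-nu_k t) + nu_k t - 1),
#' evaluated with the retained Matsubara terms. Also returns the first and
#' second derivatives (gdot in ps^-1, gddot in ps^-2, i.e. C(t) in angular
#' units), which enter modified-Redfield rates.
#'
#' @param expansion an `lh2_bath_expansion`
#' @param t time grid, ps, starting at 0
#' @return object of class `lh2_g` with fields `t`, `g`, `gdot`, `gddot`
#'   (complex vectors) and `lambda_ang`, the reorganization energy in rad/ps
#' @export
line_broadening <- function(expansion, t) {
  stopifnot(inherits(expansion, "lh2_bath_expansion"))
  if (t[1] != 0) stop("time grid must start at 0")
  nu_ang <- expansion$nu * .cm2rad()         # rad/ps
  c_ang <- expansion$c * .cm2rad()^2         # rad^2/ps^2
  E <- exp(outer(t, -nu_ang))                # nt x nk
  g <- drop((E + outer(t, nu_ang) - 1) %*% (c_ang / nu_ang^2))
  gdot <- drop((1 - E) %*% (c_ang / nu_ang))
  gddot <- drop(E %*% c_ang)
  structure(list(t = t, g = g, gdot = gdot, gddot = gddot,
                 lambda_ang = expansion$bath$lambda * .cm2rad()),
            class = "lh2_g")
}

# Direct quadrature of the integral definition of C(t) (coth kernel); an
# independent check of the Matsubara expansion used in tests.
correlation_function_quadrature <- function(bath, t, omega_max = 5000,
                                            n_omega = 20000) {
  w <- seq(1e-6, omega_max, length.out = n_omega)     # cm^-1
  J <- spectral_density(bath, w)
  beta <- 1 / (.kB() * bath$T)
  coth <- 1 / tanh(beta * w / 2)
  w_ang <- w * .cm2rad()
  dw <- w[2] - w[1]
  vapply(t, function(tt) {
    ker <- J * (coth * cos(w_ang * tt) - 1i * sin(w_ang * tt))
    (sum(ker) - 0.5 * (ker[1] + ker[length(ker)])) * dw / pi
  }, complex(1))
}
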