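# Electronic and environmental parameter sets for LH2 in its three modelled
# surroundings. One set is one column of the published parameter table:
# per-ring site energies, the four tabulated nearest-neighbour coupling
# classes, dipole constants, Drude-Lorentz bath parameters and Gaussian
# static-disorder widths.

.ENV_LABELS <- c("detergent", "POPC", "DOPC")

.ENV_TABLE <- list(
  detergent = list(
    label = "detergent",
    E_B800 = 12540, E_B850a = 12390, E_B850b = 12390,
    V_B800 = -19, V_a1b1 = 315, V_a2b1 = 245, V_B800a2 = 32,
    C_B800 = 230000, C_B850 = 348000,
    lambda_B800 = 35, lambda_B850 = 160,
    gamma_B800 = 35, gamma_B850 = 53,
    sigma_B800 = 50, sigma_B850 = 220,
    T = 300
  ),
  POPC = list(
    label = "POPC",
    E_B800 = 13021, E_B850a = 12799, E_B850b = 12806,
    V_B800 = -33, V_a1b1 = 339, V_a2b1 = 317, V_B800a2 = 42,
    C_B800 = 230000, C_B850 = 348000,
    lambda_B800 = 40, lambda_B850 = 140,
    gamma_B800 = 100, gamma_B850 = 100,
    sigma_B800 = 40, sigma_B850 = 270,
    T = 300
  ),
  DOPC = list(
    label = "DOPC",
    E_B800 = 13783, E_B850a = 13527, E_B850b = 13556,
    V_B800 = -34, V_a1b1 = 298, V_a2b1 = 266, V_B800a2 = 38,
    C_B800 = 230000, C_B850 = 348000,
    lambda_B800 = 40, lambda_B850 = 140,
    gamma_B800 = 100, gamma_B850 = 100,
    sigma_B800 = 40, sigma_B850 = 270,
    T = 300
  )
)

#' Environment parameter set for an LH2 model
#'
#' Returns the full electronic/environmental parameter set for LH2 isolated in
#' detergent or embedded in a POPC or DOPC membrane. Site energies `E_*`,
#' nearest-neighbour couplings (`V_B800`: B800-B800; `V_a1b1`/`V_a2b1`:
#' intra-/inter-dimer B850; `V_B800a2`: B800 to nearest B850 alpha), the
#' dipole-strength constants `C_*` (Angstrom^3 cm^-1) used for all remaining
#' couplings in the point-dipole approximation, the Drude-Lorentz
#' reorganization energies `lambda_*` and cutoff frequencies `gamma_*`, and
#' the static-disorder standard deviations `sigma_*` are all in cm^-1;
#' temperature `T` in K.
#'
#' @param label one of `"detergent"`, `"POPC"`, `"DOPC"`
#' @param ... named overrides for individual fields (e.g. `sigma_B850 = 100`)
#' @return object of class `lh2_params` (a named list, fields as above)
#' @export
#' @examples
#' p <- environment_parameters("detergent")
#' p$V_a1b1  # 315 cm^-1
environment_parameters <- function(label = c("detergent", "POPC", "DOPC"), ...) {
  label <- match.arg(label)
  p <- .ENV_TABLE[[label]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "lh2_params"
  validate_parameters(p)
  p
}

#' @export
print.lh2_params <- function(x, ...) {
  cat("LH2 parameter set [", x$label, "]\n", sep = "")
  cat(sprintf("  site energies (cm^-1): B800 %g, B850a %g, B850b %g\n",
              x$E_B800, x$E_B850a, x$E_B850b))
  cat(sprintf("  NN couplings  (cm^-1): V_B800 %g, V_a1b1 %g, V_a2b1 %g, V_B800a2 %g\n",
              x$V_B800, x$V_a1b1, x$V_a2b1, x$V_B800a2))
  cat(sprintf("  bath: lambda %g/%g, gamma %g/%g cm^-1; sigma %g/%g cm^-1; T %g K\n",
              x$lambda_B800, x$lambda_B850, x$gamma_B800, x$gamma_B850,
              x$sigma_B800, x$sigma_B850, x$T))
  invisible(x)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "lh2_params"))
  pos <- c("lambda_B800", "lambda_B850", "gamma_B800", "gamma_B850",
           "sigma_B800", "sigma_B850", "T", "C_B800", "C_B850")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]))
      stop("parameter ", f, " must be a single number")
  }
  if (p$T <= 0) stop("temperature must be positive")
  if (p$gamma_B800 <= 0 || p$gamma_B850 <= 0) stop("cutoff frequencies must be positive")
  if (p$lambda_B800 < 0 || p$lambda_B850 < 0) stop("reorganization energies must be non-negative")
  if (p$sigma_B800 < 0 || p$sigma_B850 < 0) stop("disorder widths must be non-negative")
  invisible(p)
}

# per-ring lookups used when assembling Hamiltonians / baths
.ring_site_energy <- function(p, ring_class) {
  switch(ring_class,
         B800 = p$E_B800, B850a = p$E_B850a, B850b = p$E_B850b,
         stop("unknown ring class: ", ring_class))
}

.ring_C <- function(p, ring_class) {
  if (ring_class == "B800") p$C_B800 else p$C_B850
}

.ring_sigma <- function(p, ring_class) {
  if (ring_class == "B800") p$sigma_B800 else p$sigma_B850
}
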