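# Exciton delocalization measures and their disorder-ensemble statistics.
#
# For a pure exciton |alpha> = sum_i C_i |i>, the l1-norm of coherence of its
# site-basis density matrix is Cl1 = sum_{i != j} |C_i C_j| = (sum_i |C_i|)^2 - 1
# and the inverse participation ratio is IPR = 1 / sum_i |C_i|^4.

.check_normalized <- function(state, tol = 1e-8) {
  n2 <- sum(Mod(state)^2)
  if (abs(n2 - 1) > tol)
    stop("state vector is not normalized (|norm^2 - 1| = ",
         format(abs(n2 - 1)), ")")
  invisible(state)
}

#' l1-norm of coherence of an exciton state
#'
#' @param state normalized coefficient vector (site basis)
#' @return Cl1, dimensionless in [0, N-1]
#' @export
l1_coherence <- function(state) {
  .check_normalized(state)
  sum(Mod(state))^2 - 1
}

#' Inverse participation ratio of an exciton state
#'
#' @param state normalized coefficient vector (site basis)
#' @return IPR, dimensionless in [1, N]
#' @export
ipr <- function(state) {
  .check_normalized(state)
  1 / sum(Mod(state)^4)
}

#' Disorder-ensemble delocalization statistics
#'
#' Draws `n_realizations` of Gaussian static disorder for the full 27-site
#' Hamiltonian, diagonalizes the B800 and B850 ring blocks of each
#' realization, and averages Cl1 and IPR per exciton label. The B850 manifold
#' averages split the 18 states at the published dividing line: the 9 lowest
#' (k = 0..+-4, "low") versus the 9 highest (k = -+5..+-8, 9, "high").
#'
#' @param params an `lh2_params`
#' @param n_realizations ensemble size (>= 1)
#' @param seed master seed
#' @param geometry optional `lh2_geometry` (defaults to the calibrated C9 ring)
#' @return list with `per_label` (data frame: ring, label, mean/rounded Cl1 and
#'   IPR, ensemble s.d.), `manifolds` (B850 high/low and overall means),
#'   `b800_average`, and metadata (`n`, `seed`, `label`)
#' @export
ensemble_delocalization <- function(params, n_realizations = 1000, seed = 1,
                                    geometry = generate_c9_geometry()) {
  stopifnot(n_realizations >= 1)
  h0 <- build_site_hamiltonian(geometry, params, "full")
  i800 <- which(h0$block_tags == "B800")
  i850 <- which(h0$block_tags != "B800")
  h800 <- .subset_hamiltonian(h0, i800, "B800")
  h850 <- .subset_hamiltonian(h0, i850, "B850")
  acc <- function(n) list(cl1 = matrix(0, n_realizations, n),
                          ipr = matrix(0, n_realizations, n))
  a800 <- acc(9); a850 <- acc(18)
  for (r in seq_len(n_realizations)) {
    hd <- apply_disorder(h0, seed, r)
    h800$H <- hd$H[i800, i800]; h850$H <- hd$H[i850, i850]
    e800 <- diagonalize_and_label(h800)
    e850 <- diagonalize_and_label(h850)
    cabs800 <- abs(e800$coefficients); cabs850 <- abs(e850$coefficients)
    a800$cl1[r, ] <- colSums(cabs800)^2 - 1
    a800$ipr[r, ] <- 1 / colSums(cabs800^4)
    a850$cl1[r, ] <- colSums(cabs850)^2 - 1
    a850$ipr[r, ] <- 1 / colSums(cabs850^4)
  }
  lab800 <- paste0("D=", 0:8)
  k850 <- .b850_labels()
  lab850 <- paste0("k=", ifelse(k850 > 0 & k850 < 9, paste0("+", k850), k850))
  per_label <- rbind(
    data.frame(ring = "B800", label = lab800, rank = 1:9,
               Cl1 = colMeans(a800$cl1), IPR = colMeans(a800$ipr),
               Cl1_sd = apply(a800$cl1, 2, stats::sd),
               IPR_sd = apply(a800$ipr, 2, stats::sd)),
    data.frame(ring = "B850", label = lab850, rank = 1:18,
               Cl1 = colMeans(a850$cl1), IPR = colMeans(a850$ipr),
               Cl1_sd = apply(a850$cl1, 2, stats::sd),
               IPR_sd = apply(a850$ipr, 2, stats::sd)))
  per_label$Cl1_rounded <- round(per_label$Cl1)
  per_label$IPR_rounded <- round(per_label$IPR)
  low <- per_label$ring == "B850" & per_label$rank <= 9
  high <- per_label$ring == "B850" & per_label$rank > 9
  manifolds <- data.frame(
    manifold = c("B850_low", "B850_high", "B850_all"),
    Cl1 = c(mean(per_label$Cl1[low]), mean(per_label$Cl1[high]),
            mean(per_label$Cl1[per_label$ring == "B850"])),
    IPR = c(mean(per_label$IPR[low]), mean(per_label$IPR[high]),
            mean(per_label$IPR[per_label$ring == "B850"])))
  list(per_label = per_label,
       manifolds = manifolds,
       b800_average = c(Cl1 = mean(per_label$Cl1[per_label$ring == "B800"]),
                        IPR = mean(per_label$IPR[per_label$ring == "B800"])),
       n = n_realizations, seed = seed, label = params$label)
}

# internal: reuse a hamiltonian skeleton for a block
.subset_hamiltonian <- function(h, idx, scope) {
  structure(list(H = h$H[idx, idx, drop = FALSE],
                 site_order = h$site_order[idx],
                 block_tags = h$block_tags[idx],
                 geometry = h$geometry[idx, ],
                 params = h$params, scope = scope),
            class = "lh2_hamiltonian")
}

#' Electronic figure of merit for a donor-acceptor exciton pair
#'
#' Combines the inter-ring nearest-neighbour electronic coupling with the
#' geometric-mean delocalization of the donor (B800) and acceptor (B850)
#' excitons of the dominant transfer pathway. Uses unrounded ensemble means.
#'
#' @param mean_Cl1_donor,mean_Cl1_acceptor ensemble-mean Cl1 of the pair
#' @param mean_IPR_donor,mean_IPR_acceptor ensemble-mean IPR of the pair
#' @param V_B800a2 B800-B850alpha nearest-neighbour coupling, cm^-1
#' @return named numeric: `fom_Cl1` = sqrt(Cl1_D * Cl1_A) * V, `fom_IPR` =
#'   sqrt(IPR_D * IPR_A) * V, `geom_Cl1` = sqrt(Cl1_D * Cl1_A)
#' @export
figure_of_merit <- function(mean_Cl1_donor, mean_Cl1_acceptor,
                            mean_IPR_donor, mean_IPR_acceptor, V_B800a2) {
  stopifnot(mean_Cl1_donor > 0, mean_Cl1_acceptor > 0,
            mean_IPR_donor > 0, mean_IPR_acceptor > 0)
  gc <- sqrt(mean_Cl1_donor * mean_Cl1_acceptor)
  gi <- sqrt(mean_IPR_donor * mean_IPR_acceptor)
  c(fom_Cl1 = gc * V_B800a2, fom_IPR = gi * V_B800a2, geom_Cl1 = gc)
}
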