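# Generalized Forster theory for B800 -> B850 exciton energy transfer.
#
# Per disorder realization: K_GFT = sum_{alpha, beta} P_alpha |V_alpha,beta|^2
# O_alpha,beta, with donor excitons alpha from the B800 block, acceptors beta
# from the B850 block, thermal donor weights P_alpha, exciton couplings from
# the inter-ring coupling block, and spectral overlaps of cumulant lineshapes
# damped by modified-Redfield lifetimes.
#
# Lineshape conventions (second-order cumulant, site baths identical within a
# ring, exciton weight w_a = sum_i C_ia^4):
#   absorption:   D_b(w)  = 2 Re Int_0^inf e^{i w t} e^{-i w_b t - w_b g(t) - t/tau_b} dt
#   fluorescence: Dt_a(w) = 2 Re Int_0^inf e^{i w t} e^{-i (w_a - 2 lambda_a) t
#                               - w_a g*(t) - t/tau_a} dt,  lambda_a = w_a lambda
# so that absorption sits blue of fluorescence, the two straddle w - lambda_a
# symmetrically in the Gaussian limit, and a monomer reproduces the exact
# independent-boson lineshape. The spectral overlap follows by Parseval:
#   O_ab = 2 Re Int_0^inf e^{i (w_ab - 2 lambda_a) t} e^{-(g_a + g_b)(t)}
#              e^{-(1/tau_a + 1/tau_b) t} dt,   w_ab = w_a - w_b.

# ---- internal: modified-Redfield rates for one ring ------------------------

# E_ang: exciton energies (rad/ps); C: real orthonormal coefficient matrix;
# gl: line-broadening list (g, gdot, gddot on uniform grid t); lam_ang: site
# reorganization energy (rad/ps). Returns N x N matrix k[b, a] = rate b -> a
# (ps^-1), zero diagonal. Derived by second-order cumulant expansion around
# the exciton-diagonal bath coupling:
#   k(b->a) = 2 Re Int dt exp[i(D - 2 lam (w_b - f2)) t - (w_a + w_b - 2 f2) g]
#             x { f2 gddot + (2 lam f3b + i (f3a - f3b) gdot)^2 }
# with f2 = sum_i C_ia^2 C_ib^2, f3a = sum_i C_ia^3 C_ib, f3b = sum_i C_ia C_ib^3.
.mr_rates <- function(E_ang, C, gl, lam_ang, dt) {
  N <- length(E_ang)
  C2 <- C^2
  W4 <- colSums(C2^2)
  F2 <- crossprod(C2)                   # F2[a,b] = sum_i C_ia^2 C_ib^2
  F3 <- crossprod(C, C * C2)            # F3[a,b] = sum_i C_ia C_ib^3
  ii <- which(matrix(TRUE, N, N) & !diag(N))
  ia <- ((ii - 1) %% N) + 1             # acceptor (row)
  ib <- ((ii - 1) %/% N) + 1            # donor (column)
  f2 <- F2[ii]
  f3b <- F3[ii]                         # sum C_ia C_ib^3
  f3a <- F3[cbind(ib, ia)]              # sum C_ia^3 C_ib
  phase <- (E_ang[ib] - E_ang[ia]) - 2 * lam_ang * (W4[ib] - f2)
  damp <- W4[ia] + W4[ib] - 2 * f2
  t <- gl$t
  Ex <- exp(outer(1i * phase, t) - outer(damp, gl$g))
  pref <- outer(f2, gl$gddot) + (outer(2 * lam_ang * f3b, rep(1, length(t))) +
                                   outer(1i * (f3a - f3b), gl$gdot))^2
  x <- Ex * pref
  val <- 2 * (Re(rowSums(x)) - 0.5 * Re(x[, 1] + x[, ncol(x)])) * dt
  K <- matrix(0, N, N)
  K[cbind(ib, ia)] <- pmax(val, 0)      # k[b, a]: b -> a; clip mR negativity
  K
}

#' Modified-Redfield relaxation rates and lifetimes for one ring
#'
#' Intra-ring exciton relaxation rates from modified Redfield theory (the
#' exciton-diagonal system-bath coupling treated nonperturbatively through
#' line-broadening functions, the off-diagonal part to second order), and the
#' resulting exciton lifetimes tau_a = 1 / sum_b k(a -> b).
#'
#' @param basis an `lh2_excitons` for a single ring
#' @param bath an `lh2_bath` shared by the ring's sites
#' @param K Matsubara terms (default 1)
#' @param t_max,dt integration grid, ps
#' @param tau_max lifetime cap, ps (applied to excitons with negligible decay)
#' @return list with `rates` (N x N matrix, `rates[b, a]` = rate b -> a in
#'   ps^-1) and `tau` (lifetimes, ps)
#' @export
modified_redfield_lifetimes <- function(basis, bath, K = 1,
                                        t_max = 2, dt = 0.002, tau_max = 1e4) {
  stopifnot(inherits(basis, "lh2_excitons"), inherits(bath, "lh2_bath"))
  ex <- matsubara_expansion(bath, K)
  t <- seq(0, t_max, by = dt)
  gl <- line_broadening(ex, t)
  rates <- .mr_rates(basis$energies * .cm2rad(), basis$coefficients, gl,
                     bath$lambda * .cm2rad(), dt)
  tot <- rowSums(rates)
  tau <- 1 / pmax(tot, 1 / tau_max)
  list(rates = rates, tau = tau)
}

#' Exciton couplings between donor and acceptor aggregates
#'
#' V_alpha,beta = sum_{i in D, j in A} C_i,alpha C_j,beta V_ij: the bilinear
#' transform of the inter-aggregate coupling block into the exciton bases.
#'
#' @param donor_basis,acceptor_basis `lh2_excitons` for disjoint site sets
#' @param inter_V coupling block (n_donor x n_acceptor, cm^-1)
#' @return matrix of V_alpha,beta in cm^-1
#' @export
exciton_coupling <- function(donor_basis, acceptor_basis, inter_V) {
  stopifnot(inherits(donor_basis, "lh2_excitons"),
            inherits(acceptor_basis, "lh2_excitons"))
  if (length(intersect(donor_basis$site_order, acceptor_basis$site_order)))
    stop("donor and acceptor site sets overlap")
  crossprod(donor_basis$coefficients, inter_V %*% acceptor_basis$coefficients)
}

#' Exciton-level environmental parameters
#'
#' Exciton reorganization energies lambda_aaaa = sum_i |C_ia|^4 lambda_i and
#' line-broadening functions g_aaaa(t) = sum_i |C_ia|^4 g_i(t).
#'
#' @param basis an `lh2_excitons`
#' @param site_lambda per-site reorganization energies (cm^-1), recycled if
#'   scalar
#' @param site_g per-site line-broadening functions: a complex matrix with one
#'   column per site (or a single vector shared by all sites)
#' @return list with `lambda` (per exciton, cm^-1) and `g` (matrix, one column
#'   per exciton)
#' @export
exciton_env_params <- function(basis, site_lambda, site_g) {
  stopifnot(inherits(basis, "lh2_excitons"))
  N <- nrow(basis$coefficients)
  w <- basis$coefficients^4
  site_lambda <- rep_len(site_lambda, N)
  if (is.null(dim(site_g))) site_g <- matrix(site_g, length(site_g), N)
  list(lambda = drop(crossprod(w, site_lambda)), g = site_g %*% w)
}

# ---- lineshapes ------------------------------------------------------------

.half_fourier <- function(x, dt, pad_factor = 4) {
  n <- length(x)
  N <- 2^ceiling(log2(n * pad_factor))
  xp <- c(x, rep(0, N - n))
  X <- stats::fft(xp, inverse = TRUE)      # sum x_n e^{+2 pi i j n / N}
  D <- 2 * dt * Re(X) - dt * Re(x[1])
  om <- 2 * pi * (seq_len(N) - 1) / (N * dt)    # rad/ps
  om[om > pi / dt] <- om[om > pi / dt] - 2 * pi / dt
  ord <- order(om)
  list(omega_cm = om[ord] / .cm2rad(), D = D[ord])
}

.lineshape_kernel <- function(type, omega_cm, w_weight, gl, tau) {
  om <- omega_cm * .cm2rad()
  if (type == "absorption") {
    exp(-1i * om * gl$t - w_weight * gl$g - gl$t / tau)
  } else {
    exp(-1i * (om - 2 * w_weight * gl$lambda_ang) * gl$t -
          w_weight * Conj(gl$g) - gl$t / tau)
  }
}

#' Cumulant absorption lineshape of one exciton
#'
#' Area-normalized so that (1/2pi) Int D(w) dw = 1 (up to grid error). The
#' peak lies between omega - lambda_exc (fast bath) and omega (slow bath),
#' i.e. never more than the exciton reorganization energy below the vertical
#' energy and always blue of the matching fluorescence line.
#'
#' @param omega_cm exciton (vertical) energy, cm^-1
#' @param w_weight participation weight sum_i C^4 scaling the ring bath
#' @param gl an `lh2_g` line-broadening object (its grid sets resolution)
#' @param tau lifetime, ps (enters as e^{-t/tau} damping)
#' @return list with `omega_cm`, `D` (ps), and `peak_cm`
#' @export
absorption_lineshape <- function(omega_cm, w_weight, gl, tau = Inf) {
  dt <- gl$t[2] - gl$t[1]
  if (dt * omega_cm * .cm2rad() > pi)
    stop("time grid too coarse for this transition energy (Nyquist violated)")
  x <- .lineshape_kernel("absorption", omega_cm, w_weight, gl, tau)
  hf <- .half_fourier(x, dt)
  hf$peak_cm <- hf$omega_cm[which.max(hf$D)]
  hf
}

#' Cumulant fluorescence lineshape of one exciton
#'
#' As [absorption_lineshape()], centred at omega - 2*lambda_exc with the
#' conjugate line-broadening function, so the emission peak is Stokes-shifted
#' red of the absorption peak.
#'
#' @inheritParams absorption_lineshape
#' @return list with `omega_cm`, `D` (ps), and `peak_cm`
#' @export
fluorescence_lineshape <- function(omega_cm, w_weight, gl, tau = Inf) {
  dt <- gl$t[2] - gl$t[1]
  if (dt * omega_cm * .cm2rad() > pi)
    stop("time grid too coarse for this transition energy (Nyquist violated)")
  x <- .lineshape_kernel("fluorescence", omega_cm, w_weight, gl, tau)
  hf <- .half_fourier(x, dt)
  hf$peak_cm <- hf$omega_cm[which.max(hf$D)]
  hf
}

#' Spectral overlap of a donor fluorescence and acceptor absorption line
#'
#' Time-domain product form (exact Parseval pairing of the two cumulant
#' lineshapes):
#' O = 2 Re Int exp[i(w_D - w_A - 2 lambda_D) t - (g_D + g_A)(t) - Gamma t] dt.
#'
#' @param omega_donor_cm,omega_acceptor_cm exciton energies, cm^-1
#' @param w_donor,w_acceptor participation weights
#' @param gl_donor,gl_acceptor `lh2_g` objects on a common time grid
#' @param tau_donor,tau_acceptor lifetimes, ps
#' @return overlap in ps (1/(rad/ps) units consistent with |V| in rad/ps)
#' @export
spectral_overlap <- function(omega_donor_cm, omega_acceptor_cm,
                             w_donor, w_acceptor, gl_donor, gl_acceptor,
                             tau_donor = Inf, tau_acceptor = Inf) {
  if (length(gl_donor$t) != length(gl_acceptor$t) ||
      any(abs(gl_donor$t - gl_acceptor$t) > 1e-12))
    stop("donor and acceptor line-broadening grids differ")
  t <- gl_donor$t
  dt <- t[2] - t[1]
  gap <- (omega_donor_cm - omega_acceptor_cm) * .cm2rad() -
    2 * w_donor * gl_donor$lambda_ang
  x <- exp(1i * gap * t - (w_donor * gl_donor$g + w_acceptor * gl_acceptor$g) -
             (1 / tau_donor + 1 / tau_acceptor) * t)
  max(2 * (Re(sum(x)) - 0.5 * Re(x[1] + x[length(x)])) * dt, 0)
}

# frequency-domain route (Eq.-25 style): (1/2pi) Int Dt_D(w) D_A(w) dw,
# used as the dual-representation cross-check of `spectral_overlap`
spectral_overlap_frequency <- function(omega_donor_cm, omega_acceptor_cm,
                                       w_donor, w_acceptor,
                                       gl_donor, gl_acceptor,
                                       tau_donor = Inf, tau_acceptor = Inf) {
  fd <- fluorescence_lineshape(omega_donor_cm, w_donor, gl_donor, tau_donor)
  fa <- absorption_lineshape(omega_acceptor_cm, w_acceptor, gl_acceptor, tau_acceptor)
  dw <- (fd$omega_cm[2] - fd$omega_cm[1]) * .cm2rad()
  sum(fd$D * fa$D) * dw / (2 * pi)
}

# ---- per-realization GFT engine --------------------------------------------

#' Precompute a generalized-Forster engine for one environment
#'
#' Bundles the disorder-free 27-site Hamiltonian, ring bath line-broadening
#' grids and integration settings so that per-realization rates are cheap.
#'
#' @param params an `lh2_params`
#' @param geometry an `lh2_geometry`
#' @param K Matsubara terms in the bath expansion (default 1)
#' @param t_max_overlap,dt_overlap spectral-overlap grid, ps
#' @param t_max_mr,dt_mr modified-Redfield grid, ps
#' @param tau_max lifetime cap, ps
#' @return an `lh2_gft_engine`
#' @export
gft_engine <- function(params, geometry = generate_c9_geometry(), K = 1,
                       t_max_overlap = 1.2, dt_overlap = 0.001,
                       t_max_mr = 1.2, dt_mr = 0.002, tau_max = 1e4) {
  h0 <- build_site_hamiltonian(geometry, params, "full")
  i800 <- which(h0$block_tags == "B800")
  i850 <- which(h0$block_tags != "B800")
  b800 <- drude_lorentz_bath(params$lambda_B800, params$gamma_B800, params$T)
  b850 <- drude_lorentz_bath(params$lambda_B850, params$gamma_B850, params$T)
  e800 <- matsubara_expansion(b800, K)
  e850 <- matsubara_expansion(b850, K)
  t_ov <- seq(0, t_max_overlap, by = dt_overlap)
  t_mr <- seq(0, t_max_mr, by = dt_mr)
  structure(list(
    params = params, geometry = geometry, h0 = h0,
    i800 = i800, i850 = i850,
    gl800_ov = line_broadening(e800, t_ov), gl850_ov = line_broadening(e850, t_ov),
    gl800_mr = line_broadening(e800, t_mr), gl850_mr = line_broadening(e850, t_mr),
    lam800_ang = params$lambda_B800 * .cm2rad(),
    lam850_ang = params$lambda_B850 * .cm2rad(),
    dt_ov = dt_overlap, dt_mr = dt_mr,
    kBT_cm = .kB() * params$T, tau_max = tau_max, K = K),
    class = "lh2_gft_engine")
}

#' One disorder realization of the generalized-Forster rate
#'
#' Applies Gaussian static disorder realization `realization` of stream
#' `seed` to the 27-site Hamiltonian, diagonalizes the B800/B850 blocks,
#' computes modified-Redfield lifetimes, thermal donor weights, exciton
#' couplings and spectral overlaps, and returns the total rate with the full
#' 9 x 18 pathway decomposition.
#'
#' @param engine an `lh2_gft_engine`
#' @param seed master seed
#' @param realization realization index (>= 1)
#' @return list: `K_GFT` (ps^-1), `P` (donor thermal weights), `k` (9 x 18
#'   pathway rates, ps^-1), `V2_cm2` (squared exciton couplings, cm^-2), `O`
#'   (overlaps, ps), `E_B800`, `E_B850` (cm^-1), `tau_B800`, `tau_B850` (ps),
#'   `Cl1_B800`, `Cl1_B850`
#' @export
gft_realization <- function(engine, seed, realization = 1) {
  stopifnot(inherits(engine, "lh2_gft_engine"))
  hd <- apply_disorder(engine$h0, seed, realization)
  H <- hd$H
  i8 <- engine$i800; i5 <- engine$i850
  es8 <- eigen(H[i8, i8], symmetric = TRUE)
  es5 <- eigen(H[i5, i5], symmetric = TRUE)
  o8 <- order(es8$values); o5 <- order(es5$values)
  E8 <- es8$values[o8]; C8 <- es8$vectors[, o8, drop = FALSE]
  E5 <- es5$values[o5]; C5 <- es5$vectors[, o5, drop = FALSE]
  cm <- .cm2rad()
  # modified-Redfield lifetimes per ring
  r8 <- .mr_rates(E8 * cm, C8, engine$gl800_mr, engine$lam800_ang, engine$dt_mr)
  r5 <- .mr_rates(E5 * cm, C5, engine$gl850_mr, engine$lam850_ang, engine$dt_mr)
  tau8 <- 1 / pmax(rowSums(r8), 1 / engine$tau_max)
  tau5 <- 1 / pmax(rowSums(r5), 1 / engine$tau_max)
  # exciton couplings (cm^-1) and thermal donor weights
  Vab <- crossprod(C8, H[i8, i5] %*% C5)
  P <- exp(-(E8 - min(E8)) / engine$kBT_cm)
  P <- P / sum(P)
  # spectral overlaps, vectorised over the 9 x 18 pathway grid
  w8 <- colSums(C8^4); w5 <- colSums(C5^4)
  t <- engine$gl800_ov$t
  np <- length(E8) * length(E5)
  ia <- rep(seq_along(E8), times = length(E5))
  ibt <- rep(seq_along(E5), each = length(E8))
  gap <- (E8[ia] - E5[ibt]) * cm - 2 * w8[ia] * engine$lam800_ang
  Gam <- 1 / tau8[ia] + 1 / tau5[ibt]
  Ex <- exp(outer(1i * gap - Gam, t) -
              outer(w8[ia], engine$gl800_ov$g) - outer(w5[ibt], engine$gl850_ov$g))
  O <- 2 * (Re(rowSums(Ex)) - 0.5 * Re(Ex[, 1] + Ex[, ncol(Ex)])) * engine$dt_ov
  O <- pmax(O, 0)
  O <- matrix(O, length(E8), length(E5))
  k <- (Vab * cm)^2 * O
  K <- sum(P * k)
  list(K_GFT = K, P = P, k = k, V2_cm2 = Vab^2, O = O,
       E_B800 = E8, E_B850 = E5, tau_B800 = tau8, tau_B850 = tau5,
       Cl1_B800 = colSums(abs(C8))^2 - 1, Cl1_B850 = colSums(abs(C5))^2 - 1,
       realization = realization)
}

#' Disorder ensemble of generalized-Forster rates
#'
#' Seeded, order-independent ensemble (realization r depends only on
#' `(seed, offset + r)`), with per-pathway accumulation for the dominant
#' pathway analysis.
#'
#' @param params an `lh2_params`
#' @param n number of realizations
#' @param seed master seed
#' @param geometry an `lh2_geometry`
#' @param engine optionally a prebuilt `lh2_gft_engine` (overrides
#'   `params`/`geometry`)
#' @param offset realization-index offset (for splitting ensembles across
#'   invocations)
#' @param pathways accumulate per-pathway means? (default TRUE)
#' @return object of class `lh2_rate_ensemble`: `K` (per-realization rates,
#'   ps^-1), `mean`, `sd`, `n`, and if requested `pathway_means` (data frame)
#' @export
rate_ensemble <- function(params, n, seed = 1,
                          geometry = generate_c9_geometry(),
                          engine = NULL, offset = 0, pathways = TRUE) {
  stopifnot(n >= 1)
  if (is.null(engine)) engine <- gft_engine(params, geometry)
  Kv <- numeric(n)
  if (pathways) {
    acc_pk <- matrix(0, 9, 18); acc_k <- matrix(0, 9, 18)
    acc_v2 <- matrix(0, 9, 18); acc_o <- matrix(0, 9, 18)
    acc_o2 <- matrix(0, 9, 18)
    acc_cl18 <- numeric(9); acc_cl15 <- numeric(18)
  }
  for (r in seq_len(n)) {
    g <- gft_realization(engine, seed, offset + r)
    Kv[r] <- g$K_GFT
    if (pathways) {
      acc_pk <- acc_pk + g$P * g$k
      acc_k <- acc_k + g$k
      acc_v2 <- acc_v2 + g$V2_cm2
      acc_o <- acc_o + g$O
      acc_o2 <- acc_o2 + g$O^2
      acc_cl18 <- acc_cl18 + g$Cl1_B800
      acc_cl15 <- acc_cl15 + g$Cl1_B850
    }
  }
  out <- list(K = Kv, mean = mean(Kv), sd = if (n > 1) stats::sd(Kv) else NA_real_,
              n = n, seed = seed, offset = offset, label = engine$params$label)
  if (n == 1) out$sd_note <- "ensemble s.d. undefined for n = 1"
  if (pathways) {
    lab8 <- paste0("D=", 0:8)
    k850 <- .b850_labels()
    lab5 <- paste0("k=", ifelse(k850 > 0 & k850 < 9, paste0("+", k850), k850))
    df <- data.frame(
      donor = rep(lab8, times = 18),
      acceptor = rep(lab5, each = 9),
      acceptor_rank = rep(seq_len(18), each = 9),
      Pk = as.vector(acc_pk) / n,
      k = as.vector(acc_k) / n,
      V2_cm2 = as.vector(acc_v2) / n,
      O = as.vector(acc_o) / n,
      O_sd = sqrt(pmax(as.vector(acc_o2) / n - (as.vector(acc_o) / n)^2, 0) *
                    n / max(n - 1, 1)),
      Cl1_donor = rep(acc_cl18 / n, times = 18),
      Cl1_acceptor = rep(acc_cl15 / n, each = 9))
    out$pathway_means <- df
  }
  class(out) <- "lh2_rate_ensemble"
  out
}

#' @export
print.lh2_rate_ensemble <- function(x, ...) {
  cat(sprintf("GFT rate ensemble [%s]: n = %d, mean = %.3f ps^-1, sd = %.3f ps^-1\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Rank B800 -> B850 transfer pathways by thermally weighted rate
#'
#' @param ensemble an `lh2_rate_ensemble` computed with `pathways = TRUE`
#' @return the pathway data frame sorted by decreasing mean P_alpha k_alpha,beta
#' @export
dominant_pathways <- function(ensemble) {
  stopifnot(inherits(ensemble, "lh2_rate_ensemble"))
  if (is.null(ensemble$pathway_means))
    stop("ensemble was computed without pathway accumulation")
  df <- ensemble$pathway_means
  df[order(-df$Pk), ]
}

#' Disorder-averaged ring spectra from lineshape theory
#'
#' alpha_A(w) propto sum_beta |mu_beta|^2 D_beta(w) (absorption) and
#' I_D(w) propto sum_alpha P_alpha |mu_alpha|^2 Dt_alpha(w) (fluorescence),
#' averaged over static disorder and normalized to unit maximum.
#'
#' @param params an `lh2_params`
#' @param n realizations to average
#' @param seed master seed
#' @param ring `"B850"` or `"B800"`
#' @param type `"absorption"` or `"fluorescence"`
#' @param geometry an `lh2_geometry`
#' @param engine optional prebuilt engine
#' @return list: `omega_cm`, `intensity` (unit maximum), `peak_cm`, and
#'   `peak_shift_cm` (peak position minus the ring's mean site energy, the
#'   coupling-induced excitonic shift used for cross-environment comparisons)
#' @export
ring_spectrum <- function(params, n = 200, seed = 1,
                          ring = c("B850", "B800"),
                          type = c("absorption", "fluorescence"),
                          geometry = generate_c9_geometry(), engine = NULL) {
  ring <- match.arg(ring); type <- match.arg(type)
  if (is.null(engine)) engine <- gft_engine(params, geometry)
  gl <- if (ring == "B850") engine$gl850_ov else engine$gl800_ov
  idx <- if (ring == "B850") engine$i850 else engine$i800
  glmr <- if (ring == "B850") engine$gl850_mr else engine$gl800_mr
  lam <- if (ring == "B850") engine$lam850_ang else engine$lam800_ang
  geo <- engine$h0$geometry[idx, ]
  mu <- sweep(as.matrix(geo[, c("dx", "dy", "dz")]), 1,
              sqrt(vapply(geo$ring_class, function(rc) .ring_C(engine$params, rc),
                          numeric(1))), `*`)
  dt <- gl$t[2] - gl$t[1]
  spec <- NULL
  for (r in seq_len(n)) {
    hd <- apply_disorder(engine$h0, seed, r)
    es <- eigen(hd$H[idx, idx], symmetric = TRUE)
    o <- order(es$values)
    E <- es$values[o]; C <- es$vectors[, o, drop = FALSE]
    w <- colSums(C^4)
    rr <- .mr_rates(E * .cm2rad(), C, glmr, lam, engine$dt_mr)
    tau <- 1 / pmax(rowSums(rr), 1 / engine$tau_max)
    dip2 <- rowSums((crossprod(C, mu))^2)
    wt <- if (type == "fluorescence") {
      p <- exp(-(E - min(E)) / engine$kBT_cm); dip2 * p / sum(p)
    } else dip2
    acc <- 0
    for (a in seq_along(E)) {
      if (wt[a] < 1e-12 * sum(wt)) next
      x <- .lineshape_kernel(type, E[a], w[a], gl, tau[a])
      acc <- acc + wt[a] * x
    }
    hf <- .half_fourier(acc, dt)
    spec <- if (is.null(spec)) hf$D else spec + hf$D
    if (r == 1) omega <- hf$omega_cm
  }
  spec <- spec / n
  keep <- omega > 0
  omega <- omega[keep]; spec <- spec[keep]
  peak <- omega[which.max(spec)]
  Ebar <- mean(vapply(geo$ring_class, function(rc) .ring_site_energy(engine$params, rc),
                      numeric(1)))
  list(omega_cm = omega, intensity = spec / max(spec), peak_cm = peak,
       peak_shift_cm = peak - Ebar, ring = ring, type = type,
       label = engine$params$label, n = n)
}
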