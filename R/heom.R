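# Hierarchical equations of motion (HEOM) front end.
#
# A model bundles a site Hamiltonian (cm^-1), per-site Drude-Lorentz baths,
# and the dipole geometry; a config fixes hierarchy truncation tier L,
# Matsubara threshold M, integrator step and memory budget. The truncated
# Matsubara residue is folded into a per-site terminator
# kappa_i = 2 lambda_i/(beta gamma_i) (1 - (beta gamma_i / 2) cot(beta gamma_i / 2))
#           - sum_{k=1}^{M} c_{k,i}/nu_k
# applied as -kappa_i [Q_i, [Q_i, .]], and convergence is improved by the
# rescaled (Shi) representation of the ADOs.

#' HEOM model
#'
#' @param H site Hamiltonian matrix, cm^-1 (real symmetric)
#' @param lambda per-site reorganization energies, cm^-1 (recycled)
#' @param gamma per-site cutoff frequencies, cm^-1 (recycled)
#' @param T temperature, K
#' @param dipoles optional N x 3 matrix of transition dipole vectors
#'   (arbitrary magnitude units) for spectra
#' @param pop_sites 1-based indices of the sites whose population is reported
#'   as `P_A` (e.g. the B800 ring)
#' @return object of class `lh2_heom_model`
#' @export
heom_model <- function(H, lambda, gamma, T = 300, dipoles = NULL,
                       pop_sites = integer(0)) {
  N <- nrow(H)
  stopifnot(ncol(H) == N, max(abs(H - t(H))) < 1e-9)
  structure(list(H = H, lambda = rep_len(lambda, N), gamma = rep_len(gamma, N),
                 T = T, dipoles = dipoles, pop_sites = as.integer(pop_sites),
                 N = N),
            class = "lh2_heom_model")
}

#' HEOM model of the LH2 complex
#'
#' @param hamiltonian an `lh2_hamiltonian` (any scope; may carry disorder)
#' @return an `lh2_heom_model` with `P_A` reporting the B800 population
#' @export
heom_model_lh2 <- function(hamiltonian) {
  stopifnot(inherits(hamiltonian, "lh2_hamiltonian"))
  p <- hamiltonian$params
  lam <- ifelse(hamiltonian$block_tags == "B800", p$lambda_B800, p$lambda_B850)
  gam <- ifelse(hamiltonian$block_tags == "B800", p$gamma_B800, p$gamma_B850)
  geo <- hamiltonian$geometry
  mu <- sweep(as.matrix(geo[, c("dx", "dy", "dz")]), 1,
              sqrt(vapply(geo$ring_class, function(rc) .ring_C(p, rc), numeric(1))), `*`)
  heom_model(hamiltonian$H, lam, gam, p$T, dipoles = mu,
             pop_sites = which(hamiltonian$block_tags == "B800"))
}

#' HEOM configuration
#'
#' @param L hierarchy truncation tier (>= 1)
#' @param M Matsubara threshold (terms k = 1..M retained explicitly; the rest
#'   folded into the terminator)
#' @param dt integrator step, ps (fixed-step RK4)
#' @param t_max propagation time, ps
#' @param scaled use the rescaled-ADO representation (default TRUE)
#' @param memory_budget_gb refuse runs whose working set exceeds this
#' @return list of class `lh2_heom_config`
#' @export
heom_config <- function(L = 4, M = 1, dt = 0.001, t_max = 5, scaled = TRUE,
                        memory_budget_gb = 4) {
  stopifnot(L >= 1, M >= 0, dt > 0, t_max > 0)
  structure(list(L = L, M = M, dt = dt, t_max = t_max, scaled = scaled,
                 memory_budget_gb = memory_budget_gb),
            class = "lh2_heom_config")
}

#' Enumerate the ADO hierarchy up to a truncation tier
#'
#' All multi-indices n over the dissipation modes with sum(n) <= L, together
#' with the +/- unit-vector neighbour maps. The count equals
#' sum_{t=0}^{L} choose(n_modes + t - 1, t).
#'
#' @param n_modes number of dissipation modes (sites x (M+1))
#' @param L truncation tier
#' @param max_ado safety cap on the hierarchy size
#' @return list with `nmat` (n_ado x n_modes), `up`, `down` (0-based neighbour
#'   indices, -1 when absent), `n_ado`
#' @export
build_hierarchy <- function(n_modes, L, max_ado = 5e6) {
  expected <- sum(vapply(0:L, function(t) choose(n_modes + t - 1, t), numeric(1)))
  if (expected > max_ado)
    stop(sprintf("hierarchy would contain %.0f ADOs (cap %.0f)", expected, max_ado))
  if (n_modes == 0) {
    return(list(nmat = matrix(0L, 1, 0), up = matrix(-1L, 1, 0),
                down = matrix(-1L, 1, 0), n_ado = 1L))
  }
  tiers <- vector("list", L + 1)
  tiers[[1]] <- matrix(0L, 1, n_modes)
  if (L >= 1) {
    for (t in seq_len(L)) {
      prev <- tiers[[t]]
      # raise each index in the last non-zero position or later to avoid dups
      out <- vector("list", nrow(prev))
      for (r in seq_len(nrow(prev))) {
        v <- prev[r, ]
        last <- if (all(v == 0)) 1L else max(which(v > 0))
        reps <- matrix(v, n_modes - last + 1, n_modes, byrow = TRUE)
        idx <- seq(last, n_modes)
        reps[cbind(seq_along(idx), idx)] <- reps[cbind(seq_along(idx), idx)] + 1L
        out[[r]] <- reps
      }
      tiers[[t + 1]] <- do.call(rbind, out)
    }
  }
  nmat <- do.call(rbind, tiers)
  n_ado <- nrow(nmat)
  key <- apply(nmat, 1, paste, collapse = ",")
  lut <- new.env(hash = TRUE, size = n_ado)
  for (i in seq_len(n_ado)) assign(key[i], i - 1L, envir = lut)
  up <- matrix(-1L, n_ado, n_modes)
  down <- matrix(-1L, n_ado, n_modes)
  for (i in seq_len(n_ado)) {
    v <- nmat[i, ]
    for (m in seq_len(n_modes)) {
      vu <- v; vu[m] <- vu[m] + 1L
      ku <- paste(vu, collapse = ",")
      if (exists(ku, envir = lut, inherits = FALSE))
        up[i, m] <- get(ku, envir = lut)
      if (v[m] > 0L) {
        vd <- v; vd[m] <- vd[m] - 1L
        down[i, m] <- get(paste(vd, collapse = ","), envir = lut)
      }
    }
  }
  list(nmat = nmat, up = up, down = down, n_ado = n_ado)
}

# per-mode expansion and per-site terminator for a model
.heom_modes <- function(model, M) {
  cm <- .cm2rad()
  active <- which(model$lambda > 0)
  site <- integer(0); cc <- complex(0); nu <- numeric(0)
  kap <- numeric(model$N)
  for (i in active) {
    b <- drude_lorentz_bath(model$lambda[i], model$gamma[i], model$T)
    ex <- matsubara_expansion(b, M)
    site <- c(site, rep(i - 1L, M + 1))
    cc <- c(cc, ex$c * cm^2)
    nu <- c(nu, ex$nu * cm)
    beta <- 1 / (.kB() * model$T)           # cm
    bg <- beta * model$gamma[i]
    kap_cm <- 2 * model$lambda[i] / bg * (1 - (bg / 2) / tan(bg / 2))
    if (M >= 1) kap_cm <- kap_cm - sum(Re(ex$c[-1]) / ex$nu[-1])
    kap[i] <- kap_cm * cm
  }
  list(site = as.integer(site), c = cc, nu = nu, kappa = kap,
       n_modes = length(site))
}

#' Estimate and enforce the HEOM memory budget
#'
#' @param model an `lh2_heom_model`
#' @param config an `lh2_heom_config`
#' @return invisible estimated working-set size in GB; errors when it exceeds
#'   the configured budget
#' @export
heom_capacity <- function(model, config) {
  md <- .heom_modes(model, config$M)
  n_ado <- sum(vapply(0:config$L, function(t) choose(md$n_modes + t - 1, t),
                      numeric(1)))
  gb <- n_ado * model$N^2 * 16 * 7 / 2^30   # state + 4 RK stages + tmp + slack
  if (gb > config$memory_budget_gb)
    stop(sprintf(paste0("HEOM run refused: %d modes at tier %d give %.0f ADOs, ",
                        "an estimated %.1f GB working set (budget %.1f GB)"),
                 md$n_modes, config$L, n_ado, gb, config$memory_budget_gb))
  invisible(gb)
}

#' Thermal (Boltzmann) initial state over a ring block
#'
#' rho(0) = exp(-beta H_block) / Tr embedded in the full site space.
#'
#' @param model an `lh2_heom_model`
#' @param sites 1-based site indices of the block (defaults to `pop_sites`)
#' @return N x N density matrix
#' @export
boltzmann_block_state <- function(model, sites = model$pop_sites) {
  Hb <- model$H[sites, sites, drop = FALSE]
  es <- eigen(Hb, symmetric = TRUE)
  p <- exp(-(es$values - min(es$values)) / (.kB() * model$T))
  p <- p / sum(p)
  rho_b <- es$vectors %*% diag(p, length(p)) %*% t(es$vectors)
  rho <- matrix(0, model$N, model$N)
  rho[sites, sites] <- rho_b
  rho
}

#' Propagate the HEOM
#'
#' Fixed-step RK4 propagation of the full ADO hierarchy from an initial
#' system state (the hierarchy starts unentangled: all higher ADOs zero).
#'
#' @param model an `lh2_heom_model`
#' @param config an `lh2_heom_config`
#' @param rho0 initial N x N density matrix (default: Boltzmann state over
#'   `pop_sites`)
#' @param stride record every `stride`-th step
#' @param return_state also return the final hierarchy state (for restarts)
#' @param state0 optional full initial hierarchy state (N x N x n_ado array,
#'   e.g. from a previous run or [heom_steady_state()]); overrides `rho0`
#' @return object of class `lh2_population_trace`: data frame columns `time`,
#'   `P_A` (population of `pop_sites`), `P_B` (complement), `trace`
#' @export
propagate_heom <- function(model, config, rho0 = NULL, stride = 10,
                           return_state = FALSE, state0 = NULL) {
  stopifnot(inherits(model, "lh2_heom_model"), inherits(config, "lh2_heom_config"))
  heom_capacity(model, config)
  md <- .heom_modes(model, config$M)
  hh <- build_hierarchy(md$n_modes, config$L)
  if (is.null(rho0)) rho0 <- boltzmann_block_state(model)
  nsteps <- round(config$t_max / config$dt)
  if (!is.null(state0)) {
    stopifnot(length(state0) == model$N^2 * hh$n_ado)
    state0 <- as.vector(state0) + 0i
  }
  res <- cpp_heom_propagate(model$H * .cm2rad() + 0i, hh$nmat, hh$up, hh$down,
                            md$site, md$c, md$nu, md$kappa, config$scaled,
                            rho0 + 0i, config$dt, nsteps, stride,
                            model$pop_sites - 1L, return_state, state0)
  out <- data.frame(time = res$time, P_A = res$P_A,
                    P_B = res$trace - res$P_A, trace = res$trace)
  attr(out, "state") <- res$state
  attr(out, "model") <- model
  attr(out, "config") <- config
  class(out) <- c("lh2_population_trace", "data.frame")
  out
}

#' Fit ring populations to a two-state Pauli master equation
#'
#' P_A(t) = (k_up + k_down exp(-(k_up + k_down) t)) / (k_up + k_down),
#' fitted by nonlinear least squares over t >= t0 (the initial coherent
#' transient is discarded). `k_down` is the reported A -> B transfer rate.
#'
#' @param trace an `lh2_population_trace` (or data frame with `time`, `P_A`)
#' @param t0 fit-window start, ps
#' @return list with `k_down`, `k_up` (ps^-1), `residual` (RMS), and the fit
#' @export
fit_pauli <- function(trace, t0 = 0.05) {
  df <- trace[trace$time >= t0, ]
  if (nrow(df) < 10) stop("fit window too short")
  if (stats::sd(df$P_A) < 1e-8)
    stop("population trace is flat over the fit window; two-state fit is degenerate")
  p0 <- df$P_A[1]
  pinf <- df$P_A[nrow(df)]
  ktot0 <- max(1 / (df$time[nrow(df)] - df$time[1]), 0.5)
  kd0 <- max(ktot0 * (1 - pinf), 0.1)
  ku0 <- max(ktot0 * pinf, 0.05)
  fit <- minpack.lm::nlsLM(
    P_A ~ (k_up + k_down * exp(-(k_up + k_down) * time)) / (k_up + k_down),
    data = df, start = list(k_down = kd0, k_up = ku0),
    lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(k_down = unname(co["k_down"]), k_up = unname(co["k_up"]),
       residual = sqrt(mean(stats::resid(fit)^2)), fit = fit,
       p0 = p0)
}

# shared driver for the optical-coherence hierarchies; the coherence is
# propagated in a rotating frame at the mean site energy (the optical carrier
# would otherwise force sub-fs steps), and the spectrum is shifted back
.heom_coherence_signal <- function(model, config, w0_fun, side, nsteps) {
  md <- .heom_modes(model, config$M)
  hh <- build_hierarchy(md$n_modes, config$L)
  gb <- hh$n_ado * model$N * 16 * 7 / 2^30
  if (gb > config$memory_budget_gb)
    stop(sprintf("coherence hierarchy exceeds memory budget (%.1f GB)", gb))
  ref <- mean(diag(model$H))
  Hrot <- model$H - diag(ref, model$N)
  sig <- 0
  for (p in 1:3) {
    d <- model$dipoles[, p]
    if (all(abs(d) < 1e-14)) next
    coh0 <- w0_fun(d, hh$n_ado)
    s <- cpp_heom_propagate_coherence(Hrot * .cm2rad() + 0i, hh$nmat, hh$up,
                                      hh$down, md$site, md$c, md$nu, md$kappa,
                                      config$scaled, coh0, d + 0i,
                                      config$dt, nsteps, side)
    sig <- sig + s
  }
  if (length(sig) == 1) sig <- rep(0 + 0i, nsteps + 1)
  list(signal = sig, ref_cm = ref)
}

#' HEOM linear absorption spectrum
#'
#' Half-Fourier transform of the ground-state dipole-dipole correlation
#' function summed over the three polarization directions, computed with a
#' hierarchy of optical coherences (one N-vector per ADO).
#'
#' @param model an `lh2_heom_model` with dipoles
#' @param config an `lh2_heom_config` (its `t_max` sets spectral resolution)
#' @return list `omega_cm`, `intensity` (unit maximum), `peak_cm`
#' @export
heom_absorption <- function(model, config) {
  if (is.null(model$dipoles)) stop("model carries no dipoles")
  nsteps <- round(config$t_max / config$dt)
  cs <- .heom_coherence_signal(model, config,
                               function(d, n_ado) {
                                 m <- matrix(0i, model$N, n_ado)
                                 m[, 1] <- d
                                 m
                               }, side = 0L, nsteps = nsteps)
  hf <- .half_fourier(cs$signal, config$dt)
  om <- hf$omega_cm + cs$ref_cm
  D <- hf$D
  keep <- om > 0 & om < 2 * cs$ref_cm
  om <- om[keep]; D <- D[keep]
  if (max(abs(D)) == 0)
    return(list(omega_cm = om, intensity = D, peak_cm = NA_real_))
  list(omega_cm = om, intensity = D / max(D), peak_cm = om[which.max(D)])
}

#' HEOM thermal steady state of the excited-state manifold
#'
#' Solves RHS(state) = 0 with the trace of the system ADO pinned to 1, using
#' matrix-free BiCGSTAB started from the Boltzmann distribution of the
#' `pop_sites` block plus the identity on the complement.
#'
#' @param model an `lh2_heom_model`
#' @param config an `lh2_heom_config`
#' @param tol residual tolerance on ||RHS|| (default 1e-8)
#' @param maxit maximum BiCGSTAB iterations
#' @param guess optional initial hierarchy state (N x N x n_ado array)
#' @return list with `state` (N x N x n_ado complex array), `rho` (system
#'   density matrix), `residual`, `iterations`
#' @export
heom_steady_state <- function(model, config, tol = 1e-8, maxit = 6000,
                              guess = NULL) {
  heom_capacity(model, config)
  md <- .heom_modes(model, config$M)
  hh <- build_hierarchy(md$n_modes, config$L)
  N <- model$N
  Hc <- model$H * .cm2rad() + 0i
  nele <- N * N * hh$n_ado
  tr_idx <- (seq_len(N) - 1) * (N + 1) + 1   # diagonal of slice 1
  Araw <- function(x) {
    dim(x) <- c(N, N, hh$n_ado)
    y <- cpp_heom_rhs(Hc, hh$nmat, hh$up, hh$down, md$site, md$c, md$nu,
                      md$kappa, config$scaled, x)
    y <- as.vector(y)
    # replace the first equation by the trace constraint; global trace
    # conservation makes the dropped component redundant
    y[1] <- sum(x[tr_idx])
    y
  }
  # Jacobi preconditioner from the diagonal of the Liouvillian: per ADO
  # damping sum(n nu) plus the coherence frequency and terminator dephasing
  gamma_n <- drop(hh$nmat %*% md$nu)
  dE <- diag(Hc)
  kap2 <- outer(md$kappa, md$kappa, function(a, b) a + b)
  diag(kap2) <- 0
  Dm <- array(0i, c(N, N, hh$n_ado))
  for (a in seq_len(hh$n_ado))
    Dm[, , a] <- -1i * outer(dE, dE, `-`) - gamma_n[a] - kap2
  Dm <- as.vector(Dm)
  Dm[1] <- 1                    # the trace-constraint row
  Dm[Mod(Dm) < 1] <- 1
  Afun <- function(y) Araw(y / Dm)
  b <- complex(nele); b[1] <- 1 + 0i
  if (is.null(guess)) {
    x0 <- complex(nele)
    rho0 <- boltzmann_block_state(model)
    comp <- setdiff(seq_len(N), model$pop_sites)
    diag(rho0)[comp] <- 1
    rho0 <- rho0 / sum(diag(rho0))
    x0[seq_len(N * N)] <- as.vector(rho0 + 0i)
  } else x0 <- as.vector(guess)
  x <- x0 * Dm                  # preconditioned variable y = D x
  # BiCGSTAB (complex, matrix-free)
  r <- b - Afun(x)
  rhat <- r
  rho_old <- 1 + 0i; alpha <- 1 + 0i; omega <- 1 + 0i
  v <- p <- complex(nele)
  it <- 0
  while (sqrt(sum(Mod(r)^2)) > tol && it < maxit) {
    it <- it + 1
    if (it %% 400 == 0) {
      # periodic restart with the true residual guards against stagnation of
      # the recursive residual
      r <- b - Afun(x)
      rhat <- r
      rho_old <- alpha <- omega <- 1 + 0i
      v <- p <- complex(nele)
    }
    rho_new <- sum(Conj(rhat) * r)
    if (!is.finite(Mod(rho_new)) || Mod(rho_new) < 1e-300) {
      # breakdown: restart with the current iterate as shadow residual
      r <- b - Afun(x)
      rhat <- r
      rho_old <- alpha <- omega <- 1 + 0i
      v <- p <- complex(nele)
      rho_new <- sum(Conj(rhat) * r)
      if (Mod(rho_new) < 1e-300) break
    }
    beta <- (rho_new / rho_old) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    v <- Afun(p)
    den <- sum(Conj(rhat) * v)
    if (!is.finite(Mod(den)) || Mod(den) < 1e-300) break
    alpha <- rho_new / den
    s <- r - alpha * v
    t_ <- Afun(s)
    den2 <- sum(Conj(t_) * t_)
    if (!is.finite(Mod(den2)) || Mod(den2) < 1e-300) break
    omega <- sum(Conj(t_) * s) / den2
    x <- x + alpha * p + omega * s
    r <- s - omega * t_
    rho_old <- rho_new
  }
  res <- sqrt(sum(Mod(r)^2))
  if (res > tol)
    warning(sprintf("steady-state solver reached residual %.2e after %d iterations",
                    res, it))
  x <- x / Dm                   # back to the physical variable
  dim(x) <- c(N, N, hh$n_ado)
  rho <- x[, , 1]
  rho <- (rho + Conj(t(rho))) / 2
  rho <- rho / Re(sum(diag(rho)))
  list(state = x, rho = rho, residual = res, iterations = it)
}

#' HEOM fluorescence spectrum
#'
#' Emission dipole correlation from the thermal steady state of the
#' excited-state manifold, normalized to unit maximum.
#'
#' @param model an `lh2_heom_model` with dipoles
#' @param config an `lh2_heom_config`
#' @param steady optional result of [heom_steady_state()]
#' @return list `omega_cm`, `intensity`, `peak_cm`
#' @export
heom_fluorescence <- function(model, config, steady = NULL) {
  if (is.null(model$dipoles)) stop("model carries no dipoles")
  if (is.null(steady)) steady <- heom_steady_state(model, config)
  st <- steady$state
  nsteps <- round(config$t_max / config$dt)
  cs <- .heom_coherence_signal(model, config,
                               function(d, n_ado) {
                                 m <- matrix(0i, model$N, n_ado)
                                 for (a in seq_len(n_ado))
                                   m[, a] <- as.vector(crossprod(st[, , a], d))
                                 m
                               }, side = 1L, nsteps = nsteps)
  # emission: transform <mu(0) mu(t)> = conj(<mu(t) mu(0)>) so the line sits
  # at positive frequency
  hf <- .half_fourier(Conj(cs$signal), config$dt)
  om <- hf$omega_cm + cs$ref_cm
  D <- hf$D
  keep <- om > 0 & om < 2 * cs$ref_cm
  om <- om[keep]; D <- D[keep]
  if (max(abs(D)) == 0)
    return(list(omega_cm = om, intensity = D, peak_cm = NA_real_))
  list(omega_cm = om, intensity = D / max(D), peak_cm = om[which.max(D)])
}
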