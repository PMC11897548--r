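# HEOM hierarchy construction, propagation, rate fitting and spectra.

cm2rad <- lh2_constants()$cm1_to_radps
kB <- lh2_constants()$kB_cm1

test_that("hierarchy enumeration matches stars-and-bars counts", {
  expect_equal(build_hierarchy(2, 2)$n_ado, 6L)       # 1 + 2 + 3
  expect_equal(build_hierarchy(5, 0)$n_ado, 1L)
  expect_equal(build_hierarchy(54, 2)$n_ado, 1540L)   # 1 + 54 + 1485
  h <- build_hierarchy(3, 3)
  expect_equal(h$n_ado, sum(choose(3 + 0:3 - 1, 0:3)))
  # neighbour maps are mutually consistent
  for (a in seq_len(h$n_ado)) for (m in 1:3) {
    iu <- h$up[a, m]
    if (iu >= 0) expect_equal(h$down[iu + 1, m], a - 1L)
  }
  expect_error(build_hierarchy(54, 4, max_ado = 1e5), "cap")
})

test_that("memory-budget estimator refuses the full 27-site tier-4 hierarchy", {
  g <- test_geometry()
  h <- build_site_hamiltonian(g, environment_parameters("detergent"), "full")
  m <- heom_model_lh2(h)
  expect_error(heom_capacity(m, heom_config(L = 4, M = 1)), "refused")
  expect_silent(heom_capacity(m, heom_config(L = 1, M = 1)))
})

test_that("lambda = 0 reduces the HEOM to unitary Schroedinger dynamics", {
  H2 <- matrix(c(12200, 100, 100, 12000), 2, 2)
  m <- heom_model(H2, lambda = 0, gamma = 53, T = 300, pop_sites = 1)
  tr <- propagate_heom(m, heom_config(L = 1, M = 0, dt = 0.001, t_max = 1),
                       rho0 = diag(c(1, 0)))
  es <- eigen(H2 * cm2rad)
  U <- es$vectors
  pa <- vapply(tr$time, function(t)
    Mod((U %*% diag(exp(-1i * es$values * t)) %*% t(U) %*% c(1, 0))[1])^2,
    numeric(1))
  expect_lt(max(abs(tr$P_A - pa)), 1e-6)
})

test_that("RHS preserves Hermiticity of a Hermitian-consistent hierarchy state", {
  H2 <- matrix(c(12100, 80, 80, 12000), 2, 2)
  m <- heom_model(H2, 160, 53, 300, pop_sites = 1)
  md <- lh2et:::.heom_modes(m, 1)
  hh <- build_hierarchy(md$n_modes, 2)
  set.seed(5)
  st <- array(0i, c(2, 2, hh$n_ado))
  for (a in seq_len(hh$n_ado)) {
    x <- matrix(rnorm(4) + 1i * rnorm(4), 2)
    st[, , a] <- (x + Conj(t(x))) / 2
  }
  d <- lh2et:::cpp_heom_rhs(H2 * cm2rad + 0i, hh$nmat, hh$up, hh$down, md$site,
                            md$c, md$nu, md$kappa, FALSE, st)
  # for real multi-index weights the physical (unscaled) hierarchy keeps each
  # ADO's anti-Hermitian part zero when seeded Hermitian... the system ADO must
  # at least stay Hermitian and traceless in its derivative
  d0 <- d[, , 1]
  expect_lt(max(Mod(d0 - Conj(t(d0)))), 1e-12)
  expect_lt(Mod(sum(diag(d0))), 1e-12)
})

test_that("trace is conserved and populations reach a stationary state", {
  m <- make_fixture("dimer", E = c(12200, 12000), V = 60)
  tr <- propagate_heom(m, heom_config(L = 4, M = 1, dt = 0.001, t_max = 5),
                       rho0 = diag(c(1, 0)))
  expect_lt(max(abs(tr$trace - 1)), 1e-6)
  tail_slope <- abs(diff(utils::tail(tr$P_A, 2))) /
    diff(utils::tail(tr$time, 2))
  expect_lt(tail_slope, 1e-4)
})

test_that("scaled and unscaled representations give identical reduced dynamics", {
  m <- make_fixture("dimer", E = c(12150, 12000), V = 80)
  cfgS <- heom_config(L = 4, M = 1, dt = 0.001, t_max = 1, scaled = TRUE)
  cfgU <- heom_config(L = 4, M = 1, dt = 0.001, t_max = 1, scaled = FALSE)
  t1 <- propagate_heom(m, cfgS, rho0 = diag(c(1, 0)))
  t2 <- propagate_heom(m, cfgU, rho0 = diag(c(1, 0)))
  expect_lt(max(abs(t1$P_A - t2$P_A)), 1e-8)
})

test_that("hierarchy tier is converged for the dimer fixture", {
  m <- heom_model(matrix(c(12200, 60, 60, 12000), 2, 2),
                  lambda = 35, gamma = 35, T = 300, pop_sites = 1)
  tr9 <- propagate_heom(m, heom_config(L = 9, M = 1, dt = 0.0005, t_max = 3),
                        rho0 = diag(c(1, 0)))
  tr10 <- propagate_heom(m, heom_config(L = 10, M = 2, dt = 0.0005, t_max = 3),
                         rho0 = diag(c(1, 0)))
  # the reported quantity is the Pauli-fit rate: it must be stable under
  # deepening both the hierarchy tier and the Matsubara threshold
  k9 <- fit_pauli(tr9)$k_down
  k10 <- fit_pauli(tr10)$k_down
  expect_lt(abs(k9 - k10) / k10, 0.03)
  # and the settled populations agree pointwise
  sel <- tr9$time >= 1.5
  expect_lt(max(abs(tr9$P_A[sel] - tr10$P_A[sel])), 0.01)
})

test_that("Pauli fit recovers synthetic rates and flags degenerate traces", {
  kd <- 1.0; ku <- 0.2
  t <- seq(0, 6, by = 0.002)
  set.seed(1)
  P <- (ku + kd * exp(-(ku + kd) * t)) / (ku + kd) + rnorm(length(t), 0, 1e-4)
  tr <- data.frame(time = t, P_A = P)
  fit <- fit_pauli(tr)
  expect_equal(fit$k_down, kd, tolerance = 0.01)
  expect_equal(fit$k_up, ku, tolerance = 0.01)
  expect_error(fit_pauli(data.frame(time = t, P_A = rep(0.5, length(t)))),
               "flat|degenerate")
})

test_that("monomer HEOM absorption matches the cumulant lineshape", {
  m <- make_fixture("monomer", E = 12000)
  ha <- heom_absorption(m, heom_config(L = 16, M = 1, dt = 0.00025, t_max = 3))
  gl <- test_gl(160, 53, K = 6)
  cl <- absorption_lineshape(12000, 1, gl, tau = Inf)
  f1 <- approxfun(ha$omega_cm, ha$intensity / max(ha$intensity))
  f2 <- approxfun(cl$omega_cm, cl$D / max(cl$D))
  gr <- seq(10500, 13500, by = 5)
  dev <- sum(abs(f1(gr) - f2(gr)), na.rm = TRUE) / sum(f2(gr), na.rm = TRUE)
  expect_lt(dev, 0.02)
})

test_that("zero dipoles produce a zero spectrum", {
  m <- make_fixture("dimer", E = c(12100, 12000), V = 50)
  m$dipoles <- m$dipoles * 0
  ha <- heom_absorption(m, heom_config(L = 2, M = 1, dt = 0.001, t_max = 0.5))
  expect_true(all(ha$intensity == 0))
})

test_that("steady state is a fixed point, near-Boltzmann for weak coupling,
           and independent of the starting guess", {
  m <- heom_model(matrix(c(12150, 15, 15, 12000), 2, 2),
                  lambda = 35, gamma = 35, T = 300, pop_sites = 1)
  cfg <- heom_config(L = 4, M = 1, dt = 0.001, t_max = 2)
  ss <- heom_steady_state(m, cfg, tol = 1e-8)
  expect_lt(ss$residual, 1e-8)
  # propagate from the full hierarchy solution: populations stay put
  p0 <- Re(diag(ss$rho))
  tr <- propagate_heom(m, cfg, state0 = ss$state)
  expect_lt(max(abs(tr$P_A - p0[1])), 1e-6)
  # weak-coupling detailed balance in the exciton basis
  es <- eigen(m$H, symmetric = TRUE)
  pexc <- Re(diag(t(es$vectors) %*% ss$rho %*% es$vectors))
  ratio <- pexc[2] / pexc[1]
  boltz <- exp(-(es$values[2] - es$values[1]) / (kB * 300))
  expect_equal(ratio, boltz, tolerance = 0.1)
  # restart from a random-but-valid guess reaches the same state
  set.seed(8)
  guess <- ss$state
  guess <- guess + (rnorm(length(guess)) + 1i * rnorm(length(guess))) * 1e-3
  ss2 <- heom_steady_state(m, cfg, tol = 1e-8, guess = guess)
  expect_lt(max(Mod(ss2$rho - ss$rho)), 1e-6)
})

test_that("monomer emission mirrors absorption about omega0 - lambda and sits
           red of it", {
  m <- make_fixture("monomer", E = 12000)
  cfg <- heom_config(L = 10, M = 1, dt = 0.0005, t_max = 2)
  ha <- heom_absorption(m, cfg)
  ss <- heom_steady_state(m, cfg, tol = 1e-7)
  hf <- heom_fluorescence(m, cfg, steady = ss)
  expect_lt(hf$peak_cm, ha$peak_cm)    # Stokes shift
  # Gaussian-limit mirror: peaks roughly symmetric about omega0 - lambda
  centre <- (ha$peak_cm + hf$peak_cm) / 2
  expect_lt(abs(centre - (12000 - 160)), 80)
})

test_that("reduced-ring HEOM transfer is faster in POPC than in detergent", {
  kd <- function(env) {
    p <- environment_parameters(env)
    m <- make_fixture("reduced-ring-3x3", p)
    rates <- numeric(2)
    sig <- attr(m, "sigma")
    for (r in 1:2) {
      seed <- lh2et:::.stream_seed(404, r)
      set.seed(seed)
      Hd <- m$H + diag(stats::rnorm(9, 0, sig))
      md <- heom_model(Hd, m$lambda, m$gamma, m$T, dipoles = m$dipoles,
                       pop_sites = 1:3)
      tr <- propagate_heom(md, heom_config(L = 2, M = 1, dt = 0.002, t_max = 3))
      expect_lt(max(abs(tr$trace - 1)), 1e-6)
      rates[r] <- fit_pauli(tr)$k_down
    }
    rates
  }
  expect_gt(mean(kd("POPC")), mean(kd("detergent")))
})
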