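# Generalized Forster machinery: exciton couplings, exciton-bath parameters,
# modified-Redfield lifetimes, lineshapes, overlaps and rates.

cm2rad <- lh2_constants()$cm1_to_radps
kB <- lh2_constants()$kB_cm1

.basis <- function(H, tags, geometry, params, scope) {
  diagonalize_and_label(structure(
    list(H = H, block_tags = tags, site_order = seq_along(tags) - 1,
         geometry = geometry, params = params, scope = scope),
    class = "lh2_hamiltonian"))
}

test_that("exciton couplings transform bilinearly and conserve Frobenius norm", {
  g <- test_geometry()
  p <- environment_parameters("detergent")
  h <- build_site_hamiltonian(g, p, "full")
  i8 <- which(h$block_tags == "B800"); i5 <- which(h$block_tags != "B800")
  d <- diagonalize_and_label(lh2et:::.subset_hamiltonian(h, i8, "B800"))
  a <- diagonalize_and_label(lh2et:::.subset_hamiltonian(h, i5, "B850"))
  V <- h$H[i8, i5]
  Vab <- exciton_coupling(d, a, V)
  expect_equal(sum(Vab^2), sum(V^2), tolerance = 1e-9)      # unitary invariance
  expect_equal(dim(Vab), c(9, 18))
  # zero inter-ring block -> all couplings zero
  expect_equal(max(abs(exciton_coupling(d, a, V * 0))), 0)
  # overlapping site sets are rejected
  expect_error(exciton_coupling(d, d, matrix(0, 9, 9)), "overlap")
  # localized donor/acceptor picks out the site coupling
  Id <- d; Id$coefficients <- diag(9); Id$site_order <- 0:8
  Ia <- a; Ia$coefficients <- diag(18)
  expect_equal(exciton_coupling(Id, Ia, V)[1, 3], V[1, 3])
})

test_that("exciton environment parameters are |C|^4-weighted site values", {
  g <- test_geometry()
  p <- environment_parameters("detergent")
  b <- .basis(build_site_hamiltonian(g, p, "B850")$H,
              rep("B850a", 18), g[10:27, ], p, "B850")
  t <- seq(0, 0.2, by = 0.01)
  gsite <- test_gl(t_max = 0.2, dt = 0.01)$g
  env <- exciton_env_params(b, 160, gsite)
  w <- colSums(b$coefficients^4)
  expect_equal(env$lambda, 160 * w, tolerance = 1e-12)
  # uniform state over N identical sites -> lambda / N
  bu <- b; bu$coefficients <- matrix(1 / sqrt(18), 18, 18)
  expect_equal(exciton_env_params(bu, 160, gsite)$lambda[1], 160 / 18)
  # localized exciton -> site value
  bl <- b; bl$coefficients <- diag(18)
  expect_equal(exciton_env_params(bl, 160, gsite)$lambda[1], 160)
  # mixed per-site values: direct weighted sum oracle
  set.seed(7)
  lam_sites <- runif(18, 30, 200)
  gm <- outer(gsite, lam_sites / 160)
  envm <- exciton_env_params(b, lam_sites, gm)
  a <- 5
  expect_equal(envm$g[, a],
               drop(gm %*% (b$coefficients[, a]^4)), tolerance = 1e-12)
})

test_that("modified-Redfield dimer rates obey detailed balance and match an
           independent quadrature", {
  p <- environment_parameters("detergent")
  g <- test_geometry()
  H <- matrix(c(12200, 60, 60, 12000), 2, 2)
  b <- .basis(H, c("B850a", "B850a"), g[10:11, ], p, "B850")
  bath <- drude_lorentz_bath(160, 53, 300)
  mr <- modified_redfield_lifetimes(b, bath, t_max = 6, dt = 0.001)
  expect_true(all(mr$rates >= 0))
  kdown <- mr$rates[2, 1]; kup <- mr$rates[1, 2]
  dE <- (b$energies[2] - b$energies[1]) / (kB * 300)
  expect_equal(kdown / kup, exp(dE), tolerance = 0.05)
  # independent direct quadrature of the rate integrand (trapezoid on a
  # separately constructed grid)
  t <- seq(0, 6, by = 0.001)
  gl <- line_broadening(matsubara_expansion(bath, 1), t)
  C <- b$coefficients
  lam <- 160 * cm2rad
  wa <- sum(C[, 1]^4); wb <- sum(C[, 2]^4)
  f2 <- sum(C[, 1]^2 * C[, 2]^2)
  f3a <- sum(C[, 1]^3 * C[, 2]); f3b <- sum(C[, 1] * C[, 2]^3)
  D <- (b$energies[2] - b$energies[1]) * cm2rad
  x <- exp(1i * (D - 2 * lam * (wb - f2)) * t - (wa + wb - 2 * f2) * gl$g) *
    (f2 * gl$gddot + (2 * lam * f3b + 1i * (f3a - f3b) * gl$gdot)^2)
  k_quad <- 2 * (sum(Re(x)) - 0.5 * Re(x[1] + x[length(x)])) * 0.001
  expect_equal(kdown, k_quad, tolerance = 0.01)
})

test_that("uncoupled distinct sites have capped (infinite) lifetimes", {
  p <- environment_parameters("detergent")
  g <- test_geometry()
  H <- diag(c(12500, 12000))
  b <- .basis(H, c("B850a", "B850a"), g[10:11, ], p, "B850")
  mr <- modified_redfield_lifetimes(b, drude_lorentz_bath(160, 53, 300),
                                    tau_max = 1e4)
  expect_equal(unname(mr$tau), c(1e4, 1e4))
})

test_that("lineshapes are normalized, Stokes-ordered and have the Lorentzian
           lifetime limit", {
  gl <- test_gl()
  ab <- absorption_lineshape(12390, 0.1, gl, tau = Inf)
  fl <- fluorescence_lineshape(12390, 0.1, gl, tau = Inf)
  dw <- (ab$omega_cm[2] - ab$omega_cm[1]) * cm2rad
  expect_equal(sum(ab$D) * dw / (2 * pi), 1, tolerance = 1e-3)
  expect_equal(sum(fl$D) * dw / (2 * pi), 1, tolerance = 1e-3)
  lam_exc <- 0.1 * 160
  expect_gte(ab$peak_cm, 12390 - lam_exc - 2)     # absorption blue of omega - lambda
  expect_lte(fl$peak_cm, 12390)                   # fluorescence red of omega
  expect_gt(ab$peak_cm, fl$peak_cm)               # Stokes ordering
  # lambda -> 0 with finite lifetime: Lorentzian of FWHM 2/tau
  gl0 <- test_gl(lambda = 1e-9)
  tau <- 0.3
  ab0 <- absorption_lineshape(12390, 1, gl0, tau = tau)
  # half-maximum crossings by linear interpolation on both flanks
  ipk <- which.max(ab0$D)
  hm <- max(ab0$D) / 2
  left <- stats::approx(ab0$D[1:ipk], ab0$omega_cm[1:ipk], xout = hm)$y
  nr <- length(ab0$D)
  right <- stats::approx(ab0$D[ipk:nr], ab0$omega_cm[ipk:nr], xout = hm)$y
  fwhm <- (right - left) * cm2rad
  expect_equal(fwhm, 2 / tau, tolerance = 0.02)
  # Nyquist guard
  glc <- test_gl(dt = 0.02)
  expect_error(absorption_lineshape(12390, 0.1, glc), "Nyquist")
})

test_that("time-domain and frequency-domain spectral overlaps agree", {
  gl8 <- test_gl(35, 35)
  gl5 <- test_gl(160, 53)
  set.seed(11)
  for (i in 1:5) {
    wd <- runif(1, 0.1, 1); wa <- runif(1, 0.05, 0.5)
    ed <- 12500 + runif(1, -200, 200)
    ea <- 12400 + runif(1, -300, 300)
    td <- runif(1, 0.2, 5); ta <- runif(1, 0.05, 2)
    o_t <- spectral_overlap(ed, ea, wd, wa, gl8, gl5, td, ta)
    o_w <- lh2et:::spectral_overlap_frequency(ed, ea, wd, wa, gl8, gl5, td, ta)
    expect_equal(o_t, o_w, tolerance = 0.01)
  }
  # widely separated lines overlap negligibly relative to resonance
  o_far <- spectral_overlap(20000, 12000, 0.3, 0.1, gl8, gl5, 1, 1)
  o_res <- spectral_overlap(12400, 12400, 0.3, 0.1, gl8, gl5, 1, 1)
  expect_lt(o_far / o_res, 1e-4)
  # identical donor/acceptor: overlap is maximal near zero gap over a scan
  gaps <- seq(-800, 800, by = 50)
  ov <- vapply(gaps, function(d)
    spectral_overlap(12400 + d, 12400, 0.3, 0.3, gl8, gl8, 1, 1), numeric(1))
  expect_gt(ov[which.min(abs(gaps))], 0)
  expect_lt(abs(gaps[which.max(ov)]), 150)
  expect_error(spectral_overlap(1, 1, 1, 1, gl8, test_gl(t_max = 1)), "grids")
})

test_that("per-realization GFT rate has the trivial coupling limits", {
  eng <- test_engine("detergent")
  r <- gft_realization(eng, 5, 1)
  expect_gt(r$K_GFT, 0)
  expect_equal(sum(r$P), 1, tolerance = 1e-9)
  expect_true(all(r$k >= 0))
  # K equals the pathway sum exactly
  expect_equal(r$K_GFT, sum(r$P * r$k), tolerance = 1e-12)
  # zero inter-ring coupling: K = 0; doubled couplings: K quadruples at
  # fixed lineshapes (|V|^2 scaling)
  K0 <- sum(r$P * (0 * r$V2_cm2) * cm2rad^2 * r$O)
  K2 <- sum(r$P * (4 * r$V2_cm2) * cm2rad^2 * r$O)
  expect_equal(K0, 0)
  expect_equal(K2, 4 * r$K_GFT, tolerance = 1e-12)
})

test_that("rate ensembles are seeded, resumable and flag n = 1", {
  g <- test_geometry()
  p <- environment_parameters("detergent")
  eng <- test_engine("detergent")
  e1 <- rate_ensemble(p, 6, seed = 99, engine = eng, pathways = FALSE)
  e2 <- rate_ensemble(p, 6, seed = 99, engine = eng, pathways = FALSE)
  expect_identical(e1$K, e2$K)
  # splitting across two invocations reproduces the single run
  ea <- rate_ensemble(p, 3, seed = 99, engine = eng, pathways = FALSE)
  eb <- rate_ensemble(p, 3, seed = 99, engine = eng, offset = 3, pathways = FALSE)
  expect_identical(c(ea$K, eb$K), e1$K)
  en1 <- rate_ensemble(p, 1, seed = 99, engine = eng, pathways = FALSE)
  expect_true(is.na(en1$sd))
  expect_match(en1$sd_note, "undefined")
})

test_that("disjoint seed ranges of the ensemble agree within sampling error", {
  p <- environment_parameters("detergent")
  eng <- test_engine("detergent")
  ea <- rate_ensemble(p, 150, seed = 31, engine = eng, pathways = FALSE)
  eb <- rate_ensemble(p, 150, seed = 31, engine = eng, offset = 5000,
                      pathways = FALSE)
  se <- sqrt(ea$sd^2 / ea$n + eb$sd^2 / eb$n)
  expect_lt(abs(ea$mean - eb$mean), 3 * se)
})
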