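# Site Hamiltonians, static disorder, exciton diagonalization and labels.

test_that("table values appear verbatim in the assembled Hamiltonians", {
  g <- test_geometry()
  hp <- build_site_hamiltonian(g, environment_parameters("POPC"), "full")
  expect_equal(hp$H[10, 11], 339)   # alpha1-beta1 intra-dimer (sites 9,10)
  expect_equal(hp$H[11, 12], 317)   # beta1-alpha2 inter-dimer (sites 10,11)
  expect_equal(hp$H[1, 12], 42)     # B800_0 - alpha_1 cross NN
  hd <- build_site_hamiltonian(g, environment_parameters("detergent"), "full")
  expect_equal(unname(diag(hd$H)[1:9]), rep(12540, 9))
  expect_identical(hd$H, t(hd$H))
})

test_that("disorder draws are per-ring, reproducible and unbiased", {
  g <- test_geometry()
  p <- environment_parameters("detergent")
  h0 <- build_site_hamiltonian(g, p, "full")
  # sigma = 0 leaves H unchanged
  p0 <- environment_parameters("detergent", sigma_B800 = 0, sigma_B850 = 0)
  h00 <- build_site_hamiltonian(g, p0, "full")
  expect_equal(apply_disorder(h00, 5, 3)$H, h00$H)
  # determinism: identical (seed, index) twice
  expect_identical(apply_disorder(h0, 11, 7)$H, apply_disorder(h0, 11, 7)$H)
  expect_false(identical(apply_disorder(h0, 11, 7)$H, apply_disorder(h0, 11, 8)$H))
  # variance of B850 offsets over many realizations matches sigma^2
  d850 <- replicate(10000, {
    hd <- apply_disorder(h0, 2, sample.int(1e6, 1))
    hd$H[15, 15] - h0$H[15, 15]
  })
  expect_equal(stats::var(d850), 220^2, tolerance = 0.03)
  expect_lt(abs(mean(d850)) / 220, 0.05)
})

test_that("zero-disorder exciton spectra show the ring degeneracy pattern", {
  g <- test_geometry()
  p <- environment_parameters("detergent")
  ex <- diagonalize_and_label(build_site_hamiltonian(g, p, "B850"))
  E <- ex$energies
  gaps <- diff(E)
  # singlet, four pairs, four pairs, singlet
  pair_idx <- c(2, 4, 6, 8, 10, 12, 14, 16)   # gaps within degenerate pairs
  expect_true(all(gaps[pair_idx] < 1e-6))
  expect_true(all(gaps[c(1, 17)] > 1))
  expect_equal(ex$labels[1], "k=0")
  expect_equal(ex$labels[18], "k=9")
  # B800: one low singlet + four pairs
  e8 <- diagonalize_and_label(build_site_hamiltonian(g, p, "B800"))
  g8 <- diff(e8$energies)
  expect_true(all(g8[c(2, 4, 6, 8)] < 1e-6))
  expect_gt(g8[1], 1)
  expect_equal(e8$labels, paste0("D=", 0:8))
})

test_that("k = +-1 excitons carry nearly all B850 dipole strength at zero disorder", {
  g <- test_geometry()
  ex <- diagonalize_and_label(
    build_site_hamiltonian(g, environment_parameters("detergent"), "B850"))
  frac <- sum(ex$dipole_strengths[2:3]) / sum(ex$dipole_strengths)
  expect_gt(frac, 0.95)
})

test_that("eigendecomposition satisfies reconstruction, orthonormality and
           the dipole sum rule", {
  g <- test_geometry()
  p <- environment_parameters("POPC")
  h <- apply_disorder(build_site_hamiltonian(g, p, "full"), 3, 1)
  for (scope in c("B800", "B850")) {
    hs <- build_site_hamiltonian(g, p, scope)
    idx <- match(hs$site_order, h$site_order)
    hs$H <- h$H[idx, idx]
    ex <- diagonalize_and_label(hs)
    C <- ex$coefficients
    expect_lt(max(abs(crossprod(C) - diag(nrow(C)))), 1e-9)
    expect_lt(max(abs(C %*% diag(ex$energies) %*% t(C) - hs$H)), 1e-8)
    mu2_sites <- sum(vapply(hs$geometry$ring_class,
                            function(rc) lh2et:::.ring_C(p, rc), numeric(1)))
    expect_equal(sum(ex$dipole_strengths), mu2_sites, tolerance = 1e-9)
  }
  expect_error(diagonalize_and_label(
    structure(list(H = matrix(c(1, 2, 0, 1), 2),
                   block_tags = c("B800", "B800"), site_order = 0:1,
                   geometry = g[1:2, ], params = p, scope = "B800"),
              class = "lh2_hamiltonian")), "symmetric")
})

test_that("eigenvalues of a toy ring match characteristic-polynomial roots", {
  # brute-force oracle: 4-site ring, roots of det(H - x I)
  H <- matrix(0, 4, 4)
  diag(H) <- c(100, 120, 90, 110)
  for (i in 1:4) { j <- i %% 4 + 1; H[i, j] <- H[j, i] <- 30 }
  ev <- sort(eigen(H, symmetric = TRUE)$values)
  # characteristic polynomial coefficients via symbolic expansion of minors
  cp <- c(det(H),
          -sum(vapply(1:4, function(i) det(H[-i, -i, drop = FALSE]), numeric(1))),
          sum(apply(utils::combn(4, 2), 2, function(ij) det(H[-ij, -ij, drop = FALSE]))),
          -sum(diag(H)), 1)
  roots <- sort(Re(polyroot(cp)))
  expect_equal(ev, roots, tolerance = 1e-8)
})

test_that("disorder-averaged energies converge to the clean spectrum as sigma -> 0", {
  g <- test_geometry()
  p1 <- environment_parameters("detergent", sigma_B800 = 1, sigma_B850 = 1)
  h0 <- build_site_hamiltonian(g, p1, "B850")
  E0 <- eigen(build_site_hamiltonian(g, environment_parameters(
    "detergent", sigma_B800 = 0, sigma_B850 = 0), "B850")$H, symmetric = TRUE,
    only.values = TRUE)$values
  acc <- 0
  n <- 1000
  for (r in seq_len(n))
    acc <- acc + sort(eigen(apply_disorder(h0, 9, r)$H, symmetric = TRUE,
                            only.values = TRUE)$values)
  expect_lt(max(abs(acc / n - sort(E0))), 1)
})

test_that("static disorder lifts the pair degeneracies monotonically", {
  g <- test_geometry()
  splits <- vapply(c(0, 50, 100, 200, 300, 400), function(sig) {
    p <- environment_parameters("detergent", sigma_B850 = max(sig, 1e-9),
                                sigma_B800 = 1e-9)
    h0 <- build_site_hamiltonian(g, p, "B850")
    mean(replicate(150, {
      E <- sort(eigen(apply_disorder(h0, 17, sample.int(1e6, 1))$H,
                      symmetric = TRUE, only.values = TRUE)$values)
      mean(E[seq(3, 17, by = 2)] - E[seq(2, 16, by = 2)])  # |E(+k) - E(-k)|
    }), numeric(1))
  }, numeric(1))
  expect_true(all(diff(splits) > 0))
})
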