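# Frenkel exciton Hamiltonians for the LH2 site basis.
#
# The diagonal carries the ring-class site energies (the tabulated "site
# energy", i.e. the vertical transition energy including reorganization);
# off-diagonal couplings come from the point-dipole formula except for the
# four tabulated nearest-neighbour classes, which are overridden with the
# parameter-table values (B800-B800, intra-/inter-dimer B850, B800-B850alpha).

#' Build the site-basis Hamiltonian
#'
#' @param geometry an `lh2_geometry`
#' @param params an `lh2_params`
#' @param scope `"full"` (27 sites), `"B800"` (9) or `"B850"` (18)
#' @return object of class `lh2_hamiltonian`: list with `H` (symmetric matrix,
#'   cm^-1), `site_order` (0-based ids), `block_tags` (ring class per index),
#'   `geometry`, `params`, `scope`
#' @export
build_site_hamiltonian <- function(geometry, params, scope = c("full", "B800", "B850")) {
  scope <- match.arg(scope)
  stopifnot(inherits(geometry, "lh2_geometry"), inherits(params, "lh2_params"))
  geo <- geometry[order(geometry$site_id), ]
  N <- nrow(geo)
  pos <- as.matrix(geo[, c("x", "y", "z")])
  dip <- as.matrix(geo[, c("dx", "dy", "dz")])
  Cs <- vapply(geo$ring_class, function(rc) .ring_C(params, rc), numeric(1))
  Cpair <- sqrt(outer(Cs, Cs))  # same-ring: the ring constant; cross-ring: geometric mean
  # pairwise point-dipole couplings, vectorised
  dd <- dip %*% t(dip)
  H <- matrix(0, N, N)
  for (i in seq_len(N - 1)) {
    j <- (i + 1):N
    r <- pos[j, , drop = FALSE] - matrix(pos[i, ], length(j), 3, byrow = TRUE)
    rn <- sqrt(rowSums(r^2))
    rh <- r / rn
    pi_ <- drop(rh %*% dip[i, ])
    pj <- rowSums(rh * dip[j, , drop = FALSE])
    v <- Cpair[i, j] * (dd[i, j] - 3 * pi_ * pj) / rn^3
    H[i, j] <- v
    H[j, i] <- v
  }
  diag(H) <- vapply(geo$ring_class, function(rc) .ring_site_energy(params, rc), numeric(1))
  # nearest-neighbour overrides (site ids are 0-based; matrix is 1-based)
  ov <- nn_pairs()
  set_pairs <- function(H, idx, value) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1] + 1; j <- idx[r, 2] + 1
      H[i, j] <- value; H[j, i] <- value
    }
    H
  }
  H <- set_pairs(H, ov$B800, params$V_B800)
  H <- set_pairs(H, ov$intra, params$V_a1b1)
  H <- set_pairs(H, ov$inter, params$V_a2b1)
  H <- set_pairs(H, ov$cross, params$V_B800a2)
  keep <- switch(scope,
                 full = seq_len(N),
                 B800 = which(geo$ring_class == "B800"),
                 B850 = which(geo$ring_class != "B800"))
  structure(list(H = H[keep, keep, drop = FALSE],
                 site_order = geo$site_id[keep],
                 block_tags = geo$ring_class[keep],
                 geometry = geo[keep, ],
                 params = params, scope = scope),
            class = "lh2_hamiltonian")
}

# deterministic per-realization RNG stream: a simple 64-bit-safe LCG mix of
# (seed, index) producing a 31-bit stream seed, so ensembles are
# order-independent and resumable
.stream_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + as.numeric(index) * 1013904223) %% m
  s <- (s * 69621) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Apply one realization of Gaussian static disorder
#'
#' Adds independent Gaussian offsets (mean 0, per-ring standard deviation
#' `sigma_B800`/`sigma_B850`) to the diagonal site energies. The draw is a
#' pure function of `(seed, realization)`: realizations form independent,
#' order-independent streams.
#'
#' @param hamiltonian an `lh2_hamiltonian`
#' @param seed master seed (integer)
#' @param realization realization index (integer >= 1)
#' @return a new `lh2_hamiltonian` with shifted diagonal
#' @export
apply_disorder <- function(hamiltonian, seed, realization = 1) {
  stopifnot(inherits(hamiltonian, "lh2_hamiltonian"))
  force(seed); force(realization)   # evaluate before touching the RNG state
  p <- hamiltonian$params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(.stream_seed(seed, realization))
  sig <- vapply(hamiltonian$block_tags, function(rc) .ring_sigma(p, rc), numeric(1))
  delta <- stats::rnorm(length(sig), mean = 0, sd = sig)
  out <- hamiltonian
  diag(out$H) <- diag(out$H) + delta
  out$realization <- realization
  out
}

# rank -> label map for the 18 B850 excitons (ascending energy):
# 0, -1, +1, -2, +2, ..., -8, +8, 9
.b850_labels <- function() {
  k <- c(0, as.vector(rbind(-(1:8), 1:8)), 9)
  k
}

#' Diagonalize a site Hamiltonian and label the excitons
#'
#' Eigenstates are sorted by ascending energy. B850 blocks get rank labels
#' k = 0, -1, +1, ..., -8, +8, 9; B800 blocks get D = 0..8. At zero disorder
#' the doubly degenerate pairs are resolved by overlap with the cos/sin ring
#' harmonics of matching order (the cosine-like combination takes the -k
#' label); under disorder plain energy ranking applies. Transition-dipole
#' strengths use mu_i = sqrt(C_ring) * d_i so that |mu_alpha|^2 is in
#' Angstrom^3 cm^-1-consistent units and the unitary sum rule holds.
#'
#' @param hamiltonian an `lh2_hamiltonian`
#' @return object of class `lh2_excitons`: `energies` (ascending, cm^-1),
#'   `coefficients` (columns are excitons), `labels` (character),
#'   `k` (numeric label), `dipole_strengths`, plus the originating block tags
#' @export
diagonalize_and_label <- function(hamiltonian) {
  stopifnot(inherits(hamiltonian, "lh2_hamiltonian"))
  H <- hamiltonian$H
  if (max(abs(H - t(H))) > 1e-9) stop("Hamiltonian must be symmetric")
  N <- nrow(H)
  es <- eigen(H, symmetric = TRUE)
  idx <- order(es$values)
  E <- es$values[idx]
  C <- es$vectors[, idx, drop = FALSE]
  geo <- hamiltonian$geometry
  # degenerate-pair resolution by ring harmonics (zero-disorder spectra)
  theta <- atan2(geo$y, geo$x)
  pure_ring <- hamiltonian$scope %in% c("B800", "B850")
  if (pure_ring) {
    m <- 1
    r <- 2
    while (r < N) {
      if (abs(E[r + 1] - E[r]) < 1e-6 * (1 + abs(E[r]))) {
        P <- C[, c(r, r + 1)]
        cm <- cos(m * theta); sm <- sin(m * theta)
        a <- drop(crossprod(P, cm)); b <- drop(crossprod(P, sm))
        if (sqrt(sum(a^2)) > 1e-8 && sqrt(sum(b^2)) > 1e-8) {
          v1 <- drop(P %*% a); v1 <- v1 / sqrt(sum(v1^2))
          v2 <- drop(P %*% b); v2 <- v2 - v1 * sum(v1 * v2)
          v2 <- v2 / sqrt(sum(v2^2))
          C[, r] <- v1; C[, r + 1] <- v2
        }
      }
      r <- r + 2; m <- m + 1
    }
  }
  # deterministic sign convention
  for (a in seq_len(N)) {
    piv <- which.max(abs(C[, a]))
    if (C[piv, a] < 0) C[, a] <- -C[, a]
  }
  if (all(hamiltonian$block_tags == "B800")) {
    k <- 0:8
    labels <- paste0("D=", k)
  } else if (!any(hamiltonian$block_tags == "B800") && N == 18) {
    k <- .b850_labels()
    labels <- paste0("k=", ifelse(k > 0 & k < 9, paste0("+", k), k))
  } else {
    k <- seq_len(N) - 1
    labels <- paste0("a=", k)
  }
  mu <- sweep(as.matrix(geo[, c("dx", "dy", "dz")]), 1,
              sqrt(vapply(geo$ring_class, function(rc) .ring_C(hamiltonian$params, rc),
                          numeric(1))), `*`)
  mu_exc <- t(C) %*% mu                     # N x 3
  dip2 <- rowSums(mu_exc^2)
  structure(list(energies = E, coefficients = C, labels = labels, k = k,
                 dipole_strengths = dip2,
                 block_tags = hamiltonian$block_tags,
                 site_order = hamiltonian$site_order,
                 scope = hamiltonian$scope,
                 geometry = geo, params = hamiltonian$params),
            class = "lh2_excitons")
}
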