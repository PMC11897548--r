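# Shared fixtures: the calibrated geometry and memoized per-environment
# engines / ensembles so expensive objects are built once per test run.

.lh2_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .lh2_cache, inherits = FALSE))
    assign(key, force(expr), envir = .lh2_cache)
  get(key, envir = .lh2_cache, inherits = FALSE)
}

test_geometry <- function() cached("geometry", generate_c9_geometry())

test_engine <- function(env) {
  cached(paste0("engine_", env),
         gft_engine(environment_parameters(env), test_geometry()))
}

# acceptance-scale GFT ensembles, shared across acceptance criteria
acceptance_ensemble <- function(env, n = 2000, seed = 421) {
  cached(paste0("acc_gft_", env, "_", n, "_", seed),
         rate_ensemble(environment_parameters(env), n = n, seed = seed,
                       geometry = test_geometry(),
                       engine = test_engine(env)))
}

acceptance_delocalization <- function(env, n = 10000, seed = 73) {
  cached(paste0("acc_del_", env, "_", n, "_", seed),
         ensemble_delocalization(environment_parameters(env), n, seed = seed,
                                 geometry = test_geometry()))
}

# default line-broadening grid for lineshape tests
test_gl <- function(lambda = 160, gamma = 53, T = 300, K = 1,
                    t_max = 3, dt = 0.001) {
  line_broadening(matsubara_expansion(drude_lorentz_bath(lambda, gamma, T), K),
                  seq(0, t_max, by = dt))
}

# write a minimal PDB file for a geometry (MG/NB/ND per BCL residue)
write_fixture_pdb <- function(geometry, path, n_residues = 27) {
  lines <- character(0)
  serial <- 1
  for (r in seq_len(min(nrow(geometry), n_residues))) {
    mg <- c(geometry$x[r], geometry$y[r], geometry$z[r])
    d <- c(geometry$dx[r], geometry$dy[r], geometry$dz[r])
    nb <- mg - d * 1.5
    nd <- mg + d * 1.5
    ch <- LETTERS[(geometry$subunit[r] %% 26) + 1]
    for (at in list(c("MG", mg), c("NB", nb), c("ND", nd))) {
      xyz <- as.numeric(at[-1])
      # strict PDB columns: name 13-16, resName 18-20, chainID 22, resSeq 23-26
      lines <- c(lines, sprintf(
        "HETATM%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, at[1], "BCL", ch, r, xyz[1], xyz[2], xyz[3],
        substr(at[1], 1, 2)))
      serial <- serial + 1
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
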