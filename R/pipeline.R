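# Campaign orchestration: seeded multi-environment ensembles, table export,
# and small test-scale fixture models.

#' Campaign configuration
#'
#' @param environments character vector drawn from detergent/POPC/DOPC
#' @param method `"gft"`, `"heom"` or `"both"`
#' @param n_realizations GFT ensemble size per environment
#' @param n_delocalization realizations for the delocalization tables
#' @param seed master seed; GFT and HEOM share per-index disorder streams
#' @param heom_n HEOM ensemble size (shared disorder indices 1..heom_n)
#' @param heom_config an [heom_config()] for the HEOM rate runs
#' @param outdir optional output directory for CSV export
#' @return list of class `lh2_campaign_config`
#' @export
campaign_config <- function(environments = c("detergent", "POPC", "DOPC"),
                            method = c("gft", "heom", "both"),
                            n_realizations = 2000, n_delocalization = 2000,
                            seed = 1, heom_n = 0,
                            heom_config = lh2et::heom_config(L = 4, M = 1),
                            outdir = NULL) {
  method <- match.arg(method)
  if (!length(environments)) stop("environment list is empty")
  bad <- setdiff(environments, .ENV_LABELS)
  if (length(bad)) stop("unknown environment(s): ", paste(bad, collapse = ", "))
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  structure(list(environments = environments, method = method,
                 n_realizations = n_realizations,
                 n_delocalization = n_delocalization, seed = seed,
                 heom_n = heom_n, heom_config = heom_config, outdir = outdir),
            class = "lh2_campaign_config")
}

#' Run a full comparison campaign
#'
#' For each environment: the GFT rate ensemble with pathway decomposition,
#' the delocalization tables, and the electronic figure of merit of the
#' dominant pathway; optionally HEOM Pauli-fit rates on the same disorder
#' realizations. Deterministic given `(config, seed)`.
#'
#' @param config an `lh2_campaign_config`
#' @param geometry an `lh2_geometry`
#' @return object of class `lh2_comparison_report`: `rates` (per environment
#'   and method: mean, sd, se, n), `delocalization`, `pathways` (top 10 per
#'   environment), `figure_of_merit`, `parameters`
#' @export
run_campaign <- function(config, geometry = generate_c9_geometry()) {
  stopifnot(inherits(config, "lh2_campaign_config"))
  rates <- NULL; deloc <- NULL; paths <- NULL; fom <- NULL; params_echo <- NULL
  ensembles <- list()
  for (env in config$environments) {
    p <- environment_parameters(env)
    params_echo <- rbind(params_echo,
                         data.frame(environment = env,
                                    field = names(unclass(p))[-1],
                                    value = unlist(lapply(unclass(p)[-1], as.character)),
                                    row.names = NULL))
    if (config$method %in% c("gft", "both")) {
      e <- rate_ensemble(p, config$n_realizations, seed = config$seed,
                         geometry = geometry)
      ensembles[[env]] <- e
      rates <- rbind(rates, data.frame(
        environment = env, method = "GFT", mean_ps1 = e$mean, sd_ps1 = e$sd,
        se_ps1 = e$sd / sqrt(e$n), n = e$n))
      dp <- dominant_pathways(e)
      paths <- rbind(paths, cbind(environment = env, utils::head(dp, 10)))
    }
    ed <- ensemble_delocalization(p, config$n_delocalization,
                                  seed = config$seed, geometry = geometry)
    pl <- ed$per_label
    deloc <- rbind(deloc, cbind(environment = env, pl))
    if (config$method %in% c("gft", "both")) {
      dp1 <- paths[paths$environment == env, ][1, ]
      cd <- pl[pl$ring == "B800" & pl$label == dp1$donor, ]
      ca <- pl[pl$ring == "B850" & pl$label == dp1$acceptor, ]
      f <- figure_of_merit(cd$Cl1, ca$Cl1, cd$IPR, ca$IPR, p$V_B800a2)
      fom <- rbind(fom, data.frame(environment = env, donor = dp1$donor,
                                   acceptor = dp1$acceptor,
                                   fom_Cl1 = f["fom_Cl1"], fom_IPR = f["fom_IPR"],
                                   geom_Cl1 = f["geom_Cl1"], row.names = NULL))
    }
    if (config$method %in% c("heom", "both") && config$heom_n > 0) {
      h0 <- build_site_hamiltonian(geometry, p, "full")
      kd <- numeric(config$heom_n)
      for (r in seq_len(config$heom_n)) {
        hd <- apply_disorder(h0, config$seed, r)
        model <- heom_model_lh2(hd)
        tr <- propagate_heom(model, config$heom_config)
        kd[r] <- fit_pauli(tr)$k_down
      }
      rates <- rbind(rates, data.frame(
        environment = env, method = "HEOM", mean_ps1 = mean(kd),
        sd_ps1 = if (config$heom_n > 1) stats::sd(kd) else NA_real_,
        se_ps1 = if (config$heom_n > 1) stats::sd(kd) / sqrt(config$heom_n) else NA_real_,
        n = config$heom_n))
    }
  }
  rep <- structure(list(rates = rates, delocalization = deloc,
                        pathways = paths, figure_of_merit = fom,
                        parameters = params_echo, config = config,
                        ensembles = ensembles),
                   class = "lh2_comparison_report")
  if (!is.null(config$outdir)) export_tables(rep, config$outdir)
  rep
}

#' Export a comparison report as CSV tables
#'
#' Writes the parameter echo, rate summary, delocalization, pathway and
#' figure-of-merit tables. Missing report sections are skipped with a note.
#'
#' @param report an `lh2_comparison_report`
#' @param outdir output directory (created if needed)
#' @return invisible vector of written file paths
#' @export
export_tables <- function(report, outdir) {
  stopifnot(inherits(report, "lh2_comparison_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) {
      message("section ", name, " missing; skipped")
      return(invisible(NULL))
    }
    path <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  wr(report$parameters, "parameters")
  wr(report$delocalization, "delocalization")
  if (!is.null(report$pathways)) {
    pw <- report$pathways[order(report$pathways$environment, -report$pathways$Pk), ]
    wr(pw, "pathways")
  }
  wr(report$figure_of_merit, "figure_of_merit")
  wr(report$rates, "rate_summary")
  invisible(written)
}

#' Small fixture models for testing and method development
#'
#' Reduced systems with the same structure as the LH2 model (site energies,
#' nearest-neighbour couplings, per-site Drude-Lorentz baths, optional
#' disorder widths) but few sites, sized for fast HEOM runs:
#' `monomer` (1 site), `dimer` (2), `trimer` (3), and `reduced-ring-3x3`
#' (a C3-symmetric miniature of LH2: 3 B800 sites + 6 B850 sites with
#' intra-/inter-dimer alternation and B800-B850alpha cross couplings).
#'
#' @param kind fixture name
#' @param params an `lh2_params` supplying energies, couplings and baths
#' @param E,V energy/coupling overrides for monomer/dimer/trimer (cm^-1)
#' @return an `lh2_heom_model`; attribute `"block_tags"` marks ring
#'   membership for the reduced ring
#' @export
make_fixture <- function(kind = c("dimer", "trimer", "reduced-ring-3x3", "monomer"),
                         params = environment_parameters("detergent"),
                         E = NULL, V = NULL) {
  kind <- match.arg(kind)
  p <- params
  if (kind == "monomer") {
    H <- matrix(if (is.null(E)) p$E_B850a else E[1], 1, 1)
    return(heom_model(H, p$lambda_B850, p$gamma_B850, p$T,
                      dipoles = matrix(c(1, 0, 0), 1, 3), pop_sites = 1L))
  }
  if (kind == "dimer") {
    Ev <- if (is.null(E)) c(p$E_B800, p$E_B850a) else rep_len(E, 2)
    Vv <- if (is.null(V)) p$V_B800a2 else V[1]
    H <- matrix(c(Ev[1], Vv, Vv, Ev[2]), 2, 2)
    return(heom_model(H, c(p$lambda_B800, p$lambda_B850),
                      c(p$gamma_B800, p$gamma_B850), p$T,
                      dipoles = rbind(c(1, 0, 0), c(0, 1, 0)), pop_sites = 1L))
  }
  if (kind == "trimer") {
    Ev <- if (is.null(E)) c(p$E_B800, p$E_B850a, p$E_B850b) else rep_len(E, 3)
    Vv <- if (is.null(V)) c(p$V_B800a2, p$V_a1b1) else rep_len(V, 2)
    H <- diag(Ev)
    H[1, 2] <- H[2, 1] <- Vv[1]
    H[2, 3] <- H[3, 2] <- Vv[2]
    return(heom_model(H, c(p$lambda_B800, p$lambda_B850, p$lambda_B850),
                      c(p$gamma_B800, p$gamma_B850, p$gamma_B850), p$T,
                      dipoles = rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)),
                      pop_sites = 1L))
  }
  # reduced-ring-3x3: sites 1-3 B800, then alpha/beta x3
  N <- 9
  tags <- c(rep("B800", 3), rep(c("B850a", "B850b"), 3))
  H <- diag(c(rep(p$E_B800, 3), rep(c(p$E_B850a, p$E_B850b), 3)))
  setpair <- function(H, i, j, v) { H[i, j] <- v; H[j, i] <- v; H }
  for (n in 0:2) {
    H <- setpair(H, n + 1, (n + 1) %% 3 + 1, p$V_B800)                 # B800 ring
    a <- 4 + 2 * n; b <- 5 + 2 * n
    H <- setpair(H, a, b, p$V_a1b1)                                    # intra dimer
    H <- setpair(H, b, 4 + 2 * ((n + 1) %% 3), p$V_a2b1)               # inter dimer
    H <- setpair(H, n + 1, 4 + 2 * ((n + 1) %% 3), p$V_B800a2)         # cross
  }
  th <- (0:2) * 2 * pi / 3
  dip <- rbind(cbind(-sin(th), cos(th), 0),
               do.call(rbind, lapply(0:2, function(n) {
                 rbind(c(-sin(th[n + 1]), cos(th[n + 1]), 0),
                       -c(-sin(th[n + 1] + 0.3), cos(th[n + 1] + 0.3), 0))
               })))
  m <- heom_model(H, ifelse(tags == "B800", p$lambda_B800, p$lambda_B850),
                  ifelse(tags == "B800", p$gamma_B800, p$gamma_B850), p$T,
                  dipoles = dip, pop_sites = 1:3)
  attr(m, "block_tags") <- tags
  attr(m, "sigma") <- ifelse(tags == "B800", p$sigma_B800, p$sigma_B850)
  m
}

#' Load a campaign configuration from a YAML or JSON file
#'
#' The file may contain any subset of the [campaign_config()] fields
#' (`environments`, `method`, `n_realizations`, `n_delocalization`, `seed`,
#' `heom_n`, `outdir`); missing fields take the defaults.
#'
#' @param path configuration file (extension `.yml`/`.yaml` or `.json`)
#' @return an `lh2_campaign_config`
#' @export
load_campaign_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  allowed <- c("environments", "method", "n_realizations", "n_delocalization",
               "seed", "heom_n", "outdir")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(campaign_config, raw)
}
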