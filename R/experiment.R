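#' Run a declarative experiment
#'
#' Executes a generate -> simulate/solve -> analyse pipeline described by
#' a YAML configuration file and writes CSV outputs plus a JSON manifest
#' (parameters, seeds, package version, wall time) into `out_dir`.
#' Identical configurations produce byte-identical outputs.
#'
#' The configuration must contain `seed`, `mode` (one of `simulate`,
#' `ame`, `sweep`, `boundaries`), a `network` section (`degree`: kind and
#' parameters; `weights`: kind, `mu`, `sigma`, `delta`) and a `dynamics`
#' section (`phi`, `p`, `t_max`, optional `rho_stop`, `sample_dt`).
#' Defaults mirror the regular-network benchmark: `k = 7`, `mu = 1`,
#' `delta = 0.5`, `p = 2e-4`, `N = 10000`, `rho_target = 0.75`, 25
#' replicates.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return named list of output file paths, invisibly.
#' @export
run_experiment <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list")
  need <- function(path, default = NULL) {
    node <- cfg
    for (f in path) {
      if (is.null(node[[f]])) {
        if (!is.null(default)) return(default)
        stop("config field missing: ", paste(path, collapse = "."))
      }
      node <- node[[f]]
    }
    node
  }
  seed <- as.integer(need("seed"))
  mode <- match.arg(need("mode", "simulate"),
                    c("simulate", "ame", "sweep", "boundaries"))
  N <- as.integer(need(c("network", "N"), 10000L))
  dkind <- need(c("network", "degree", "kind"), "regular")
  dspec <- switch(dkind,
    regular = degree_spec("regular", N = N,
                          k = need(c("network", "degree", "k"), 7L)),
    powerlaw = degree_spec("powerlaw", N = N,
                           tau = need(c("network", "degree", "tau"), 2.5),
                           k_min = need(c("network", "degree", "k_min"), 2L),
                           k_max = need(c("network", "degree", "k_max"), 1000L)),
    stop("unsupported degree kind: ", dkind))
  mu <- need(c("network", "weights", "mu"), 1)
  delta <- need(c("network", "weights", "delta"), 0.5)
  sigma <- need(c("network", "weights", "sigma"), 0.5)
  wkind <- need(c("network", "weights", "kind"), "bimodal")
  phi <- need(c("dynamics", "phi"))
  p <- need(c("dynamics", "p"), 2e-4)
  t_max <- need(c("dynamics", "t_max"), 1000)
  rho_target <- need(c("dynamics", "rho_target"), 0.75)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  files <- list()
  csv <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    files[[name]] <<- path
    path
  }
  if (mode == "simulate") {
    scheme <- weight_scheme(wkind, mu = mu, sigma = sigma, delta = delta)
    reps <- as.integer(need("reps", 25L))
    per_rep <- list()
    for (r in seq_len(reps)) {
      rep_seed <- seed + 1000L * r
      net <- generate_network(dspec, scheme, seed = rep_seed,
                              n_types = if (wkind == "bimodal") NULL else 2L)
      simc <- sim_config(phi = phi, p = p, t_max = t_max,
                         rho_stop = need(c("dynamics", "rho_stop"), 1),
                         sample_dt = need(c("dynamics", "sample_dt"), 0.1),
                         seed = rep_seed + 7L)
      ser <- run_mc(net, simc)
      df <- data.frame(rep = r, t = ser$times, rho = ser$rho)
      if (!is.null(ser$E_II)) {
        colnames(ser$E_II) <- paste0("E_II_", seq_len(ncol(ser$E_II)))
        colnames(ser$E_SI) <- paste0("E_SI_", seq_len(ncol(ser$E_SI)))
        df <- cbind(df, ser$E_II, ser$E_SI)
      }
      per_rep[[r]] <- df
    }
    allreps <- do.call(rbind, per_rep)
    csv(allreps, "trajectories")
    t_a <- vapply(per_rep, function(df)
      absolute_time(list(times = df$t, rho = df$rho), rho_target), 0)
    csv(data.frame(rep = seq_len(reps), t_a = t_a), "t_a")
  } else if (mode == "ame") {
    scheme <- weight_scheme(wkind, mu = mu, sigma = sigma, delta = delta)
    n_types <- as.integer(need(c("dynamics", "n_types"),
                               if (wkind == "bimodal") 2L else 6L))
    basis <- discretise_weights(scheme, n_types)
    P_k <- truncate_degree_distribution(degree_distribution(dspec))
    form <- need(c("dynamics", "form"), "reduced")
    if (form == "full") {
      traj <- integrate_full_ame(P_k, basis, phi, p, t_max = t_max)
      ef <- ame_edge_fractions(traj)
      df <- data.frame(t = traj$times, rho = traj$rho)
      colnames(traj$nu) <- paste0("nu_", seq_len(ncol(traj$nu)))
      colnames(ef$E_II) <- paste0("E_II_", seq_len(ncol(ef$E_II)))
      colnames(ef$E_SI) <- paste0("E_SI_", seq_len(ncol(ef$E_SI)))
      df <- cbind(df, traj$nu, ef$E_II, ef$E_SI)
    } else {
      traj <- integrate_reduced(P_k, basis, phi, p, t_max = t_max)
      df <- data.frame(t = traj$times, rho = traj$rho)
      colnames(traj$nu) <- paste0("nu_", seq_len(ncol(traj$nu)))
      df <- cbind(df, traj$nu)
    }
    csv(df, "ame")
  } else if (mode == "sweep") {
    grid <- parameter_sweep(
      dspec,
      sigma_values = unlist(need(c("grid", "sigma"))),
      phi_values = unlist(need(c("grid", "phi"))),
      mu = mu, delta = delta, p = p,
      engine = need("engine", "ame"),
      reps = as.integer(need("reps", 25L)), seed = seed,
      rho_target = rho_target, t_max = t_max)
    grid$t_a[!is.finite(grid$t_a)] <- Inf
    csv(grid, "sweep")
  } else {
    bounds <- enumerate_boundaries(
      k = unlist(need(c("boundaries", "k"), 7L)), mu = mu, delta = delta,
      sigma_range = unlist(need(c("boundaries", "sigma_range"), c(0, 1))),
      phi_range = unlist(need(c("boundaries", "phi_range"), c(0.05, 0.5))))
    csv(bounds, "boundaries")
  }
  manifest <- list(package = "wtcascade",
                   version = as.character(packageVersion("wtcascade")),
                   config = cfg,
                   outputs = lapply(files, normalizePath),
                   elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  files$manifest <- mpath
  invisible(files)
}

#' Generate small deterministic fixture networks
#'
#' Writes four small edge lists used for exercising the toolkit: the
#' complete graph on 8 nodes (unit weights), a 7-regular network on 100
#' nodes, a truncated power-law network on 500 nodes, and a signed edge
#' list whose positive-tie fraction is 0.88.
#'
#' @param seed integer RNG seed.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
make_fixtures <- function(seed = 1L, dir = ".") {
  seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(k8 = file.path(dir, "complete_k8.tsv"),
             regular = file.path(dir, "regular7_n100.tsv"),
             powerlaw = file.path(dir, "powerlaw_n500.tsv"),
             signed = file.path(dir, "signed_delta088.tsv"))
  pairs <- t(combn(0:7, 2L))
  write_edge_list(weighted_network(
    data.frame(from = pairs[, 1L], to = pairs[, 2L], weight = 1)), paths["k8"])
  reg <- build_configuration_model(rep(7L, 100L), seed = seed)
  write_edge_list(reg, paths["regular"])
  pl <- degree_spec("powerlaw", N = 500L, tau = 2.5, k_min = 2L, k_max = 50L)
  plnet <- build_configuration_model(sample_degree_sequence(pl, seed = seed),
                                     seed = seed + 1L)
  write_edge_list(plnet, paths["powerlaw"])
  # signed fixture: 7-regular topology, exactly round(0.88 E) positive ties
  set.seed(seed + 2L)
  sn <- build_configuration_model(rep(7L, 100L), seed = seed + 3L)
  E <- nrow(sn$edges)
  sgn <- rep(-1L, E)
  sgn[sample.int(E, round(0.88 * E))] <- 1L
  writeLines(sprintf("%d\t%d\t%+d", sn$edges$from, sn$edges$to, sgn),
             paths["signed"])
  paths
}
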