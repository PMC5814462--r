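#' Simulation configuration
#'
#' Parameters of the asynchronous Monte Carlo dynamics. Time is measured in
#' sweeps: one sweep is `N` single-node updates, with time advancing `1/N`
#' per update.
#'
#' @param phi adoption threshold, in (0, 1): a susceptible node adopts when
#'   its partial strength `q_m` (summed weight to infected neighbours)
#'   reaches `phi * q_k` (total strength).
#' @param p spontaneous adoption probability per node update, in \[0, 1\].
#' @param t_max maximum simulated time in sweeps.
#' @param rho_stop stop once the infected density reaches this value.
#' @param sample_dt sampling interval for the recorded time series, sweeps.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(phi, p = 2e-4, t_max = 1000, rho_stop = 1,
                       sample_dt = 0.1, seed = 1L) {
  stopifnot(phi > 0, phi < 1, p >= 0, p <= 1, t_max > 0,
            rho_stop > 0, rho_stop <= 1, sample_dt > 0, sample_dt <= t_max)
  structure(list(phi = phi, p = p, t_max = t_max, rho_stop = rho_stop,
                 sample_dt = sample_dt, seed = as.integer(seed)),
            class = "sim_config")
}

#' Weighted threshold rule
#'
#' `TRUE` when the partial strength reaches the threshold fraction of the
#' total strength, `q_m >= phi * q_k`, with a relative tolerance of
#' `1e-12 * q_k` so that exact-equality configurations adopt despite
#' floating-point rounding.
#'
#' @param q_m partial strength (summed weight to infected neighbours).
#' @param q_k total node strength; must be positive (zero-strength nodes
#'   receive no influence and are handled by the caller).
#' @param phi threshold in (0, 1).
#' @return logical.
#' @export
threshold_satisfied <- function(q_m, q_k, phi) {
  stopifnot(all(q_k > 0))
  q_m >= phi * q_k - 1e-12 * q_k
}

#' Run the Monte Carlo threshold dynamics
#'
#' Asynchronous simulation of the monotone weighted threshold model: in
#' each update a uniformly chosen node, if susceptible, adopts
#' spontaneously with probability `p` or else adopts iff
#' `q_m >= phi * q_k`. Infected nodes never revert. The run ends at
#' `t_max`, when the infected density reaches `rho_stop`, or (for `p = 0`)
#' when no susceptible node can still adopt (frozen state).
#'
#' If the network edges carry a `type` column, per-type bulk and surface
#' edge fractions are tracked: `E_II[j]` is the fraction of type-j edges
#' among infected-infected edges, `E_SI[j]` among susceptible-infected
#' edges; each is `NA` while its category is empty.
#'
#' @param net a [weighted_network()].
#' @param cfg a [sim_config()].
#' @param init_infected integer vector of initially infected node ids
#'   (0-based); default none.
#' @return an object of class `cascade_series`: list with `times`, `rho`
#'   (non-decreasing), optional matrices `E_II`, `E_SI` (one column per
#'   type), `final_state` (0/1 per node) and `t_end`.
#' @export
run_mc <- function(net, cfg, init_infected = integer(0)) {
  stopifnot(inherits(net, "weighted_network"), inherits(cfg, "sim_config"))
  if (net$N < 1L) stop("empty network")
  init_infected <- as.integer(init_infected)
  if (length(init_infected) > 0L &&
      (any(init_infected < 0L) || any(init_infected >= net$N)))
    stop("init_infected ids must lie in [0, N)")
  etype <- net$edges$type
  if (is.null(etype)) {
    etype <- integer(nrow(net$edges))
    n_types <- 0L
  } else {
    n_types <- max(etype)
  }
  set.seed(cfg$seed)
  res <- mc_core(net$edges$from, net$edges$to, net$edges$weight,
                 as.integer(etype), n_types, net$N,
                 cfg$phi, cfg$p, cfg$t_max, cfg$sample_dt, cfg$rho_stop,
                 init_infected)
  structure(res, class = "cascade_series")
}

#' @export
print.cascade_series <- function(x, ...) {
  cat(sprintf("cascade_series: %d samples to t = %.2f sweeps, final rho = %.4f\n",
              length(x$times), x$t_end, x$rho[length(x$rho)]))
  invisible(x)
}

# per-node degree, strength, infected-neighbour count and partial strength
node_exposure <- function(net, states) {
  stopifnot(length(states) == net$N)
  e <- net$edges
  inf <- as.logical(states)
  idx <- c(e$from, e$to) + 1L
  other_inf <- c(inf[e$to + 1L], inf[e$from + 1L])
  w2 <- rep(e$weight, 2L)
  acc <- function(vals) {
    agg <- rowsum(vals, idx)
    out <- numeric(net$N)
    out[as.integer(rownames(agg))] <- agg[, 1L]
    out
  }
  list(k = network_degrees(net),
       q_k = acc(w2),
       m = as.integer(acc(as.numeric(other_inf))),
       q_m = acc(w2 * other_inf))
}

#' Bulk and surface edge fractions from a state snapshot
#'
#' For each weight type j, `E_II[j]` is the fraction of type-j edges among
#' edges joining two infected nodes (the cascade bulk) and `E_SI[j]` the
#' fraction among edges joining a susceptible and an infected node (the
#' cascade surface). Each family sums to 1; a family is all-`NA` while its
#' category is empty.
#'
#' @param net a [weighted_network()] whose edges carry a `type` column.
#' @param states 0/1 (or logical) vector of node states.
#' @return list with numeric vectors `E_II` and `E_SI` (length = number of
#'   types).
#' @export
measure_edge_fractions_mc <- function(net, states) {
  stopifnot(inherits(net, "weighted_network"))
  if (is.null(net$edges$type)) stop("network edges carry no weight types")
  inf <- as.logical(states)
  n_types <- max(net$edges$type)
  fi <- inf[net$edges$from + 1L]
  ti <- inf[net$edges$to + 1L]
  frac <- function(sel) {
    if (!any(sel)) return(rep(NA_real_, n_types))
    tabulate(net$edges$type[sel], nbins = n_types) / sum(sel)
  }
  list(E_II = frac(fi & ti), E_SI = frac(xor(fi, ti)))
}

#' Aggregated infection rate by (k, m) class
#'
#' Averages the per-node adoption rate (1 if the weighted threshold is
#' satisfied, else `p`; always `p` for zero-strength nodes) over the
#' susceptible nodes in each (degree, infected-neighbour-count) class.
#' In the unweighted limit this is exactly `p` below `ceiling(phi * k)`
#' infected neighbours and 1 at or above; with heterogeneous weights a
#' class mixes adopting and non-adopting weight configurations and its
#' aggregated rate falls strictly between `p` and 1.
#'
#' @param net a [weighted_network()].
#' @param states 0/1 (or logical) vector of node states.
#' @param cfg a [sim_config()] supplying `phi` and `p`.
#' @return data.frame with columns `k`, `m`, `F` (mean rate) and `n_nodes`,
#'   one row per non-empty susceptible class.
#' @export
aggregated_infection_rate_mc <- function(net, states, cfg) {
  stopifnot(inherits(net, "weighted_network"), inherits(cfg, "sim_config"))
  ex <- node_exposure(net, states)
  sus <- !as.logical(states)
  rate <- ifelse(ex$q_k > 0 & threshold_satisfied_vec(ex$q_m, ex$q_k, cfg$phi),
                 1, cfg$p)
  df <- data.frame(k = ex$k[sus], m = ex$m[sus], rate = rate[sus])
  agg <- aggregate(rate ~ k + m, data = df, FUN = mean)
  cnt <- aggregate(rate ~ k + m, data = df, FUN = length)
  out <- data.frame(k = agg$k, m = agg$m, F = agg$rate, n_nodes = cnt$rate)
  out[order(out$k, out$m), , drop = FALSE]
}

# vectorised threshold rule tolerating q_k = 0 (returns FALSE there)
threshold_satisfied_vec <- function(q_m, q_k, phi) {
  q_k > 0 & q_m >= phi * q_k - 1e-12 * q_k
}
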