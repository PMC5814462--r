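# Independent oracles and small fixture builders used across the suite.

# Deterministic closure of the threshold rule (p = 0): repeatedly infect
# every susceptible node whose partial strength reaches phi * q_k until a
# fixed point. Direct O(N^2)-ish iteration, independent of the simulator.
brute_force_cascade <- function(net, phi, init_infected) {
  inf <- rep(FALSE, net$N)
  inf[init_infected + 1L] <- TRUE
  e <- net$edges
  qk <- network_strengths(net)
  repeat {
    qm <- numeric(net$N)
    for (r in seq_len(nrow(e))) {
      if (inf[e$to[r] + 1L]) qm[e$from[r] + 1L] <- qm[e$from[r] + 1L] + e$weight[r]
      if (inf[e$from[r] + 1L]) qm[e$to[r] + 1L] <- qm[e$to[r] + 1L] + e$weight[r]
    }
    newly <- !inf & qk > 0 & qm >= phi * qk - 1e-12 * qk
    if (!any(newly)) return(as.integer(inf))
    inf <- inf | newly
  }
}

# Classic unweighted dynamic-Watts reduced AME (scalar nu), written
# directly from binomial sums with dbinom; independent of the package's
# reduced_system() table machinery.
unweighted_watts_trajectory <- function(P_k, phi, p, times) {
  z <- sum(P_k$k * P_k$prob)
  deriv <- function(t, y, parms) {
    nu <- min(max(y[1L], 0), 1); rho <- y[2L]
    ft <- 1 - (1 - p) * exp(-p * t)
    g <- 0; h <- 0
    for (r in seq_len(nrow(P_k))) {
      k <- P_k$k[r]
      msat <- function(m) m >= phi * k - 1e-12 * k
      if (k >= 1) {
        mm <- 0:(k - 1)
        g <- g + (k / z) * P_k$prob[r] *
          sum(dbinom(mm[msat(mm)], k - 1, nu))
      }
      mm <- 0:k
      if (k > 0) h <- h + P_k$prob[r] * sum(dbinom(mm[msat(mm)], k, nu))
    }
    list(c(ft + (1 - ft) * g - nu, ft + (1 - ft) * h - rho))
  }
  sol <- deSolve::ode(c(0, 0), times, deriv, NULL, rtol = 1e-8, atol = 1e-10)
  list(times = sol[, 1L], nu = sol[, 2L], rho = sol[, 3L])
}

complete_graph_k8 <- function(weight = 1) {
  pairs <- t(combn(0:7, 2L))
  weighted_network(data.frame(from = pairs[, 1L], to = pairs[, 2L],
                              weight = weight))
}

benchmark_pk <- function() data.frame(k = 7, prob = 1)

benchmark_basis <- function(sigma, mu = 1, delta = 0.5) {
  if (sigma == 0) return(weight_type_basis(c(mu, mu), c(delta, 1 - delta)))
  discretise_weights(weight_scheme("bimodal", mu = mu, sigma = sigma,
                                   delta = delta), 2L)
}
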