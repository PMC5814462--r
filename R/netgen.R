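#' Degree specification
#'
#' Describes the degree side of a configuration-model ensemble: `regular`
#' (every node has degree `k`), `powerlaw` (degrees drawn from
#' P(k) proportional to k^(-tau) on `[k_min, k_max]`), or `explicit` (a
#' user-supplied degree sequence).
#'
#' @param kind one of `"regular"`, `"powerlaw"`, `"explicit"`.
#' @param N node count.
#' @param k degree of every node (regular).
#' @param tau power-law exponent (> 1).
#' @param k_min,k_max truncation of the power-law support. The default
#'   `k_max = 1000` keeps the truncated-zeta mean close to the realised
#'   average degree of the scale-free ensembles studied with this model.
#' @param degrees explicit degree sequence of length `N`.
#' @return an object of class `degree_spec`.
#' @export
degree_spec <- function(kind = c("regular", "powerlaw", "explicit"),
                        N, k = NULL, tau = NULL, k_min = 2L, k_max = 1000L,
                        degrees = NULL) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  stopifnot(N >= 1L)
  spec <- list(kind = kind, N = N)
  if (kind == "regular") {
    stopifnot(!is.null(k))
    k <- as.integer(k)
    if (k < 0L) stop("k must be non-negative")
    if (k >= N) stop("regular degree k must satisfy k < N")
    spec$k <- k
  } else if (kind == "powerlaw") {
    stopifnot(!is.null(tau))
    if (tau <= 1) stop("tau must exceed 1")
    k_min <- as.integer(k_min); k_max <- as.integer(k_max)
    if (k_min < 1L) stop("k_min must be at least 1")
    if (k_max > N - 1L) k_max <- N - 1L
    if (k_max < k_min) stop("k_max must be at least k_min")
    spec$tau <- tau; spec$k_min <- k_min; spec$k_max <- k_max
  } else {
    stopifnot(!is.null(degrees))
    degrees <- as.integer(degrees)
    if (length(degrees) != N) stop("length(degrees) must equal N")
    if (any(degrees < 0L)) stop("degrees must be non-negative")
    if (any(degrees >= N)) stop("degrees must be below N")
    spec$degrees <- degrees
  }
  structure(spec, class = "degree_spec")
}

#' Degree distribution of a degree specification
#'
#' @param spec a [degree_spec()].
#' @return data.frame with columns `k` and `prob`.
#' @export
degree_distribution <- function(spec) {
  stopifnot(inherits(spec, "degree_spec"))
  switch(spec$kind,
    regular = data.frame(k = spec$k, prob = 1),
    powerlaw = {
      k <- spec$k_min:spec$k_max
      p <- k^(-spec$tau)
      data.frame(k = k, prob = p / sum(p))
    },
    explicit = {
      tb <- table(spec$degrees)
      data.frame(k = as.integer(names(tb)),
                 prob = as.numeric(tb) / length(spec$degrees))
    })
}

#' Sample a degree sequence
#'
#' Regular specs return `rep(k, N)` (an error if `k * N` is odd, since no
#' graph realises an odd stub count). Power-law specs sample i.i.d. from
#' the truncated distribution; if the sum comes out odd, the last entry is
#' resampled (up to 1000 attempts) until parity is restored.
#'
#' @param spec a [degree_spec()].
#' @param seed integer RNG seed.
#' @return integer vector of length `spec$N` with even sum.
#' @export
sample_degree_sequence <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "degree_spec"))
  if (spec$kind == "regular") {
    if ((spec$k * spec$N) %% 2L == 1L)
      stop("unsatisfiable parity: k * N is odd")
    return(rep(spec$k, spec$N))
  }
  if (spec$kind == "explicit") {
    if (sum(spec$degrees) %% 2L == 1L)
      stop("unsatisfiable parity: degree sum is odd")
    return(spec$degrees)
  }
  set.seed(as.integer(seed))
  pk <- degree_distribution(spec)
  deg <- sample(pk$k, spec$N, replace = TRUE, prob = pk$prob)
  for (try in seq_len(1000L)) {
    if (sum(deg) %% 2L == 0L) return(deg)
    deg[spec$N] <- sample(pk$k, 1L, prob = pk$prob)
  }
  stop("could not repair degree-sequence parity")  # nocov
}

#' Mean of a truncated power-law degree distribution
#'
#' The analytic mean of P(k) proportional to k^(-tau) on `[k_min, k_max]`,
#' used to predict the realised average degree of sampled sequences.
#'
#' @param tau exponent; @param k_min,k_max integer support bounds.
#' @return the mean degree.
#' @export
powerlaw_mean_degree <- function(tau, k_min, k_max) {
  k <- k_min:k_max
  sum(k * k^(-tau)) / sum(k^(-tau))
}

#' Build a configuration-model graph
#'
#' Realises a simple undirected graph with exactly the requested degree
#' sequence, maximally random otherwise (stub matching followed by
#' degree-preserving edge switches). All edges get unit weight; use
#' [assign_weights()] to overlay a weight distribution.
#'
#' @param degrees integer degree sequence with even sum.
#' @param seed integer RNG seed.
#' @return a [weighted_network()] with unit weights.
#' @export
build_configuration_model <- function(degrees, seed = 1L) {
  degrees <- as.integer(degrees)
  if (sum(degrees) %% 2L == 1L) stop("degree sum is odd")
  if (!igraph::is_graphical(degrees))
    stop("degree sequence is not realisable as a simple graph")
  set.seed(as.integer(seed))
  g <- igraph::sample_degseq(degrees, method = "edge.switching.simple")
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  weighted_network(data.frame(from = el[, 1L], to = el[, 2L], weight = 1),
                   N = length(degrees))
}

#' Bimodal weight values
#'
#' A bimodal weight distribution with mean `mu`, standard deviation
#' `sigma` and strong-link fraction `delta` concentrates on two values:
#' strong links `w1 = mu + sigma * sqrt((1 - delta) / delta)` and weak
#' links `w2 = mu - sigma * sqrt(delta / (1 - delta))`. At
#' `sigma = mu * sqrt((1 - delta) / delta)` (the diluted limit) the weak
#' weight vanishes.
#'
#' @param mu mean weight (> 0).
#' @param sigma weight standard deviation (>= 0).
#' @param delta fraction of strong links, in (0, 1).
#' @return numeric `c(w1, w2)`.
#' @export
bimodal_weight_values <- function(mu, sigma, delta) {
  stopifnot(mu > 0, sigma >= 0)
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  lim <- mu * sqrt((1 - delta) / delta)
  if (sigma > lim + 1e-12 * mu)
    stop(sprintf("sigma = %g exceeds the diluted limit %g for mu = %g, delta = %g",
                 sigma, lim, mu, delta))
  c(w1 = mu + sigma * sqrt((1 - delta) / delta),
    w2 = max(0, mu - sigma * sqrt(delta / (1 - delta))))
}

#' Weight scheme
#'
#' Describes the weight side of the ensemble: `bimodal` (two values, see
#' [bimodal_weight_values()]), `lognormal` (parameterised by the desired
#' mean `mu` and standard deviation `sigma` of the weight itself, not of
#' its logarithm), or `empirical` (a weight multiset, optionally contracted
#' towards its mean by the affine `alpha` transformation of
#' [rescale_weight_set()]).
#'
#' @param kind one of `"bimodal"`, `"lognormal"`, `"empirical"`.
#' @param mu mean weight.
#' @param sigma weight standard deviation.
#' @param delta strong-link fraction (bimodal only).
#' @param weights empirical weight vector.
#' @param alpha empirical contraction factor in \[0, 1\].
#' @return an object of class `weight_scheme` with fields `mu`, `sigma`.
#' @export
weight_scheme <- function(kind = c("bimodal", "lognormal", "empirical"),
                          mu = NULL, sigma = NULL, delta = 0.5,
                          weights = NULL, alpha = 1) {
  kind <- match.arg(kind)
  if (kind == "bimodal") {
    stopifnot(!is.null(mu), !is.null(sigma))
    bimodal_weight_values(mu, sigma, delta)  # validates
    out <- list(kind = kind, mu = mu, sigma = sigma, delta = delta)
  } else if (kind == "lognormal") {
    stopifnot(!is.null(mu), !is.null(sigma))
    if (mu <= 0 || sigma <= 0)
      stop("lognormal scheme requires mu > 0 and sigma > 0")
    out <- list(kind = kind, mu = mu, sigma = sigma)
  } else {
    stopifnot(!is.null(weights))
    if (any(weights <= 0)) stop("empirical weights must be positive")
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    w <- rescale_weight_set(weights, alpha)
    out <- list(kind = kind, mu = mean(w),
                sigma = sqrt(mean((w - mean(w))^2)),
                weights = w, alpha = alpha)
  }
  structure(out, class = "weight_scheme")
}

#' Rescale a weight set towards its mean
#'
#' Applies `w' = mu + alpha * (w - mu)` to every weight, where `mu` is the
#' set mean. The mean is preserved and the standard deviation scales to
#' `alpha * sigma`, so `alpha` tunes heterogeneity without changing the
#' shape of the distribution: `alpha = 1` leaves the set unchanged and
#' `alpha = 0` collapses it to a point mass at `mu`.
#'
#' @param weights positive numeric vector.
#' @param alpha contraction factor in \[0, 1\].
#' @return the transformed weight vector.
#' @export
rescale_weight_set <- function(weights, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  stopifnot(all(weights > 0))
  mu <- mean(weights)
  mu + alpha * (weights - mu)
}

# solve (meanlog, sdlog) so that the lognormal has mean mu and sd sigma
lognormal_params <- function(mu, sigma) {
  sdlog2 <- log1p((sigma / mu)^2)
  c(meanlog = log(mu) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Assign weights to a network
#'
#' Overlays i.i.d. weights from a [weight_scheme()] on the edges of a
#' unit-weight configuration-model graph, independently of topology.
#' Bimodal schemes draw the strong value `w1` with probability `delta` and
#' record a per-edge `type` (1 = strong, 2 = weak) used by the bulk/surface
#' edge observables; empirical schemes resample the (rescaled) weight set
#' with replacement.
#'
#' @param net a [weighted_network()] (weights are overwritten).
#' @param scheme a [weight_scheme()].
#' @param seed integer RNG seed.
#' @param n_types for continuous schemes, optionally label each edge with
#'   the quantile bin (1..n_types, descending weight) it falls in, for
#'   type-resolved observables.
#' @return the network with new weights (and possibly a `type` column).
#' @export
assign_weights <- function(net, scheme, seed = 1L, n_types = NULL) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(scheme, "weight_scheme"))
  set.seed(as.integer(seed))
  E <- nrow(net$edges)
  edges <- net$edges
  if (scheme$kind == "bimodal") {
    w12 <- bimodal_weight_values(scheme$mu, scheme$sigma, scheme$delta)
    strong <- runif(E) < scheme$delta
    edges$weight <- ifelse(strong, w12[1L], w12[2L])
    edges$type <- ifelse(strong, 1L, 2L)
  } else {
    if (scheme$kind == "lognormal") {
      par <- lognormal_params(scheme$mu, scheme$sigma)
      edges$weight <- rlnorm(E, par["meanlog"], par["sdlog"])
    } else {
      edges$weight <- sample(scheme$weights, E, replace = TRUE)
    }
    if (!is.null(n_types)) {
      qs <- quantile(edges$weight, probs = seq(0, 1, length.out = n_types + 1L))
      bin <- cut(edges$weight, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
      nb <- max(bin)
      edges$type <- nb - bin + 1L  # type 1 = heaviest bin
    }
  }
  weighted_network(edges, N = net$N)
}

#' Convert a signed edge list into a bimodally weighted network
#'
#' Maps `+` ties to the strong weight `w1` and `-` ties to the weak weight
#' `w2` of a bimodal distribution whose strong fraction `delta` is measured
#' from the data as the fraction of positive ties. Self-loops are dropped;
#' when a node pair appears with conflicting signs, one sign is chosen at
#' random (seeded).
#'
#' @param edges data.frame `from, to, sign` with signs in `{-1, +1}`
#'   (as returned by `read_edge_list(path, signed = TRUE)`).
#' @param mu,sigma mean and standard deviation of the target bimodal
#'   distribution; `sigma` must not exceed the diluted limit for the
#'   measured `delta`.
#' @param seed integer RNG seed for conflicting-sign resolution.
#' @return a [weighted_network()] with a `type` column (1 = strong).
#' @export
signed_to_weighted <- function(edges, mu, sigma, seed = 1L) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "sign") %in% names(edges)))
  if (nrow(edges) == 0L) stop("edge list is empty")
  if (!all(edges$sign %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) == 0L) stop("edge list is empty after removing self-loops")
  set.seed(as.integer(seed))
  lo <- pmin(edges$from, edges$to); hi <- pmax(edges$from, edges$to)
  key <- paste(lo, hi)
  sgn <- vapply(split(edges$sign, key), function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else sample(u, 1L)
  }, 1L)
  first <- !duplicated(key)
  ord_key <- key[first]
  lo <- lo[first]; hi <- hi[first]
  sgn <- sgn[ord_key]
  delta <- mean(sgn == 1L)
  if (delta <= 0 || delta >= 1)
    stop(sprintf("measured strong fraction delta = %g is degenerate; %s",
                 delta, "a bimodal weight map needs both signs present"))
  w12 <- bimodal_weight_values(mu, sigma, delta)
  net <- weighted_network(data.frame(
    from = lo, to = hi,
    weight = ifelse(sgn == 1L, w12[1L], w12[2L]),
    type = ifelse(sgn == 1L, 1L, 2L)))
  attr(net, "delta") <- delta
  net
}

#' Generate a weighted configuration-model network
#'
#' Convenience wrapper: sample a degree sequence, realise the configuration
#' model, and overlay weights. Distinct sub-seeds for the three stages are
#' derived deterministically from `seed`.
#'
#' @param dspec a [degree_spec()].
#' @param wscheme a [weight_scheme()].
#' @param seed integer RNG seed.
#' @param n_types see [assign_weights()].
#' @return a [weighted_network()].
#' @export
generate_network <- function(dspec, wscheme, seed = 1L, n_types = NULL) {
  seed <- as.integer(seed)
  deg <- sample_degree_sequence(dspec, seed = seed)
  net <- build_configuration_model(deg, seed = seed + 1L)
  assign_weights(net, wscheme, seed = seed + 2L, n_types = n_types)
}
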