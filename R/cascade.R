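#' Absolute time of cascade emergence
#'
#' First time the infected density reaches `rho_target`, linearly
#' interpolated between samples. Returns `Inf` (the partial-cascade flag)
#' if the trajectory never crosses the target.
#'
#' @param series a `cascade_series` (from [run_mc()]), an
#'   `ame_trajectory`, a `reduced_trajectory`, or a list with numeric
#'   `times` and `rho`.
#' @param rho_target target infected density (default 0.75).
#' @return crossing time in sweeps, or `Inf`.
#' @export
absolute_time <- function(series, rho_target = 0.75) {
  tt <- series$times; rho <- series$rho
  if (is.null(tt) || is.null(rho) || length(tt) == 0L) stop("empty series")
  stopifnot(length(tt) == length(rho))
  if (rho[1L] >= rho_target) return(tt[1L])
  hit <- which(rho >= rho_target)
  if (length(hit) == 0L) return(Inf)
  i <- hit[1L]
  tt[i - 1L] + (tt[i] - tt[i - 1L]) *
    (rho_target - rho[i - 1L]) / (rho[i] - rho[i - 1L])
}

#' Relative time of cascade emergence
#'
#' `t_r = (t_a(0, phi) - t_a(sigma, phi)) / t_a(0, phi)`: positive when
#' the weighted process is faster than the unweighted reference at the
#' same threshold, zero at equal speed, negative when slower.
#'
#' @param t_a_unweighted reference crossing time at `sigma = 0` (finite,
#'   positive).
#' @param t_a_weighted crossing time of the weighted run (may be `Inf`
#'   for a partial cascade, giving `t_r = -Inf`).
#' @return the relative time.
#' @export
relative_time <- function(t_a_unweighted, t_a_weighted) {
  if (!is.finite(t_a_unweighted) || t_a_unweighted <= 0)
    stop("reference time t_a(0, phi) must be finite and positive")
  (t_a_unweighted - t_a_weighted) / t_a_unweighted
}

# weight values as linear functions of sigma: w1 = mu + a*sigma,
# w2 = mu - b*sigma with a = sqrt((1-delta)/delta), b = sqrt(delta/(1-delta))
bimodal_slopes <- function(delta) {
  c(a = sqrt((1 - delta) / delta), b = sqrt(delta / (1 - delta)))
}

#' Threshold boundary phi(sigma) for one (k, m) class
#'
#' Setting the threshold rule to equality gives
#' `phi = (m . w) / (k . w)`; with bimodal weights `w(sigma)` this is a
#' rational function of `sigma`, the boundary in the (sigma, phi) plane
#' across which the class flips between adopting (rate 1) and
#' non-adopting (rate p).
#'
#' @param k_vec,m_vec length-2 integer vectors (strong, weak counts) with
#'   `0 <= m_vec <= k_vec`.
#' @param sigma weight standard deviation (vectorised).
#' @param mu mean weight; @param delta strong-link fraction.
#' @return `phi` value(s); `NaN` where the class strength vanishes.
#' @export
boundary_phi <- function(k_vec, m_vec, sigma, mu = 1, delta = 0.5) {
  stopifnot(length(k_vec) == 2L, length(m_vec) == 2L,
            all(m_vec >= 0), all(m_vec <= k_vec), sum(k_vec) > 0)
  sl <- bimodal_slopes(delta)
  num <- mu * sum(m_vec) + sigma * (m_vec[1L] * sl["a"] - m_vec[2L] * sl["b"])
  den <- mu * sum(k_vec) + sigma * (k_vec[1L] * sl["a"] - k_vec[2L] * sl["b"])
  out <- num / den
  out[abs(den) < 1e-14] <- NaN
  unname(out)
}

#' Boundary sigma(phi) for one (k, m) class
#'
#' Inverts [boundary_phi()]: the `sigma` at which the class (k, m) sits
#' exactly on the threshold at the given `phi`. Returns `NA` when no
#' solution lies in the valid range `[0, sigma_max]` (the diluted limit).
#'
#' @inheritParams boundary_phi
#' @param phi threshold in (0, 1).
#' @return the boundary `sigma`, or `NA`.
#' @export
boundary_sigma <- function(k_vec, m_vec, phi, mu = 1, delta = 0.5) {
  stopifnot(phi > 0, phi < 1)
  sl <- bimodal_slopes(delta)
  # mu*m + sigma*(m1 a - m2 b) = phi * (mu*k + sigma*(k1 a - k2 b))
  num <- mu * (phi * sum(k_vec) - sum(m_vec))
  den <- (m_vec[1L] * sl["a"] - m_vec[2L] * sl["b"]) -
    phi * (k_vec[1L] * sl["a"] - k_vec[2L] * sl["b"])
  if (abs(den) < 1e-14) return(NA_real_)
  sigma <- unname(num / den)
  s_max <- mu * sqrt((1 - delta) / delta)
  if (sigma < 0 || sigma > s_max) return(NA_real_)
  sigma
}

#' Enumerate boundary curves in a (sigma, phi) window
#'
#' Lists every (**k**, **m**) class of the given total degree(s) whose
#' boundary curve `phi(sigma)` enters the requested window, sampling each
#' curve on a `sigma` grid. Classes whose boundaries coincide as rational
#' functions (proportional cross-multiplied coefficients) are merged
#' under a combined label.
#'
#' @param k total degree, or vector of degrees.
#' @param mu,delta bimodal weight parameters.
#' @param sigma_range,phi_range numeric length-2 windows.
#' @param n_sigma number of grid points per curve.
#' @return data.frame with columns `label`, `k1`, `k2`, `m1`, `m2`,
#'   `sigma`, `phi` (curve samples inside the window).
#' @export
enumerate_boundaries <- function(k, mu = 1, delta = 0.5,
                                 sigma_range = c(0, 1),
                                 phi_range = c(0.05, 0.5),
                                 n_sigma = 101L) {
  sl <- bimodal_slopes(delta)
  sig <- seq(sigma_range[1L], sigma_range[2L], length.out = n_sigma)
  seen <- character(0)
  out <- list()
  for (ktot in sort(unique(as.integer(k)))) {
    for (k1 in 0:ktot) {
      kv <- c(k1, ktot - k1)
      for (m1 in 0:kv[1L]) for (m2 in 0:kv[2L]) {
        mv <- c(m1, m2)
        if (sum(mv) == 0L) next
        # rational-function signature (A + B sigma) / (C + D sigma), scaled
        coefs <- c(mu * sum(mv), mv[1L] * sl["a"] - mv[2L] * sl["b"],
                   mu * sum(kv), kv[1L] * sl["a"] - kv[2L] * sl["b"])
        sigid <- paste(signif(coefs / coefs[1L], 10), collapse = "|")
        phi <- boundary_phi(kv, mv, sig, mu, delta)
        inw <- is.finite(phi) & phi >= phi_range[1L] & phi <= phi_range[2L]
        if (!any(inw)) next
        lab <- sprintf("k=(%d,%d) m=(%d,%d)", kv[1L], kv[2L], mv[1L], mv[2L])
        if (sigid %in% seen) {
          prev <- which(vapply(out, function(o) o$sigid == sigid, TRUE))[1L]
          out[[prev]]$label <- paste(out[[prev]]$label, lab, sep = " / ")
          next
        }
        seen <- c(seen, sigid)
        out[[length(out) + 1L]] <- list(
          sigid = sigid, label = lab, kv = kv, mv = mv,
          sigma = sig[inw], phi = phi[inw])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(label = character(0), k1 = integer(0), k2 = integer(0),
                      m1 = integer(0), m2 = integer(0),
                      sigma = numeric(0), phi = numeric(0)))
  do.call(rbind, lapply(out, function(o)
    data.frame(label = o$label, k1 = o$kv[1L], k2 = o$kv[2L],
               m1 = o$mv[1L], m2 = o$mv[2L], sigma = o$sigma, phi = o$phi)))
}

# t_a from the reduced AME for one (sigma, phi) cell
ame_t_a <- function(P_k, mu, delta, sigma, phi, p, rho_target = 0.75,
                    t_max = 3000) {
  basis <- if (sigma == 0) weight_type_basis(mu, 1) else
    discretise_weights(weight_scheme("bimodal", mu = mu, sigma = sigma,
                                     delta = delta), 2L)
  traj <- integrate_reduced(P_k, basis, phi, p, t_max = t_max,
                            times = seq(0, t_max, by = 0.25),
                            rho_stop = min(rho_target + 0.05, 0.999))
  absolute_time(traj, rho_target)
}

# mean t_a over MC replicates for one (sigma, phi) cell; one shared
# topology/weight-pattern seed per replicate across cells
mc_t_a <- function(dspec, mu, delta, sigma, phi, p, reps, seed,
                   rho_target = 0.75, t_max = 3000) {
  tas <- numeric(reps)
  for (r in seq_len(reps)) {
    rep_seed <- as.integer(seed) + 1000L * r
    scheme <- weight_scheme("bimodal", mu = mu, sigma = sigma, delta = delta)
    net <- generate_network(dspec, scheme, seed = rep_seed)
    cfg <- sim_config(phi = phi, p = p, t_max = t_max,
                      rho_stop = min(rho_target + 0.02, 1),
                      sample_dt = 0.1, seed = rep_seed + 7L)
    tas[r] <- absolute_time(run_mc(net, cfg), rho_target)
  }
  mean(tas)
}

#' Sweep the (sigma, phi) parameter plane
#'
#' Computes the absolute cascade-emergence time `t_a` for every grid cell
#' with the chosen engine (deterministic reduced-AME solution, or Monte
#' Carlo averaged over replicates), and the relative time `t_r` against
#' the unweighted `sigma = 0` reference at the same `phi` (computed with
#' the same engine, and for MC with the same replicate seed set).
#' Non-finite `t_a` cells (partial cascades within the window) are
#' flagged and excluded from `t_r`.
#'
#' @param dspec a [degree_spec()] (MC engine) -- its
#'   [degree_distribution()] is used by the AME engine.
#' @param sigma_values,phi_values grid coordinates (`sigma = 0` is added
#'   automatically as the reference when absent).
#' @param mu,delta bimodal weight parameters.
#' @param p spontaneous rate.
#' @param engine `"ame"` or `"mc"`.
#' @param reps MC replicates per cell.
#' @param seed integer base seed (MC engine).
#' @param rho_target density defining `t_a`.
#' @param t_max simulated window per cell, sweeps.
#' @return data.frame with columns `sigma`, `phi`, `t_a`, `t_r`,
#'   `partial` (logical flag).
#' @export
parameter_sweep <- function(dspec, sigma_values, phi_values,
                            mu = 1, delta = 0.5, p = 2e-4,
                            engine = c("ame", "mc"), reps = 25L, seed = 1L,
                            rho_target = 0.75, t_max = 3000) {
  engine <- match.arg(engine)
  stopifnot(inherits(dspec, "degree_spec"))
  sigma_values <- sort(unique(c(0, sigma_values)))
  P_k <- degree_distribution(dspec)
  cell <- function(sigma, phi) {
    if (engine == "ame")
      ame_t_a(P_k, mu, delta, sigma, phi, p, rho_target, t_max)
    else
      mc_t_a(dspec, mu, delta, sigma, phi, p, reps, seed, rho_target, t_max)
  }
  out <- expand.grid(sigma = sigma_values, phi = phi_values,
                     KEEP.OUT.ATTRS = FALSE)
  out$t_a <- NA_real_
  for (phi in phi_values)
    for (sigma in sigma_values)
      out$t_a[out$sigma == sigma & out$phi == phi] <- cell(sigma, phi)
  out$partial <- !is.finite(out$t_a)
  out$t_r <- NA_real_
  for (phi in phi_values) {
    ref <- out$t_a[out$sigma == 0 & out$phi == phi]
    if (is.finite(ref) && ref > 0) {
      rows <- out$phi == phi & is.finite(out$t_a)
      out$t_r[rows] <- (ref - out$t_a[rows]) / ref
    }
  }
  out
}
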