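#' Weight-type basis
#'
#' Discretised weight distribution used by the AME solvers: `n` weight
#' types with values `w` (the weight vector) and per-link probabilities
#' `type_prob` (chance that a randomly chosen edge carries each type).
#'
#' @param w positive-or-zero weight values, one per type.
#' @param type_prob probability vector summing to 1.
#' @return an object of class `weight_basis` with fields `n`, `w`,
#'   `type_prob`.
#' @export
weight_type_basis <- function(w, type_prob) {
  w <- as.numeric(w); type_prob <- as.numeric(type_prob)
  stopifnot(length(w) == length(type_prob), all(w >= 0), all(type_prob > 0))
  if (abs(sum(type_prob) - 1) > 1e-10) stop("type_prob must sum to 1")
  structure(list(n = length(w), w = w, type_prob = type_prob),
            class = "weight_basis")
}

#' Discretise a weight scheme into n types
#'
#' Bimodal schemes map exactly onto two types `(w1, w2)` with
#' probabilities `(delta, 1 - delta)`. Continuous (lognormal) and
#' empirical schemes are split into `n` equal-probability quantile bins,
#' each represented by its conditional mean, so that the discretised mean
#' equals `mu` (up to the bin-mean quadrature for continuous schemes).
#' `n = 1` collapses any scheme to the unweighted limit `w = mu`.
#'
#' @param scheme a [weight_scheme()].
#' @param n number of weight types (>= 1).
#' @return a [weight_type_basis()] (types ordered by decreasing weight).
#' @export
discretise_weights <- function(scheme, n) {
  stopifnot(inherits(scheme, "weight_scheme"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (n == 1L) return(weight_type_basis(scheme$mu, 1))
  if (scheme$kind == "bimodal") {
    if (n != 2L) stop("a bimodal scheme discretises exactly into n = 2 types")
    w12 <- bimodal_weight_values(scheme$mu, scheme$sigma, scheme$delta)
    return(weight_type_basis(c(w12[1L], w12[2L]),
                             c(scheme$delta, 1 - scheme$delta)))
  }
  if (scheme$kind == "lognormal") {
    par <- lognormal_params(scheme$mu, scheme$sigma)
    qs <- qlnorm(seq(0, 1, length.out = n + 1L), par["meanlog"], par["sdlog"])
    # E[W | q_{i-1} < W <= q_i] via the lognormal partial expectation
    zs <- (log(qs) - par["meanlog"]) / par["sdlog"] - par["sdlog"]
    cdf <- pnorm(zs); cdf[1L] <- 0; cdf[n + 1L] <- 1
    bin_mean <- scheme$mu * diff(cdf) * n
    return(weight_type_basis(rev(bin_mean), rep(1 / n, n)))
  }
  # empirical: equal-count bins of the sorted weight multiset
  ws <- sort(scheme$weights)
  bin <- cut(seq_along(ws), breaks = n, labels = FALSE)
  bin_mean <- as.numeric(tapply(ws, bin, mean))
  prob <- as.numeric(table(bin)) / length(ws)
  weight_type_basis(rev(bin_mean), rev(prob))
}

# all length-n non-negative integer vectors summing to k (rows)
compositions <- function(k, n) {
  if (n == 1L) return(matrix(k, 1L, 1L))
  out <- NULL
  for (k1 in 0:k) {
    rest <- compositions(k - k1, n - 1L)
    out <- rbind(out, cbind(k1, rest))
  }
  unname(out)
}

# multinomial P(kvec | k) with type probabilities p
multinom_prob <- function(kmat, p) {
  k <- rowSums(kmat)
  lg <- lgamma(k + 1) - rowSums(lgamma(kmat + 1))
  lp <- kmat %*% ifelse(p > 0, log(p), 0)
  # a zero-probability type with positive count has probability 0
  zero <- rowSums(kmat[, p == 0, drop = FALSE]) > 0
  out <- exp(lg + as.numeric(lp))
  out[zero] <- 0
  out
}

as_pk <- function(P_k) {
  if (inherits(P_k, "degree_spec")) P_k <- degree_distribution(P_k)
  stopifnot(is.data.frame(P_k), all(c("k", "prob") %in% names(P_k)),
            all(P_k$prob >= 0))
  P_k <- P_k[P_k$prob > 0, , drop = FALSE]
  if (abs(sum(P_k$prob) - 1) > 1e-8) stop("degree probabilities must sum to 1")
  if (any(P_k$k < 0) || any(P_k$k != floor(P_k$k))) stop("invalid degrees")
  P_k
}

#' Truncate a degree distribution for the AME class expansion
#'
#' Keeps the smallest leading degrees whose cumulative probability exceeds
#' `1 - tol` and renormalises; bounds the AME class count for heavy-tailed
#' degree distributions.
#'
#' @param P_k data.frame with columns `k`, `prob`.
#' @param tol discarded tail mass (default `1e-6`).
#' @return truncated, renormalised data.frame.
#' @export
truncate_degree_distribution <- function(P_k, tol = 1e-6) {
  P_k <- as_pk(P_k)
  P_k <- P_k[order(P_k$k), , drop = FALSE]
  last <- which(cumsum(P_k$prob) >= 1 - tol)[1L]
  out <- P_k[seq_len(last), , drop = FALSE]
  out$prob <- out$prob / sum(out$prob)
  out
}

#' Enumerate AME classes
#'
#' Expands a degree distribution and a weight-type basis into the full set
#' of (**k**, **m**) compartments: for every degree k, every composition
#' **k** of k into n types (with multinomial probability, reflecting the
#' independent weight assignment of the configuration model), and every
#' infected-neighbour vector **m** with `0 <= m_j <= k_j`.
#'
#' @param P_k degree distribution (data.frame `k`, `prob`, or a
#'   [degree_spec()]).
#' @param basis a [weight_type_basis()].
#' @return list with matrices `K`, `M` (one row per class), totals `ktot`,
#'   `mtot`, strengths `qk`, `qm`, the class weight `prob` =
#'   P(k) P(**k**) (shared by all **m** rows of one **k**), the **k**-group
#'   id `kvec_id`, and `shift`, a C x n matrix giving the row of
#'   (**k**, **m** - e_j) (0 where `m_j = 0`).
#' @export
enumerate_classes <- function(P_k, basis) {
  P_k <- as_pk(P_k)
  stopifnot(inherits(basis, "weight_basis"))
  n <- basis$n
  Klist <- list(); Mlist <- list(); plist <- list(); glist <- list()
  gid <- 0L
  for (r in seq_len(nrow(P_k))) {
    k <- P_k$k[r]
    kv <- compositions(k, n)
    pkv <- P_k$prob[r] * multinom_prob(kv, basis$type_prob)
    for (i in seq_len(nrow(kv))) {
      gid <- gid + 1L
      mv <- as.matrix(expand.grid(lapply(kv[i, ], function(kj) 0:kj)))
      cnt <- nrow(mv)
      Klist[[gid]] <- matrix(kv[i, ], cnt, n, byrow = TRUE)
      Mlist[[gid]] <- unname(mv)
      plist[[gid]] <- rep(pkv[i], cnt)
      glist[[gid]] <- rep(gid, cnt)
    }
  }
  K <- do.call(rbind, Klist); M <- do.call(rbind, Mlist)
  prob <- unlist(plist); kvec_id <- unlist(glist)
  C <- nrow(K)
  key <- function(km, mm) apply(cbind(km, mm), 1L, paste, collapse = ",")
  row_of <- setNames(seq_len(C), key(K, M))
  shift <- matrix(0L, C, n)
  for (j in seq_len(n)) {
    Mj <- M; Mj[, j] <- Mj[, j] - 1L
    ok <- Mj[, j] >= 0L
    shift[ok, j] <- row_of[key(K[ok, , drop = FALSE], Mj[ok, , drop = FALSE])]
  }
  list(K = K, M = M, ktot = rowSums(K), mtot = rowSums(M),
       qk = as.numeric(K %*% basis$w), qm = as.numeric(M %*% basis$w),
       prob = prob, kvec_id = kvec_id, shift = shift, n = n, basis = basis)
}

#' Infection rate of an AME class
#'
#' The stepwise rate of the monotone threshold dynamics: `p` below the
#' threshold, 1 at or above it (`q_m >= phi * q_k`, relative tolerance
#' 1e-12). Nodes that receive no influence (degree 0, or zero strength in
#' the diluted limit where all incident weights vanish) adopt only
#' spontaneously, at rate `p`.
#'
#' @param k_vec,m_vec integer vectors (or matrices, one class per row) of
#'   per-type degrees and infected-neighbour counts.
#' @param phi threshold in (0, 1).
#' @param p spontaneous rate.
#' @param basis a [weight_type_basis()].
#' @return numeric rate(s).
#' @export
infection_rate_F <- function(k_vec, m_vec, phi, p, basis) {
  stopifnot(inherits(basis, "weight_basis"))
  if (is.null(dim(k_vec))) k_vec <- matrix(k_vec, nrow = 1L)
  if (is.null(dim(m_vec))) m_vec <- matrix(m_vec, nrow = 1L)
  stopifnot(all(m_vec >= 0), all(m_vec <= k_vec))
  qk <- as.numeric(k_vec %*% basis$w)
  qm <- as.numeric(m_vec %*% basis$w)
  ktot <- rowSums(k_vec)
  ifelse(ktot > 0 & qk > 0 & qm >= phi * qk - 1e-12 * qk, 1, p)
}

#' Assemble the full AME system
#'
#' Precomputes the class enumeration, stepwise rates and flux indices for
#' the full approximate-master-equation system of the weighted threshold
#' dynamics.
#'
#' @inheritParams enumerate_classes
#' @param phi threshold; @param p spontaneous rate.
#' @return an object of class `ame_system`.
#' @export
ame_system <- function(P_k, basis, phi, p) {
  cls <- enumerate_classes(P_k, basis)
  cls$phi <- phi; cls$p <- p
  cls$F <- infection_rate_F(cls$K, cls$M, phi, p, basis)
  cls$KM <- cls$K - cls$M
  # shift with 0 -> sentinel row C+1 pointing at an appended zero entry
  Cn <- nrow(cls$K)
  sh <- cls$shift; sh[sh == 0L] <- Cn + 1L
  cls$shift1 <- sh
  cls$C <- Cn
  structure(cls, class = "ame_system")
}

#' Neighbour infection rates beta
#'
#' The rates at which a type-j susceptible neighbour of a susceptible
#' (`beta_s`) or infected (`beta_i`) node becomes infected. Only
#' susceptible nodes change state, so both rates average the stepwise
#' rate F over susceptible classes: for `beta_s` the neighbour is reached
#' across an S-S edge (class weight proportional to `k_j - m_j` times
#' `s`), for `beta_i` across an S-I edge (weight proportional to `m_j`
#' times `s`). An empty category (zero denominator) yields rate 0.
#'
#' @param sys an [ame_system()].
#' @param s,i class-fraction vectors (susceptible, infected; `i` is
#'   accepted for interface symmetry but the rates depend on `s` only).
#' @return list with numeric vectors `beta_s`, `beta_i` of length `n`.
#' @export
beta_rates <- function(sys, s, i) {
  stopifnot(inherits(sys, "ame_system"))
  if (min(s) < -1e-8 || min(i) < -1e-8) stop("negative state entries")
  s <- pmax(s, 0)
  ws <- sys$prob * s
  num_s <- as.numeric(crossprod(sys$KM, ws * sys$F))
  den_s <- as.numeric(crossprod(sys$KM, ws))
  num_i <- as.numeric(crossprod(sys$M, ws * sys$F))
  den_i <- as.numeric(crossprod(sys$M, ws))
  list(beta_s = ifelse(den_s > 0, num_s / pmax(den_s, 1e-300), 0),
       beta_i = ifelse(den_i > 0, num_i / pmax(den_i, 1e-300), 0))
}

#' Full AME right-hand side
#'
#' Time derivatives of the class fractions: susceptible mass leaves a
#' class by own infection (rate F) and by neighbour infections (rates
#' `beta_s`, multiplicity `k_j - m_j`), and enters from the class with one
#' fewer infected j-neighbour; infected mass gains `F s` and flows
#' analogously with `beta_i`.
#'
#' @param sys an [ame_system()].
#' @param s,i class-fraction vectors.
#' @return list with `ds`, `di` and the `beta` rates used.
#' @export
full_ame_rhs <- function(sys, s, i) {
  b <- beta_rates(sys, s, i)
  s_ext <- c(s, 0); i_ext <- c(i, 0)
  loss_s <- as.numeric(sys$KM %*% b$beta_s)
  loss_i <- as.numeric(sys$KM %*% b$beta_i)
  gain_s <- numeric(sys$C); gain_i <- numeric(sys$C)
  for (j in seq_len(sys$n)) {
    mult <- sys$KM[, j] + 1
    gain_s <- gain_s + b$beta_s[j] * mult * s_ext[sys$shift1[, j]]
    gain_i <- gain_i + b$beta_i[j] * mult * i_ext[sys$shift1[, j]]
  }
  list(ds = -sys$F * s - loss_s * s + gain_s,
       di = sys$F * s - loss_i * i + gain_i,
       beta = b)
}

#' Integrate the full AME system
#'
#' Solves the full class-resolved system from the near-zero-seed initial
#' condition (all susceptible mass at **m** = 0) with an adaptive
#' stiff-capable integrator, and derives the infected density `rho(t)`,
#' the neighbour-infection probabilities `nu_j(t)` and the per-**k**
#' normalisation check.
#'
#' @inheritParams ame_system
#' @param t_max integration horizon (sweeps).
#' @param times output grid (default every 0.1 sweeps).
#' @param rtol,atol solver tolerances.
#' @param rho_stop optional early-stopping density (root finding).
#' @return an object of class `ame_trajectory`: list with `times`, `rho`,
#'   `nu` (matrix), `s`, `i` (class-fraction matrices, one row per time),
#'   `norm_dev` (max per-**k** normalisation deviation per time) and the
#'   `sys` used.
#' @export
integrate_full_ame <- function(P_k, basis, phi, p, t_max = 50,
                               times = NULL, rtol = 1e-8, atol = 1e-10,
                               rho_stop = NULL) {
  sys <- ame_system(P_k, basis, phi, p)
  if (is.null(times)) times <- seq(0, t_max, by = 0.1)
  Cn <- sys$C
  y0 <- c(as.numeric(sys$mtot == 0), numeric(Cn))
  deriv <- function(t, y, parms) {
    r <- full_ame_rhs(sys, y[seq_len(Cn)], y[Cn + seq_len(Cn)])
    list(c(r$ds, r$di))
  }
  if (is.null(rho_stop)) {
    sol <- deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
  } else {
    root <- function(t, y, parms)
      (1 - sum(sys$prob * y[seq_len(Cn)])) - rho_stop
    sol <- deSolve::ode(y0, times, deriv, NULL, method = "lsodar",
                        rtol = rtol, atol = atol, rootfunc = root)
  }
  tt <- sol[, 1L]
  S <- sol[, 1L + seq_len(Cn), drop = FALSE]
  I <- sol[, 1L + Cn + seq_len(Cn), drop = FALSE]
  rho <- pmin(pmax(1 - as.numeric(S %*% sys$prob), 0), 1)  # solver rounding
  # per-kvec normalisation deviation
  gsum <- t(rowsum(t(S + I), sys$kvec_id))
  norm_dev <- apply(abs(gsum - 1), 1L, max)
  # nu_j diagnostic: class-weighted ratio of infected to total j-stubs of
  # susceptible nodes (degree vectors with k_j = 0 contribute 0)
  nu <- matrix(NA_real_, length(tt), sys$n)
  first <- !duplicated(sys$kvec_id)
  pk_g <- sys$prob[first]
  for (j in seq_len(sys$n)) {
    mjs <- t(rowsum(t(S) * sys$M[, j], sys$kvec_id))
    kjs <- t(rowsum(t(S) * sys$K[, j], sys$kvec_id))
    ratio <- ifelse(kjs > 1e-300, mjs / pmax(kjs, 1e-300), 0)
    nu[, j] <- as.numeric(ratio %*% pk_g)
  }
  structure(list(times = tt, rho = rho, nu = nu, s = S, i = I,
                 norm_dev = norm_dev, sys = sys),
            class = "ame_trajectory")
}

#' @export
print.ame_trajectory <- function(x, ...) {
  cat(sprintf("ame_trajectory: %d classes, %d times to t = %.2f, final rho = %.4f\n",
              x$sys$C, length(x$times), max(x$times), x$rho[length(x$rho)]))
  invisible(x)
}

#' Bulk and surface edge fractions from a full AME trajectory
#'
#' Per weight type j, the share of j-type edges among edges inside the
#' infected cluster (`E_II`, weighting class fractions `i` by `m_j`) and
#' on its susceptible-infected surface (`E_SI`, weighting `s` by `m_j`).
#' Each family sums to 1; rows where a category still has zero mass
#' (e.g. t = 0) are `NA`.
#'
#' @param traj an `ame_trajectory` from [integrate_full_ame()].
#' @return list of matrices `E_II`, `E_SI` (times x types).
#' @export
ame_edge_fractions <- function(traj) {
  stopifnot(inherits(traj, "ame_trajectory"))
  sys <- traj$sys
  wII_den <- as.numeric(traj$i %*% (sys$prob * sys$mtot))
  wSI_den <- as.numeric(traj$s %*% (sys$prob * sys$mtot))
  E_II <- matrix(NA_real_, length(traj$times), sys$n)
  E_SI <- matrix(NA_real_, length(traj$times), sys$n)
  for (j in seq_len(sys$n)) {
    numII <- as.numeric(traj$i %*% (sys$prob * sys$M[, j]))
    numSI <- as.numeric(traj$s %*% (sys$prob * sys$M[, j]))
    E_II[, j] <- ifelse(wII_den > 1e-14, numII / wII_den, NA_real_)
    E_SI[, j] <- ifelse(wSI_den > 1e-14, numSI / wSI_den, NA_real_)
  }
  list(E_II = E_II, E_SI = E_SI)
}

#' Assemble the reduced AME system
#'
#' For the stepwise threshold rate the full system reduces exactly to
#' `n + 1` equations in the neighbour-infection probabilities `nu_j` and
#' the density `rho`. This precomputes the binomial-sum tables: for every
#' degree vector, the set of infected-neighbour vectors satisfying the
#' threshold, with multinomial/size-biased coefficients.
#'
#' @inheritParams ame_system
#' @return an object of class `reduced_system`.
#' @export
reduced_system <- function(P_k, basis, phi, p) {
  P_k <- as_pk(P_k)
  stopifnot(inherits(basis, "weight_basis"))
  n <- basis$n
  z <- sum(P_k$k * P_k$prob)
  z_j <- z * basis$type_prob
  sat <- function(kv, mv) {  # threshold satisfied, influence present
    qk <- sum(kv * basis$w); qm <- sum(mv * basis$w)
    sum(kv) > 0 && qk > 0 && qm >= phi * qk - 1e-12 * qk
  }
  h_rows <- list(); g_rows <- lapply(seq_len(n), function(j) list())
  hr <- 0L; gr <- integer(n)
  for (r in seq_len(nrow(P_k))) {
    k <- P_k$k[r]
    kvm <- compositions(k, n)
    pkv <- P_k$prob[r] * multinom_prob(kvm, basis$type_prob)
    for (i in seq_len(nrow(kvm))) {
      if (pkv[i] <= 0) next
      kv <- kvm[i, ]
      mv_all <- as.matrix(expand.grid(lapply(kv, function(kj) 0:kj)))
      for (mrow in seq_len(nrow(mv_all))) {
        mv <- as.integer(mv_all[mrow, ])
        if (!sat(kv, mv)) next
        hr <- hr + 1L
        h_rows[[hr]] <- c(pkv[i] * prod(choose(kv, mv)), mv, kv - mv)
      }
      for (j in seq_len(n)) {
        if (kv[j] < 1L) next
        kv_red <- kv; kv_red[j] <- kv[j] - 1L
        mv_all_j <- as.matrix(expand.grid(lapply(kv_red, function(kj) 0:kj)))
        for (mrow in seq_len(nrow(mv_all_j))) {
          mv <- as.integer(mv_all_j[mrow, ])
          if (!sat(kv, mv)) next
          coef <- (kv[j] / z_j[j]) * pkv[i] * prod(choose(kv_red, mv))
          gr[j] <- gr[j] + 1L
          g_rows[[j]][[gr[j]]] <- c(coef, mv, kv_red - mv)
        }
      }
    }
  }
  pack <- function(rows) {
    if (length(rows) == 0L)
      return(list(coef = numeric(0), Mexp = matrix(0, 0, n),
                  Cexp = matrix(0, 0, n)))
    mat <- do.call(rbind, rows)
    list(coef = mat[, 1L],
         Mexp = mat[, 1L + seq_len(n), drop = FALSE],
         Cexp = mat[, 1L + n + seq_len(n), drop = FALSE])
  }
  structure(list(n = n, basis = basis, phi = phi, p = p, z_j = z_j,
                 h = pack(h_rows), g = lapply(g_rows, pack)),
            class = "reduced_system")
}

binom_table_sum <- function(tab, nu) {
  if (length(tab$coef) == 0L) return(0)
  val <- tab$coef
  for (j in seq_along(nu))
    val <- val * nu[j]^tab$Mexp[, j] * (1 - nu[j])^tab$Cexp[, j]
  sum(val)
}

#' Reduced AME right-hand side
#'
#' `dnu_j/dt = g_j(nu, t) - nu_j` and `drho/dt = h(nu, t) - rho`, where
#' `g_j` and `h` are the precomputed binomial sums over
#' threshold-satisfying classes and `f_t = 1 - (1 - p) exp(-p t)` is the
#' cumulative spontaneous-adoption probability.
#'
#' @param rsys a [reduced_system()].
#' @param state numeric vector `c(nu_1..n, rho)`.
#' @param t time.
#' @return derivative vector `c(dnu, drho)`.
#' @export
reduced_rhs <- function(rsys, state, t) {
  stopifnot(inherits(rsys, "reduced_system"))
  nu <- pmin(pmax(state[seq_len(rsys$n)], 0), 1)
  rho <- state[rsys$n + 1L]
  ft <- 1 - (1 - rsys$p) * exp(-rsys$p * t)
  g <- vapply(seq_len(rsys$n), function(j)
    ft + (1 - ft) * binom_table_sum(rsys$g[[j]], nu), 0)
  h <- ft + (1 - ft) * binom_table_sum(rsys$h, nu)
  c(g - nu, h - rho)
}

#' Integrate the reduced AME system
#'
#' Solves the `n + 1`-dimensional reduced system from
#' `(nu, rho) = (0, 0)` (an infinitesimal random seed).
#'
#' @inheritParams integrate_full_ame
#' @return an object of class `reduced_trajectory`: list with `times`,
#'   `rho`, `nu` (matrix) and the `rsys` used.
#' @export
integrate_reduced <- function(P_k, basis, phi, p, t_max = 50,
                              times = NULL, rtol = 1e-8, atol = 1e-10,
                              rho_stop = NULL) {
  rsys <- reduced_system(P_k, basis, phi, p)
  if (is.null(times)) times <- seq(0, t_max, by = 0.1)
  y0 <- numeric(rsys$n + 1L)
  deriv <- function(t, y, parms) list(reduced_rhs(rsys, y, t))
  if (is.null(rho_stop)) {
    sol <- deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
  } else {
    root <- function(t, y, parms) y[rsys$n + 1L] - rho_stop
    sol <- deSolve::ode(y0, times, deriv, NULL, method = "lsodar",
                        rtol = rtol, atol = atol, rootfunc = root)
  }
  structure(list(times = sol[, 1L],
                 nu = sol[, 1L + seq_len(rsys$n), drop = FALSE],
                 rho = pmin(pmax(sol[, rsys$n + 2L], 0), 1),
                 rsys = rsys),
            class = "reduced_trajectory")
}

#' @export
print.reduced_trajectory <- function(x, ...) {
  cat(sprintf("reduced_trajectory: n = %d, %d times to t = %.2f, final rho = %.4f\n",
              x$rsys$n, length(x$times), max(x$times), x$rho[length(x$rho)]))
  invisible(x)
}
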