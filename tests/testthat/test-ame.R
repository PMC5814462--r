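test_that("weight discretisation reproduces schemes exactly or in the mean", {
  b <- discretise_weights(weight_scheme("bimodal", mu = 1, sigma = 0.5,
                                        delta = 0.5), 2L)
  expect_equal(b$w, c(1.5, 0.5))
  expect_equal(b$type_prob, c(0.5, 0.5))
  b1 <- discretise_weights(weight_scheme("lognormal", mu = 2, sigma = 1), 1L)
  expect_equal(b1$w, 2)
  expect_equal(b1$type_prob, 1)
  bl <- discretise_weights(weight_scheme("lognormal", mu = 1, sigma = 0.5), 10L)
  expect_equal(sum(bl$w * bl$type_prob), 1, tolerance = 1e-3)
  expect_true(all(bl$w > 0) && all(diff(bl$w) < 0))
  set.seed(2); wset <- rlnorm(1000, 0, 0.4)
  be <- discretise_weights(weight_scheme("empirical", weights = wset), 5L)
  expect_equal(sum(be$w * be$type_prob), mean(wset), tolerance = 1e-10)
  expect_error(discretise_weights(weight_scheme("bimodal", mu = 1, sigma = 0.2), 0L))
})

test_that("class enumeration counts compositions with multinomial weights", {
  basis <- benchmark_basis(0.5)
  cl <- enumerate_classes(benchmark_pk(), basis)
  expect_equal(nrow(cl$K), 120L)  # sum over k1 of (k1+1)(8-k1)
  expect_equal(length(unique(cl$kvec_id)), 8L)
  p25 <- unique(cl$prob[cl$K[, 1] == 2 & cl$K[, 2] == 5])
  expect_equal(p25, choose(7, 2) / 2^7)
  # probabilities sum to 1 over degree vectors (one row each)
  expect_equal(sum(cl$prob[!duplicated(cl$kvec_id)]), 1)
  # n = 1 collapses to (k, m) classes
  cl1 <- enumerate_classes(benchmark_pk(), weight_type_basis(1, 1))
  expect_equal(nrow(cl1$K), 8L)
  expect_equal(sort(cl1$M[, 1]), 0:7)
})

test_that("the stepwise class rate follows the threshold rule", {
  basis <- benchmark_basis(0.7)
  p <- 2e-4
  expect_equal(infection_rate_F(c(0, 0), c(0, 0), 0.25, p, basis), p)
  expect_equal(infection_rate_F(c(1, 6), c(1, 0), 0.25, p, basis), 1)
  expect_equal(infection_rate_F(c(2, 5), c(0, 2), 0.25, p, basis), p)
  expect_equal(infection_rate_F(c(3, 4), c(0, 0), 0.25, p, basis), p)
  # zero-strength nodes in the diluted limit only adopt spontaneously
  bd <- benchmark_basis(1)  # w = (2, 0)
  expect_equal(infection_rate_F(c(0, 7), c(0, 0), 0.25, p, bd), p)
  expect_equal(infection_rate_F(c(0, 7), c(0, 7), 0.25, p, bd), p)
})

test_that("startup rates and fluxes match the analytic initial condition", {
  p <- 2e-4
  sys <- ame_system(benchmark_pk(), benchmark_basis(0.5), 0.25, p)
  s0 <- as.numeric(sys$mtot == 0); i0 <- numeric(sys$C)
  b <- beta_rates(sys, s0, i0)
  expect_equal(b$beta_s, rep(p, 2))
  expect_equal(b$beta_i, rep(0, 2))
  r <- full_ame_rhs(sys, s0, i0)
  # ds/dt of an (k, 0) class is -p(1 + k); overall drho/dt = p
  m0 <- sys$mtot == 0
  expect_equal(r$ds[m0], -p * (1 + sys$ktot[m0]))
  expect_equal(-sum(sys$prob * r$ds), p)
  # per-degree-vector mass is conserved by the fluxes at any state
  set.seed(6)
  for (rep in 1:5) {
    sr <- runif(sys$C); ir <- runif(sys$C)
    tot <- rowsum(sr + ir, sys$kvec_id)[, 1]
    sr <- sr / tot[sys$kvec_id]; ir <- ir / tot[sys$kvec_id]
    rr <- full_ame_rhs(sys, sr, ir)
    grp <- rowsum(rr$ds + rr$di, sys$kvec_id)[, 1]
    expect_lt(max(abs(grp)), 1e-12)
  }
})

test_that("full AME conserves class normalisation and stays in bounds", {
  traj <- integrate_full_ame(benchmark_pk(), benchmark_basis(0.5),
                             phi = 0.25, p = 2e-4, t_max = 50)
  expect_lt(max(traj$norm_dev), 1e-6)
  expect_true(all(traj$s > -1e-8) && all(traj$i > -1e-8))
  expect_true(all(traj$rho >= 0) && all(traj$rho <= 1 + 1e-8))
  expect_true(all(diff(traj$rho) >= -1e-10))
  # p = 0 from the all-susceptible start is absorbing
  sys <- ame_system(benchmark_pk(), benchmark_basis(0.5), 0.25, 0)
  r <- full_ame_rhs(sys, as.numeric(sys$mtot == 0), numeric(sys$C))
  expect_equal(max(abs(c(r$ds, r$di))), 0)
})

test_that("reduced and full AME solutions coincide", {
  pk <- benchmark_pk()
  for (sigma in c(0.5, 0.7)) {
    basis <- benchmark_basis(sigma)
    full <- integrate_full_ame(pk, basis, 0.25, 2e-4, t_max = 50)
    red <- integrate_reduced(pk, basis, 0.25, 2e-4, t_max = 50)
    expect_lt(max(abs(full$rho - red$rho)), 1e-4)
  }
})

test_that("reduced RHS has the analytic fixed points and startup slope", {
  rsys <- reduced_system(benchmark_pk(), benchmark_basis(0.5), 0.25, 2e-4)
  d0 <- reduced_rhs(rsys, c(0, 0, 0), 0)
  expect_equal(d0[3], 2e-4)        # drho/dt = f_0 = p
  expect_equal(d0[1:2], rep(2e-4, 2))
  # all-infected state is a fixed point
  d1 <- reduced_rhs(rsys, c(1, 1, 1), 10)
  expect_equal(max(abs(d1)), 0, tolerance = 1e-12)
  # p = 0: no spontaneous term, origin is a fixed point
  rsys0 <- reduced_system(benchmark_pk(), benchmark_basis(0.5), 0.25, 0)
  expect_equal(max(abs(reduced_rhs(rsys0, c(0, 0, 0), 5))), 0)
})

test_that("n = 1 reduced dynamics matches an independent unweighted solver", {
  times <- seq(0, 120, by = 0.5)
  for (pk in list(benchmark_pk(),
                  data.frame(k = c(3, 5, 8), prob = c(0.3, 0.4, 0.3)))) {
    mine <- integrate_reduced(pk, weight_type_basis(1, 1), 0.25, 2e-4,
                              t_max = max(times), times = times)
    oracle <- unweighted_watts_trajectory(pk, 0.25, 2e-4, times)
    expect_lt(max(abs(mine$rho - oracle$rho)), 1e-6)
    expect_lt(max(abs(mine$nu[, 1] - oracle$nu)), 1e-6)
  }
})

test_that("the sigma = 0 limit is independent of delta and label order", {
  pk <- benchmark_pk()
  times <- seq(0, 80, by = 0.5)
  ref <- integrate_reduced(pk, weight_type_basis(1, 1), 0.25, 2e-4,
                           t_max = 80, times = times)$rho
  for (delta in c(0.3, 0.5)) {
    two <- integrate_reduced(pk, weight_type_basis(c(1, 1), c(delta, 1 - delta)),
                             0.25, 2e-4, t_max = 80, times = times)$rho
    expect_lt(max(abs(two - ref)), 1e-6)
  }
  # permuting weight-type labels leaves rho unchanged
  b <- benchmark_basis(0.7, delta = 0.3)
  fwd <- integrate_reduced(pk, b, 0.25, 2e-4, t_max = 60, times = seq(0, 60, 0.5))
  bperm <- weight_type_basis(rev(b$w), rev(b$type_prob))
  bwd <- integrate_reduced(pk, bperm, 0.25, 2e-4, t_max = 60,
                           times = seq(0, 60, 0.5))
  expect_lt(max(abs(fwd$rho - bwd$rho)), 1e-6)
  expect_lt(max(abs(fwd$nu - bwd$nu[, 2:1])), 1e-6)
})

test_that("AME edge fractions are symmetric at sigma = 0 and sum to one", {
  pk <- benchmark_pk()
  f0 <- integrate_full_ame(pk, weight_type_basis(c(1, 1), c(0.5, 0.5)),
                           0.25, 2e-4, t_max = 40)
  ef0 <- ame_edge_fractions(f0)
  ok <- which(!is.na(ef0$E_II[, 1]))
  expect_true(all(abs(ef0$E_II[ok, ] - 0.5) < 1e-8))
  ok2 <- which(!is.na(ef0$E_SI[, 1]))
  expect_true(all(abs(ef0$E_SI[ok2, ] - 0.5) < 1e-8))
  # single type: both fractions are identically 1
  f1 <- integrate_full_ame(pk, weight_type_basis(1, 1), 0.25, 2e-4, t_max = 30)
  ef1 <- ame_edge_fractions(f1)
  expect_true(all(abs(ef1$E_II[!is.na(ef1$E_II)] - 1) < 1e-10))
  # accelerative regime: strong ties crowd the bulk, weak ties the surface
  f7 <- integrate_full_ame(pk, benchmark_basis(0.7), 0.25, 2e-4, t_max = 45)
  ef7 <- ame_edge_fractions(f7)
  mid <- which(f7$rho > 0.01 & f7$rho < 0.5)
  expect_true(all(ef7$E_II[mid, 1] > 0.5))
  expect_true(all(ef7$E_SI[mid, 1] < 0.5))
  sums <- c(rowSums(ef7$E_II[mid, ]), rowSums(ef7$E_SI[mid, ]))
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("AME and MC agree on the cascade trajectory", {
  # sigma = 0.5 benchmark at moderate size: theory curve inside MC spread
  pk <- benchmark_pk()
  red <- integrate_reduced(pk, benchmark_basis(0.5), 0.25, 2e-4,
                           t_max = 200, times = seq(0, 200, 0.25),
                           rho_stop = 0.8)
  t_ame <- absolute_time(red, 0.75)
  tas <- vapply(1:6, function(r) {
    net <- generate_network(degree_spec("regular", N = 10000L, k = 7L),
                            weight_scheme("bimodal", mu = 1, sigma = 0.5,
                                          delta = 0.5), seed = 100L + r)
    ser <- run_mc(net, sim_config(phi = 0.25, p = 2e-4, t_max = 400,
                                  rho_stop = 0.77, seed = 200L + r))
    absolute_time(ser, 0.75)
  }, 0)
  expect_lt(abs(mean(tas) - t_ame) / t_ame, 0.08)
})
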