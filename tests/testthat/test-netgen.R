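test_that("regular degree sequences respect feasibility and parity", {
  spec <- degree_spec("regular", N = 10L, k = 7L)
  expect_identical(sample_degree_sequence(spec), rep(7L, 10L))
  expect_error(degree_spec("regular", N = 5L, k = 7L), "k < N")
  expect_error(sample_degree_sequence(degree_spec("regular", N = 5L, k = 3L)),
               "parity")
})

test_that("power-law degree sampling matches the truncated-zeta mean", {
  spec <- degree_spec("powerlaw", N = 10000L, tau = 2.5, k_min = 2L,
                      k_max = 1000L)
  deg <- sample_degree_sequence(spec, seed = 42L)
  expect_true(all(deg >= 2L & deg <= 1000L))
  expect_equal(sum(deg) %% 2L, 0L)
  mu <- powerlaw_mean_degree(2.5, 2L, 1000L)
  # heavy-tailed: allow a generous multiple of the SE of the sample mean
  k <- 2:1000; pk <- k^-2.5 / sum(k^-2.5)
  se <- sqrt((sum(k^2 * pk) - mu^2) / length(deg))
  expect_lt(abs(mean(deg) - mu), 5 * se)
  # sampling is deterministic in the seed
  expect_identical(deg, sample_degree_sequence(spec, seed = 42L))
})

test_that("configuration model realises the degree sequence exactly", {
  # [1,1] forces the single edge; 7-regular on 8 nodes forces K8
  net11 <- build_configuration_model(c(1L, 1L), seed = 1L)
  expect_identical(net11$edges$from, 0L)
  expect_identical(net11$edges$to, 1L)
  k8 <- build_configuration_model(rep(7L, 8L), seed = 1L)
  expect_equal(nrow(k8$edges), 28L)
  expect_identical(network_degrees(k8), rep(7L, 8L))
  expect_error(build_configuration_model(c(3L, 1L)), "odd|realisable")
  expect_error(build_configuration_model(c(3L, 1L, 0L, 0L)), "realisable")
  # simple graph with the requested degrees on a random heterogeneous case
  deg <- sample_degree_sequence(
    degree_spec("powerlaw", N = 300L, tau = 2.5, k_min = 2L, k_max = 30L),
    seed = 7L)
  net <- build_configuration_model(deg, seed = 8L)
  expect_identical(network_degrees(net), as.integer(deg))
  expect_false(any(duplicated(paste(net$edges$from, net$edges$to))))
})

test_that("bimodal weight values obey the printed identities", {
  expect_equal(unname(bimodal_weight_values(1, 0, 0.5)), c(1, 1))
  expect_equal(unname(bimodal_weight_values(1, 0.5, 0.5)), c(1.5, 0.5))
  expect_equal(unname(bimodal_weight_values(1, 1, 0.5)), c(2, 0))  # diluted
  expect_equal(unname(bimodal_weight_values(3, 1, 0.2)), c(5, 2.5))
  expect_error(bimodal_weight_values(1, 1.2, 0.5), "diluted")
  # mean/variance identities hold to machine precision across the plane
  for (mu in c(0.5, 1, 3)) for (delta in c(0.2, 0.5, 0.9)) {
    smax <- mu * sqrt((1 - delta) / delta)
    for (sigma in c(0, 0.3 * smax, 0.9 * smax, smax)) {
      w <- bimodal_weight_values(mu, sigma, delta)
      expect_equal(delta * w[[1]] + (1 - delta) * w[[2]], mu, tolerance = 1e-14)
      expect_equal(delta * (w[[1]] - mu)^2 + (1 - delta) * (w[[2]] - mu)^2,
                   sigma^2, tolerance = 1e-12)
    }
  }
})

test_that("assign_weights samples the scheme independently of topology", {
  deg <- sample_degree_sequence(
    degree_spec("powerlaw", N = 2000L, tau = 2.5, k_min = 2L, k_max = 100L),
    seed = 3L)
  net <- build_configuration_model(deg, seed = 3L)
  E <- nrow(net$edges)
  wnet <- assign_weights(net, weight_scheme("bimodal", mu = 1, sigma = 0.5,
                                            delta = 0.5), seed = 11L)
  # strong-link fraction within 3 binomial SD of delta
  frac <- mean(wnet$edges$type == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / E))
  # sigma = 0 collapses to the mean
  w0 <- assign_weights(net, weight_scheme("bimodal", mu = 1, sigma = 0,
                                          delta = 0.5), seed = 11L)
  expect_true(all(w0$edges$weight == 1))
  # weight uncorrelated with endpoint degree
  dg <- network_degrees(wnet)
  ksum <- dg[wnet$edges$from + 1L] + dg[wnet$edges$to + 1L]
  expect_lt(abs(cor(wnet$edges$weight, ksum)), 4 / sqrt(E))
})

test_that("lognormal weights hit the requested mean and stay positive", {
  net <- build_configuration_model(rep(4L, 50000L), seed = 2L)
  wnet <- assign_weights(net, weight_scheme("lognormal", mu = 1, sigma = 0.5),
                         seed = 9L)
  w <- wnet$edges$weight
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 1), 4 * 0.5 / sqrt(length(w)))
  expect_lt(abs(sd(w) - 0.5), 0.02)
})

test_that("rescale_weight_set is a mean-preserving affine contraction", {
  w <- c(1, 3)
  expect_equal(rescale_weight_set(w, 1), w)
  expect_equal(rescale_weight_set(w, 0), c(2, 2))
  expect_equal(rescale_weight_set(w, 0.5), c(1.5, 2.5))
  expect_error(rescale_weight_set(w, 1.5), "alpha")
  set.seed(1)
  ws <- rlnorm(500, 0, 1)
  for (a in c(0.2, 0.7)) for (b in c(0.3, 0.9)) {
    expect_equal(rescale_weight_set(rescale_weight_set(ws, a), b),
                 rescale_weight_set(ws, a * b), tolerance = 1e-12)
  }
  expect_equal(mean(rescale_weight_set(ws, 0.37)), mean(ws), tolerance = 1e-12)
  expect_equal(sd(rescale_weight_set(ws, 0.37)), 0.37 * sd(ws),
               tolerance = 1e-10)
  expect_true(all(rescale_weight_set(ws, 0) > 0))
})

test_that("signed edge lists map to bimodal weights via the measured delta", {
  set.seed(4)
  edges <- data.frame(from = rep(0:9, each = 10), to = rep(10:19, 10))
  edges <- edges[sample.int(nrow(edges), 100L), ]
  edges$sign <- c(rep(1L, 88), rep(-1L, 12))
  net <- signed_to_weighted(edges, mu = 1, sigma = 0.3, seed = 1L)
  expect_equal(attr(net, "delta"), 0.88)
  w <- bimodal_weight_values(1, 0.3, 0.88)
  expect_equal(sort(unique(net$edges$weight)), sort(unname(w)))
  expect_equal(mean(net$edges$type == 1L), 0.88)
  # degenerate single-sign input is rejected
  allplus <- transform(edges, sign = 1L)
  expect_error(signed_to_weighted(allplus, 1, 0.1), "degenerate")
  # sigma = 0 erases the sign distinction in the weights
  net0 <- signed_to_weighted(edges, mu = 2, sigma = 0, seed = 1L)
  expect_true(all(net0$edges$weight == 2))
  # conflicting duplicate pairs resolve deterministically under a seed
  conf <- data.frame(from = c(0L, 1L, 2L, 3L), to = c(1L, 0L, 3L, 2L),
                     sign = c(1L, -1L, 1L, -1L))
  n1 <- signed_to_weighted(conf, 1, 0.2, seed = 5L)
  n2 <- signed_to_weighted(conf, 1, 0.2, seed = 5L)
  expect_identical(n1$edges, n2$edges)
})

test_that("edge-list files round-trip and reject malformed input", {
  net <- assign_weights(build_configuration_model(rep(3L, 20L), seed = 6L),
                        weight_scheme("bimodal", mu = 1, sigma = 0.5,
                                      delta = 0.5), seed = 6L)
  f <- tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_equal(back$edges$from, net$edges$from)
  expect_equal(back$edges$to, net$edges$to)
  expect_equal(back$edges$weight, net$edges$weight)
  f2 <- tempfile(fileext = ".tsv")
  write_edge_list(back, f2)
  expect_identical(readLines(f), readLines(f2))

  g <- tempfile()
  writeLines(c("# comment", "0\t1\t1.5"), g)
  one <- read_edge_list(g)
  expect_equal(one$edges, data.frame(from = 0L, to = 1L, weight = 1.5))
  writeLines("0\t0\t1.0", g)
  expect_error(read_edge_list(g), "self-loop on line 1")
  writeLines(c("0\t1\t1.0", "1\t2"), g)
  expect_error(read_edge_list(g), "line 2")
  writeLines("0\t1\t-2", g)
  expect_error(read_edge_list(g), "non-positive")
})
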