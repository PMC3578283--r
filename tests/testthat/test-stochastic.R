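test_that("response function has the sigmoid's symmetries and values", {
  expect_equal(response_function(0, 0.7), 0.5)
  h <- c(-2, -0.3, 0.1, 1.5)
  expect_equal(response_function(h, 0.5) + response_function(-h, 0.5),
               rep(1, 4))
  expect_equal(response_function(1, 0.5), (1 + tanh(2)) / 2)
  expect_true(all(diff(response_function(seq(-3, 3, 0.1), 1.2)) > 0))
  expect_error(response_function(0, -1), "positive")
  expect_error(model_params(T = 0), "T")
  expect_equal(deterministic_response(c(-2, 0, 3)), c(0, 0.5, 1))
})

test_that("synapse updates follow the depression/facilitation arithmetic", {
  pats <- generate_patterns(6, 3, 0.2, seed = 1)
  params <- model_params(T = 1, tau_R = 4, tau_F = 2, U_se = 0.1, N = 6)
  # rest state is a fixed point of the synapse dynamics
  rest <- structure(list(s = rep(0L, 6), x = rep(1, 6), u = rep(0.1, 6),
                         t = 0L), class = "network_state")
  out <- stpmem:::with_seed(1, net_step(rest, pats, params))
  expect_equal(out$x, rep(1, 6))
  expect_equal(out$u, rep(0.1, 6))
  # active neuron at rest synapse: x drops by U_se, u gains U_se(1 - U_se)
  act <- structure(list(s = rep(1L, 6), x = rep(1, 6), u = rep(0.1, 6),
                        t = 0L), class = "network_state")
  out <- stpmem:::with_seed(1, net_step(act, pats, params))
  expect_equal(out$x, rep(1 - 0.1, 6))
  expect_equal(out$u, rep(0.1 + 0 + 0.1 * 0.9, 6))
})

test_that("state bounds are preserved over long stochastic runs", {
  pats <- generate_patterns(200, 3, 0.2, seed = 9)
  for (prm in list(model_params(T = 0.5, tau_R = 10, tau_F = 2, N = 200),
                   model_params(T = 1.0, tau_R = 4, tau_F = 24, N = 200),
                   model_params(T = 0.2, tau_R = 1, tau_F = 1, N = 200))) {
    run <- simulate_network(pats, prm, 500, init = "random", seed = 31)
    st <- run$final
    expect_true(all(st$x >= 0 & st$x <= 1))
    expect_true(all(st$u >= prm$U_se - 1e-12 & st$u <= 1 + 1e-12))
    expect_true(all(abs(run$M) <= 1))
  }
})

test_that("the recurrent field is equivariant under neuron relabeling", {
  pats <- generate_patterns(80, 3, 0.2, seed = 6)
  set.seed(3)
  sig <- runif(80, -1, 1)
  perm <- sample(80)
  pats_p <- pats
  pats_p$parent <- pats$parent[perm]
  pats_p$children <- pats$children[perm, ]
  expect_equal(synaptic_field(pats_p, sig[perm]),
               synaptic_field(pats, sig)[perm])
})

test_that("overlaps measure pattern alignment exactly", {
  pats <- generate_patterns(40, 3, 0.2, seed = 2)
  s_hit <- (pats$children[, 2] + 1) / 2
  expect_equal(overlap(s_hit, pats$children[, 2]), 1)
  expect_equal(overlap(1 - s_hit, pats$children[, 2]), -1)
  expect_equal(overlap(c(1, 1, 1, 1), c(1, 1, -1, -1)), 0)
  expect_error(overlap(c(0, 1), c(1, 1, -1)), "length")
})

test_that("simulations start where the init policy says and reproduce bit-exactly", {
  pats <- generate_patterns(2000, 3, 0.2, seed = 17)
  params <- model_params(T = 1.0, N = 2000)
  run_p <- simulate_network(pats, params, 3, init = "pattern", mu = 2,
                            seed = 5)
  expect_equal(run_p$M[1, 2], 1)
  run_r <- simulate_network(pats, params, 3, init = "random", seed = 5)
  expect_true(all(abs(run_r$M[1, ]) < 4 / sqrt(2000)))
  run_r2 <- simulate_network(pats, params, 3, init = "random", seed = 5)
  expect_identical(run_r$M, run_r2$M)
  expect_equal(dim(run_r$M), c(4L, 3L))
})

test_that("a stochastic run at retrieval parameters settles on the mean-field memory state", {
  # scaled-down version of the T = 1.0 retrieval run; the overlap must
  # approach the mean-field MEM fixed point
  pats <- generate_patterns(2000, 3, 0.2, seed = 23)
  params <- model_params(T = 1.0, tau_R = 4, tau_F = 2, N = 2000)
  fp <- solve_from_seed("MEM+1", spec02, params)
  run <- simulate_network(pats, params, 120, init = "pattern", mu = 1,
                          seed = 7)
  m_avg <- colMeans(run$M[71:121, ])
  expect_lt(abs(m_avg[1] - fp$overlaps[1]), 0.05)
  expect_lt(abs(m_avg[2] - fp$overlaps[2]), 0.05)
})
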