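test_that("steady-state synapse maps match hand arithmetic and the rest state", {
  params <- model_params(T = 1, tau_R = 4, tau_F = 2, U_se = 0.1)
  ss0 <- steady_state_maps(0, params)
  expect_equal(ss0$X, 1)
  expect_equal(ss0$U, 0.1)
  ss <- steady_state_maps(0.5, params)
  expect_equal(ss$U, 0.1 * 2 / 1.1)
  expect_equal(ss$X, 1 / (1 + 4 * (0.2 / 1.1) * 0.5))
  # full-facilitation limit
  ssf <- steady_state_maps(1, model_params(T = 1, tau_F = 1e8))
  expect_equal(ssf$U, 1, tolerance = 1e-6)
  # the composite drive equals the closed-form self-consistency bracket
  m <- seq(0, 1, 0.05)
  ssm <- steady_state_maps(m, params)
  lhs <- 2 * m * ssm$X * ssm$U / params$U_se - 1
  rhs <- 2 * m * (1 + params$tau_F * m) /
    (1 + (params$tau_F + params$tau_R) * params$U_se * m +
       params$U_se * params$tau_F * params$tau_R * m^2) - 1
  expect_equal(lhs, rhs)
  # iterating the synapse updates at clamped m lands on the same values
  X <- 1; U <- params$U_se
  for (i in 1:2000) {
    X_new <- X + (1 - X) / params$tau_R - 0.5 * X * U
    U <- U + (params$U_se - U) / params$tau_F + params$U_se * (1 - U) * 0.5
    X <- X_new
  }
  expect_equal(X, ss$X, tolerance = 1e-10)
  expect_equal(U, ss$U, tolerance = 1e-10)
})

test_that("the paramagnetic state is an exact fixed point of the macroscopic map", {
  params <- model_params(T = 0.7)
  st <- stpmem:::state_from_m(rep(0.5, 8), params)
  out <- macro_mf_step(st, spec02, params)
  expect_equal(out$m, st$m)
  expect_equal(out$X, st$X, tolerance = 1e-14)
  expect_equal(out$U, st$U, tolerance = 1e-14)
  # and the silent rest state keeps its synapse variables
  rest <- sublattice_state(rep(0, 8), rep(1, 8), rep(params$U_se, 8))
  out <- macro_mf_step(rest, spec02, params)
  expect_equal(out$X, rest$X)
  expect_equal(out$U, rest$U)
})

test_that("overlaps from sublattices agree with the microscopic overlap exactly", {
  # perfect retrieval of pattern 2: M2 = 1, the others sit at cos(theta) = b^2
  expect_equal(
    overlaps_from_sublattices(
      sublattice_state(as.numeric(spec02$eta[, 2] == 1), rep(1, 8),
                       rep(0.1, 8)), spec02),
    c(0.04, 1, 0.04), tolerance = 1e-12)
  expect_equal(overlaps_from_sublattices(
    sublattice_state(rep(0.5, 8), rep(1, 8), rep(0.1, 8)), spec02),
    rep(0, 3))
  # algebraic identity at finite N with empirical sizes
  pats <- generate_patterns(800, 3, 0.2, seed = 31)
  sl <- build_sublattices(pats)
  spec_e <- mf_spec(sizes = "empirical", patterns = pats)
  m_eta <- runif(8)
  s_micro <- m_eta[sl$membership]          # sublattice-constant activity
  M_micro <- drop(crossprod(pats$children, 2 * s_micro - 1)) / pats$N
  M_macro <- overlaps_from_sublattices(
    sublattice_state(m_eta, rep(1, 8), rep(0.1, 8)), spec_e)
  expect_equal(M_micro, M_macro, tolerance = 1e-12)
})

test_that("the sublattice reduction of the microscopic mean field is exact", {
  pats <- generate_patterns(800, 3, 0.2, seed = 41)
  sl <- build_sublattices(pats)
  spec_e <- mf_spec(sizes = "empirical", patterns = pats)
  params <- model_params(T = 0.8, tau_R = 6, tau_F = 3, N = 800)
  set.seed(12)
  m_eta <- runif(8)
  st <- stpmem:::state_from_m(m_eta, params)
  # microscopic per-neuron trajectory, constant within sublattices,
  # with the self-coupling retained (the infinite-N identification)
  m <- st$m[sl$membership]; X <- st$X[sl$membership]; U <- st$U[sl$membership]
  macro <- macro_mf_simulate(st, spec_e, params, 1000)
  for (t in 1:1000) {
    upd <- micro_mf_step(m, X, U, pats, params, exclude_self = FALSE)
    m <- upd$m; X <- upd$X; U <- upd$U
  }
  expect_lt(max(abs(m - macro$m[1001, ][sl$membership])), 1e-10)
  expect_lt(max(abs(X - macro$X[1001, ][sl$membership])), 1e-10)
  expect_lt(max(abs(U - macro$U[1001, ][sl$membership])), 1e-10)
  # with the self term excluded (the network's j != i field) the
  # trajectory deviates only at O(p/N)
  m2 <- st$m[sl$membership]; X2 <- st$X[sl$membership]
  U2 <- st$U[sl$membership]
  for (t in 1:50) {
    upd <- micro_mf_step(m2, X2, U2, pats, params)
    m2 <- upd$m; X2 <- upd$X; U2 <- upd$U
  }
  expect_lt(max(abs(m2 - macro$m[51, ][sl$membership])), 0.05)
  expect_gt(max(abs(m2 - macro$m[51, ][sl$membership])), 0)
})

test_that("macroscopic states stay in their admissible ranges under long iteration", {
  for (prm in list(model_params(T = 0.9, tau_R = 10, tau_F = 2),
                   model_params(T = 1.9, tau_R = 4, tau_F = 24))) {
    st <- stpmem:::state_from_m(c(0.9, 0.2, 0.7, 0.4, 0.6, 0.3, 0.8, 0.1),
                                prm)
    run <- macro_mf_simulate(st, spec02, prm, 1e5, record = FALSE)
    expect_true(all(run$final$m >= 0 & run$final$m <= 1))
    expect_true(all(run$final$X >= 0 & run$final$X <= 1))
    expect_true(all(run$final$U >= prm$U_se - 1e-12 & run$final$U <= 1))
    expect_true(all(abs(c(run$M_min, run$M_max)) <= 1))
    traj <- macro_mf_simulate(st, spec02, prm, 2000)
    expect_true(all(traj$m >= 0 & traj$m <= 1))
    expect_true(all(traj$X >= 0 & traj$X <= 1))
    expect_true(all(traj$U >= prm$U_se - 1e-12 & traj$U <= 1))
  }
})

test_that("the compiled trajectory matches the R reference step", {
  params <- model_params(T = 0.9, tau_R = 10, tau_F = 2)
  st <- stpmem:::state_from_m(c(0.9, 0.2, 0.7, 0.4, 0.6, 0.3, 0.8, 0.1),
                              params)
  run <- macro_mf_simulate(st, spec02, params, 50)
  ref <- st
  for (t in 1:50) ref <- macro_mf_step(ref, spec02, params)
  expect_equal(run$final$m, ref$m, tolerance = 1e-12)
  expect_equal(run$final$X, ref$X, tolerance = 1e-12)
  expect_equal(run$final$U, ref$U, tolerance = 1e-12)
  expect_equal(run$M[51, ], overlaps_from_sublattices(ref, spec02),
               tolerance = 1e-12)
})

test_that("fixed points satisfy the self-consistent steady-state equations", {
  params <- model_params(T = 1.0, tau_R = 4, tau_F = 2)
  fp <- solve_from_seed("MEM+1", spec02, params)
  expect_lt(fp$residual, 1e-10)
  ss <- steady_state_maps(fp$state$m, params)
  expect_equal(fp$state$U, ss$U, tolerance = 1e-9)
  expect_equal(fp$state$X, ss$X, tolerance = 1e-9)
})

test_that("every fixed point is paired under inversion and negation symmetry", {
  for (prm in list(model_params(T = 0.9, tau_R = 4, tau_F = 2),
                   model_params(T = 0.4, tau_R = 10, tau_F = 2))) {
    fps <- enumerate_fixed_points(spec02, prm)
    expect_gt(length(fps), 1)
    for (fp in fps) {
      img <- inversion_image(fp$state, prm)
      res_img <- max(abs(stpmem:::pack_state(macro_mf_step(img, spec02, prm)) -
                           stpmem:::pack_state(img)))
      expect_lt(res_img, 1e-8)
      expect_equal(overlaps_from_sublattices(img, spec02), fp$overlaps,
                   tolerance = 1e-8)
      neg <- state_negation(fp$state)
      res_neg <- max(abs(stpmem:::pack_state(macro_mf_step(neg, spec02, prm)) -
                           stpmem:::pack_state(neg)))
      expect_lt(res_neg, 1e-8)
      expect_equal(overlaps_from_sublattices(neg, spec02), -fp$overlaps,
                   tolerance = 1e-8)
    }
  }
})
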