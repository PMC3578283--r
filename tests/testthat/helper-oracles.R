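# Independent oracles used across the suite. These deliberately take the
# naive route (dense matrices, finite differences, direct arithmetic) so
# they stay independent of the implementation paths they check.

# dense-matrix Hebbian field: J_ij = (1/N) sum_mu xi_i xi_j, J_ii = 0
dense_field <- function(patterns, signal) {
  Xi <- patterns$children
  J <- Xi %*% t(Xi) / patterns$N
  diag(J) <- 0
  drop(J %*% signal)
}

# central-difference Jacobian of the macroscopic map on the packed state
fd_jacobian <- function(state, spec, params, h = 1e-6) {
  z0 <- c(state$m, state$X, state$U)
  n <- length(z0)
  Fz <- function(z) {
    st <- sublattice_state(z[1:(n / 3)], z[(n / 3 + 1):(2 * n / 3)],
                          z[(2 * n / 3 + 1):n])
    out <- macro_mf_step(st, spec, params)
    c(out$m, out$X, out$U)
  }
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h
    K[, j] <- (Fz(z0 + e) - Fz(z0 - e)) / (2 * h)
  }
  K
}

# a random admissible sublattice state
random_state <- function(params, n = 8L) {
  m <- runif(n)
  X <- runif(n)
  U <- runif(n, params$U_se, 1)
  sublattice_state(m, X, U)
}

spec02 <- mf_spec(b = 0.2)

params_pseudo <- function(T = 1.0) model_params(T = T, tau_R = 4, tau_F = 2)
params_depr   <- function(T = 0.5) model_params(T = T, tau_R = 10, tau_F = 2)
params_facil  <- function(T = 1.9) model_params(T = T, tau_R = 4, tau_F = 24)

# solve a fixed point from a named standard seed
solve_from_seed <- function(seed_name, spec, params, ...) {
  solve_fixed_point(standard_seeds(spec, params)[[seed_name]], spec, params,
                    ...)
}
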