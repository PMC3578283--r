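#' Sigmoidal neural response function
#'
#' Probability that a neuron fires given its field `h` at noise intensity
#' `T = 1/beta`: `g(h) = (1 + tanh(h/T)) / 2`. Monotone increasing in `h`,
#' equal to 1/2 at `h = 0`.
#'
#' @param h field value(s).
#' @param T noise intensity, > 0.
#' @return firing probability in \[0, 1\], vectorized over `h`.
#' @export
response_function <- function(h, T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("'T' must be a single positive number")
  (1 + tanh(h / T)) / 2
}

# derivative of the response function wrt h: beta/2 * (1 - tanh(beta h)^2)
response_function_deriv <- function(h, T) {
  (1 - tanh(h / T)^2) / (2 * T)
}

#' Deterministic-limit response
#'
#' Sign-threshold response for exploratory use of the zero-noise limit,
#' where the stochastic update degenerates to `s = 1` iff `h > 0` (ties at
#' `h = 0` resolved to 1/2). The simulation itself requires `T >= 1e-6`.
#'
#' @param h field value(s).
#' @return 0, 1/2 or 1, vectorized over `h`.
#' @export
deterministic_response <- function(h) {
  (sign(h) + 1) / 2
}

#' Initial state of the stochastic network
#'
#' All synapses start at rest (`x = 1`, `u = U_se`). The activity `s` is
#' either uniformly random (overlaps near zero), a stored pattern
#' (`s_i = (xi_i^mu + 1)/2`, overlap one with pattern `mu`), or the
#' inverted pattern.
#'
#' @param patterns a [generate_patterns()] object.
#' @param params a [model_params()] object.
#' @param init `"random"`, `"pattern"`, or `"antipattern"`.
#' @param mu pattern index for `"pattern"` / `"antipattern"` inits.
#' @return a `"network_state"`: list with `s` (0/1), `x`, `u`, `t`.
#' @export
network_state <- function(patterns, params, init = c("random", "pattern",
                                                     "antipattern"),
                          mu = 1L) {
  init <- match.arg(init)
  N <- patterns$N
  s <- switch(init,
    random      = as.integer(stats::runif(N) < 0.5),
    pattern     = as.integer((patterns$children[, mu] + 1L) %/% 2L),
    antipattern = as.integer((1L - patterns$children[, mu]) %/% 2L))
  structure(list(s = s, x = rep(1, N), u = rep(params$U_se, N), t = 0L),
            class = "network_state")
}

#' One synchronous update of the stochastic network
#'
#' All neurons and synapses advance simultaneously from their time-`t`
#' values. The field is `h_i = sum_{j != i} J_ij (2 s_j x_j u_j / U_se - 1)`;
#' each `s_i(t+1)` is drawn independently with probability
#' `g(h_i)`; the resource and utilization variables follow
#' `x(t+1) = x + (1 - x)/tau_R - s x u` and
#' `u(t+1) = u + (U_se - u)/tau_F + U_se (1 - u) s`, with the
#' pre-facilitation `u(t)` entering the depletion term of `x`.
#'
#' @param state a `"network_state"`.
#' @param patterns a [generate_patterns()] object.
#' @param params a [model_params()] object.
#' @return the updated `"network_state"`.
#' @export
net_step <- function(state, patterns, params) {
  s <- state$s; x <- state$x; u <- state$u
  sig <- 2 * s * x * u / params$U_se - 1
  h <- synaptic_field(patterns, sig)
  prob <- response_function(h, params$T)
  s_new <- as.integer(stats::runif(patterns$N) < prob)
  x_new <- x + (1 - x) / params$tau_R - s * x * u
  u_new <- u + (params$U_se - u) / params$tau_F + params$U_se * (1 - u) * s
  structure(list(s = s_new, x = x_new, u = u_new, t = state$t + 1L),
            class = "network_state")
}

#' Overlap of a binary activity vector with a memory pattern
#'
#' `M = (1/N) sum_i xi_i (2 s_i - 1)`; equals 1 iff the +/-1-coded
#' activity matches the pattern exactly, -1 for the inverted pattern.
#'
#' @param s binary 0/1 activity vector.
#' @param pattern +/-1 pattern vector of the same length.
#' @return overlap in \[-1, 1\].
#' @export
overlap <- function(s, pattern) {
  if (length(s) != length(pattern)) stop("'s' and 'pattern' lengths differ")
  mean(pattern * (2 * s - 1))
}

#' Simulate the stochastic network
#'
#' Iterates [net_step()] for `n_steps` synchronous updates, recording the
#' overlap with every stored pattern at each step (including the initial
#' state at `t = 0`). Optionally records a raster of the activity of a
#' subset of neurons; by default the first 96 neurons after sorting by
#' sublattice label, so retrieval is visible as stripes.
#'
#' @param patterns a [generate_patterns()] object.
#' @param params a [model_params()] object.
#' @param n_steps number of update steps.
#' @param init initial-state policy, see [network_state()].
#' @param mu pattern index for pattern-aligned inits.
#' @param seed optional integer seed for the simulation stream (independent
#'   of the pattern seed); `NULL` uses the current RNG state.
#' @param raster `FALSE`, `TRUE` (default subset), or an integer vector of
#'   0-based neuron indices to record.
#' @return list with `times` (0..n_steps), `M` (`(n_steps+1) x p` overlap
#'   matrix), `final` (final `"network_state"`), and `raster` (data frame
#'   of active `(t, neuron)` pairs, 0-based, or `NULL`).
#' @export
simulate_network <- function(patterns, params, n_steps,
                             init = "random", mu = 1L, seed = NULL,
                             raster = FALSE) {
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  run <- function() {
    state <- network_state(patterns, params, init, mu)
    keep <- NULL
    if (isTRUE(raster)) {
      ord <- order(build_sublattices(patterns)$membership)
      keep <- ord[seq_len(min(96L, patterns$N))] - 1L
    } else if (is.numeric(raster)) keep <- as.integer(raster)
    M <- matrix(NA_real_, n_steps + 1L, patterns$p)
    M[1L, ] <- crossprod(patterns$children, 2 * state$s - 1) / patterns$N
    ras <- list()
    for (t in seq_len(n_steps)) {
      state <- net_step(state, patterns, params)
      M[t + 1L, ] <- crossprod(patterns$children, 2 * state$s - 1) / patterns$N
      if (!is.null(keep)) {
        on_now <- keep[state$s[keep + 1L] == 1L]
        if (length(on_now))
          ras[[length(ras) + 1L]] <- data.frame(t = t, neuron = on_now)
      }
    }
    list(times = 0:n_steps, M = M, final = state,
         raster = if (!is.null(keep)) do.call(rbind, ras) else NULL)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write an overlap trace as CSV
#'
#' @param trace result of [simulate_network()] or [macro_mf_simulate()]
#'   (anything with `times` and `M`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t = trace$times, trace$M)
  names(df) <- c("t", paste0("M", seq_len(ncol(trace$M))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
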