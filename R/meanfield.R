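#' Sublattice state of the macroscopic mean-field map
#'
#' The macroscopic state is one triple `(m_eta, X_eta, U_eta)` per
#' sublattice: mean activity, mean releasable resource, and mean
#' utilization. For `p = 3` this is a 24-dimensional state. Entries are
#' ordered as in [sublattice_labels()].
#'
#' @param m mean activities in \[0, 1\], length `2^p`.
#' @param X mean resources in \[0, 1\], length `2^p`.
#' @param U mean utilizations in \[U_se, 1\], length `2^p`.
#' @return an object of class `"sublattice_state"`.
#' @export
sublattice_state <- function(m, X, U) {
  n <- length(m)
  if (length(X) != n || length(U) != n)
    stop("'m', 'X', 'U' must have equal length")
  structure(list(m = as.numeric(m), X = as.numeric(X), U = as.numeric(U)),
            class = "sublattice_state")
}

#' @export
print.sublattice_state <- function(x, ...) {
  cat("Sublattice state (", length(x$m), " sublattices):\n", sep = "")
  print(round(rbind(m = x$m, X = x$X, U = x$U), 4))
  invisible(x)
}

pack_state <- function(state) c(state$m, state$X, state$U)

unpack_state <- function(z) {
  n <- length(z) / 3L
  sublattice_state(z[seq_len(n)], z[n + seq_len(n)], z[2L * n + seq_len(n)])
}

#' Steady-state synapse variables at constant activity
#'
#' At a constant mean activity `m`, the resource and utilization variables
#' relax to `U = U_se (1 + tau_F m) / (1 + tau_F U_se m)` and
#' `X = 1 / (1 + tau_R U m)`. The composite drive
#' `2 m X U / U_se - 1` is then the self-consistent bracket of the
#' steady-state activity equation.
#'
#' @param m mean activity value(s) in \[0, 1\].
#' @param params a [model_params()] object.
#' @return list with components `X` and `U`, vectorized over `m`.
#' @export
steady_state_maps <- function(m, params) {
  U <- params$U_se * (1 + params$tau_F * m) / (1 + params$tau_F * params$U_se * m)
  X <- 1 / (1 + params$tau_R * U * m)
  list(X = X, U = U)
}

# sublattice_state with X, U at their steady-state values for activity m
state_from_m <- function(m, params) {
  ss <- steady_state_maps(m, params)
  sublattice_state(m, ss$X, ss$U)
}

#' One step of the macroscopic mean-field map
#'
#' Advances the sublattice state by the deterministic map
#' `m_eta <- g(sum_eta' p_eta' (eta . eta') (2 m X U / U_se - 1))` with the
#' resource/utilization updates applied sublattice-wise. Exact for the
#' Hebbian network in the infinite-N limit.
#'
#' @param state a [sublattice_state()].
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @return the updated `"sublattice_state"`.
#' @export
macro_mf_step <- function(state, spec, params) {
  sig <- 2 * state$m * state$X * state$U / params$U_se - 1
  h <- drop(spec$D %*% (spec$sizes * sig))
  m_new <- response_function(h, params$T)
  X_new <- state$X + (1 - state$X) / params$tau_R - state$m * state$X * state$U
  U_new <- state$U + (params$U_se - state$U) / params$tau_F +
    params$U_se * (1 - state$U) * state$m
  sublattice_state(m_new, X_new, U_new)
}

#' Iterate the macroscopic mean-field map
#'
#' Deterministic trajectory of the sublattice map, recording the overlaps
#' with each stored pattern at every step. The inner loop runs in compiled
#' code.
#'
#' @param state0 initial [sublattice_state()].
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @param n_steps number of steps, >= 1.
#' @param record if `FALSE`, only the final state and overlap extrema are
#'   returned (no per-step storage).
#' @return list with `times` (0..n_steps), `M` (`(n_steps+1) x p` overlaps),
#'   `m`, `X`, `U` (`(n_steps+1) x 2^p` state trajectories) when
#'   `record = TRUE`; otherwise `final`, `M_min`, `M_max`.
#'   Always contains `final`, the final `"sublattice_state"`.
#' @export
macro_mf_simulate <- function(state0, spec, params, n_steps, record = TRUE) {
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  res <- macro_traj_cpp(state0$m, state0$X, state0$U,
                        spec$D, spec$sizes, spec$eta,
                        params$U_se, params$tau_R, params$tau_F, params$T,
                        as.integer(n_steps), isTRUE(record))
  final <- sublattice_state(res$m_final, res$X_final, res$U_final)
  if (isTRUE(record)) {
    list(times = 0:n_steps, M = res$M, m = res$m, X = res$X, U = res$U,
         final = final)
  } else {
    list(final = final, M_min = drop(res$M_min), M_max = drop(res$M_max))
  }
}

#' Overlaps from a sublattice state
#'
#' `M^mu = sum_eta p_eta eta^mu (2 m_eta - 1)`: the macroscopic expression
#' of the pattern overlap, exact for sublattice-constant states.
#'
#' @param state a [sublattice_state()].
#' @param spec an [mf_spec()].
#' @return length-`p` overlap vector.
#' @export
overlaps_from_sublattices <- function(state, spec) {
  unname(drop(crossprod(spec$eta, spec$sizes * (2 * state$m - 1))))
}

#' One step of the microscopic mean-field map
#'
#' The per-neuron noise-averaged map: `m_i <- g(h_i)` with the O(Np) Hebbian
#' field on the effective signal `2 m_j X_j U_j / U_se - 1` (self-term
#' excluded), and the synapse updates applied per neuron. Serves as the
#' validation bridge between the stochastic network and the macroscopic
#' sublattice map: a trajectory started constant within each sublattice
#' stays so and coincides with the macroscopic trajectory up to the
#' `O(p/N)` self-coupling correction, exactly so when the self-term is
#' retained (see `exclude_self`).
#'
#' @param m,X,U length-`N` vectors of per-neuron means.
#' @param patterns a [generate_patterns()] object.
#' @param params a [model_params()] object.
#' @param exclude_self if `TRUE` (default) the field excludes the
#'   self-coupling `j = i`, matching the network; if `FALSE` the self term
#'   is kept, which makes the sublattice reduction exact at finite N.
#' @return list with updated `m`, `X`, `U`.
#' @export
micro_mf_step <- function(m, X, U, patterns, params, exclude_self = TRUE) {
  sig <- 2 * m * X * U / params$U_se - 1
  if (exclude_self) {
    h <- synaptic_field(patterns, sig)
  } else {
    Xi <- patterns$children
    h <- drop(Xi %*% crossprod(Xi, sig)) / patterns$N
  }
  list(m = response_function(h, params$T),
       X = X + (1 - X) / params$tau_R - m * X * U,
       U = U + (params$U_se - U) / params$tau_F + params$U_se * (1 - U) * m)
}

#' Symmetry images of a sublattice state
#'
#' Two exact symmetries of the macroscopic map relate fixed points to
#' fixed points.
#'
#' `inversion_image()` is the activity inversion `m'(eta) = 1 - m(-eta)`
#' with `X'`, `U'` re-derived from [steady_state_maps()] at `m'` (the raw
#' synapse variables do not simply relabel because depression and
#' facilitation act only on active neurons). It preserves the overlap
#' vector: every fixed point is paired with an inversion image that is
#' again a fixed point with the same overlaps.
#'
#' `state_negation()` is the pure sublattice relabeling
#' `(m, X, U)(eta) -> (m, X, U)(-eta)`, which maps a fixed point with
#' overlaps `M` to one with overlaps `-M` — a retrieved pattern to its
#' sign-flipped counterpart.
#'
#' `permute_patterns()` applies a permutation of the `p` stored patterns
#' to the state (relabeling `eta` component-wise), the remaining exact
#' symmetry; together with `state_negation()` it generates the six-fold
#' orbit of a memory state.
#'
#' @param state a [sublattice_state()].
#' @param params a [model_params()] object (for `inversion_image`).
#' @param perm integer permutation of `1:p` (for `permute_patterns`).
#' @param spec an [mf_spec()] (for `permute_patterns`).
#' @return the image `"sublattice_state"`.
#' @export
inversion_image <- function(state, params) {
  n <- length(state$m)
  m_new <- 1 - state$m[n:1L]  # canonical order lists -eta at mirrored index
  state_from_m(m_new, params)
}

#' @rdname inversion_image
#' @export
state_negation <- function(state) {
  n <- length(state$m)
  sublattice_state(state$m[n:1L], state$X[n:1L], state$U[n:1L])
}

#' @rdname inversion_image
#' @export
permute_patterns <- function(state, perm, spec) {
  eta_perm <- spec$eta[, perm, drop = FALSE]
  # row of eta that each permuted label corresponds to
  key <- function(M) apply(M, 1L, paste, collapse = ",")
  idx <- match(key(eta_perm), key(spec$eta))
  sublattice_state(state$m[idx], state$X[idx], state$U[idx])
}
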