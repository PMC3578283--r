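#' Model parameters for the dynamic-synapse associative memory network
#'
#' Bundles the parameters of the stochastic network and of its mean-field
#' reduction. `T` is the noise intensity (the inverse gain `1/beta` of the
#' sigmoidal response function); `tau_R` and `tau_F` are the recovery and
#' facilitation time constants of the dynamic synapses, in time steps;
#' `U_se` is the baseline fraction of neurotransmitter released per
#' activation; `b` is the correlation level among memory patterns; `p` the
#' number of stored patterns and `N` the number of neurons.
#'
#' The defaults are the headline setting used throughout the analyses:
#' `U_se = 0.1`, `b = 0.2`, `p = 3`, `N = 1e4`, with the "pseudo-constant"
#' synapse time constants `tau_R = 4`, `tau_F = 2`.
#'
#' @param T noise intensity, > 0. Values below `1e-6` are rejected: the
#'   response function degenerates to a step in the deterministic limit
#'   (see [deterministic_response()] for exploratory use of that limit).
#' @param tau_R recovery time constant of the releasable resource, >= 1.
#' @param tau_F facilitation time constant of the utilization variable, >= 1.
#' @param U_se baseline release fraction, in (0, 1].
#' @param b correlation level among memory patterns, in \[0, 1\].
#' @param p number of stored (child) patterns, >= 1.
#' @param N number of neurons, >= 1.
#' @return an object of class `"model_params"` (a validated named list).
#' @export
#' @examples
#' model_params(T = 1.0)
model_params <- function(T = 1.0, tau_R = 4, tau_F = 2, U_se = 0.1,
                         b = 0.2, p = 3L, N = 10000L) {
  stopifnot(is.numeric(T), length(T) == 1L,
            is.numeric(tau_R), length(tau_R) == 1L,
            is.numeric(tau_F), length(tau_F) == 1L,
            is.numeric(U_se), length(U_se) == 1L,
            is.numeric(b), length(b) == 1L)
  if (!is.finite(T) || T < 1e-6)
    stop("'T' must be finite and >= 1e-6 (deterministic limit not supported)")
  if (tau_R < 1) stop("'tau_R' must be >= 1")
  if (tau_F < 1) stop("'tau_F' must be >= 1")
  if (U_se <= 0 || U_se > 1) stop("'U_se' must be in (0, 1]")
  if (b < 0 || b > 1) stop("'b' must be in [0, 1]")
  p <- as.integer(p); N <- as.integer(N)
  if (p < 1) stop("'p' must be >= 1")
  if (N < 1) stop("'N' must be >= 1")
  structure(list(T = T, tau_R = tau_R, tau_F = tau_F, U_se = U_se,
                 b = b, p = p, N = N),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  T = %g (noise intensity), tau_R = %g, tau_F = %g, U_se = %g\n",
              x$T, x$tau_R, x$tau_F, x$U_se))
  cat(sprintf("  b = %g, p = %d, N = %d\n", x$b, x$p, x$N))
  invisible(x)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
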