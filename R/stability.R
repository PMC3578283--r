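#' Analytic Jacobian of the macroscopic mean-field map
#'
#' Assembles the `3*2^p` square Jacobian `K` of the sublattice map at a
#' given (not necessarily fixed) state, in the canonical sublattice order
#' with the `m`, `X`, `U` blocks stacked in that order. The activity rows
#' couple all sublattices through the field; the synapse rows are diagonal:
#' \deqn{\partial F_m/\partial m' = g'(h) p' (\eta\cdot\eta') 2XU/U_{se},}
#' and analogously with `2mU/U_se` for the `X` derivative and `2mX/U_se`
#' for the `U` derivative; `dF_X/dX = 1 - 1/tau_R - mU`,
#' `dF_X/dm = -UX`, `dF_X/dU = -mX`, `dF_U/dm = U_se(1 - U)`,
#' `dF_U/dX = 0`, `dF_U/dU = 1 - 1/tau_F - U_se m`.
#'
#' @param state a [sublattice_state()].
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @return a `3n x 3n` numeric matrix, `n = 2^p`.
#' @export
jacobian_matrix <- function(state, spec, params) {
  n <- length(state$m)
  m <- state$m; X <- state$X; U <- state$U
  Use <- params$U_se
  sig <- 2 * m * X * U / Use - 1
  h <- drop(spec$D %*% (spec$sizes * sig))
  gp <- response_function_deriv(h, params$T)
  W <- spec$D * rep(spec$sizes, each = n)          # W[i,k] = D[i,k] p_k
  A <- gp * W * rep(2 * X * U / Use, each = n)     # dFm/dm
  B <- gp * W * rep(2 * m * U / Use, each = n)     # dFm/dX
  C <- gp * W * rep(2 * m * X / Use, each = n)     # dFm/dU
  K <- matrix(0, 3L * n, 3L * n)
  im <- seq_len(n); iX <- n + im; iU <- 2L * n + im
  K[im, im] <- A
  K[im, iX] <- B
  K[im, iU] <- C
  K[cbind(iX, im)] <- -U * X
  K[cbind(iX, iX)] <- 1 - 1 / params$tau_R - m * U
  K[cbind(iX, iU)] <- -m * X
  K[cbind(iU, im)] <- Use * (1 - U)
  K[cbind(iU, iU)] <- 1 - 1 / params$tau_F - Use * m
  K
}

# residual of the fixed-point condition, F(z) - z on the packed state
fp_residual <- function(z, spec, params) {
  st <- unpack_state(z)
  pack_state(macro_mf_step(st, spec, params)) - z
}

#' Solve a fixed point of the macroscopic map
#'
#' Newton iteration on `F(z) - z = 0` over the packed `(m, X, U)` state,
#' using the analytic [jacobian_matrix()]. Iterates are clipped to the
#' admissible box; non-convergence or convergence outside the box returns
#' `NULL` so callers can try other seeds.
#'
#' @param seed_state initial [sublattice_state()] guess.
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @param tol residual tolerance (max norm), default `1e-12`.
#' @param max_iter Newton iteration cap.
#' @return an object of class `"fixed_point"`: list with `state`, `params`,
#'   `T`, `residual`, `overlaps`, `eigenvalues`, `spectral_radius`,
#'   `stable`, `marginal`, `label` — or `NULL` on failure.
#' @export
solve_fixed_point <- function(seed_state, spec, params, tol = 1e-12,
                              max_iter = 60L) {
  n <- length(seed_state$m)
  z <- pack_state(seed_state)
  lo <- c(rep(0, n), rep(0, n), rep(params$U_se, n))
  hi <- rep(1, 3L * n)
  slack <- 1e-3  # iterates may overshoot the box slightly mid-iteration
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- fp_residual(z, spec, params)
    if (max(abs(r)) < tol) { converged <- TRUE; break }
    K <- jacobian_matrix(unpack_state(z), spec, params)
    J <- K - diag(3L * n)
    dz <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz))) return(NULL)
    z <- pmin(pmax(z + dz, lo - slack), hi + slack)
  }
  if (!converged) return(NULL)
  if (any(z < lo - 1e-9) || any(z > hi + 1e-9)) return(NULL)
  z <- pmin(pmax(z, lo), hi)
  state <- unpack_state(z)
  fixed_point(state, spec, params,
              residual = max(abs(fp_residual(z, spec, params))))
}

# assemble a fixed_point object (spectrum, stability, label) from a state
fixed_point <- function(state, spec, params, residual, margin = 1e-8) {
  ev <- eigen(jacobian_matrix(state, spec, params), only.values = TRUE)$values
  rho <- max(Mod(ev))
  M <- overlaps_from_sublattices(state, spec)
  label <- if (spec$p == 3L) classify_fixed_point(M)
           else new_state_label("UNCLASSIFIED")
  structure(list(state = state, params = params, T = params$T,
                 residual = residual, overlaps = M, eigenvalues = ev,
                 spectral_radius = rho,
                 stable = rho < 1 - margin,
                 marginal = abs(rho - 1) <= margin,
                 label = label),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point [%s] at T = %g: |M| = (%s), rho = %.6f (%s)\n",
              format(x$label), x$T,
              paste(sprintf("%.4f", x$overlaps), collapse = ", "),
              x$spectral_radius,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

# leading real eigenvalue (largest Re among eigenvalues with negligible
# imaginary part) and leading complex modulus, for crossing indicators
eig_indicators <- function(ev, im_tol = 1e-7) {
  is_real <- abs(Im(ev)) <= im_tol
  list(real_max = if (any(is_real)) max(Re(ev[is_real])) else -Inf,
       cplx_mod = if (any(!is_real)) max(Mod(ev[!is_real])) else -Inf)
}

#' Seed states for fixed-point enumeration
#'
#' The standard seed family at `p = 3`: the paramagnetic seed `m = 1/2`;
#' six memory seeds `m = (1 + c eta^mu)/2` aligned with `+/-xi^mu`; two
#' symmetric-mixture seeds aligned with `+/-sgn(xi^1 + xi^2 + xi^3)`; six
#' asymmetric-mixture seeds aligned with the sign patterns
#' `+/-sgn(-xi^mu + xi^nu + xi^rho)`. Synapse variables start at their
#' steady-state values for the seed activity.
#'
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @param c_align alignment strength of the seeds, default 0.8.
#' @return named list of [sublattice_state()] seeds.
#' @export
standard_seeds <- function(spec, params, c_align = 0.8) {
  eta <- spec$eta
  seeds <- list(PARA = rep(0.5, nrow(eta)))
  for (mu in seq_len(ncol(eta))) {
    seeds[[paste0("MEM+", mu)]] <- (1 + c_align * eta[, mu]) / 2
    seeds[[paste0("MEM-", mu)]] <- (1 - c_align * eta[, mu]) / 2
  }
  smix <- sign(rowSums(eta))
  seeds[["SMIX+"]] <- (1 + c_align * smix) / 2
  seeds[["SMIX-"]] <- (1 - c_align * smix) / 2
  for (mu in seq_len(ncol(eta))) {
    amix <- sign(rowSums(eta) - 2 * eta[, mu])  # sgn(-eta^mu + others)
    seeds[[paste0("AMIX+", mu)]] <- (1 + c_align * amix) / 2
    seeds[[paste0("AMIX-", mu)]] <- (1 - c_align * amix) / 2
  }
  lapply(seeds, state_from_m, params = params)
}

#' Enumerate fixed points from the standard seed family
#'
#' Runs [solve_fixed_point()] from every seed in [standard_seeds()] and
#' deduplicates converged solutions.
#'
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @param seeds optional named list of seed states; default
#'   [standard_seeds()].
#' @param tol Newton tolerance.
#' @param dedup_tol max-norm distance under which two solutions are the
#'   same point.
#' @return list of `"fixed_point"` objects (named by the seed that first
#'   reached each).
#' @export
enumerate_fixed_points <- function(spec, params, seeds = NULL,
                                   tol = 1e-12, dedup_tol = 1e-6) {
  if (is.null(seeds)) seeds <- standard_seeds(spec, params)
  found <- list()
  zs <- list()
  for (nm in names(seeds)) {
    fp <- solve_fixed_point(seeds[[nm]], spec, params, tol = tol)
    if (is.null(fp)) next
    z <- pack_state(fp$state)
    dup <- any(vapply(zs, function(zz) max(abs(zz - z)) < dedup_tol,
                      logical(1)))
    if (!dup) {
      found[[nm]] <- fp
      zs[[length(zs) + 1L]] <- z
    }
  }
  found
}

with_T <- function(params, T) {
  params$T <- T
  params
}

#' Continue a fixed-point branch in the noise intensity
#'
#' Natural-parameter continuation of a fixed point from its current `T`
#' toward `T_to`, with a secant predictor and adaptive step halving. The
#' branch ends either at `T_to` or when the step underflows (`min_step`),
#' which signals a fold: the branch cannot be continued past a saddle-node.
#' A branch-jump guard rejects solutions far from the predictor, so the
#' continuation cannot silently hop to a different branch near folds or
#' branch intersections.
#'
#' @param fp a converged `"fixed_point"` seed.
#' @param spec an [mf_spec()].
#' @param T_to target noise intensity.
#' @param step initial step in `T`, default `5e-3`.
#' @param min_step smallest step before the branch is declared ended.
#' @param tol Newton tolerance per point.
#' @param max_points safety cap on the number of accepted points.
#' @return an object of class `"branch"`: list with `T` (vector),
#'   `points` (list of `"fixed_point"`), `reason` (`"completed"` or
#'   `"step_underflow"`), `direction`.
#' @export
continue_branch <- function(fp, spec, T_to, step = 5e-3, min_step = 1e-6,
                            tol = 1e-12, max_points = 5000L) {
  stopifnot(inherits(fp, "fixed_point"))
  dir <- sign(T_to - fp$T)
  if (dir == 0) stop("'T_to' equals the seed fixed point's T")
  pts <- list(fp)
  Ts <- fp$T
  z_prev <- NULL
  z_last <- pack_state(fp$state)
  T_last <- fp$T
  h <- step
  reason <- "completed"
  while (length(pts) < max_points) {
    if (dir * (T_to - T_last) <= 0) break
    h <- min(h, abs(T_to - T_last))
    T_next <- T_last + dir * h
    # secant predictor along the branch
    z_pred <- if (is.null(z_prev)) z_last else {
      dT_old <- T_last - Ts[length(Ts) - 1L]
      z_last + (z_last - z_prev) * (dir * h / dT_old)
    }
    cand <- solve_fixed_point(unpack_state(z_pred), spec,
                              with_T(fp$params, T_next), tol = tol)
    ok <- FALSE
    if (!is.null(cand)) {
      z_new <- pack_state(cand$state)
      move <- if (is.null(z_prev)) Inf else max(abs(z_last - z_prev))
      jump_tol <- 10 * (min(move, 1) + h) + 1e-4
      ok <- max(abs(z_new - z_pred)) <= jump_tol
    }
    if (ok) {
      pts[[length(pts) + 1L]] <- cand
      Ts <- c(Ts, T_next)
      z_prev <- z_last; z_last <- z_new; T_last <- T_next
      h <- min(step, h * 2)
    } else {
      h <- h / 2
      if (h < min_step) { reason <- "step_underflow"; break }
    }
  }
  structure(list(T = Ts, points = pts, reason = reason, direction = dir,
                 spec = spec, params = fp$params),
            class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  lab <- x$points[[1L]]$label
  cat(sprintf("Branch [%s]: %d points, T in [%g, %g], end: %s\n",
              format(lab), length(x$T), min(x$T), max(x$T), x$reason))
  invisible(x)
}

#' Branch summary table
#'
#' @param branch a `"branch"`.
#' @return data frame with `T`, sublattice activities, overlaps, spectral
#'   radius, stability flag and label per accepted point.
#' @export
branch_table <- function(branch) {
  rows <- lapply(branch$points, function(fp) {
    data.frame(T = fp$T,
               t(stats::setNames(fp$state$m,
                                 paste0("m_", seq_along(fp$state$m)))),
               t(stats::setNames(fp$overlaps,
                                 paste0("M", seq_along(fp$overlaps)))),
               spectral_radius = fp$spectral_radius,
               stable = fp$stable,
               label = format(fp$label))
  })
  do.call(rbind, rows)
}

# solve a fixed point at T, seeded by linear interpolation between two
# bracketing branch points; used by the bisection refinements
solve_between <- function(T, fp_lo, fp_hi, spec, params, tol = 1e-10) {
  w <- if (fp_hi$T != fp_lo$T) (T - fp_lo$T) / (fp_hi$T - fp_lo$T) else 0.5
  z <- (1 - w) * pack_state(fp_lo$state) + w * pack_state(fp_hi$state)
  solve_fixed_point(unpack_state(z), spec, with_T(params, T), tol = tol)
}

#' Detect and classify bifurcations along a branch
#'
#' Scans consecutive branch points for unit-circle crossings of the
#' Jacobian spectrum and refines each crossing by bisection in `T` (each
#' bisection step re-solves the fixed point). Complex-pair crossings are
#' Neimark-Sacker (NS) points. Real crossings of +1 are classified from
#' the local branch geometry, probed by Newton solves seeded off the
#' critical eigenvector on either side of the crossing:
#' \describe{
#'   \item{TC}{a transversally intersecting branch of distinct fixed
#'     points exists on both sides — stability is exchanged
#'     (transcritical).}
#'   \item{PF}{a symmetry-related pair of branches exists on one side only
#'     and the carrying branch is invariant under the sublattice negation
#'     `eta -> -eta` (the symmetric trunk) — pitchfork.}
#'   \item{SN}{a pair of distinct fixed points exists on one side only and
#'     annihilates at the crossing (fold of the colliding pair), or the
#'     continuation itself ends in a fold (step underflow) with a real
#'     eigenvalue at +1.}
#' }
#' Real crossings that fit none of these geometries are reported as type
#' `"RC"` (real crossing, unclassified) rather than guessed.
#'
#' @param branch a `"branch"` from [continue_branch()].
#' @param refine_tol bisection tolerance in `T`, default `1e-4`.
#' @param probe_delta parameter offset used when probing for transversal
#'   branches around a real crossing.
#' @return data frame with columns `T`, `type`, `branch_label`,
#'   `eigen_re`, `eigen_im` (critical eigenvalue at detection).
#' @export
detect_bifurcations <- function(branch, refine_tol = 1e-4,
                                probe_delta = 0.02) {
  spec <- branch$spec
  params <- branch$params
  pts <- branch$points
  out <- list()
  ind <- lapply(pts, function(fp) eig_indicators(fp$eigenvalues))
  crossings <- function(get) {
    v <- vapply(ind, get, numeric(1)) - 1
    which(v[-length(v)] * v[-1] < 0 & is.finite(v[-length(v)]) &
            is.finite(v[-1]))
  }
  refine <- function(i, get, quiet_fail = TRUE) {
    lo <- pts[[i]]; hi <- pts[[i + 1L]]
    f_lo <- get(eig_indicators(lo$eigenvalues)) - 1
    while (abs(hi$T - lo$T) > refine_tol) {
      mid <- solve_between((lo$T + hi$T) / 2, lo, hi, spec, params)
      if (is.null(mid)) break
      f_mid <- get(eig_indicators(mid$eigenvalues)) - 1
      if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid }
      else hi <- mid
    }
    list(T = (lo$T + hi$T) / 2, at = hi)
  }
  for (i in crossings(function(x) x$real_max)) {
    r <- refine(i, function(x) x$real_max)
    ev <- r$at$eigenvalues
    crit <- ev[which.min(Mod(ev - 1))]
    type <- classify_real_crossing(r, pts[[i]], pts[[i + 1L]], spec, params,
                                   probe_delta)
    out[[length(out) + 1L]] <- data.frame(
      T = r$T, type = type, branch_label = format(pts[[i]]$label),
      eigen_re = Re(crit), eigen_im = Im(crit))
  }
  for (i in crossings(function(x) x$cplx_mod)) {
    r <- refine(i, function(x) x$cplx_mod)
    ev <- r$at$eigenvalues
    cplx <- ev[abs(Im(ev)) > 1e-7]
    crit <- cplx[which.max(Mod(cplx))]
    out[[length(out) + 1L]] <- data.frame(
      T = r$T, type = "NS", branch_label = format(pts[[i]]$label),
      eigen_re = Re(crit), eigen_im = Im(crit))
  }
  if (branch$reason == "step_underflow") {
    last <- pts[[length(pts)]]
    rm1 <- eig_indicators(last$eigenvalues)$real_max
    ev <- last$eigenvalues
    crit <- ev[which.min(Mod(ev - 1))]
    out[[length(out) + 1L]] <- data.frame(
      T = last$T, type = if (abs(rm1 - 1) < 0.05) "SN" else "RC",
      branch_label = format(last$label),
      eigen_re = Re(crit), eigen_im = Im(crit))
  }
  if (!length(out))
    return(data.frame(T = numeric(), type = character(),
                      branch_label = character(), eigen_re = numeric(),
                      eigen_im = numeric()))
  res <- do.call(rbind, out)
  res[order(res$T), , drop = FALSE]
}

# probe for transversally intersecting fixed points on both sides of a
# refined real crossing: seeds displaced along the critical eigenvector
# from branch points near T* +/- delta. Distinct fixed points on both
# sides -> TC; one side only -> PF on a negation-invariant trunk, SN
# (annihilating pair) otherwise; none -> RC (unclassified).
classify_real_crossing <- function(refined, fp_lo, fp_hi, spec, params,
                                   delta, kappa = 0.08) {
  side_has_branch <- function(fp_near, T_probe) {
    fp <- solve_between(T_probe, fp_lo, fp_hi, spec, params, tol = 1e-10)
    if (is.null(fp)) fp <- fp_near
    K <- jacobian_matrix(fp$state, spec, with_T(params, T_probe))
    ed <- eigen(K)
    j <- which.min(Mod(ed$values - 1))
    v <- Re(ed$vectors[, j])
    v <- v / max(abs(v))
    z <- pack_state(fp$state)
    for (sgn in c(1, -1)) {
      cand <- solve_fixed_point(unpack_state(z + sgn * kappa * v), spec,
                                with_T(params, T_probe), tol = 1e-10)
      if (is.null(cand)) next
      d <- max(abs(pack_state(cand$state) - z))
      if (d > 1e-5 && d < 0.5) return(TRUE)
    }
    FALSE
  }
  below <- side_has_branch(fp_lo, refined$T - delta)
  above <- side_has_branch(fp_hi, refined$T + delta)
  if (below && above) return("TC")
  if (below || above) {
    if (is_negation_invariant(refined$at$state)) "PF" else "SN"
  } else "RC"
}

# invariance under the sublattice relabeling eta -> -eta (the symmetric
# trunk containing the paramagnetic state)
is_negation_invariant <- function(state, tol = 1e-6) {
  max(abs(pack_state(state_negation(state)) - pack_state(state))) < tol
}

#' Brute-force oscillation scan over a grid of noise intensities
#'
#' Iterates the macroscopic map along `T_grid` with orbit inheritance (the
#' attractor found at one `T` seeds the next), discarding a transient and
#' measuring overlap extrema and the mean effective dimension over a
#' window. Oscillation is declared when the largest peak-to-peak overlap
#' amplitude exceeds `amp_tol`. Sweeping with decreasing `T` locates the
#' subcritical onset of an invariant circle that coexists with stable
#' fixed points; the associated Neimark-Sacker point itself comes from the
#' fixed-point spectrum.
#'
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object (its `T` is overridden).
#' @param T_grid noise intensities, traversed in the given order.
#' @param state0 initial [sublattice_state()] (an orbit point at
#'   `T_grid[1]`, e.g. from [find_attractor()]).
#' @param transient steps discarded per grid point, default 5000.
#' @param window measurement steps per grid point, default 10000.
#' @param amp_tol amplitude threshold for oscillation, default `1e-3`.
#' @param epsilon effective-dimension tolerance, default `1e-5`.
#' @return data frame with one row per `T`: `T`, `amplitude`, `MED`,
#'   `oscillating`, `label` (OS class or fixed-point class), and
#'   `M1_min..M3_max` extrema. The per-`T` final states are attached as
#'   attribute `"states"`.
#' @export
oscillation_range <- function(spec, params, T_grid, state0,
                              transient = 5000L, window = 10000L,
                              amp_tol = 1e-3, epsilon = 1e-5) {
  E <- spec$eta; storage.mode(E) <- "double"
  res <- macro_sweep_cpp(state0$m, state0$X, state0$U, spec$D, spec$sizes,
                         E, params$U_se, params$tau_R, params$tau_F,
                         T_grid, as.integer(transient), as.integer(window),
                         epsilon)
  osc <- res$amplitude > amp_tol
  lab <- character(length(T_grid))
  for (i in seq_along(T_grid)) {
    if (osc[i]) {
      med <- res$med[i]
      lab[i] <- if (med <= 1 + 1e-9) "OS1" else if (med <= 2) "OS2" else "OS3"
    } else {
      Mmid <- (res$M_min[i, ] + res$M_max[i, ]) / 2
      lab[i] <- format(classify_fixed_point(Mmid, tol_zero = 1e-4,
                                            tol_equal = 1e-4))
    }
  }
  p <- ncol(res$M_min)
  ext <- cbind(res$M_min, res$M_max)
  colnames(ext) <- c(paste0("M", seq_len(p), "_min"),
                     paste0("M", seq_len(p), "_max"))
  out <- data.frame(T = T_grid, amplitude = res$amplitude, MED = res$med,
                    oscillating = osc, label = lab, ext)
  attr(out, "states") <- res$states
  out
}

#' Locate an attractor of the macroscopic map at one parameter point
#'
#' Iterates the map from one or more seeds (default: small symmetric
#' perturbations of the standard seed family) and returns the first
#' attractor found, preferring oscillatory ones when `prefer = "oscillation"`.
#'
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @param seeds list of [sublattice_state()] seeds; default derived from
#'   [standard_seeds()] with a slight symmetry-breaking perturbation.
#' @param transient,window iteration lengths.
#' @param amp_tol oscillation amplitude threshold.
#' @param prefer `"oscillation"` or `"any"`.
#' @return list with `state` (a point on the attractor), `amplitude`,
#'   `oscillating`, `M_min`, `M_max`; or `NULL` if `prefer = "oscillation"`
#'   and no seed reaches an oscillatory attractor.
#' @export
find_attractor <- function(spec, params, seeds = NULL, transient = 5000L,
                           window = 5000L, amp_tol = 1e-3,
                           prefer = c("oscillation", "any")) {
  prefer <- match.arg(prefer)
  if (is.null(seeds)) {
    base <- standard_seeds(spec, params, c_align = 0.7)
    # slight asymmetric tilt so trajectories are not trapped on invariant
    # symmetric subspaces
    tilt <- seq(-0.01, 0.01, length.out = nrow(spec$eta))
    seeds <- lapply(base, function(st)
      sublattice_state(pmin(pmax(st$m + tilt, 0), 1), st$X, st$U))
  }
  best <- NULL
  for (st in seeds) {
    warm <- macro_mf_simulate(st, spec, params, transient, record = FALSE)
    meas <- macro_mf_simulate(warm$final, spec, params, window,
                              record = FALSE)
    amp <- max(meas$M_max - meas$M_min)
    cand <- list(state = meas$final, amplitude = amp,
                 oscillating = amp > amp_tol,
                 M_min = meas$M_min, M_max = meas$M_max)
    if (cand$oscillating) return(cand)
    if (is.null(best)) best <- cand
  }
  if (prefer == "oscillation") NULL else best
}

#' Random near-zero-overlap initial state
#'
#' The mean-field analogue of initializing the stochastic network with
#' random activity (all overlaps close to zero), resting synapses
#' (`x = 1`, `u = U_se`): sublattice activities `1/2` plus Gaussian
#' fluctuations of the size expected from a finite network,
#' `sigma ~ 1/(2 sqrt(N p_eta))` (about 0.015 at `N = 1e4`).
#'
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object.
#' @param sigma fluctuation scale of the sublattice activities.
#' @return a [sublattice_state()].
#' @export
random_overlap_state <- function(spec, params, sigma = 0.015) {
  n <- nrow(spec$eta)
  m <- pmin(pmax(0.5 + stats::rnorm(n, 0, sigma), 0), 1)
  sublattice_state(m, rep(1, n), rep(params$U_se, n))
}

#' Onset of oscillatory states by brute force
#'
#' Scans a descending grid of noise intensities and, at each `T`, asks
#' whether an oscillatory attractor is reached from the random
#' near-zero-overlap initial state ([random_overlap_state()]): a batch of
#' `n_seeds` independent trajectories is iterated past a transient and a
#' `T` counts as oscillating when any trajectory sustains a peak-to-peak
#' overlap amplitude above `amp_tol` over the measurement window. The scan
#' stops after `patience` consecutive non-oscillating grid points; the
#' onset is the smallest oscillating `T` found. This emergence criterion
#' matches how oscillatory regimes appear in simulations started from
#' unbiased activity; the underlying invariant circle itself can persist
#' to lower `T` as a coexisting attractor, which [oscillation_range()]
#' tracks by orbit inheritance.
#'
#' @param spec an [mf_spec()].
#' @param params a [model_params()] object (its `T` is overridden).
#' @param T_start upper end of the scan (oscillation expected here).
#' @param T_floor lower bound of the scan.
#' @param step grid step, default 0.001.
#' @param n_seeds trajectories per grid point, default 20.
#' @param sigma initial fluctuation scale, see [random_overlap_state()].
#' @param transient,window iteration lengths, defaults 5000 and 10000.
#' @param amp_tol oscillation amplitude threshold, default `1e-3`.
#' @param patience consecutive silent grid points before stopping.
#' @return list with `onset` (smallest oscillating `T`, `NA` if none),
#'   `scan` (data frame of `T`, `hit`, `amplitude`, `MED`).
#' @export
oscillation_onset <- function(spec, params, T_start, T_floor, step = 0.001,
                              n_seeds = 20L, sigma = 0.015,
                              transient = 5000L, window = 10000L,
                              amp_tol = 1e-3, patience = 3L) {
  T_grid <- seq(T_start, T_floor, by = -abs(step))
  hits <- logical(0); amps <- numeric(0); meds <- numeric(0)
  silent <- 0L
  for (T in T_grid) {
    p <- with_T(params, T)
    hit <- FALSE; best_amp <- 0; best_med <- NA_real_
    for (k in seq_len(n_seeds)) {
      st <- random_overlap_state(spec, p, sigma)
      warm <- macro_mf_simulate(st, spec, p, transient, record = FALSE)
      sw <- oscillation_range(spec, p, T, warm$final, transient = 0L,
                              window = window, amp_tol = amp_tol)
      if (sw$amplitude > best_amp) { best_amp <- sw$amplitude
                                     best_med <- sw$MED }
      if (sw$amplitude > amp_tol) { hit <- TRUE; break }
    }
    hits <- c(hits, hit); amps <- c(amps, best_amp); meds <- c(meds, best_med)
    silent <- if (hit) 0L else silent + 1L
    if (silent >= patience) break
  }
  scanned <- T_grid[seq_along(hits)]
  list(onset = if (any(hits)) min(scanned[hits]) else NA_real_,
       scan = data.frame(T = scanned, hit = hits, amplitude = amps,
                         MED = meds))
}

#' Brute-force phase diagram over two parameter axes
#'
#' At each grid cell, enumerates the fixed points from the standard seed
#' family, records which state classes are present and stable, and runs a
#' short brute-force attractor search for oscillatory states binned by
#' mean effective dimension. Cells where a stability flag flips relative
#' to the neighbouring cell mark the bifurcation boundaries.
#'
#' @param params_base a [model_params()] object; cells override two fields.
#' @param axis1,axis2 lists `list(name = , values = )` with `name` in
#'   `"T"`, `"tau_R"`, `"tau_F"`, `"U_se"`, `"b"`.
#' @param transient,window iteration lengths for the oscillation search.
#' @param amp_tol oscillation amplitude threshold.
#' @return data frame in long format: one row per cell with the axis
#'   values, logical columns `MEM`, `SMIX`, `AMIX`, `PARA` (a stable fixed
#'   point of that class exists) and `OS1`, `OS2`, `OS3` (an oscillatory
#'   attractor of that class was found), plus `boundary` marking cells
#'   where any flag differs from the previous cell along `axis1`.
#' @export
phase_diagram <- function(params_base, axis1, axis2, transient = 2000L,
                          window = 4000L, amp_tol = 1e-3) {
  ax_ok <- c("T", "tau_R", "tau_F", "U_se", "b")
  stopifnot(axis1$name %in% ax_ok, axis2$name %in% ax_ok)
  rows <- list()
  flags <- c("MEM", "SMIX", "AMIX", "PARA", "OS1", "OS2", "OS3")
  for (v2 in axis2$values) {
    prev <- NULL
    for (v1 in axis1$values) {
      pl <- unclass(params_base)
      pl[[axis1$name]] <- v1
      pl[[axis2$name]] <- v2
      params <- do.call(model_params, pl[c("T", "tau_R", "tau_F", "U_se",
                                           "b", "p", "N")])
      spec <- mf_spec(b = params$b, p = params$p)
      fps <- enumerate_fixed_points(spec, params, tol = 1e-10)
      cell <- stats::setNames(rep(FALSE, length(flags)), flags)
      for (fp in fps)
        if (fp$stable && fp$label$kind %in% names(cell))
          cell[fp$label$kind] <- TRUE
      att <- find_attractor(spec, params, transient = transient,
                            window = window, amp_tol = amp_tol)
      if (!is.null(att) && att$oscillating) {
        run <- macro_mf_simulate(att$state, spec, params,
                                 min(window, 4000L))
        lab <- tryCatch(classify_oscillation(run$M, amp_tol = amp_tol),
                        error = function(e) NULL)
        if (!is.null(lab)) cell[lab$kind] <- TRUE
      }
      boundary <- !is.null(prev) && any(cell != prev)
      row <- data.frame(v1 = v1, v2 = v2, t(cell), boundary = boundary)
      names(row)[1:2] <- c(axis1$name, axis2$name)
      rows[[length(rows) + 1L]] <- row
      prev <- cell
    }
  }
  do.call(rbind, rows)
}
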