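#' Generate correlated memory patterns
#'
#' Draws a parent pattern with i.i.d. uniform +/-1 entries and `p` child
#' patterns correlated with it: each child entry equals the parent entry
#' with probability `(1 + b)/2` and its negation otherwise. The children
#' are the stored memories; the expected direction cosine between a child
#' and the parent is `b`, and between two children `b^2`.
#'
#' @param N number of neurons.
#' @param p number of child patterns.
#' @param b correlation level in \[0, 1\].
#' @param seed integer RNG seed; pattern generation uses its own RNG stream
#'   so that a pattern set is reproducible independently of any simulation
#'   run alongside it.
#' @return an object of class `"memory_patterns"`: a list with `N`, `p`,
#'   `b`, `seed`, `parent` (length-`N` vector over `{-1, 1}`) and
#'   `children` (`N x p` matrix over `{-1, 1}`).
#' @export
#' @examples
#' pats <- generate_patterns(N = 1000, p = 3, b = 0.2, seed = 1)
#' mean(pats$parent * pats$children[, 1])  # close to b
generate_patterns <- function(N, p = 3L, b = 0.2, seed = 1L) {
  N <- as.integer(N); p <- as.integer(p)
  if (N < 1L) stop("'N' must be >= 1")
  if (p < 1L) stop("'p' must be >= 1")
  if (!is.numeric(b) || length(b) != 1L || b < 0 || b > 1)
    stop("'b' must be a single value in [0, 1]")
  with_seed(seed, {
    parent <- sample(c(-1L, 1L), N, replace = TRUE)
    flip <- matrix(stats::runif(N * p) < (1 + b) / 2, N, p)
    children <- matrix(parent, N, p) * ifelse(flip, 1L, -1L)
  })
  storage.mode(children) <- "integer"
  structure(list(N = N, p = p, b = b, seed = seed,
                 parent = parent, children = children),
            class = "memory_patterns")
}

#' @export
print.memory_patterns <- function(x, ...) {
  cat(sprintf("Correlated memory patterns: N = %d, p = %d, b = %g, seed = %d\n",
              x$N, x$p, x$b, x$seed))
  cos0 <- colMeans(x$parent * x$children)
  cat("  empirical parent-child cosines:",
      paste(sprintf("%.3f", cos0), collapse = ", "), "\n")
  invisible(x)
}

#' Sublattice labels in canonical order
#'
#' The `2^p` pattern vectors `eta` in `{-1, 1}^p`, ordered with
#' `(1, ..., 1)` first and the sign flipped fastest in the last component,
#' i.e. for p = 3: (1,1,1), (1,1,-1), (1,-1,1), (1,-1,-1), (-1,1,1),
#' (-1,1,-1), (-1,-1,1), (-1,-1,-1). All state vectors, Jacobians and
#' branches in the package use this fixed order.
#'
#' @param p number of patterns.
#' @return a `2^p x p` integer matrix, one label per row.
#' @export
sublattice_labels <- function(p = 3L) {
  p <- as.integer(p)
  # expand.grid varies the first factor fastest; reverse the columns so the
  # LAST component flips fastest and (1,...,1) comes first
  m <- as.matrix(expand.grid(rep(list(c(1L, -1L)), p)))
  eta <- m[, p:1, drop = FALSE]
  dimnames(eta) <- list(apply(eta, 1L, function(r) paste(r, collapse = ",")),
                        paste0("mu", seq_len(p)))
  eta
}

#' Partition neurons into sublattices
#'
#' A sublattice is the set of neurons sharing the same p-tuple of pattern
#' bits `(xi_i^1, ..., xi_i^p)`. The partition is the basis of the exact
#' mean-field reduction of the Hebbian network.
#'
#' @param patterns a [generate_patterns()] object.
#' @return an object of class `"sublattice_spec"`: list with `p`, `eta`
#'   (label matrix from [sublattice_labels()]), `membership` (length-`N`
#'   integer vector of row indices into `eta`), and `sizes` (relative sizes
#'   `p_eta`, summing to 1).
#' @export
build_sublattices <- function(patterns) {
  stopifnot(inherits(patterns, "memory_patterns"))
  p <- patterns$p
  eta <- sublattice_labels(p)
  # encode each row of children as an index into eta's row order:
  # component mu contributes bit (1 - xi^mu)/2 with the last mu fastest
  bits <- (1L - patterns$children) %/% 2L
  idx <- as.vector(bits %*% 2L^((p - 1L):0L)) + 1L
  sizes <- tabulate(idx, nbins = 2L^p) / patterns$N
  names(sizes) <- rownames(eta)
  structure(list(p = p, eta = eta, membership = idx, sizes = sizes,
                 N = patterns$N),
            class = "sublattice_spec")
}

#' @export
print.sublattice_spec <- function(x, ...) {
  cat(sprintf("Sublattice partition: p = %d, %d sublattices\n", x$p, 2L^x$p))
  print(round(x$sizes, 4))
  invisible(x)
}

#' Ideal sublattice sizes for three correlated patterns
#'
#' Closed-form relative sizes of the eight sublattices in the infinite-N
#' limit of the parent/child pattern scheme: `(1 + 3 b^2)/8` for
#' `eta = +/-(1,1,1)` and `(1 - b^2)/8` for the other six labels.
#' Available only for `p = 3`; for other `p` use empirical counts from
#' [build_sublattices()].
#'
#' @param b correlation level in \[0, 1\].
#' @param p number of patterns; must be 3.
#' @return named length-8 vector of relative sizes in canonical label order.
#' @export
#' @examples
#' expected_sublattice_sizes(0.2)  # 0.14 for +/-(1,1,1), 0.12 otherwise
expected_sublattice_sizes <- function(b, p = 3L) {
  if (as.integer(p) != 3L)
    stop("closed-form sublattice sizes are available only for p = 3")
  if (b < 0 || b > 1) stop("'b' must be in [0, 1]")
  eta <- sublattice_labels(3L)
  uniform <- abs(rowSums(eta)) == 3L
  sizes <- ifelse(uniform, (1 + 3 * b^2) / 8, (1 - b^2) / 8)
  names(sizes) <- rownames(eta)
  sizes
}

#' Mean-field sublattice specification
#'
#' Builds the sublattice geometry used by the macroscopic map: the label
#' matrix `eta`, the relative sizes `p_eta`, and the inner-product matrix
#' `D[eta, eta'] = eta . eta'`. Sizes are either the ideal infinite-N
#' values (default, `p = 3` only) or empirical counts from a concrete
#' pattern draw.
#'
#' @param b correlation level (used for ideal sizes).
#' @param p number of patterns.
#' @param sizes `"ideal"` or `"empirical"`.
#' @param patterns a [generate_patterns()] object, required when
#'   `sizes = "empirical"`.
#' @return an object of class `"mf_spec"`: list with `p`, `eta`, `sizes`,
#'   `D`.
#' @export
mf_spec <- function(b = 0.2, p = 3L, sizes = c("ideal", "empirical"),
                    patterns = NULL) {
  sizes <- match.arg(sizes)
  p <- as.integer(p)
  if (sizes == "ideal") {
    sz <- expected_sublattice_sizes(b, p)
    eta <- sublattice_labels(p)
  } else {
    if (is.null(patterns)) stop("empirical sizes require 'patterns'")
    sl <- build_sublattices(patterns)
    sz <- sl$sizes
    eta <- sl$eta
    p <- sl$p
  }
  structure(list(p = p, eta = eta, sizes = sz, D = eta %*% t(eta)),
            class = "mf_spec")
}

#' Recurrent field through the Hebbian couplings
#'
#' Computes `h_i = sum_{j != i} J_ij * sig_j` for the rank-p Hebbian
#' coupling `J_ij = (1/N) sum_mu xi_i^mu xi_j^mu` with no self-coupling
#' (`J_ii = 0`). The field is evaluated in O(Np) through the pattern
#' overlaps, `h = (1/N) Xi (Xi' sig) - (p/N) sig`; the dense `N x N`
#' coupling matrix is never formed.
#'
#' @param patterns a [generate_patterns()] object.
#' @param effective_signal length-`N` numeric vector; in the network
#'   dynamics this is `2 s_j x_j u_j / U_se - 1`.
#' @return length-`N` numeric field vector.
#' @export
synaptic_field <- function(patterns, effective_signal) {
  stopifnot(inherits(patterns, "memory_patterns"))
  if (length(effective_signal) != patterns$N)
    stop("'effective_signal' must have length N = ", patterns$N)
  Xi <- patterns$children
  ov <- crossprod(Xi, effective_signal)        # p x 1 pattern overlaps
  drop(Xi %*% ov - patterns$p * effective_signal) / patterns$N
}

#' Write / read a pattern set as CSV
#'
#' One row per neuron with columns `parent, child_1..child_p` over
#' `{-1, 1}`, for fixture reuse across runs.
#'
#' @param patterns a [generate_patterns()] object.
#' @param path file path.
#' @return `write_patterns_csv` returns `path` invisibly;
#'   `read_patterns_csv` returns a `"memory_patterns"` object (with
#'   `b`/`seed` taken from the header comment when present, else `NA`).
#' @export
write_patterns_csv <- function(patterns, path) {
  stopifnot(inherits(patterns, "memory_patterns"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# memory patterns: N=%d p=%d b=%g seed=%d",
                     patterns$N, patterns$p, patterns$b, patterns$seed), con)
  df <- data.frame(parent = patterns$parent, patterns$children)
  names(df) <- c("parent", paste0("child_", seq_len(patterns$p)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns_csv
#' @export
read_patterns_csv <- function(path) {
  header <- readLines(path, n = 1L)
  b <- NA_real_; seed <- NA_integer_
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("b=([0-9.eE+-]+) seed=([0-9-]+)", header))[[1]]
    if (length(m) == 3L) { b <- as.numeric(m[2]); seed <- as.integer(m[3]) }
  }
  df <- utils::read.csv(path, comment.char = "#")
  children <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(children) <- "integer"
  if (!all(children %in% c(-1L, 1L)) || !all(df$parent %in% c(-1L, 1L)))
    stop("pattern entries must be -1 or +1")
  structure(list(N = nrow(df), p = ncol(children), b = b, seed = seed,
                 parent = as.integer(df$parent), children = unname(children)),
            class = "memory_patterns")
}
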