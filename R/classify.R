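#' Effective dimension of a three-pattern overlap vector
#'
#' Counts how many of the three overlaps are distinguishable at tolerance
#' `epsilon`: 1 if all pairwise absolute differences are below `epsilon`,
#' 3 if all are above, 2 otherwise. Defined for `p = 3` only.
#'
#' @param M length-3 overlap vector.
#' @param epsilon tolerance, default `1e-5`.
#' @return integer 1, 2 or 3.
#' @export
#' @examples
#' effective_dimension(c(0.5, 0.5, 0.5))  # 1
#' effective_dimension(c(0.5, 0.5, 0.1))  # 2
#' effective_dimension(c(0.3, 0.2, 0.1))  # 3
effective_dimension <- function(M, epsilon = 1e-5) {
  if (length(M) != 3L)
    stop("effective dimension is defined only for p = 3")
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  d <- abs(c(M[1] - M[2], M[2] - M[3], M[3] - M[1]))
  if (all(d < epsilon)) 1L else if (all(d > epsilon)) 3L else 2L
}

#' Mean effective dimension of an overlap trace
#'
#' Average of the per-step effective dimension over the last `window` rows
#' of an overlap trace.
#'
#' @param M an `(n x 3)` overlap matrix, or a list with an `M` component
#'   (as returned by [simulate_network()] / [macro_mf_simulate()]).
#' @param epsilon tolerance, default `1e-5`.
#' @param window number of trailing steps to average over; default all.
#' @return MED in \[1, 3\].
#' @export
mean_effective_dimension <- function(M, epsilon = 1e-5, window = NULL) {
  if (is.list(M)) M <- M$M
  n <- nrow(M)
  if (is.null(window)) window <- n
  if (window < 1L || window > n) stop("'window' must be in [1, nrow]")
  rows <- (n - window + 1L):n
  d12 <- abs(M[rows, 1] - M[rows, 2])
  d23 <- abs(M[rows, 2] - M[rows, 3])
  d31 <- abs(M[rows, 3] - M[rows, 1])
  ed <- ifelse(d12 < epsilon & d23 < epsilon & d31 < epsilon, 1L,
               ifelse(d12 > epsilon & d23 > epsilon & d31 > epsilon, 3L, 2L))
  mean(ed)
}

new_state_label <- function(kind, detail = NA_character_, med = NA_real_) {
  structure(list(kind = kind, detail = detail, MED = med),
            class = "state_label")
}

#' @export
print.state_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.state_label <- function(x, ...) {
  if (is.na(x$detail) || !nzchar(x$detail)) x$kind else x$detail
}

#' Classify a fixed point from its overlaps
#'
#' Assigns the retrieval class of a steady state from its length-3 overlap
#' vector `(M1, M2, M3)`:
#' \describe{
#'   \item{PARA}{all overlaps zero — no pattern retrieved.}
#'   \item{MEM}{two overlaps equal, all of one sign, the distinct one of
#'     strictly larger magnitude: single-pattern retrieval, e.g.
#'     `(M, M*, M*)` with `M > M* > 0`.}
#'   \item{SMIX}{all three equal and nonzero: symmetric mixture
#'     `sgn(xi^1 + xi^2 + xi^3)` or its inverse.}
#'   \item{AMIX}{two equal, the distinct one of opposite sign and smaller
#'     magnitude: asymmetric mixture, e.g. `(-M'', M', M')` with
#'     `M' > M'' > 0`.}
#' }
#' Anything else (including exact magnitude ties between the MEM and AMIX
#' forms) is labelled UNCLASSIFIED rather than guessed.
#'
#' @param M length-3 overlap vector.
#' @param tol_zero magnitude below which an overlap counts as zero.
#' @param tol_equal tolerance for overlap equality.
#' @return a `"state_label"`: list with `kind`, `detail` (short code such
#'   as `"MEM+1"`, `"AMIX-3"`, `"SMIX+"`, `"PARA"`), `MED` (NA for fixed
#'   points).
#' @export
#' @examples
#' classify_fixed_point(c(0, 0, 0))        # PARA
#' classify_fixed_point(c(0.9, 0.3, 0.3))  # MEM+1
#' classify_fixed_point(c(-0.2, 0.6, 0.6)) # AMIX+1
classify_fixed_point <- function(M, tol_zero = 1e-6, tol_equal = 1e-6) {
  if (length(M) != 3L) stop("fixed-point classification requires p = 3")
  if (max(abs(M)) < tol_zero)
    return(new_state_label("PARA", "PARA"))
  eq <- c(abs(M[1] - M[2]) < tol_equal,
          abs(M[2] - M[3]) < tol_equal,
          abs(M[3] - M[1]) < tol_equal)
  if (all(eq)) {
    sgn <- if (mean(M) > 0) "+" else "-"
    return(new_state_label("SMIX", paste0("SMIX", sgn)))
  }
  if (sum(eq) == 1L) {
    # index of the distinct overlap: pair (1,2) equal -> 3, etc.
    k <- c(3L, 1L, 2L)[which(eq)]
    pairval <- mean(M[-k])
    if (abs(M[k]) < tol_zero || abs(pairval) < tol_zero)
      return(new_state_label("UNCLASSIFIED"))
    same_sign <- sign(M[k]) == sign(pairval)
    if (same_sign && abs(M[k]) > abs(pairval) + tol_equal) {
      sgn <- if (M[k] > 0) "+" else "-"
      return(new_state_label("MEM", paste0("MEM", sgn, k)))
    }
    if (!same_sign && abs(M[k]) < abs(pairval) - tol_equal) {
      # AMIX+k retrieves sgn(-xi^k + xi^nu + xi^rho); its inverse is AMIX-k
      sgn <- if (pairval > 0) "+" else "-"
      return(new_state_label("AMIX", paste0("AMIX", sgn, k)))
    }
  }
  new_state_label("UNCLASSIFIED")
}

#' Classify an oscillatory overlap trace
#'
#' Bins a post-transient oscillatory trajectory of the macroscopic map by
#' its mean effective dimension: OS1 (`MED = 1`, in-phase mixture
#' oscillation), OS2 (`1 < MED <= 2`, one pattern oscillating against its
#' inverse), OS3 (`2 < MED <= 3`, circulation among the three patterns).
#' Non-oscillatory traces (peak-to-peak amplitude below `amp_tol`) are
#' rejected; classify those with [classify_fixed_point()].
#'
#' @param M `(n x 3)` overlap matrix or list with an `M` component.
#' @param epsilon effective-dimension tolerance, default `1e-5`.
#' @param window trailing steps to use; default all.
#' @param amp_tol minimum peak-to-peak amplitude to count as oscillation.
#' @return a `"state_label"` with `kind` in OS1/OS2/OS3, `detail` (dominant
#'   pattern for OS2, circulation order for OS3 when detectable) and `MED`.
#' @export
classify_oscillation <- function(M, epsilon = 1e-5, window = NULL,
                                 amp_tol = 1e-3) {
  if (is.list(M)) M <- M$M
  n <- nrow(M)
  if (is.null(window)) window <- n
  rows <- (n - window + 1L):n
  Mw <- M[rows, , drop = FALSE]
  amp <- apply(Mw, 2L, function(col) diff(range(col)))
  if (max(amp) < amp_tol)
    stop("trace is not oscillatory (amplitude ", signif(max(amp), 3),
         " < ", amp_tol, "); use classify_fixed_point()")
  med <- mean_effective_dimension(Mw, epsilon)
  if (med <= 1 + 1e-9) {
    new_state_label("OS1", "OS1", med)
  } else if (med <= 2) {
    new_state_label("OS2", paste0("OS2:", which.max(amp)), med)
  } else {
    ord <- circulation_order(Mw)
    new_state_label("OS3", if (is.na(ord)) "OS3" else paste0("OS3:", ord), med)
  }
}

# order in which the three patterns take over the largest |overlap|;
# NA when no circulation is detectable over the window
circulation_order <- function(Mw) {
  dom <- max.col(abs(Mw), ties.method = "first")
  runs <- rle(dom)$values
  if (length(runs) < 4L) return(NA_character_)
  trip <- unique(vapply(seq_len(length(runs) - 2L), function(i)
    paste(runs[i:(i + 2L)], collapse = ">"), character(1)))
  full <- trip[vapply(strsplit(trip, ">"), function(v)
    length(unique(v)) == 3L, logical(1))]
  if (length(full)) full[1L] else NA_character_
}
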