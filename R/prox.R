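#' Elementwise soft-thresholding
#'
#' The proximal operator of the weighted \eqn{\ell_1} norm:
#' \eqn{S(v, \tau)_j = \mathrm{sign}(v_j)\max(|v_j| - \tau_j, 0)}.
#'
#' @param v Numeric vector.
#' @param tau Non-negative threshold(s); scalar or a vector of `length(v)`.
#' @return Numeric vector of the same length as `v`.
#' @examples
#' soft_threshold(c(3, -0.5, -2.5), 1)  # 2, 0, -1.5
#' @export
soft_threshold <- function(v, tau) {
  if (any(tau < 0))
    sgp_stop("soft-threshold requires non-negative tau", "sgp_range_error")
  sign(v) * pmax(abs(v) - tau, 0)
}

#' Group (block) shrinkage
#'
#' The proximal operator of \eqn{\tau \|\cdot\|_2}: returns the zero vector
#' when \eqn{\|v\|_2 \le \tau}, otherwise \eqn{(1 - \tau/\|v\|_2) v}.  This
#' is the operator that zeroes whole groups in the group lasso.
#'
#' @param v Numeric vector (one group block).
#' @param tau Non-negative scalar threshold.
#' @return Numeric vector of the same length as `v`.
#' @examples
#' group_shrink(c(3, 4), 2)  # (1.8, 2.4)
#' @export
group_shrink <- function(v, tau) {
  if (length(tau) != 1L || tau < 0)
    sgp_stop("group_shrink requires a single non-negative tau",
             "sgp_range_error")
  nv <- sqrt(sum(v * v))
  if (nv <= tau) return(rep(0, length(v)))
  (1 - tau / nv) * v
}

#' Proximal operator of the sparse-group penalty
#'
#' Applies, independently per group, soft-thresholding at the per-feature
#' \eqn{\ell_1} thresholds followed by group shrinkage at the per-group
#' threshold.  For the sum of an \eqn{\ell_1} and a group-\eqn{\ell_2}
#' penalty on the same block this composition is the exact proximal map, so
#' the output minimizes
#' \deqn{\tfrac12\|x - v\|_2^2 + \sum_j \tau_j |x_j|
#'   + \sum_l \tau^G_l \|x^{(l)}\|_2.}
#' In the solver the thresholds are \eqn{\tau_j = t\,\alpha\lambda\omega^F_j}
#' and \eqn{\tau^G_l = t\,(1-\alpha)\lambda\omega^G_l} for step size \eqn{t};
#' the unpenalized block `b` is never passed through this map.
#'
#' @param v Numeric vector of length `p`.
#' @param l1 Non-negative per-feature thresholds (scalar or length `p`).
#' @param group_tau Non-negative per-group thresholds (scalar or length `L`).
#' @param groups Group label vector of length `p`.
#' @return Numeric vector of length `p` with exact zeros where thresholded.
#' @examples
#' sparse_group_prox(c(3, 4), l1 = 1, group_tau = 1, groups = c(1, 1))
#' @export
sparse_group_prox <- function(v, l1, group_tau, groups) {
  glab <- as.character(groups)
  labels <- unique(glab)
  gidx <- match(glab, labels)
  if (any(group_tau < 0))
    sgp_stop("group thresholds must be non-negative", "sgp_range_error")
  if (length(group_tau) == 1L) group_tau <- rep(group_tau, length(labels))
  if (length(group_tau) != length(labels))
    sgp_stop("group_tau must be scalar or one value per group",
             "sgp_dimension_error")
  .sg_prox(v, l1, group_tau, gidx, length(labels))
}

## Fast path used inside the solver: gidx contiguous 1..L, all checks done.
.sg_prox <- function(v, l1, group_tau, gidx, L) {
  if (any(l1 < 0))
    sgp_stop("l1 thresholds must be non-negative", "sgp_range_error")
  w <- sign(v) * pmax(abs(v) - l1, 0)
  nr <- sqrt(drop(rowsum(w * w, gidx, reorder = TRUE)))
  scale <- numeric(L)
  over <- nr > group_tau
  scale[over] <- 1 - group_tau[over] / nr[over]
  w * scale[gidx]
}
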