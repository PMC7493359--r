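#' Least-squares fit of the unpenalized block
#'
#' At the top of the regularization path the penalized block is entirely
#' zero, so the optimal unpenalized coefficients are the least-squares fit of
#' `y` on `X` alone.  The minimum-norm solution is returned when `X` is rank
#' deficient, which makes the path start reproducible.  With `q = 0` the
#' baseline residual is simply `y`.
#'
#' @param problem An [sgp_problem()].
#' @return List with `b0` (length `q`) and the residual `r0 = y - X b0`
#'   (length `n`), orthogonal to the column space of `X`.
#' @export
unpenalized_baseline <- function(problem) {
  if (problem$q == 0L)
    return(list(b0 = numeric(0), r0 = problem$y))
  sv <- svd(problem$X)
  tol <- max(dim(problem$X)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  b0 <- if (!any(pos)) rep(0, problem$q) else
    drop(sv$v[, pos, drop = FALSE] %*%
           (crossprod(sv$u[, pos, drop = FALSE], problem$y) / sv$d[pos]))
  list(b0 = b0, r0 = problem$y - drop(problem$X %*% b0))
}

#' Smallest penalty with an all-zero penalized block
#'
#' Computes the smallest \eqn{\lambda} at which \eqn{(b_0, u = 0)}, with
#' \eqn{b_0} the unpenalized baseline fit, satisfies the optimality
#' conditions of the weighted sparse-group objective — the top of the
#' regularization path.  Writing \eqn{g^{(l)} = Z^{(l)\top} r_0 / n}:
#' \itemize{
#'   \item \eqn{\alpha = 1}: \eqn{\lambda_{max} = \max_j |g_j| / \omega^F_j};
#'   \item \eqn{\alpha = 0}: \eqn{\lambda_{max} = \max_l \|g^{(l)}\|_2 /
#'     \omega^G_l};
#'   \item \eqn{0 < \alpha < 1}: per group the critical \eqn{\lambda_l}
#'     solves \eqn{\|S(g^{(l)}, \alpha\lambda\omega^F)\|_2 =
#'     (1-\alpha)\lambda\omega^G_l} (strictly monotone; solved by bisection
#'     to relative tolerance 1e-10) and \eqn{\lambda_{max} = \max_l \lambda_l}.
#' }
#'
#' @param problem An [sgp_problem()].
#' @param alpha Mixing parameter in `[0, 1]`.
#' @return Positive scalar \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(problem, alpha = 0.95) {
  check_alpha(alpha)
  base <- unpenalized_baseline(problem)
  g <- drop(crossprod(problem$Z, base$r0)) / problem$n
  if (max(abs(g)) == 0)
    sgp_stop(paste("degenerate problem: Z' r0 is identically zero",
                   "(y lies in the column space of X)"),
             "sgp_degenerate_error")
  fw <- problem$feature_weights
  gw <- problem$group_weights
  gidx <- problem$group_index
  L <- length(problem$group_sizes)
  if (alpha == 1) return(max(abs(g) / fw))
  if (alpha == 0) return(max(.group_norms(g, gidx, L) / gw))

  lam <- 0
  for (l in seq_len(L)) {
    j <- which(gidx == l)
    gl <- g[j]
    if (max(abs(gl)) == 0) next
    wl <- fw[j]
    h <- function(lambda) {
      s <- pmax(abs(gl) - alpha * lambda * wl, 0)
      sqrt(sum(s * s)) - (1 - alpha) * lambda * gw[l]
    }
    lo <- 0
    hi <- max(abs(gl) / (alpha * wl))   # soft-threshold vanishes here
    for (it in 1:200) {
      mid <- 0.5 * (lo + hi)
      if (h(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-10 * hi) break
    }
    if (hi > lam) lam <- hi             # upper bracket: never below the root
  }
  lam
}

#' Logarithmic grid of penalty parameters
#'
#' Builds the decreasing sequence
#' \eqn{\lambda_k = \lambda_{max}\,\xi^{k/(K-1)}}, \eqn{k = 0, \dots, K-1},
#' log-equispaced from \eqn{\lambda_{max}} down to
#' \eqn{\lambda_{min} = \xi\,\lambda_{max}}.
#'
#' @param lambda_max Positive scalar, the top of the path.
#' @param xi Ratio \eqn{\lambda_{min}/\lambda_{max}} in `(0, 1]`.
#' @param nlambda Grid length `K >= 1`; `K = 1` returns `lambda_max` alone.
#' @return Numeric vector of length `nlambda`, strictly decreasing for
#'   `xi < 1`.
#' @examples
#' lambda_grid(1, xi = 0.01, nlambda = 3)  # 1, 0.1, 0.01
#' @export
lambda_grid <- function(lambda_max, xi = 0.001, nlambda = 50L) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      !is.finite(lambda_max) || lambda_max <= 0)
    sgp_stop("lambda_max must be a single positive value", "sgp_range_error")
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0 || xi > 1)
    sgp_stop("xi must lie in (0, 1]", "sgp_range_error")
  K <- as.integer(nlambda)
  if (is.na(K) || K < 1L)
    sgp_stop("nlambda must be a positive integer", "sgp_range_error")
  if (K == 1L) return(lambda_max)
  lambda_max * xi^((seq_len(K) - 1) / (K - 1))
}
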