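#' @keywords internal
"_PACKAGE"

## Classed error helper: every user-facing failure carries a named condition
## class (sgp_dimension_error, sgp_weight_error, ...) under the umbrella
## class "sgp_error", so callers and the CLI can dispatch on failure kind.
sgp_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "sgp_error")))
}

#' Assemble and validate a penalized regression problem
#'
#' Bundles the response, an optional unpenalized design block, the penalized
#' design block, the group structure of the penalized features and positive
#' per-feature weights into a validated problem object used by all fitting
#' routines.  The model is
#' \deqn{y = X b + Z u + e,}
#' where \eqn{b} (length \eqn{q}) is never penalized and \eqn{u} (length
#' \eqn{p}) is penalized by a convex combination of a weighted lasso and a
#' weighted group lasso penalty (see [sgp_objective()]).
#'
#' Group labels may be arbitrary (character, factor or integer); internally
#' they are mapped to contiguous indices in order of first appearance, which
#' fixes the group ordering in all outputs.  Original labels are retained.
#' Per-group weights are derived from the feature weights as
#' \eqn{\omega^G_l = \sqrt{p_l \, \bar\omega^F_l}} with \eqn{\bar\omega^F_l}
#' the mean feature weight in group \eqn{l}; with unit feature weights this
#' reduces to the classical \eqn{\sqrt{p_l}} factor.
#'
#' No intercept is added and no centering or scaling is performed: users
#' wanting an intercept supply a ones column in `X`, and estimates are always
#' reported on the input scale.
#'
#' @param y Numeric response vector of length `n`.
#' @param Z Numeric matrix `n x p` of penalized features (`p >= 1`).
#' @param groups Vector of length `p` assigning each column of `Z` to one of
#'   `L` non-overlapping groups.
#' @param X Optional numeric matrix `n x q` of unpenalized covariates; `NULL`
#'   (the default) means `q = 0`.
#' @param feature_weights Optional positive numeric vector of length `p`
#'   (default all ones).  See [ipf_weights()] and [maf_weights()] for
#'   common constructions.
#' @return An object of class `"sgp_problem"`: a list with components `y`,
#'   `X`, `Z`, `n`, `p`, `q`, `group_index` (contiguous integer codes),
#'   `group_labels`, `group_sizes`, `feature_weights`, `group_weights`,
#'   `feature_ids` and `unpenalized_ids`.
#' @examples
#' pr <- sgp_problem(y = rnorm(10), Z = matrix(rnorm(40), 10, 4),
#'                   groups = c("a", "a", "b", "b"))
#' pr$group_sizes
#' @export
sgp_problem <- function(y, Z, groups, X = NULL, feature_weights = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  p <- ncol(Z)
  if (p < 1L)
    sgp_stop("Z must have at least one column", "sgp_dimension_error")
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
  }
  q <- ncol(X)
  if (nrow(Z) != n)
    sgp_stop(sprintf("length(y) is %d but Z has %d rows", n, nrow(Z)),
             "sgp_dimension_error")
  if (q > 0L && nrow(X) != n)
    sgp_stop(sprintf("length(y) is %d but X has %d rows", n, nrow(X)),
             "sgp_dimension_error")
  if (length(groups) != p)
    sgp_stop(sprintf("groups has length %d but Z has %d columns",
                     length(groups), p), "sgp_dimension_error")
  if (is.null(feature_weights)) feature_weights <- rep(1, p)
  fw <- as.numeric(feature_weights)
  if (length(fw) != p)
    sgp_stop(sprintf("feature_weights has length %d but Z has %d columns",
                     length(fw), p), "sgp_dimension_error")
  if (anyNA(y) || any(!is.finite(y)) || any(!is.finite(Z)) ||
      (q > 0L && any(!is.finite(X))) || any(!is.finite(fw)))
    sgp_stop("non-finite entries in y, X, Z or feature_weights",
             "sgp_nonfinite_error")
  if (any(fw <= 0))
    sgp_stop("all feature weights must be strictly positive",
             "sgp_weight_error")

  glab <- as.character(groups)
  labels <- unique(glab)                 # first-appearance order
  gidx <- match(glab, labels)
  L <- length(labels)
  sizes <- tabulate(gidx, nbins = L)
  if (any(sizes == 0L))
    sgp_stop("empty group after relabelling", "sgp_empty_group_error")

  gw <- .group_weights(fw, gidx, L, sizes)

  fid <- colnames(Z)
  if (is.null(fid)) fid <- paste0("f", seq_len(p))
  uid <- colnames(X)
  if (q > 0L && is.null(uid)) uid <- paste0("b", seq_len(q))
  if (q == 0L) uid <- character(0)

  structure(list(
    y = y, X = X, Z = Z, n = n, p = p, q = q,
    group_index = gidx, group_labels = labels, group_sizes = sizes,
    feature_weights = fw, group_weights = gw,
    feature_ids = fid, unpenalized_ids = uid
  ), class = "sgp_problem")
}

## omega^G_l = sqrt(p_l * mean_{j in l} omega^F_j)
.group_weights <- function(fw, gidx, L, sizes) {
  means <- drop(rowsum(fw, gidx, reorder = TRUE)) / sizes
  sqrt(sizes * means)
}

#' Per-group penalty weights from feature weights
#'
#' Computes \eqn{\omega^G_l = \sqrt{p_l \, \bar\omega^F_l}}, the group-lasso
#' weight of group \eqn{l} with size \eqn{p_l} and mean feature weight
#' \eqn{\bar\omega^F_l}.  With unit feature weights this is \eqn{\sqrt{p_l}}.
#'
#' @param feature_weights Positive numeric vector, one entry per feature.
#' @param groups Group label vector of the same length.
#' @return Named numeric vector of group weights, one per group in order of
#'   first appearance.
#' @examples
#' group_weights(c(1, 2, 3), c("g1", "g1", "g1"))  # sqrt(6)
#' @export
group_weights <- function(feature_weights, groups) {
  fw <- as.numeric(feature_weights)
  if (length(fw) != length(groups))
    sgp_stop("feature_weights and groups must have equal length",
             "sgp_dimension_error")
  if (any(!is.finite(fw)) || any(fw <= 0))
    sgp_stop("all feature weights must be strictly positive and finite",
             "sgp_weight_error")
  glab <- as.character(groups)
  labels <- unique(glab)
  gidx <- match(glab, labels)
  sizes <- tabulate(gidx, nbins = length(labels))
  stats::setNames(.group_weights(fw, gidx, length(labels), sizes), labels)
}

## Euclidean norm of each group block of u; gidx must be contiguous 1..L
.group_norms <- function(u, gidx, L) {
  sqrt(drop(rowsum(u * u, gidx, reorder = TRUE)))
}

.residual <- function(problem, b, u) {
  r <- problem$y - drop(problem$Z %*% u)
  if (problem$q > 0L) r <- r - drop(problem$X %*% b)
  r
}

#' Penalized objective function
#'
#' Evaluates
#' \deqn{\frac{1}{2n}\|y - Xb - Zu\|_2^2
#'   + \alpha\lambda \sum_j \omega^F_j |u_j|
#'   + (1-\alpha)\lambda \sum_l \omega^G_l \|u^{(l)}\|_2,}
#' the sparse-group lasso objective with per-feature and per-group weights.
#' With all feature weights equal to 1 the weights reduce to the classical
#' unweighted sparse-group lasso; \eqn{\alpha = 1} gives the (weighted)
#' lasso and \eqn{\alpha = 0} the group lasso.
#'
#' @param problem An [sgp_problem()].
#' @param b Numeric vector of length `q` (ignored when `q = 0`).
#' @param u Numeric vector of length `p`.
#' @param lambda Non-negative penalty parameter.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @return The objective value (non-negative scalar).
#' @export
sgp_objective <- function(problem, b, u, lambda, alpha) {
  check_alpha(alpha)
  r <- .residual(problem, b, u)
  fit <- 0.5 * sum(r * r) / problem$n
  if (lambda == 0) return(fit)
  gn <- .group_norms(u, problem$group_index, length(problem$group_sizes))
  fit + alpha * lambda * sum(problem$feature_weights * abs(u)) +
    (1 - alpha) * lambda * sum(problem$group_weights * gn)
}

#' Gradient of the smooth (least-squares) part of the objective
#'
#' Returns the gradient of \eqn{\frac{1}{2n}\|y - Xb - Zu\|_2^2} with respect
#' to `(b, u)`, i.e. \eqn{(-X^\top r / n,\; -Z^\top r / n)} with residual
#' \eqn{r = y - Xb - Zu}.  The penalty terms are handled by the proximal
#' operator, not by this gradient.
#'
#' @inheritParams sgp_objective
#' @return List with components `b` (length `q`) and `u` (length `p`).
#' @export
sgp_gradient <- function(problem, b, u) {
  r <- .residual(problem, b, u)
  gb <- if (problem$q > 0L) -drop(crossprod(problem$X, r)) / problem$n
        else numeric(0)
  gu <- -drop(crossprod(problem$Z, r)) / problem$n
  list(b = gb, u = gu)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1)
    sgp_stop("alpha must be a single value in [0, 1]", "sgp_range_error")
  invisible(alpha)
}

#' @export
print.sgp_problem <- function(x, ...) {
  cat(sprintf(
    "sgp_problem: n = %d, q = %d unpenalized, p = %d penalized in %d groups\n",
    x$n, x$q, x$p, length(x$group_sizes)))
  cat("group sizes: ", paste(x$group_sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}
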