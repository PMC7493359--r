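#' Solver control parameters
#'
#' @param rel_acc Relative accuracy \eqn{\varepsilon_{rel}}: iteration stops
#'   once the max-norm change of the concatenated \eqn{(b, u)} iterate,
#'   scaled by the current iterate's Euclidean norm, drops to this value.
#'   Default `1e-4`.
#' @param max_iter Maximum proximal-gradient iterations per penalty value.
#' @param step0 Initial step size for the backtracking line search.
#' @param shrink Multiplicative backtracking factor in `(0, 1)`.
#' @return List of class `"sgp_control"`.
#' @export
sgp_control <- function(rel_acc = 1e-4, max_iter = 1000L,
                        step0 = 1, shrink = 0.5) {
  if (!is.numeric(rel_acc) || length(rel_acc) != 1L || rel_acc <= 0)
    sgp_stop("rel_acc must be a single positive value", "sgp_range_error")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    sgp_stop("max_iter must be a positive integer", "sgp_range_error")
  if (!is.numeric(step0) || length(step0) != 1L || step0 <= 0)
    sgp_stop("step0 must be a single positive value", "sgp_range_error")
  if (!is.numeric(shrink) || length(shrink) != 1L || shrink <= 0 ||
      shrink >= 1)
    sgp_stop("shrink must lie in (0, 1)", "sgp_range_error")
  structure(list(rel_acc = rel_acc, max_iter = max_iter,
                 step0 = step0, shrink = shrink),
            class = "sgp_control")
}

.smooth_value <- function(problem, b, u) {
  r <- .residual(problem, b, u)
  0.5 * sum(r * r) / problem$n
}

#' One proximal-gradient step with backtracking line search
#'
#' From the current iterate, takes the proximal-gradient candidate
#' \eqn{b^+ = b - t \nabla_b f}, \eqn{u^+ = \mathrm{prox}_{t}(u - t
#' \nabla_u f)} and accepts it when the quadratic majorization
#' \deqn{f(x^+) \le f(x) + \nabla f(x)^\top (x^+ - x)
#'   + \tfrac{1}{2t}\|x^+ - x\|_2^2}
#' of the smooth term \eqn{f} holds; otherwise the step is shrunk by the
#' factor `shrink` and the candidate recomputed.  Acceptance at some
#' \eqn{t > 0} is guaranteed because the majorization holds for any
#' \eqn{t \le n / \|Z\|_2^2}.
#'
#' @inheritParams sgp_objective
#' @param t Positive trial step size.
#' @param shrink Backtracking factor in `(0, 1)`.
#' @return List with components `b`, `u` (accepted candidate), `t` (accepted
#'   step) and `smooth` (smooth-term value at the candidate).
#' @export
backtracking_step <- function(problem, b, u, lambda, alpha,
                              t = 1, shrink = 0.5) {
  if (t <= 0) sgp_stop("step size must be positive", "sgp_range_error")
  gr <- sgp_gradient(problem, b, u)
  fs <- .smooth_value(problem, b, u)
  fw <- problem$feature_weights
  gw <- problem$group_weights
  gidx <- problem$group_index
  L <- length(problem$group_sizes)
  slack <- 1e-12 * max(1, abs(fs))
  repeat {
    bc <- if (problem$q > 0L) b - t * gr$b else numeric(0)
    uc <- .sg_prox(u - t * gr$u,
                   t * alpha * lambda * fw,
                   t * (1 - alpha) * lambda * gw, gidx, L)
    db <- bc - b
    du <- uc - u
    sq <- sum(db * db) + sum(du * du)
    fc <- .smooth_value(problem, bc, uc)
    bound <- fs + sum(gr$b * db) + sum(gr$u * du) + sq / (2 * t)
    if (fc <= bound + slack)
      return(list(b = bc, u = uc, t = t, smooth = fc))
    t <- t * shrink
    if (t < 1e-30)
      sgp_stop("backtracking line search failed: step size underflow",
               "sgp_linesearch_error")
  }
}

#' Solve the penalized problem at a single penalty value
#'
#' Runs proximal gradient descent with backtracking line search from the
#' supplied starting point until the relative-accuracy stopping criterion
#' \deqn{\frac{\|(b,u)^{[k]} - (b,u)^{[k-1]}\|_\infty}
#'   {\|(b,u)^{[k]}\|_2} \le \varepsilon_{rel}}
#' holds or `max_iter` is reached.  At least one iteration is always
#' performed.  If the current iterate is identically zero, the criterion is
#' declared met only when the step change is also exactly zero.
#' Non-convergence within `max_iter` is reported in the diagnostics, not as
#' an error.
#'
#' @inheritParams sgp_objective
#' @param init Optional list with starting values `b`, `u` (default: zero
#'   vectors) and optionally `t`, the initial line-search step.
#' @param control An [sgp_control()] list.
#' @return List with `b`, `u` (the solution; `u` contains exact zeros) and
#'   `diagnostics`: `iterations`, `converged`, `final_step`,
#'   `objective_trace` (non-increasing; first entry is the objective at the
#'   start) and `kkt_residual`.
#' @export
sgp_solve <- function(problem, lambda, alpha = 0.95, init = NULL,
                      control = sgp_control()) {
  check_alpha(alpha)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    sgp_stop("lambda must be a single non-negative value", "sgp_range_error")
  b <- if (is.null(init$b)) rep(0, problem$q) else as.numeric(init$b)
  u <- if (is.null(init$u)) rep(0, problem$p) else as.numeric(init$u)
  t <- if (is.null(init$t)) control$step0 else init$t
  trace <- numeric(control$max_iter + 1L)
  trace[1L] <- sgp_objective(problem, b, u, lambda, alpha)
  converged <- FALSE
  k <- 0L
  while (k < control$max_iter) {
    k <- k + 1L
    st <- backtracking_step(problem, b, u, lambda, alpha,
                            t = t, shrink = control$shrink)
    delta_inf <- max(abs(c(st$b - b, st$u - u)))
    b <- st$b
    u <- st$u
    t <- st$t
    trace[k + 1L] <- sgp_objective(problem, b, u, lambda, alpha)
    denom <- sqrt(sum(b * b) + sum(u * u))
    converged <- if (denom == 0) delta_inf == 0
                 else delta_inf / denom <= control$rel_acc
    if (converged) break
  }
  list(b = b, u = u,
       diagnostics = list(
         iterations = k,
         converged = converged,
         final_step = t,
         objective_trace = trace[seq_len(k + 1L)],
         kkt_residual = kkt_residual(problem, b, u, lambda, alpha)))
}

#' KKT optimality residual
#'
#' Independent certificate of optimality: the maximum violation of the
#' stationarity (subgradient) conditions of the weighted sparse-group
#' objective at `(b, u)`.  The gradient with respect to `b` must vanish
#' exactly; for each group of `u`, zero groups are checked against the dual
#' condition \eqn{\|S(g^{(l)}, \alpha\lambda\omega^F)\|_2 \le
#' (1-\alpha)\lambda\omega^G_l} (with \eqn{g = Z^\top r / n}), zero entries
#' inside active groups against \eqn{|g_j| \le \alpha\lambda\omega^F_j}, and
#' non-zero entries against exact stationarity.  The residual is 0 at an
#' exact solution and grows with the distance from optimality.
#'
#' @inheritParams sgp_objective
#' @return Non-negative scalar.
#' @export
kkt_residual <- function(problem, b, u, lambda, alpha) {
  check_alpha(alpha)
  r <- .residual(problem, b, u)
  res <- 0
  if (problem$q > 0L)
    res <- max(abs(crossprod(problem$X, r))) / problem$n
  g <- drop(crossprod(problem$Z, r)) / problem$n   # = -grad of smooth part
  fw <- problem$feature_weights
  gw <- problem$group_weights
  gidx <- problem$group_index
  for (l in seq_along(problem$group_sizes)) {
    j <- which(gidx == l)
    ul <- u[j]
    gl <- g[j]
    wl <- fw[j]
    if (all(ul == 0)) {
      s <- pmax(abs(gl) - alpha * lambda * wl, 0)
      viol <- sqrt(sum(s * s)) - (1 - alpha) * lambda * gw[l]
      res <- max(res, viol)
    } else {
      nl <- sqrt(sum(ul * ul))
      act <- ul != 0
      stat <- -gl[act] + alpha * lambda * wl[act] * sign(ul[act]) +
        (1 - alpha) * lambda * gw[l] * ul[act] / nl
      res <- max(res, abs(stat))
      if (any(!act)) {
        viol <- abs(gl[!act]) - alpha * lambda * wl[!act]
        res <- max(res, viol)
      }
    }
  }
  max(res, 0)
}

#' Fit the full regularization path
#'
#' Computes \eqn{\lambda_{max}} (the smallest penalty at which the penalized
#' block is entirely zero), builds the decreasing logarithmic grid
#' \eqn{\lambda_{min} = \xi \lambda_{max}} of length `nlambda`, and solves
#' the weighted sparse-group problem at every grid point by proximal
#' gradient descent.  The path is warm started: the solution at each
#' \eqn{\lambda} (and the accepted line-search step) initializes the solve
#' at the next, smaller \eqn{\lambda}; the first grid point starts from the
#' unpenalized baseline fit with `u = 0`.
#'
#' `alpha = 1` gives the (weighted) lasso, `alpha = 0` the group lasso, and
#' intermediate values the sparse-group lasso.  Per-modality penalty factors
#' ([ipf_weights()]) with `alpha = 1` give the IPF-lasso.
#'
#' @param y Response vector, or an [sgp_problem()] (in which case `Z` and
#'   `groups` are ignored).
#' @param Z Penalized design matrix `n x p`.
#' @param groups Group labels of length `p`.
#' @param X Optional unpenalized design matrix `n x q`.
#' @param feature_weights Optional positive per-feature weights.
#' @param alpha Mixing parameter in `[0, 1]`; default 0.95.
#' @param nlambda Grid length; default 50.
#' @param lambda_min_ratio Ratio \eqn{\xi = \lambda_{min}/\lambda_{max}} in
#'   `(0, 1]`; default 0.001.
#' @param standardize If `TRUE`, columns of `Z` are scaled to unit standard
#'   deviation before fitting and estimates are rescaled to the input scale
#'   afterwards; default `FALSE` (no implicit standardization, matching the
#'   objective as written).
#' @param control An [sgp_control()] list.
#' @return Object of class `"sgp_path"`: list with `lambda` (decreasing grid),
#'   `alpha`, coefficient matrices `b` (`q x K`) and `u` (`p x K`, exact
#'   zeros preserved), `lambda_max`, `diagnostics` (one row per grid point:
#'   `lambda`, `iterations`, `converged`, `final_step`, `kkt_residual`,
#'   `nonzero`, `objective`), `objective_trace` (list of per-solve traces),
#'   and the identifiers and group structure needed for output.
#' @examples
#' sim <- sgp_simulate(n = 40, n_groups = 4, group_size = 3, seed = 1)
#' fit <- sgp_fit(sim$problem, alpha = 0.95, nlambda = 10)
#' fit
#' @export
sgp_fit <- function(y, Z = NULL, groups = NULL, X = NULL,
                    feature_weights = NULL, alpha = 0.95, nlambda = 50L,
                    lambda_min_ratio = 0.001, standardize = FALSE,
                    control = sgp_control()) {
  problem <- if (inherits(y, "sgp_problem")) y
             else sgp_problem(y, Z, groups, X = X,
                              feature_weights = feature_weights)
  check_alpha(alpha)
  zscale <- NULL
  fit_problem <- problem
  if (isTRUE(standardize)) {
    zscale <- apply(problem$Z, 2L, stats::sd)
    if (any(!is.finite(zscale)) || any(zscale == 0))
      sgp_stop("cannot standardize: constant column in Z",
               "sgp_degenerate_error")
    fit_problem <- sgp_problem(problem$y,
                               sweep(problem$Z, 2L, zscale, "/"),
                               problem$group_index, X = problem$X,
                               feature_weights = problem$feature_weights)
    fit_problem$feature_ids <- problem$feature_ids
    fit_problem$group_labels <- problem$group_labels
    fit_problem$unpenalized_ids <- problem$unpenalized_ids
  }

  base <- unpenalized_baseline(fit_problem)
  lmax <- lambda_max(fit_problem, alpha)
  lam <- lambda_grid(lmax, xi = lambda_min_ratio, nlambda = nlambda)
  K <- length(lam)

  bmat <- matrix(0, fit_problem$q, K)
  umat <- matrix(0, fit_problem$p, K)
  diag_rows <- vector("list", K)
  traces <- vector("list", K)
  init <- list(b = base$b0, u = rep(0, fit_problem$p), t = control$step0)
  for (k in seq_len(K)) {
    sol <- sgp_solve(fit_problem, lam[k], alpha, init = init,
                     control = control)
    if (fit_problem$q > 0L) bmat[, k] <- sol$b
    umat[, k] <- sol$u
    d <- sol$diagnostics
    traces[[k]] <- d$objective_trace
    diag_rows[[k]] <- data.frame(
      lambda = lam[k], iterations = d$iterations, converged = d$converged,
      final_step = d$final_step, kkt_residual = d$kkt_residual,
      nonzero = sum(sol$u != 0),
      objective = d$objective_trace[length(d$objective_trace)])
    init <- list(b = sol$b, u = sol$u, t = d$final_step)  # warm start
  }
  if (!is.null(zscale)) umat <- umat / zscale

  rownames(umat) <- problem$feature_ids
  if (problem$q > 0L) rownames(bmat) <- problem$unpenalized_ids
  structure(list(
    lambda = lam, alpha = alpha, lambda_max = lmax,
    b = bmat, u = umat,
    diagnostics = do.call(rbind, diag_rows),
    objective_trace = traces,
    feature_ids = problem$feature_ids,
    unpenalized_ids = problem$unpenalized_ids,
    group_labels = problem$group_labels[problem$group_index],
    group_index = problem$group_index,
    n = problem$n, p = problem$p, q = problem$q,
    standardize = isTRUE(standardize)
  ), class = "sgp_path")
}

#' @export
print.sgp_path <- function(x, ...) {
  cat(sprintf(
    "sgp_path: alpha = %g, %d lambda values in [%g, %g]\n",
    x$alpha, length(x$lambda), min(x$lambda), max(x$lambda)))
  cat(sprintf("  n = %d, q = %d unpenalized, p = %d penalized\n",
              x$n, x$q, x$p))
  df <- x$diagnostics[, c("lambda", "iterations", "converged", "nonzero")]
  print(utils::head(df, 5L), row.names = FALSE)
  if (nrow(df) > 5L) cat(sprintf("  ... %d more rows\n", nrow(df) - 5L))
  invisible(x)
}

#' Coefficients of a fitted path
#'
#' @param object An `"sgp_path"`.
#' @param ... Unused.
#' @return Matrix `(q + p) x K` stacking the unpenalized block over the
#'   penalized block, one column per penalty value.
#' @export
coef.sgp_path <- function(object, ...) {
  rbind(object$b, object$u)
}

#' Predict from a fitted path
#'
#' @param object An `"sgp_path"`.
#' @param Z Penalized design matrix of new observations.
#' @param X Unpenalized design matrix of new observations (required when the
#'   fit used one).
#' @param index Optional grid indices; default all.
#' @param ... Unused.
#' @return Matrix `nrow(Z) x length(index)` of fitted values.
#' @export
predict.sgp_path <- function(object, Z, X = NULL, index = NULL, ...) {
  Z <- as.matrix(Z)
  if (ncol(Z) != object$p)
    sgp_stop("Z has the wrong number of columns", "sgp_dimension_error")
  if (is.null(index)) index <- seq_along(object$lambda)
  pred <- Z %*% object$u[, index, drop = FALSE]
  if (object$q > 0L) {
    if (is.null(X))
      sgp_stop("fit has unpenalized covariates: X is required",
               "sgp_dimension_error")
    X <- as.matrix(X)
    if (ncol(X) != object$q)
      sgp_stop("X has the wrong number of columns", "sgp_dimension_error")
    pred <- pred + X %*% object$b[, index, drop = FALSE]
  }
  pred
}
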