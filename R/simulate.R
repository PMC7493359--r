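#' Simulate a grouped, correlated, group-sparse regression problem
#'
#' Generates a seeded problem instance with known truth, emulating the
#' regime the sparse-group lasso targets: many correlated features in known
#' groups, effects concentrated in a few groups, and (optionally) an
#' unpenalized covariate block.  Rows of `Z` are zero-mean unit-variance
#' Gaussian with block-diagonal correlation: `rho` between features of the
#' same group, 0 across groups.  The true penalized coefficients are
#' `± effect_size` on `n_active` randomly chosen groups and exactly zero
#' elsewhere; when `q >= 1` the first column of `X` is a ones column
#' (intercept) and the true unpenalized coefficients are all 1.  Finally
#' `y = X b + Z u + e` with Gaussian noise of standard deviation `noise_sd`.
#'
#' The generator is fully determined by `seed` and restores the caller's RNG
#' state on exit.  To build a hold-out set that shares the generating truth,
#' pass the `truth` element of a previous call back in via `truth` together
#' with a different `seed`: new `Z`, `X` and noise are drawn but the
#' coefficients (and active groups) are reused.
#'
#' @param n Number of observations.
#' @param n_groups Number of groups `L`.
#' @param group_size Features per group (so `p = n_groups * group_size`).
#' @param q Number of unpenalized covariates (0 for none; the first is a
#'   ones column).
#' @param n_active Number of groups carrying true effects.
#' @param effect_size Magnitude of the true non-zero coefficients (signs are
#'   random).
#' @param rho Within-group correlation in `[0, 1)`.
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed; the instance is reproducible from it.
#' @param truth Optional truth list from a previous call (fields `b_true`,
#'   `u_true`, `active_groups`) to reuse when drawing new data.
#' @return List with `problem` (an [sgp_problem()]) and `truth` (list with
#'   `b_true`, `u_true`, `active_groups` — group labels — `noise_sd`,
#'   `seed`).
#' @examples
#' sim <- sgp_simulate(n = 50, n_groups = 5, group_size = 4, seed = 7)
#' dim(sim$problem$Z)  # 50 x 20
#' @export
sgp_simulate <- function(n = 100L, n_groups = 10L, group_size = 6L, q = 1L,
                         n_active = 2L, effect_size = 1, rho = 0.3,
                         noise_sd = 1, seed = 1L, truth = NULL) {
  n <- as.integer(n); L <- as.integer(n_groups)
  gs <- as.integer(group_size); q <- as.integer(q)
  n_active <- as.integer(n_active)
  if (any(is.na(c(n, L, gs, q, n_active))) || n < 1L || L < 1L || gs < 1L ||
      q < 0L || n_active < 0L || n_active > L)
    sgp_stop("inconsistent simulation sizes", "sgp_range_error")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    sgp_stop("rho must lie in [0, 1)", "sgp_range_error")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    sgp_stop("noise_sd must be positive", "sgp_range_error")
  p <- L * gs

  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))

  groups <- rep(paste0("g", seq_len(L)), each = gs)
  Z <- matrix(0, n, p)
  for (l in seq_len(L)) {
    shared <- stats::rnorm(n)
    idio <- matrix(stats::rnorm(n * gs), n, gs)
    Z[, ((l - 1L) * gs + 1L):(l * gs)] <-
      sqrt(rho) * shared + sqrt(1 - rho) * idio
  }
  colnames(Z) <- paste0("f", seq_len(p))

  X <- NULL
  if (q >= 1L) {
    X <- cbind(rep(1, n),
               if (q > 1L) matrix(stats::rnorm(n * (q - 1L)), n) else NULL)
    colnames(X) <- paste0("b", seq_len(q))
  }

  if (is.null(truth)) {
    active <- sort(sample.int(L, n_active))
    u_true <- numeric(p)
    for (l in active) {
      j <- ((l - 1L) * gs + 1L):(l * gs)
      u_true[j] <- effect_size * sample(c(-1, 1), gs, replace = TRUE)
    }
    b_true <- rep(1, q)
    active_labels <- paste0("g", active)
  } else {
    u_true <- truth$u_true
    b_true <- truth$b_true
    active_labels <- truth$active_groups
    if (length(u_true) != p || length(b_true) != q)
      sgp_stop("supplied truth does not match the requested dimensions",
               "sgp_dimension_error")
  }

  y <- drop(Z %*% u_true) + stats::rnorm(n, sd = noise_sd)
  if (q >= 1L) y <- y + drop(X %*% b_true)

  list(problem = sgp_problem(y, Z, groups, X = X),
       truth = list(b_true = b_true, u_true = u_true,
                    active_groups = active_labels,
                    noise_sd = noise_sd, seed = as.integer(seed)))
}

#' Evaluate a fitted path on hold-out data
#'
#' Computes the hold-out mean squared prediction error at every penalty
#' value of a fitted path, locates its minimum, and reports the squared
#' correlation between predictions and hold-out response as well as the
#' number of non-zero penalized coefficients at that optimum.  Non-zero
#' counts are exact: the proximal solver produces exact zeros, so no
#' thresholding is applied.
#'
#' @param path An [sgp_fit()] result.
#' @param holdout An [sgp_problem()] with the same feature and covariate
#'   layout as the training problem.
#' @return List of class `"sgp_eval"` with `mse` (length `K`), `best_index`
#'   (first minimum), `lambda_best`, `r_squared` and `nonzero` at the
#'   optimum.
#' @export
sgp_evaluate <- function(path, holdout) {
  if (!inherits(path, "sgp_path"))
    sgp_stop("path must be an sgp_path", "sgp_dimension_error")
  if (!inherits(holdout, "sgp_problem") || holdout$p != path$p ||
      holdout$q != path$q)
    sgp_stop("holdout problem does not match the fitted path",
             "sgp_dimension_error")
  pred <- predict(path, Z = holdout$Z,
                  X = if (holdout$q > 0L) holdout$X else NULL)
  err <- sweep(pred, 1L, holdout$y, "-")
  mse <- colMeans(err * err)
  best <- which.min(mse)               # first minimum on ties
  pb <- pred[, best]
  r2 <- if (stats::sd(pb) == 0 || stats::sd(holdout$y) == 0) 0
        else stats::cor(pb, holdout$y)^2
  structure(list(mse = mse, best_index = best,
                 lambda_best = path$lambda[best],
                 r_squared = r2,
                 nonzero = sum(path$u[, best] != 0)),
            class = "sgp_eval")
}

#' @export
print.sgp_eval <- function(x, ...) {
  cat(sprintf(
    "sgp_eval: best lambda index %d (lambda = %g)\n", x$best_index,
    x$lambda_best))
  cat(sprintf("  holdout MSE = %g, R^2 = %g, non-zero coefficients = %d\n",
              x$mse[x$best_index], x$r_squared, x$nonzero))
  invisible(x)
}
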