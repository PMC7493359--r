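## Independent oracles used across the suite.
##
## 1. Brute-force prox oracle: minimizes
##      0.5 ||x - v||^2 + sum_j tau_j |x_j| + sum_l tau_g_l ||x_(l)||
##    by exhaustive enumeration of sign patterns.  The problem separates over
##    groups; within a group, for a fixed sign pattern sigma in {-1,0,1}^p
##    the restricted minimizer is available in closed form from the
##    stationarity equation x (1 + tau_g/||x||) = v - tau*sigma.  This
##    derivation is independent of the soft-threshold/group-shrink
##    composition used by the package.

oracle_prox_group <- function(v, tau, tau_g) {
  p <- length(v)
  if (length(tau) == 1L) tau <- rep(tau, p)
  best <- rep(0, p)
  best_val <- 0.5 * sum(v^2)
  obj <- function(x) 0.5 * sum((x - v)^2) + sum(tau * abs(x)) +
    tau_g * sqrt(sum(x^2))
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (i in seq_len(nrow(patterns))) {
    sg <- patterns[i, ]
    act <- which(sg != 0)
    if (length(act) == 0L) next
    w <- v[act] - tau[act] * sg[act]
    nw <- sqrt(sum(w^2))
    r <- nw - tau_g
    if (r <= 0) next
    xa <- w * r / nw
    if (any(sign(xa) != sg[act])) next
    x <- rep(0, p)
    x[act] <- xa
    val <- obj(x)
    if (val < best_val) {
      best_val <- val
      best <- x
    }
  }
  best
}

oracle_prox <- function(v, l1, group_tau, gidx) {
  if (length(l1) == 1L) l1 <- rep(l1, length(v))
  out <- numeric(length(v))
  for (l in seq_along(group_tau)) {
    j <- which(gidx == l)
    out[j] <- oracle_prox_group(v[j], l1[j], group_tau[l])
  }
  out
}

## 2. Generic convex solver oracle: SciPy SLSQP on the smooth epigraph
##    reformulation of the full objective (shipped with the package).
##    Takes a list of problem descriptions, returns a list of results with
##    $objective, $b, $u.
py_sgl_oracle <- function(problems) {
  script <- system.file("oracle", "sgl_reference.py", package = "sgpath")
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  jsonlite::write_json(problems, infile, digits = NA, auto_unbox = TRUE,
                       null = "null")
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  stopifnot(status == 0)
  jsonlite::read_json(outfile, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

as_py_problem <- function(problem, lambda, alpha) {
  list(y = problem$y, Z = problem$Z,
       X = if (problem$q > 0L) problem$X else NULL,
       groups = problem$group_index, wf = problem$feature_weights,
       wg = problem$group_weights, lambda = lambda, alpha = alpha)
}

## Random problem instances (local RNG under a fixed seed)
rand_instance <- function(seed, n = NULL, p = NULL, L = NULL, q = NULL,
                          weighted = TRUE) {
  withr::local_seed(seed)
  if (is.null(n)) n <- sample(10:30, 1)
  if (is.null(p)) p <- sample(4:15, 1)
  if (is.null(L)) L <- sample(1:3, 1)
  if (is.null(q)) q <- sample(0:2, 1)
  groups <- sort(sample.int(L, p, replace = TRUE))
  groups <- match(groups, unique(groups))   # contiguous, every group present
  X <- if (q > 0) matrix(stats::rnorm(n * q), n) else NULL
  Z <- matrix(stats::rnorm(n * p), n)
  y <- stats::rnorm(n, sd = 2)
  fw <- if (weighted) stats::runif(p, 0.5, 2) else rep(1, p)
  sgp_problem(y, Z, groups, X = X, feature_weights = fw)
}

## Objective of a glmnet (weighted lasso) solution under the package's
## parameterization; glmnet rescales penalty factors to sum to nvars, so the
## grid is rescaled accordingly.
glmnet_objective_at <- function(problem, lambda_seq, thresh = 1e-14) {
  pf <- c(rep(0, problem$q), problem$feature_weights)
  W <- cbind(problem$X, problem$Z)
  lam_g <- lambda_seq * sum(pf) / ncol(W)
  fit <- glmnet::glmnet(W, problem$y, family = "gaussian", lambda = lam_g,
                        standardize = FALSE, intercept = FALSE,
                        penalty.factor = pf, thresh = thresh)
  cf <- as.matrix(stats::coef(fit))[-1L, , drop = FALSE]
  vapply(seq_along(lambda_seq), function(k) {
    b <- cf[seq_len(problem$q), k]
    u <- cf[problem$q + seq_len(problem$p), k]
    sgp_objective(problem, b, u, lambda_seq[k], 1)
  }, numeric(1))
}
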