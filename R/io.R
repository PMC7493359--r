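#' Read a penalized regression problem from delimited text files
#'
#' Assembles an [sgp_problem()] from plain-text inputs:
#' \itemize{
#'   \item `y_file`: one response value per line (no header);
#'   \item `Z_file`: `n x p` delimited matrix, optionally with a header row
#'     of feature identifiers (controlled by `header`);
#'   \item `groups_file`: two columns, no header: `feature_id`,
#'     `group_label`;
#'   \item `X_file` (optional): `n x q` delimited matrix of unpenalized
#'     covariates; omitted means `q = 0`;
#'   \item `weights_file` (optional): two columns, no header: `feature_id`,
#'     `weight`; omitted means all weights 1 (the unweighted objective).
#' }
#' Without a header, features are identified as `f1 ... fp` in column
#' order, and the groups/weights files must use those names.  Groups and
#' weights are matched to features by identifier, so row order in those
#' files is free.
#'
#' @param y_file,Z_file,groups_file,X_file,weights_file File paths; see
#'   Details.
#' @param delim Field delimiter (default tab).
#' @param header Whether `Z_file` (and `X_file`) carry a header row.
#' @return A validated [sgp_problem()].
#' @export
read_problem <- function(y_file, Z_file, groups_file, X_file = NULL,
                         weights_file = NULL, delim = "\t", header = TRUE) {
  for (f in c(y_file, Z_file, groups_file, X_file, weights_file))
    if (!file.exists(f))
      sgp_stop(sprintf("input file not found: %s", f), "sgp_parse_error")

  read_tab <- function(file, header) {
    tryCatch(
      utils::read.table(file, sep = delim, header = header,
                        check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "", quote = "\""),
      error = function(e)
        sgp_stop(sprintf("failed to parse %s: %s", file,
                         conditionMessage(e)), "sgp_parse_error"))
  }

  ytab <- read_tab(y_file, header = FALSE)
  if (ncol(ytab) != 1L || !is.numeric(ytab[[1L]]))
    sgp_stop("y file must contain a single numeric column",
             "sgp_parse_error")
  y <- ytab[[1L]]

  Ztab <- read_tab(Z_file, header = header)
  Z <- as.matrix(Ztab)
  if (!is.numeric(Z))
    sgp_stop("Z file contains non-numeric entries", "sgp_parse_error")
  ids <- if (header) colnames(Ztab) else paste0("f", seq_len(ncol(Z)))
  colnames(Z) <- ids
  if (anyDuplicated(ids))
    sgp_stop("duplicated feature identifiers in Z header",
             "sgp_duplicate_feature_error")

  gtab <- read_tab(groups_file, header = FALSE)
  if (ncol(gtab) != 2L)
    sgp_stop("groups file must have two columns: feature_id, group_label",
             "sgp_parse_error")
  gid <- as.character(gtab[[1L]])
  if (anyDuplicated(gid))
    sgp_stop("duplicated feature identifiers in groups file",
             "sgp_duplicate_feature_error")
  unknown <- setdiff(gid, ids)
  if (length(unknown))
    sgp_stop(sprintf("groups file references unknown features: %s",
                     paste(utils::head(unknown, 5L), collapse = ", ")),
             "sgp_unknown_feature_error")
  missing <- setdiff(ids, gid)
  if (length(missing))
    sgp_stop(sprintf("features missing from groups file: %s",
                     paste(utils::head(missing, 5L), collapse = ", ")),
             "sgp_missing_group_error")
  groups <- as.character(gtab[[2L]])[match(ids, gid)]

  X <- NULL
  if (!is.null(X_file)) {
    Xtab <- read_tab(X_file, header = header)
    X <- as.matrix(Xtab)
    if (!is.numeric(X))
      sgp_stop("X file contains non-numeric entries", "sgp_parse_error")
  }

  fw <- NULL
  if (!is.null(weights_file)) {
    wtab <- read_tab(weights_file, header = FALSE)
    if (ncol(wtab) != 2L || !is.numeric(wtab[[2L]]))
      sgp_stop("weights file must have two columns: feature_id, weight",
               "sgp_parse_error")
    wid <- as.character(wtab[[1L]])
    if (anyDuplicated(wid))
      sgp_stop("duplicated feature identifiers in weights file",
               "sgp_duplicate_feature_error")
    unknown <- setdiff(wid, ids)
    if (length(unknown))
      sgp_stop(sprintf("weights file references unknown features: %s",
                       paste(utils::head(unknown, 5L), collapse = ", ")),
               "sgp_unknown_feature_error")
    fw <- rep(1, ncol(Z))
    fw[match(wid, ids)] <- wtab[[2L]]
  }

  sgp_problem(y, Z, groups, X = X, feature_weights = fw)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a fitted path to delimited text files
#'
#' Emits two files with deterministic row order (decreasing penalty, then
#' input feature order) and floats at 17 significant digits so that values
#' round-trip exactly through text:
#' \itemize{
#'   \item `coef_file`: long-format table with columns `lambda_index`,
#'     `lambda`, `coefficient_id`, `group_label` (empty for the unpenalized
#'     block) and `estimate`; per penalty value the unpenalized coefficients
#'     come first, then all penalized features;
#'   \item `diag_file`: one row per penalty value with columns `lambda`,
#'     `iterations`, `converged`, `kkt_residual` and `nonzero_count`.
#' }
#'
#' @param path An [sgp_fit()] result.
#' @param coef_file,diag_file Output paths.
#' @param delim Field delimiter (default tab).
#' @return Invisibly, the two file paths.
#' @export
write_path <- function(path, coef_file, diag_file, delim = "\t") {
  if (!inherits(path, "sgp_path"))
    sgp_stop("path must be an sgp_path", "sgp_dimension_error")
  K <- length(path$lambda)
  ids <- c(path$unpenalized_ids, path$feature_ids)
  glab <- c(rep("", path$q), path$group_labels)
  est <- coef(path)
  coef_df <- data.frame(
    lambda_index = rep(seq_len(K), each = length(ids)),
    lambda = fmt17(rep(path$lambda, each = length(ids))),
    coefficient_id = rep(ids, K),
    group_label = rep(glab, K),
    estimate = fmt17(as.vector(est)),
    stringsAsFactors = FALSE)
  diag_df <- data.frame(
    lambda = fmt17(path$diagnostics$lambda),
    iterations = path$diagnostics$iterations,
    converged = path$diagnostics$converged,
    kkt_residual = fmt17(path$diagnostics$kkt_residual),
    nonzero_count = path$diagnostics$nonzero,
    stringsAsFactors = FALSE)
  tryCatch({
    utils::write.table(coef_df, coef_file, sep = delim, quote = FALSE,
                       row.names = FALSE)
    utils::write.table(diag_df, diag_file, sep = delim, quote = FALSE,
                       row.names = FALSE)
  }, error = function(e)
    sgp_stop(sprintf("failed to write output: %s", conditionMessage(e)),
             "sgp_write_error"))
  invisible(c(coef_file, diag_file))
}

#' Write a simulated problem to delimited text files
#'
#' Companion to [sgp_simulate()] and [read_problem()]: writes `y`, `Z`,
#' the groups mapping and (if present) `X` in exactly the layout that
#' [read_problem()] consumes.
#'
#' @param problem An [sgp_problem()].
#' @param y_file,Z_file,groups_file,X_file Output paths (`X_file` ignored
#'   when `q = 0`).
#' @param delim Field delimiter.
#' @return Invisibly, the written file paths.
#' @export
write_problem <- function(problem, y_file, Z_file, groups_file,
                          X_file = NULL, delim = "\t") {
  if (!inherits(problem, "sgp_problem"))
    sgp_stop("problem must be an sgp_problem", "sgp_dimension_error")
  utils::write.table(data.frame(y = fmt17(problem$y)), y_file, sep = delim,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  Zc <- matrix(fmt17(problem$Z), nrow = problem$n,
               dimnames = list(NULL, problem$feature_ids))
  utils::write.table(Zc, Z_file, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  gl <- problem$group_labels[problem$group_index]
  utils::write.table(data.frame(problem$feature_ids, gl), groups_file,
                     sep = delim, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  out <- c(y_file, Z_file, groups_file)
  if (problem$q > 0L && !is.null(X_file)) {
    Xc <- matrix(fmt17(problem$X), nrow = problem$n,
                 dimnames = list(NULL, problem$unpenalized_ids))
    utils::write.table(Xc, X_file, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    out <- c(out, X_file)
  }
  invisible(out)
}
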