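#' Per-modality penalty factors (IPF-lasso weights)
#'
#' Expands per-modality penalty factors into a per-feature weight vector:
#' every feature of modality `m` receives `factors[m]`.  Modalities are
#' contiguous column blocks of `Z`, in order.  Using these weights with
#' `alpha = 1` turns the weighted lasso into the Integrative LASSO with
#' Penalty Factors (IPF-lasso), whose modality-specific penalties are
#' \eqn{\lambda^{(m)} \propto \lambda \cdot \mathrm{factors}[m]}.  (The
#' classical IPF-lasso notation writes \eqn{\lambda_j = 2n\lambda\omega^F_j};
#' the \eqn{2n} factor is absorbed into the \eqn{\lambda} grid here, so only
#' the ratios of the factors matter.)
#'
#' @param sizes Positive integer vector: number of features per modality,
#'   summing to `p`.
#' @param factors Positive numeric vector of the same length: penalty factor
#'   per modality.
#' @return Positive numeric vector of length `sum(sizes)`.
#' @examples
#' ipf_weights(sizes = c(2, 2), factors = c(1, 2))  # 1 1 2 2
#' @export
ipf_weights <- function(sizes, factors) {
  sizes <- as.integer(sizes)
  if (length(sizes) != length(factors) || length(sizes) == 0L)
    sgp_stop("sizes and factors must be non-empty and of equal length",
             "sgp_dimension_error")
  if (any(is.na(sizes)) || any(sizes < 1L))
    sgp_stop("modality sizes must be positive integers", "sgp_range_error")
  factors <- as.numeric(factors)
  if (any(!is.finite(factors)) || any(factors <= 0))
    sgp_stop("penalty factors must be strictly positive", "sgp_weight_error")
  rep(factors, times = sizes)
}

#' Minor-allele-frequency based feature weights
#'
#' Computes \eqn{\omega_j = 2\sqrt{\mathrm{MAF}_j (1 - \mathrm{MAF}_j)}},
#' the standard deviation of an allele count at Hardy-Weinberg equilibrium
#' scaled to 1 at MAF 0.5.  Variants with common alleles are penalized more
#' than rare ones, so the weight increases strictly on `(0, 0.5]` and is
#' maximal (= 1) at 0.5.  A MAF of 0 would give weight 0 and silently
#' unpenalize the feature, so entries must lie in `(0, 0.5]`.
#'
#' @param maf Numeric vector of minor allele frequencies in `(0, 0.5]`.
#' @return Positive numeric vector of the same length.
#' @examples
#' maf_weights(c(0.5, 0.1))  # 1.0, 0.6
#' @export
maf_weights <- function(maf) {
  maf <- as.numeric(maf)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
    sgp_stop("minor allele frequencies must lie in (0, 0.5]",
             "sgp_range_error")
  2 * sqrt(maf * (1 - maf))
}
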