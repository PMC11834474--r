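# Between-sample normalization of bulk RNA-seq counts: trimmed mean of
# M-values (TMM) scaling factors and the log2 counts-per-million transform
# with the half-count offset. TMM is implemented here from the published
# procedure rather than called from an external package; precision weights
# for downstream modelling are deliberately NOT computed because the
# downstream synergy model is ordinary least squares.

# TMM factor of one sample against the reference. Genes that are zero in
# either sample are excluded before any trimming; the two-sided trims act
# on the ranks of the M (log-ratio) and A (mean log-abundance) values; the
# surviving M values are averaged with inverse delta-method variances.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  # delta-method variance of M for count data
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)  # identical composition: exactly 1
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- sum(M[keep2] / v[keep2], na.rm = TRUE) / sum(1 / v[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM scaling factors
#'
#' Computes trimmed-mean-of-M-values normalization factors for a bulk count
#' matrix. The reference sample is the one whose upper-quartile count
#' fraction is closest to the mean upper-quartile fraction across samples.
#' For every sample, M (log2 expression ratio vs the reference) and A (mean
#' log2 abundance) values are computed over genes non-zero in both samples;
#' the most extreme `trim_m` fraction of M values and `trim_a` fraction of
#' A values are trimmed symmetrically; the factor is 2 to the power of the
#' precision-weighted mean of the surviving M values. Factors are rescaled
#' so their geometric mean is exactly 1.
#'
#' @param counts genes x samples count matrix (see [validate_counts()]).
#' @param trim_m total fraction of M values trimmed (default 0.30).
#' @param trim_a total fraction of A values trimmed (default 0.05).
#' @return named numeric vector of positive factors, one per sample,
#'   geometric mean 1.
#' @examples
#' counts <- matrix(rpois(200, 50), 50, 4,
#'                  dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
#' tmm_factors(counts)
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stop2("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop2("sample(s) with all-zero counts: ",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  # reference: upper-quartile count fraction closest to the mean
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    tmm_pair_factor(counts[, k], counts[, ref], lib[k], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' log2 counts-per-million transform
#'
#' Converts counts to log2-cpm with the standard half-count offset:
#' `log2((count + 0.5) / (libsize * factor + 1) * 1e6)`. The offset
#' guarantees finite values for zero counts. Per-observation precision
#' weights are intentionally not computed.
#'
#' @param counts genes x samples count matrix.
#' @param factors optional named normalization factors as returned by
#'   [tmm_factors()]; defaults to TMM factors of `counts`. Must cover every
#'   sample of `counts`.
#' @return genes x samples numeric matrix of log2-cpm values.
#' @examples
#' counts <- matrix(c(100L, 900L, 200L, 800L), 2, 2,
#'                  dimnames = list(c("A", "B"), c("s1", "s2")))
#' log2_cpm(counts, factors = c(s1 = 1, s2 = 1))
#' @export
log2_cpm <- function(counts, factors = NULL) {
  validate_counts(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (is.null(names(factors)) || !setequal(names(factors), colnames(counts))) {
    stop2("normalization factors must be named for exactly the samples of 'counts'")
  }
  factors <- factors[colnames(counts)]
  if (any(!is.finite(factors) | factors <= 0)) stop2("normalization factors must be positive")
  lib <- colSums(counts)
  eff <- lib * factors + 1
  expr <- log2(sweep(counts + 0.5, 2, eff, "/") * 1e6)
  dimnames(expr) <- dimnames(counts)
  expr
}
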