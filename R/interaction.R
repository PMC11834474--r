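# Patient-scale synergy statistics: the target ~ HH + IL6 + HH:IL6
# ordinary-least-squares interaction model, Welch's unpaired t test, and
# Spearman rank correlation. A positive interaction coefficient means the
# two pathways induce the target more than additively.

#' Fit the two-pathway interaction (synergy) model
#'
#' Ordinary least squares for `y ~ hh + il6 + hh:il6` with classical
#' standard errors and two-sided t p-values. The IL6 predictor is always a
#' binary high/low indicator; the HH predictor may be binary or a
#' continuous activity score — the fit records which encoding was used.
#' A rank-deficient design (e.g. a constant predictor) is a hard error,
#' never a silent coefficient drop.
#'
#' @param y numeric response per sample (target-gene log2-cpm).
#' @param hh numeric or logical HH predictor (binary 0/1 label or
#'   continuous activity score).
#' @param il6 binary IL6 predictor (0/1, logical, or a `strata_labels`
#'   "high"/"low" vector).
#' @return object of class `interaction_fit` with elements `coefficients`,
#'   `standard_errors`, `t_values`, `p_values` (named `intercept`, `hh`,
#'   `il6`, `hh:il6`), `residual_df`, `r_squared`, `n`, `encoding`.
#' @examples
#' set.seed(1)
#' hh <- rbinom(40, 1, 0.5); il6 <- rbinom(40, 1, 0.5)
#' y <- 1 + 1 * hh + 1 * il6 + 1.5 * hh * il6 + rnorm(40)
#' fit_interaction(y, hh, il6)
#' @export
fit_interaction <- function(y, hh, il6) {
  hh <- as_numeric_predictor(hh, "hh")
  il6 <- as_numeric_predictor(il6, "il6")
  y <- as.numeric(y)
  n <- length(y)
  if (length(hh) != n || length(il6) != n) stop2("y, hh and il6 must have equal length")
  if (n < 5L) stop2("interaction model needs at least 5 samples")
  if (any(!is.finite(c(y, hh, il6)))) stop2("non-finite values in model inputs")
  if (!all(il6 %in% c(0, 1))) stop2("il6 must be binary (0/1 or high/low)")
  X <- cbind(intercept = 1, hh = hh, il6 = il6, `hh:il6` = hh * il6)
  qx <- qr(X)
  if (qx$rank < 4L) {
    stop2("singular design: the [1, hh, il6, hh:il6] matrix is rank ",
          qx$rank, " (a predictor or the interaction is constant/collinear)")
  }
  beta <- qr.coef(qx, y)
  resid <- y - X %*% beta
  df <- n - 4L
  rss <- sum(resid^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  encoding <- list(
    hh = if (all(hh %in% c(0, 1))) "binary" else "continuous",
    il6 = "binary")
  structure(list(coefficients = beta, standard_errors = se, t_values = tval,
                 p_values = pval, residual_df = df, r_squared = r2, n = n,
                 sigma = sqrt(sigma2), encoding = encoding,
                 vcov_unscaled = XtXinv),
            class = "interaction_fit")
}

as_numeric_predictor <- function(x, what) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (!all(x %in% c("high", "low"))) {
      stop2(what, " labels must be 'high'/'low' when given as text")
    }
    return(as.numeric(x == "high"))
  }
  as.numeric(x)
}

#' Confidence intervals for an interaction fit
#'
#' @param object an `interaction_fit`.
#' @param parm coefficients to report (default all).
#' @param level confidence level (default 0.95 per the published analysis).
#' @param ... unused.
#' @return matrix with lower and upper bounds per coefficient.
#' @export
confint.interaction_fit <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  if (is.null(parm)) parm <- names(cf)
  q <- stats::qt(1 - (1 - level) / 2, object$residual_df)
  out <- cbind(lower = cf[parm] - q * object$standard_errors[parm],
               upper = cf[parm] + q * object$standard_errors[parm])
  rownames(out) <- parm
  out
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Two-pathway interaction model (n = ", x$n, ", HH encoding: ",
      x$encoding$hh, ")\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$standard_errors,
               t = x$t_values, p = x$p_values)
  print(round(tab, 4))
  cat("Residual df:", x$residual_df, " R-squared:", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' Welch's unpaired two-sample t test
#'
#' The unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value, as used for the patient group comparisons.
#' Both groups having zero variance leaves the statistic undefined and is
#' rejected.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return object of class `group_comparison` with means, `t_statistic`,
#'   fractional `df` and `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop2("each group needs at least 2 observations")
  if (any(!is.finite(c(a, b)))) stop2("non-finite values in input")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stop2("both groups have zero variance; Welch statistic undefined")
  }
  na <- length(a); nb <- length(b)
  sem2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(sem2)
  df <- sem2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb,
                 t_statistic = t_stat, df = df, p_value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch t test: mean_a = %.4g (n=%d), mean_b = %.4g (n=%d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  cat(sprintf("t = %.4g, df = %.2f, p = %.4g\n", x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; the p-value uses the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop2("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop2("Spearman correlation needs at least 3 pairs")
  if (any(!is.finite(c(x, y)))) stop2("non-finite values in input")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop2("correlation undefined: a vector is constant")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
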