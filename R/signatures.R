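# Pathway-activity signature scoring: z-scale each gene across samples,
# average the z-values over a signature's genes per sample, and stratify
# samples into pathway-high/low at a cutoff. The published analysis uses a
# cutoff of -0.5 for the Hedgehog signature and 0 for the IL6 signature.

#' Z-scale each gene across samples
#'
#' Centers and scales every gene row to mean 0 and standard deviation 1
#' (n - 1 denominator, the `scale()` convention). Zero-variance rows cannot
#' be scaled and become all-zero, with a warning.
#'
#' @param expr genes x samples numeric matrix (typically log2-cpm).
#' @return matrix of the same shape with row-wise z-values.
#' @export
scale_genes <- function(expr) {
  check_matrix_ids(expr, "expression matrix")
  if (ncol(expr) < 2L) stop2("scaling needs at least 2 samples")
  if (any(!is.finite(expr))) stop2("expression matrix contains non-finite values")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warn2(sum(flat), " zero-variance gene row(s) set to all-zero: ",
          paste(utils::head(rownames(expr)[flat], 5), collapse = ", "))
    sdv[flat] <- 1
  }
  z <- (expr - mu) / sdv
  z[flat, ] <- 0
  z
}

#' Pathway-activity score of a gene set
#'
#' Per-sample activity is the unweighted mean of z-scaled expression over
#' the signature genes present in the matrix. Missing signature genes are
#' dropped with a warning; a signature with zero overlap is an error.
#'
#' @param zexpr z-scaled genes x samples matrix, from [scale_genes()].
#' @param sig a [gene_set()].
#' @return object of class `activity_scores`: list with `signature_name`,
#'   `scores` (named per-sample vector), `n_genes_used`, `genes_missing`.
#' @export
signature_score <- function(zexpr, sig) {
  check_matrix_ids(zexpr, "z-scaled matrix")
  stopifnot(inherits(sig, "gene_set"))
  present <- sig$genes[sig$genes %in% rownames(zexpr)]
  missing <- setdiff(sig$genes, present)
  if (length(present) == 0) {
    stop2("signature '", sig$name, "' shares no genes with the expression matrix")
  }
  if (length(missing) > 0) {
    warn2("signature '", sig$name, "': ", length(missing),
          " gene(s) absent from the matrix: ",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  scores <- colMeans(zexpr[present, , drop = FALSE])
  structure(list(signature_name = sig$name, scores = scores,
                 n_genes_used = length(present), genes_missing = missing),
            class = "activity_scores")
}

#' @export
print.activity_scores <- function(x, ...) {
  cat("Activity scores for '", x$signature_name, "' over ", x$n_genes_used,
      " genes (", length(x$genes_missing), " missing), ",
      length(x$scores), " samples\n", sep = "")
  print(summary(unname(x$scores)))
  invisible(x)
}

#' Stratify samples into pathway-high and pathway-low
#'
#' A sample is called `high` when its score is greater than or equal to the
#' cutoff, `low` otherwise; the tie at the cutoff is assigned to `high` so
#' the threshold is an inclusive lower bound on activity (set
#' `ties = "low"` for the open-bound variant).
#'
#' @param scores an `activity_scores` object or a named numeric vector.
#' @param cutoff stratification threshold on the mean-z scale (the
#'   published analysis uses -0.5 for Hedgehog, 0 for IL6).
#' @param ties which label the boundary score receives, `"high"` (default)
#'   or `"low"`.
#' @return object of class `strata_labels`: list with `signature_name`,
#'   `cutoff`, `labels` (named character, `"high"`/`"low"`) and `counts`.
#' @export
stratify <- function(scores, cutoff, ties = c("high", "low")) {
  ties <- match.arg(ties)
  sig_name <- if (inherits(scores, "activity_scores")) scores$signature_name else NA_character_
  s <- if (inherits(scores, "activity_scores")) scores$scores else scores
  if (!is.numeric(s) || any(!is.finite(s))) stop2("scores must be finite numerics")
  high <- if (ties == "high") s >= cutoff else s > cutoff
  labels <- ifelse(high, "high", "low")
  names(labels) <- names(s)
  structure(list(signature_name = sig_name, cutoff = cutoff, labels = labels,
                 counts = c(high = sum(high), low = sum(!high))),
            class = "strata_labels")
}

#' @export
print.strata_labels <- function(x, ...) {
  cat("Strata for '", x$signature_name, "' at cutoff ", x$cutoff, ": ",
      x$counts["high"], " high / ", x$counts["low"], " low\n", sep = "")
  invisible(x)
}
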