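# Bench-side quantification arithmetic: delta-delta-Ct qPCR fold changes,
# the factorial synergy score, ChIP-qPCR percent of input chromatin, and
# internal-standard (ISTD) normalized metabolite fold changes. All Ct
# arithmetic assumes a fixed amplification efficiency (default 2.0 per
# cycle), exposed as a parameter.

check_ct <- function(ct, what) {
  if (any(!is.finite(ct))) stop2("missing or non-finite ", what, " Ct value")
  if (any(ct <= 0 | ct > 45)) stop2(what, " Ct values must lie in (0, 45]")
  invisible(ct)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per condition before differencing; the
#' fold change of a condition versus the control is
#' `efficiency^-(dCt_condition - dCt_control)` where
#' `dCt = mean(ct_target) - mean(ct_reference)`. The control condition maps
#' to fold 1 exactly.
#'
#' @param measurements data frame with columns `condition`, `ct_target`,
#'   `ct_reference` (one row per replicate).
#' @param control_condition name of the calibrator condition.
#' @param efficiency amplification factor per cycle (default 2).
#' @return named numeric vector of fold changes, one per condition, in
#'   first-appearance order.
#' @export
relative_expression <- function(measurements, control_condition,
                                efficiency = 2) {
  need <- c("condition", "ct_target", "ct_reference")
  if (!all(need %in% names(measurements))) {
    stop2("measurements need columns: ", paste(need, collapse = ", "))
  }
  check_ct(measurements$ct_target, "target")
  check_ct(measurements$ct_reference, "reference")
  conds <- unique(as.character(measurements$condition))
  if (!control_condition %in% conds) {
    stop2("control condition '", control_condition, "' not present")
  }
  dct <- vapply(conds, function(cc) {
    rows <- measurements$condition == cc
    mean(measurements$ct_target[rows]) - mean(measurements$ct_reference[rows])
  }, numeric(1))
  fold <- efficiency^(-(dct - dct[[control_condition]]))
  fold[[control_condition]] <- 1
  fold
}

#' Factorial synergy score
#'
#' Compares the combined induction with the sum of the single-agent
#' inductions, each in excess of the untreated baseline (fold 1):
#' `score = ((fold_a - 1) + (fold_b - 1)) / (fold_ab - 1)`. A score below 1
#' means the combination induces more than additively (synergy); exactly 1
#' is the additive boundary; above 1 is sub-additive. The formula is kept
#' behind this single function so an alternative factorial-synergy
#' definition can be swapped in; the result records the formula used.
#'
#' @param fold_a,fold_b single-treatment fold changes (>= 0).
#' @param fold_ab combined-treatment fold change; must exceed 1 (the
#'   combination must induce) or the score is undefined.
#' @return object of class `synergy_result` with `score` and
#'   `interpretation` (`"synergistic"`, `"additive"` or `"sub-additive"`).
#' @examples
#' synergy_score(2, 3, 7)   # 0.5, synergistic
#' synergy_score(2, 3, 4)   # 1.0, additive boundary
#' @export
synergy_score <- function(fold_a, fold_b, fold_ab) {
  if (any(!is.finite(c(fold_a, fold_b, fold_ab)))) stop2("folds must be finite")
  if (fold_a < 0 || fold_b < 0) stop2("single-agent folds must be >= 0")
  if (fold_ab <= 1) {
    stop2("synergy undefined: combined fold (", fold_ab,
          ") must exceed 1 (combination must induce the target)")
  }
  score <- ((fold_a - 1) + (fold_b - 1)) / (fold_ab - 1)
  interpretation <- if (score < 1) "synergistic" else if (score == 1) "additive" else "sub-additive"
  structure(list(fold_a = fold_a, fold_b = fold_b, fold_ab = fold_ab,
                 score = score, interpretation = interpretation,
                 formula = "excess-over-baseline ratio"),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("Synergy score = %.3g (%s); folds: a=%.3g, b=%.3g, ab=%.3g\n",
              x$score, x$interpretation, x$fold_a, x$fold_b, x$fold_ab))
  invisible(x)
}

#' ChIP-qPCR enrichment as percent of input chromatin
#'
#' The input Ct is first adjusted for the input dilution
#' (`ct_input - log_e(1/input_fraction) / log_e(efficiency)`), then
#' `%input = 100 * efficiency^(adjusted_input_ct - ct_ip)`. One IP cycle
#' above the adjusted input halves the percentage (at efficiency 2).
#'
#' @param ct_ip Ct of the immunoprecipitated sample (vectorized).
#' @param ct_input Ct of the diluted input sample.
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @param efficiency amplification factor per cycle (default 2).
#' @return numeric percentage(s) of input.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction, efficiency = 2) {
  if (any(!is.finite(c(ct_ip, ct_input)))) stop2("Ct values must be finite")
  if (!is.finite(input_fraction) || input_fraction <= 0 || input_fraction > 1) {
    stop2("input_fraction must lie in (0, 1]")
  }
  adjusted <- ct_input - log(1 / input_fraction, base = efficiency)
  100 * efficiency^(adjusted - ct_ip)
}

#' ISTD-normalized metabolite fold changes
#'
#' Each peak area is first normalized to its internal-standard (ISTD) peak
#' area; per analyte, replicate ratios are averaged per condition and
#' divided by the mean control ratio.
#'
#' @param records data frame with columns `analyte`, `condition`,
#'   `peak_area` (>= 0) and `istd_area` (> 0).
#' @param control_condition reference condition, required per analyte.
#' @return data frame with columns `analyte`, `condition`, `fold`.
#' @export
metabolite_fold <- function(records, control_condition) {
  need <- c("analyte", "condition", "peak_area", "istd_area")
  if (!all(need %in% names(records))) {
    stop2("records need columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$peak_area)) || any(records$peak_area < 0)) {
    stop2("peak areas must be finite and >= 0")
  }
  if (any(!is.finite(records$istd_area)) || any(records$istd_area <= 0)) {
    stop2("ISTD areas must be finite and > 0")
  }
  records$ratio <- records$peak_area / records$istd_area
  out <- do.call(rbind, lapply(unique(as.character(records$analyte)), function(an) {
    sub <- records[records$analyte == an, , drop = FALSE]
    conds <- unique(as.character(sub$condition))
    if (!control_condition %in% conds) {
      stop2("control condition '", control_condition,
            "' missing for analyte '", an, "'")
    }
    mean_ratio <- vapply(conds, function(cc) mean(sub$ratio[sub$condition == cc]),
                         numeric(1))
    if (mean_ratio[[control_condition]] == 0) {
      stop2("zero control ratio for analyte '", an, "': fold change undefined")
    }
    data.frame(analyte = an, condition = conds,
               fold = unname(mean_ratio / mean_ratio[[control_condition]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
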