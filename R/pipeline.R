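# End-to-end orchestration: bulk synergy analysis (normalize -> scale ->
# score -> stratify -> group comparisons -> interaction fit) and the
# single-cell co-activity analysis (classify -> contingency -> Fisher),
# each returning a self-describing machine-readable report. Single-cell
# patients are always analyzed separately, never pooled.

#' Run the bulk synergy pipeline
#'
#' From raw counts (or ready log2-cpm values), computes pathway-activity
#' scores for the HH and IL6 signatures, stratifies samples at the given
#' cutoffs, compares target-gene expression between strata with Welch's t
#' test, and fits the target ~ HH + IL6 + HH:IL6 interaction model. Every
#' stage result, plus the parameters that produced it, is echoed into the
#' report; the pipeline is deterministic (no randomness), so the same
#' inputs give an identical report.
#'
#' @param data genes x samples matrix: raw counts (`data_type = "counts"`)
#'   or log2-cpm expression (`data_type = "expression"`).
#' @param gene_sets named list of two [gene_set()]s; names must match
#'   `names(cutoffs)`. The first is treated as the HH-like signature whose
#'   score/label enters the model as the `hh` predictor, the second as the
#'   IL6-like binary predictor.
#' @param target target gene name (default `"IDO1"`).
#' @param cutoffs named stratification cutoffs, default
#'   `c(HH = -0.5, IL6 = 0)` — the published thresholds.
#' @param hh_encoding `"binary"` (default; both predictors enter as
#'   high/low indicators) or `"continuous"` (the HH score enters as-is).
#' @param data_type whether `data` are raw counts or log2-cpm values.
#' @param trim_m,trim_a TMM trim fractions, used only for counts.
#' @param correlate_with optional gene names to correlate (Spearman) with
#'   the target; absent genes are skipped silently.
#' @return object of class `bulk_report`: parameters, normalization
#'   factors (if applied), per-signature scores and strata, per-stratum
#'   target means with Welch comparisons, and the `interaction_fit`.
#' @export
run_bulk_pipeline <- function(data, gene_sets,
                              target = "IDO1",
                              cutoffs = c(HH = -0.5, IL6 = 0),
                              hh_encoding = c("binary", "continuous"),
                              data_type = c("counts", "expression"),
                              trim_m = 0.30, trim_a = 0.05,
                              correlate_with = "GLI2") {
  hh_encoding <- match.arg(hh_encoding)
  data_type <- match.arg(data_type)
  if (length(gene_sets) != 2L || is.null(names(gene_sets))) {
    stop2("gene_sets must be a named list of exactly two signatures")
  }
  if (!setequal(names(gene_sets), names(cutoffs))) {
    stop2("names of gene_sets and cutoffs must agree")
  }
  if (!target %in% rownames(data)) {
    stop2("stage interaction_model: target gene '", target, "' absent from the matrix")
  }
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  factors <- NULL
  if (data_type == "counts") {
    factors <- tmm_factors(data, trim_m = trim_m, trim_a = trim_a)
    expr <- log2_cpm(data, factors)
    note("normalization: ", nrow(data), " genes x ", ncol(data),
         " samples -> log2-cpm (TMM)")
  } else {
    expr <- data
    note("normalization: skipped (input already log2-cpm scale)")
  }
  zexpr <- scale_genes(expr)
  note("scaling: ", nrow(zexpr), " gene rows z-scaled across ", ncol(zexpr), " samples")

  sig_names <- names(cutoffs)
  scores <- list(); strata <- list()
  for (sn in sig_names) {
    scores[[sn]] <- signature_score(zexpr, gene_sets[[sn]])
    strata[[sn]] <- stratify(scores[[sn]], cutoffs[[sn]])
    note("signature '", sn, "': ", scores[[sn]]$n_genes_used, " genes -> ",
         strata[[sn]]$counts["high"], " high / ", strata[[sn]]$counts["low"], " low")
  }

  y <- expr[target, ]
  comparisons <- list()
  for (sn in sig_names) {
    lab <- strata[[sn]]$labels
    if (all(c("high", "low") %in% lab) &&
        sum(lab == "high") >= 2 && sum(lab == "low") >= 2) {
      comparisons[[sn]] <- welch_t(y[lab == "high"], y[lab == "low"])
      note("comparison '", sn, "' high vs low: p = ",
           signif(comparisons[[sn]]$p_value, 3))
    } else {
      note("comparison '", sn, "': skipped (a stratum has < 2 samples)")
    }
  }

  hh_name <- sig_names[1]; il6_name <- sig_names[2]
  hh_pred <- if (hh_encoding == "binary") {
    as.numeric(strata[[hh_name]]$labels == "high")
  } else {
    scores[[hh_name]]$scores
  }
  il6_pred <- as.numeric(strata[[il6_name]]$labels == "high")
  fit <- fit_interaction(y, hh_pred, il6_pred)
  note("interaction fit (HH ", hh_encoding, "): interaction p = ",
       signif(fit$p_values[["hh:il6"]], 3))

  correlations <- list()
  for (g in setdiff(intersect(correlate_with, rownames(expr)), target)) {
    correlations[[g]] <- spearman(expr[g, ], y)
  }

  structure(list(
    parameters = list(target = target, cutoffs = as.list(cutoffs),
                      hh_encoding = hh_encoding, data_type = data_type,
                      trim_m = trim_m, trim_a = trim_a,
                      signatures = lapply(gene_sets, `[[`, "genes")),
    dimensions = c(genes = nrow(data), samples = ncol(data)),
    norm_factors = factors,
    scores = scores, strata = strata,
    group_comparisons = comparisons,
    interaction = fit,
    correlations = correlations,
    log = log,
    version = as.character(utils::packageVersion("glistat"))),
    class = "bulk_report")
}

#' @export
print.bulk_report <- function(x, ...) {
  cat("Bulk synergy pipeline report (glistat ", x$version, ")\n", sep = "")
  for (l in x$log) cat(" -", l, "\n")
  print(x$interaction)
  invisible(x)
}

#' Run the single-cell co-activity pipeline
#'
#' For each patient dataset independently: classify tumor cells, build the
#' IDO1-by-double-positivity contingency table with its four-state
#' percentage breakdown, and run Fisher's exact test. Patients are never
#' pooled.
#'
#' @param cells a [sparse_cell_matrix()] or a named list of them (one per
#'   patient).
#' @param tumor_label annotation label selecting tumor cells.
#' @param min_count detection threshold for [classify_cells()].
#' @param or_method odds-ratio estimator for [fisher_exact()].
#' @return object of class `sc_report`: one section per patient, each with
#'   the cell counts, state percentages, 2x2 table and `fisher_result`.
#' @export
run_sc_pipeline <- function(cells, tumor_label = "Tumor", min_count = 1,
                            or_method = "sample") {
  if (inherits(cells, "sparse_cell_matrix")) cells <- list(patient_1 = cells)
  if (is.null(names(cells))) names(cells) <- paste0("patient_", seq_along(cells))
  patients <- lapply(names(cells), function(id) {
    states <- classify_cells(cells[[id]], tumor_label = tumor_label,
                             min_count = min_count)
    cont <- coactivity_contingency(states)
    fisher <- fisher_exact(cont$table, or_method = or_method)
    list(patient = id, n_cells = cont$n_cells,
         n_ido1_positive = sum(states$ido1_positive),
         state_percentages = cont$state_percentages,
         table = cont$table, fisher = fisher)
  })
  names(patients) <- names(cells)
  structure(list(parameters = list(tumor_label = tumor_label,
                                   min_count = min_count,
                                   or_method = or_method),
                 patients = patients,
                 version = as.character(utils::packageVersion("glistat"))),
            class = "sc_report")
}

#' @export
print.sc_report <- function(x, ...) {
  cat("Single-cell co-activity report (glistat ", x$version, ")\n", sep = "")
  for (p in x$patients) {
    cat("--", p$patient, ":", p$n_cells, "tumor cells,",
        p$n_ido1_positive, "IDO1-positive\n")
    print(p$fisher)
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes a report (or any nested result list) as pretty-printed JSON,
#' flattening the package's S3 result objects into plain lists.
#'
#' @param report a `bulk_report` or `sc_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (is.matrix(x)) {
    x <- as.data.frame(x)
  }
  x
}
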