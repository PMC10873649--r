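# Machine-readable report emission: JSON (nested by attribute -> category ->
# metric) plus flat delimited twins for spreadsheet use.

#' Nested metric report for one or more attributes
#'
#' @param cohort A [scored_cohort()].
#' @param attributes Attribute names; default all declared attributes.
#' @param min_tpr Minimum population TPR for the thresholded FPR metric.
#' @return Nested list `attribute -> category -> metrics`, suitable for JSON
#'   serialisation; the flat table twin is attached as
#'   `attr(x, "flat_table")`.
#' @export
metric_report <- function(cohort, attributes = NULL, min_tpr = 0.95) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (is.null(attributes)) attributes <- cohort_attributes(cohort)
  tables <- lapply(attributes, function(a)
    subgroup_metrics(cohort, a, min_tpr))
  names(tables) <- attributes
  nested <- lapply(tables, function(tab) {
    per_cat <- lapply(seq_len(nrow(tab)), function(i)
      list(sauroc = tab$sauroc[i],
           naive_auroc = tab$naive_auroc[i],
           fpr_at_min_tpr = tab$fpr_at_min_tpr[i],
           mean_score_normal = tab$mean_score_normal[i],
           mean_score_diseased = tab$mean_score_diseased[i],
           n_sub_pos = tab$n_sub_pos[i],
           n_sub_neg = tab$n_sub_neg[i]))
    names(per_cat) <- tab$category
    per_cat
  })
  out <- list(min_tpr = min_tpr,
              n_samples = nrow(cohort),
              metrics = nested)
  attr(out, "flat_table") <- do.call(rbind, tables)
  out
}

#' Write a metric report as JSON and a flat delimited table
#'
#' @param report A [metric_report()].
#' @param json_path Output path for the nested JSON report; `NULL` skips it.
#' @param table_path Output path for the flat CSV twin; `NULL` skips it.
#' @return Invisibly, the flat table.
#' @export
write_metric_report <- function(report, json_path = NULL, table_path = NULL) {
  flat <- attr(report, "flat_table")
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(table_path))
    utils::write.csv(flat, table_path, row.names = FALSE, quote = FALSE)
  invisible(flat)
}

#' Serialise law fits as a JSON-ready list
#'
#' @param fits A list of [fit_law()] results (one per category).
#' @return Unclassed nested list keyed by category.
#' @export
law_report <- function(fits) {
  out <- lapply(fits, function(f) {
    stopifnot(inherits(f, "law_fit"))
    list(slope = f$slope, intercept = f$intercept,
         pearson_r = f$pearson_r, degenerate = f$degenerate,
         interpolation_mae = f$interpolation_mae,
         interpolation_mae_sd = f$interpolation_mae_sd,
         ci = if (is.null(f$ci)) NULL else
           list(slope = as.list(f$ci$slope),
                intercept = as.list(f$ci$intercept)),
         n_points = f$n_points, n_seeds = f$n_seeds)
  })
  names(out) <- vapply(fits, `[[`, character(1), "category")
  out
}

#' Serialise an intersectional report as a JSON-ready list
#'
#' @param report An [intersectional_report()].
#' @return Unclassed nested list.
#' @export
intersectional_json <- function(report) {
  stopifnot(inherits(report, "intersectional_report"))
  list(attributes = as.list(report$attributes),
       cells = report$cells,
       marginals = report$marginals,
       deltas = report$deltas,
       amplification = report$amplification,
       n_pop_positives = report$n_pop_positives)
}
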