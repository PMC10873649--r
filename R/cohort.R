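#' Construct a scored cohort
#'
#' A scored cohort is the unit every fairness metric in this package
#' consumes: one row per sample carrying an anomaly score (real-valued,
#' higher = more anomalous), a binary disease label (1 = diseased/positive,
#' 0 = normal/negative) and one or more categorical protected attributes
#' (e.g. sex, age group). Scores typically come from an unsupervised anomaly
#' detection model; the package never looks at the model, only at its scores.
#'
#' @param data A data frame with columns `sample_id`, `patient_id`, `score`,
#'   `label`, plus one column per protected attribute.
#' @param attributes Character vector naming the protected-attribute columns.
#' @return A `scored_cohort`: a data frame restricted to the required columns,
#'   with the protected-attribute column names stored in
#'   `attr(x, "protected")`.
#' @details Validation enforces: at least one row; finite scores; labels
#'   exactly 0 or 1; every sample has a non-missing category for every
#'   declared attribute; unique `sample_id`s.
#' @examples
#' d <- data.frame(sample_id = 1:4, patient_id = 1:4,
#'                 score = c(0.9, 0.2, 0.8, 0.1), label = c(1, 0, 1, 0),
#'                 sex = c("f", "f", "m", "m"))
#' cohort <- scored_cohort(d, attributes = "sex")
#' @export
scored_cohort <- function(data, attributes) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  if (!is.character(attributes) || length(attributes) < 1)
    stop("`attributes` must name at least one protected-attribute column")
  required <- c("sample_id", "patient_id", "score", "label")
  missing_cols <- setdiff(c(required, attributes), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(data) < 1) stop("a scored cohort needs at least one sample")

  out <- as.data.frame(data)[, c(required, attributes), drop = FALSE]
  out$sample_id <- as.character(out$sample_id)
  out$patient_id <- as.character(out$patient_id)
  out$score <- as.numeric(out$score)
  out$label <- as.integer(out$label)

  if (anyDuplicated(out$sample_id))
    stop("sample_id values must be unique")
  if (any(!is.finite(out$score)))
    stop("scores must be finite reals")
  if (!all(out$label %in% c(0L, 1L)))
    stop("labels must be exactly 0 (normal) or 1 (diseased)")
  for (a in attributes) {
    out[[a]] <- as.character(out[[a]])
    if (any(is.na(out[[a]]) | out[[a]] == ""))
      stop("attribute '", a, "' has missing categories")
  }
  rownames(out) <- NULL
  structure(out, protected = attributes,
            class = c("scored_cohort", "data.frame"))
}

#' Protected attributes of a scored cohort
#'
#' @param cohort A [scored_cohort()].
#' @return Character vector of protected-attribute column names.
#' @export
cohort_attributes <- function(cohort) {
  stopifnot(inherits(cohort, "scored_cohort"))
  attr(cohort, "protected")
}

#' @export
print.scored_cohort <- function(x, ...) {
  attrs <- attr(x, "protected")
  cat(sprintf("Scored cohort: %d samples, %d patients (%d diseased, %d normal)\n",
              nrow(x), length(unique(x$patient_id)),
              sum(x$label == 1L), sum(x$label == 0L)))
  for (a in attrs) {
    tab <- table(x[[a]])
    cat(sprintf("  %s: %s\n", a,
                paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Read a score table from delimited text
#'
#' The on-disk format is comma-separated with a header row:
#' `sample_id, patient_id, score, label`, then one column per protected
#' attribute.
#'
#' @param path Path to a CSV score table.
#' @param attributes Protected-attribute column names; `NULL` (default) takes
#'   every column after the four required ones.
#' @return A [scored_cohort()].
#' @export
read_score_table <- function(path, attributes = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        patient_id = "character"))
  if (is.null(attributes))
    attributes <- setdiff(names(tab),
                          c("sample_id", "patient_id", "score", "label"))
  scored_cohort(tab, attributes)
}

#' Write a score table as delimited text
#'
#' Scores are serialised with 17 significant digits so that
#' `read_score_table(write_score_table(x))` reproduces `x` exactly.
#'
#' @param cohort A [scored_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "scored_cohort"))
  out <- as.data.frame(cohort)
  out$score <- sprintf("%.17g", out$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
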