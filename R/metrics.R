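# Threshold-free and thresholded subgroup performance metrics.
#
# The central quantity is the subgroup-AUROC (sAUROC): for a subgroup s of a
# population P, sweep the decision threshold t over the observed scores; at
# each t a sample is flagged anomalous iff score >= t; the true positive rate
# is counted over ALL positives in P while the false positive rate is counted
# over the negatives of s only. The area under the resulting
# (FPR_s, TPR_P) curve is the sAUROC. Because thresholds are shared across
# subgroups, score-location shifts between subgroups (the signature failure
# mode of anomaly detectors on under-represented groups) show up in the
# metric, unlike the naive per-subgroup AUROC.

# number of elements of `sorted_vals` (ascending) that are >= each t
.count_ge <- function(sorted_vals, t) {
  length(sorted_vals) - findInterval(t, sorted_vals, left.open = TRUE)
}

# operating points of the score-sweep ROC between two score sets; thresholds
# taken from `candidate_scores` (defaults to the union), plus a sentinel
# above the maximum so the curve is anchored at (0, 0). The lowest observed
# score flags everything, anchoring (1, 1).
.roc_points <- function(pos, neg, candidate_scores = c(pos, neg)) {
  ts <- sort(unique(candidate_scores), decreasing = TRUE)
  ts <- c(ts[1] + 1, ts)
  spos <- sort(pos)
  sneg <- sort(neg)
  list(thresholds = ts,
       tpr = .count_ge(spos, ts) / length(pos),
       fpr = .count_ge(sneg, ts) / length(neg))
}

# trapezoidal area under (fpr, tpr); exact on the finite operating points
.trapezoid <- function(fpr, tpr) {
  k <- length(fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-k]) / 2)
}

# area between two raw score sets (positives vs negatives); used by sAUROC,
# naive AUROC and the intersectional cells alike
.roc_trapz <- function(pos, neg, candidate_scores = c(pos, neg)) {
  pts <- .roc_points(pos, neg, candidate_scores)
  .trapezoid(pts$fpr, pts$tpr)
}

.subgroup_scores <- function(cohort, attribute, category) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!attribute %in% cohort_attributes(cohort))
    stop("'", attribute, "' is not a declared protected attribute")
  in_sub <- cohort[[attribute]] == category
  if (!any(in_sub))
    stop("no samples in subgroup ", attribute, "=", category)
  list(pos = cohort$score[cohort$label == 1L],
       sub_neg = cohort$score[cohort$label == 0L & in_sub],
       sub_pos = cohort$score[cohort$label == 1L & in_sub])
}

#' Subgroup ROC curve (population TPR vs subgroup FPR)
#'
#' Traces the operating curve of a subgroup over all decision thresholds: at
#' each threshold `t` a sample is flagged anomalous iff its score is `>= t`;
#' the TPR is computed over every positive in the whole cohort, the FPR only
#' over the negatives of the named subgroup. Candidate thresholds are the
#' distinct observed scores of the cohort plus a sentinel above the maximum,
#' so the curve is anchored at (0, 0) and (1, 1).
#'
#' @param cohort A [scored_cohort()].
#' @param attribute Protected-attribute name.
#' @param category Category of `attribute` defining the subgroup.
#' @return A `subgroup_roc` object: thresholds (strictly decreasing),
#'   `tpr_population`, `fpr_subgroup` (each non-decreasing), and the counts
#'   `n_pop_positives`, `n_sub_negatives`.
#' @seealso [sauroc()] for the area under this curve.
#' @export
subgroup_roc <- function(cohort, attribute, category) {
  s <- .subgroup_scores(cohort, attribute, category)
  if (length(s$pos) == 0)
    stop("no positive samples in the population: TPR undefined, ",
         "sAUROC cannot be computed")
  if (length(s$sub_neg) == 0)
    stop("no negative samples in subgroup ", attribute, "=", category,
         ": FPR undefined, sAUROC cannot be computed")
  pts <- .roc_points(s$pos, s$sub_neg, candidate_scores = cohort$score)
  structure(list(thresholds = pts$thresholds,
                 tpr_population = pts$tpr,
                 fpr_subgroup = pts$fpr,
                 n_pop_positives = length(s$pos),
                 n_sub_negatives = length(s$sub_neg),
                 attribute = attribute,
                 category = category),
            class = "subgroup_roc")
}

#' @export
print.subgroup_roc <- function(x, ...) {
  cat(sprintf("Subgroup ROC (%s=%s): %d operating points, %d population positives, %d subgroup negatives\n",
              x$attribute, x$category, length(x$thresholds),
              x$n_pop_positives, x$n_sub_negatives))
  invisible(x)
}

#' Subgroup-AUROC: area under a subgroup ROC curve
#'
#' Trapezoidal integral of the population TPR over the subgroup FPR on
#' \[0, 1\]. Over the finite operating points this is exactly the
#' tie-corrected Mann-Whitney statistic between the population's positive
#' scores and the subgroup's negative scores (pairs with positive > negative
#' count 1, ties count 1/2), which is the identity the test suite verifies.
#'
#' @param curve A [subgroup_roc()] curve.
#' @return The sAUROC, a number in \[0, 1\].
#' @export
sauroc <- function(curve) {
  stopifnot(inherits(curve, "subgroup_roc"))
  .trapezoid(curve$fpr_subgroup, curve$tpr_population)
}

#' Naive (within-subgroup) AUROC
#'
#' Standard AUROC computed using only the subgroup's own positives and
#' negatives. Included for comparison: because each subgroup is ranked
#' against itself, uniform score shifts of a subgroup are invisible to it,
#' so it fails to register the representation effects that [sauroc()]
#' captures.
#'
#' @inheritParams subgroup_roc
#' @return AUROC in \[0, 1\].
#' @export
naive_auroc <- function(cohort, attribute, category) {
  s <- .subgroup_scores(cohort, attribute, category)
  if (length(s$sub_pos) == 0)
    stop("subgroup ", attribute, "=", category,
         " has no positive samples: naive AUROC undefined")
  if (length(s$sub_neg) == 0)
    stop("subgroup ", attribute, "=", category,
         " has no negative samples: naive AUROC undefined")
  .roc_trapz(s$sub_pos, s$sub_neg)
}

#' Subgroup FPR at a minimum population TPR
#'
#' Finds the single largest threshold `t*` whose population-wide TPR reaches
#' `min_tpr` (flagging rule: score `>= t*`), then reports each subgroup's
#' false positive rate at that shared threshold. Using one population-level
#' threshold for all subgroups is what makes the resulting FPRs comparable:
#' a deployed screening model cannot pick thresholds per subgroup when group
#' membership is unavailable at decision time.
#'
#' @param cohort A [scored_cohort()].
#' @param attribute Protected-attribute name.
#' @param min_tpr Minimum required population TPR, in (0, 1\]; default 0.95.
#' @return Named numeric vector, one FPR in \[0, 1\] per category of
#'   `attribute`; the selected threshold is attached as
#'   `attr(x, "threshold")`.
#' @export
fpr_at_min_tpr <- function(cohort, attribute, min_tpr = 0.95) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!is.numeric(min_tpr) || length(min_tpr) != 1 ||
      min_tpr <= 0 || min_tpr > 1)
    stop("`min_tpr` must be a single value in (0, 1]")
  if (!attribute %in% cohort_attributes(cohort))
    stop("'", attribute, "' is not a declared protected attribute")
  pos <- cohort$score[cohort$label == 1L]
  if (length(pos) == 0)
    stop("no positive samples in the population: TPR undefined")

  ts <- sort(unique(cohort$score), decreasing = TRUE)
  tpr <- .count_ge(sort(pos), ts) / length(pos)
  t_star <- ts[which(tpr >= min_tpr)[1]]  # largest t meeting the constraint

  cats <- sort(unique(cohort[[attribute]]))
  out <- vapply(cats, function(cat) {
    neg <- cohort$score[cohort$label == 0L & cohort[[attribute]] == cat]
    if (length(neg) == 0)
      stop("subgroup ", attribute, "=", cat,
           " has no negative samples: FPR undefined")
    mean(neg >= t_star)
  }, numeric(1))
  names(out) <- cats
  attr(out, "threshold") <- t_star
  out
}

#' Mean anomaly score per (category, label) cell
#'
#' @param cohort A [scored_cohort()].
#' @param attribute Protected-attribute name.
#' @return Data frame with columns `category`, `label`, `n`, `mean_score`;
#'   empty cells are absent, never reported as zero.
#' @export
score_summary <- function(cohort, attribute) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (!attribute %in% cohort_attributes(cohort))
    stop("'", attribute, "' is not a declared protected attribute")
  agg <- stats::aggregate(cohort$score,
                          by = list(category = cohort[[attribute]],
                                    label = cohort$label),
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  out <- data.frame(category = agg$category,
                    label = agg$label,
                    n = as.integer(agg$x[, "n"]),
                    mean_score = agg$x[, "mean"],
                    stringsAsFactors = FALSE)
  out[order(out$category, out$label), , drop = FALSE]
}

#' Full per-subgroup metric table for one attribute
#'
#' Convenience wrapper computing, for every category of `attribute`: sAUROC,
#' naive AUROC, FPR at the shared `min_tpr` threshold, mean scores of the
#' subgroup's normal and diseased samples, and class counts.
#'
#' @inheritParams fpr_at_min_tpr
#' @return Data frame, one row per category.
#' @export
subgroup_metrics <- function(cohort, attribute, min_tpr = 0.95) {
  fprs <- fpr_at_min_tpr(cohort, attribute, min_tpr)
  cats <- names(fprs)
  rows <- lapply(cats, function(cat) {
    in_sub <- cohort[[attribute]] == cat
    sub_neg <- cohort$score[cohort$label == 0L & in_sub]
    sub_pos <- cohort$score[cohort$label == 1L & in_sub]
    data.frame(attribute = attribute,
               category = cat,
               sauroc = sauroc(subgroup_roc(cohort, attribute, cat)),
               naive_auroc = naive_auroc(cohort, attribute, cat),
               fpr_at_min_tpr = unname(fprs[cat]),
               mean_score_normal = mean(sub_neg),
               mean_score_diseased = mean(sub_pos),
               n_sub_pos = length(sub_pos),
               n_sub_neg = length(sub_neg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "min_tpr") <- min_tpr
  attr(out, "threshold") <- attr(fprs, "threshold")
  out
}
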