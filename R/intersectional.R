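# Intersectional disparity analysis: sAUROC per joint subgroup (e.g.
# old female), per marginal subgroup, and the disparity deltas between
# them. The sAUROC definition is applied unchanged in every cell: TPR over
# the whole cohort's positives, FPR over the cell's negatives, so a cell's
# metric remains comparable with every other cell's.

#' Signed disparity between two sAUROC values
#'
#' @param sauroc_a,sauroc_b Values in \[0, 1\].
#' @return `sauroc_a - sauroc_b`. The sign follows the argument order; the
#'   magnitude is the conventional disparity Delta.
#' @export
disparity_delta <- function(sauroc_a, sauroc_b) {
  if (any(c(sauroc_a, sauroc_b) < 0) || any(c(sauroc_a, sauroc_b) > 1))
    stop("sAUROC values must lie in [0, 1]")
  sauroc_a - sauroc_b
}

#' Intersectional disparity report over two protected attributes
#'
#' Computes the sAUROC of every (catA, catB) cell and of every marginal
#' category, then the conditional disparities: for each conditioning
#' category `b` of attribute B, `Delta(A | B=b) = sAUROC(a1, b) -
#' sAUROC(a2, b)` where `(a1, a2)` are attribute A's categories in sorted
#' order (and symmetrically for B conditioned on A). An attribute's
#' disparity is flagged as amplified under the conditioning category where
#' its absolute conditional delta is largest. Cell positives play no special
#' role: the TPR always comes from the entire cohort's positives, only the
#' negatives are restricted to the cell.
#'
#' @param cohort A [scored_cohort()].
#' @param attributes Character pair of protected-attribute names.
#' @return An `intersectional_report`: `cells` and `marginals` data frames
#'   (category, sAUROC, negative count), `deltas` (one row per conditional
#'   or marginal comparison), and `amplification` (per attribute, which
#'   conditioning category amplifies its disparity).
#' @export
intersectional_report <- function(cohort, attributes) {
  stopifnot(inherits(cohort, "scored_cohort"), length(attributes) == 2)
  declared <- cohort_attributes(cohort)
  missing_attrs <- setdiff(attributes, declared)
  if (length(missing_attrs))
    stop("not declared protected attributes: ",
         paste(missing_attrs, collapse = ", "))
  a_name <- attributes[1]
  b_name <- attributes[2]
  cats_a <- sort(unique(cohort[[a_name]]))
  cats_b <- sort(unique(cohort[[b_name]]))
  pos <- cohort$score[cohort$label == 1L]
  if (length(pos) == 0)
    stop("no positive samples in the population: sAUROC undefined")

  cell_sauroc <- function(a, b) {
    neg <- cohort$score[cohort$label == 0L &
                          cohort[[a_name]] == a & cohort[[b_name]] == b]
    if (length(neg) == 0)
      stop("cell ", a_name, "=", a, " & ", b_name, "=", b,
           " has no negative samples: sAUROC undefined")
    c(sauroc = .roc_trapz(pos, neg, candidate_scores = cohort$score),
      n_neg = length(neg))
  }

  cells <- do.call(rbind, lapply(cats_a, function(a)
    do.call(rbind, lapply(cats_b, function(b) {
      v <- cell_sauroc(a, b)
      data.frame(cat_a = a, cat_b = b, sauroc = v[["sauroc"]],
                 n_neg = as.integer(v[["n_neg"]]), stringsAsFactors = FALSE)
    }))))

  marginals <- do.call(rbind, lapply(seq_along(attributes), function(i) {
    attr_i <- attributes[i]
    do.call(rbind, lapply(sort(unique(cohort[[attr_i]])), function(cat) {
      neg <- cohort$score[cohort$label == 0L & cohort[[attr_i]] == cat]
      data.frame(attribute = attr_i, category = cat,
                 sauroc = .roc_trapz(pos, neg, candidate_scores = cohort$score),
                 n_neg = length(neg), stringsAsFactors = FALSE)
    }))
  }))

  cell_val <- function(a, b) cells$sauroc[cells$cat_a == a & cells$cat_b == b]
  marg_val <- function(attr_i, cat)
    marginals$sauroc[marginals$attribute == attr_i & marginals$category == cat]

  deltas <- list()
  add_delta <- function(attribute, comparison, conditioning, value) {
    deltas[[length(deltas) + 1]] <<- data.frame(
      attribute = attribute, comparison = comparison,
      conditioning = conditioning, delta = value, stringsAsFactors = FALSE)
  }

  if (length(cats_a) >= 2) {
    cmp_a <- paste(cats_a[1], "vs", cats_a[2])
    add_delta(a_name, cmp_a, "(marginal)",
              disparity_delta(marg_val(a_name, cats_a[1]),
                              marg_val(a_name, cats_a[2])))
    for (b in cats_b)
      add_delta(a_name, cmp_a, paste0(b_name, "=", b),
                disparity_delta(cell_val(cats_a[1], b), cell_val(cats_a[2], b)))
  }
  if (length(cats_b) >= 2) {
    cmp_b <- paste(cats_b[1], "vs", cats_b[2])
    add_delta(b_name, cmp_b, "(marginal)",
              disparity_delta(marg_val(b_name, cats_b[1]),
                              marg_val(b_name, cats_b[2])))
    for (a in cats_a)
      add_delta(b_name, cmp_b, paste0(a_name, "=", a),
                disparity_delta(cell_val(a, cats_b[1]), cell_val(a, cats_b[2])))
  }
  deltas <- if (length(deltas)) do.call(rbind, deltas) else
    data.frame(attribute = character(0), comparison = character(0),
               conditioning = character(0), delta = numeric(0))

  amplification <- do.call(rbind, lapply(unique(deltas$attribute), function(attr_i) {
    cond <- deltas[deltas$attribute == attr_i &
                     deltas$conditioning != "(marginal)", , drop = FALSE]
    if (nrow(cond) < 2) return(NULL)
    k <- which.max(abs(cond$delta))
    data.frame(attribute = attr_i,
               amplifying_condition = cond$conditioning[k],
               delta_abs = abs(cond$delta[k]),
               amplified = abs(diff(range(abs(cond$delta)))) > 0,
               stringsAsFactors = FALSE)
  }))

  structure(list(attributes = attributes, cells = cells,
                 marginals = marginals, deltas = deltas,
                 amplification = amplification,
                 n_pop_positives = length(pos)),
            class = "intersectional_report")
}

#' @export
print.intersectional_report <- function(x, ...) {
  cat(sprintf("Intersectional report over (%s, %s); %d population positives\n",
              x$attributes[1], x$attributes[2], x$n_pop_positives))
  cat("Cell sAUROC:\n")
  print(x$cells, row.names = FALSE)
  cat("Disparities (signed Delta; magnitude is the reported disparity):\n")
  print(x$deltas, row.names = FALSE)
  if (!is.null(x$amplification) && nrow(x$amplification)) {
    cat("Amplification:\n")
    print(x$amplification, row.names = FALSE)
  }
  invisible(x)
}

#' Flat table of an intersectional report
#'
#' One row per cell and per marginal, for delimited-text export.
#'
#' @param report An [intersectional_report()].
#' @return Data frame with `scope`, `category`, `sauroc`, `n_neg`.
#' @export
intersectional_table <- function(report) {
  stopifnot(inherits(report, "intersectional_report"))
  cells <- data.frame(scope = "cell",
                      category = paste(report$cells$cat_a,
                                       report$cells$cat_b, sep = " & "),
                      sauroc = report$cells$sauroc,
                      n_neg = report$cells$n_neg,
                      stringsAsFactors = FALSE)
  marg <- data.frame(scope = "marginal",
                     category = paste(report$marginals$attribute,
                                      report$marginals$category, sep = "="),
                     sauroc = report$marginals$sauroc,
                     n_neg = report$marginals$n_neg,
                     stringsAsFactors = FALSE)
  rbind(cells, marg)
}
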