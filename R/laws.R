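# Empirical "fairness laws": per-subgroup linear relationships between a
# subgroup's share of the training data and its sAUROC. The law is fitted by
# ordinary least squares to per-(proportion, seed) points, validated by
# two-point linear interpolation from the composition extremes (0% and 100%),
# and summarized with Gaussian confidence intervals over seeds. Welch's
# unequal-variance t-test quantifies residual disparity at balanced (50/50)
# composition.

#' Assemble a composition sweep
#'
#' A composition sweep holds one sAUROC value per (category, training
#' proportion, seed): the raw material of a fairness law. `proportion` is
#' the training share of the *second* category (`g1`); a category's own
#' representation is `proportion` for `g1` and `1 - proportion` for `g0`.
#'
#' @param results Data frame with columns `category`, `proportion`, `seed`,
#'   `sauroc` (an `attribute` column is optional and carried through).
#' @param categories Ordered pair `c(g0, g1)`.
#' @param attribute Attribute name label; default taken from `results` or
#'   `"group"`.
#' @return A `composition_sweep` data frame.
#' @export
composition_sweep <- function(results, categories, attribute = NULL) {
  stopifnot(is.data.frame(results), length(categories) == 2)
  required <- c("category", "proportion", "seed", "sauroc")
  missing_cols <- setdiff(required, names(results))
  if (length(missing_cols))
    stop("sweep results are missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.null(attribute))
    attribute <- if ("attribute" %in% names(results))
      results$attribute[1] else "group"
  out <- as.data.frame(results)
  out$attribute <- attribute
  out <- out[, c("attribute", "category", "proportion", "seed", "sauroc")]
  if (any(out$sauroc < 0 | out$sauroc > 1))
    stop("sAUROC values must lie in [0, 1]")
  if (any(out$proportion < 0 | out$proportion > 1))
    stop("proportions must lie in [0, 1]")
  if (!all(out$category %in% categories))
    stop("sweep contains categories outside the declared pair")
  # every (proportion, seed) must cover both categories
  key <- interaction(out$proportion, out$seed, drop = TRUE)
  cover <- tapply(out$category, key, function(x) all(categories %in% x))
  if (!all(cover))
    stop("every (proportion, seed) combination needs a value for each category")
  rownames(out) <- NULL
  structure(out, categories = as.character(categories),
            class = c("composition_sweep", "data.frame"))
}

#' Own-representation axis of a sweep
#'
#' @param sweep A [composition_sweep()].
#' @return Numeric vector: each row's category's own training representation.
#' @export
sweep_representation <- function(sweep) {
  stopifnot(inherits(sweep, "composition_sweep"))
  g1 <- attr(sweep, "categories")[2]
  ifelse(sweep$category == g1, sweep$proportion, 1 - sweep$proportion)
}

#' Read / write a sweep as a long-format delimited table
#'
#' Columns: `attribute, category, proportion, seed, sauroc`.
#'
#' @param sweep A [composition_sweep()].
#' @param path CSV path.
#' @param categories For reading: the ordered pair `(g0, g1)`; with `NULL`
#'   the two categories are taken in sorted order, which is only correct
#'   when that matches the convention the table was written under.
#' @return `write_sweep_table`: `path`, invisibly. `read_sweep_table`: a
#'   [composition_sweep()].
#' @export
write_sweep_table <- function(sweep, path) {
  stopifnot(inherits(sweep, "composition_sweep"))
  out <- as.data.frame(sweep)
  out$sauroc <- sprintf("%.17g", out$sauroc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_table
#' @export
read_sweep_table <- function(path, categories = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(categories)) categories <- sort(unique(tab$category))
  composition_sweep(tab, categories)
}

#' Linear interpolation from the composition extremes
#'
#' Predicts a subgroup's sAUROC at any training representation from the two
#' extreme measurements alone: `(1 - proportion) * y_at_0 + proportion *
#' y_at_1`. Requests outside \[0, 1\] fail; extrapolation must be an explicit
#' caller decision, not a silent one.
#'
#' @param y_at_0,y_at_1 sAUROC measured at 0% and 100% own representation.
#' @param proportion Representation(s) at which to predict, each in \[0, 1\].
#' @return Predicted value(s).
#' @export
interpolate_from_extremes <- function(y_at_0, y_at_1, proportion) {
  if (any(proportion < 0 | proportion > 1))
    stop("proportion outside [0, 1]: extrapolation must be requested explicitly")
  (1 - proportion) * y_at_0 + proportion * y_at_1
}

#' Interpolation error of the two-point fairness law
#'
#' Per seed, predicts every intermediate proportion's sAUROC from that seed's
#' own endpoint values (0% and 100% representation) via
#' [interpolate_from_extremes()], and takes the mean absolute error over the
#' intermediate proportions; reported as mean and sd over seeds.
#'
#' @param sweep A [composition_sweep()].
#' @param category Category whose law to validate.
#' @return List with `mean`, `sd` (NA for a single seed) and `per_seed`.
#' @export
interpolation_mae <- function(sweep, category) {
  stopifnot(inherits(sweep, "composition_sweep"))
  rows <- sweep[sweep$category == category, , drop = FALSE]
  if (nrow(rows) == 0) stop("no sweep rows for category '", category, "'")
  rows$rep <- sweep_representation(sweep)[sweep$category == category]
  per_seed <- vapply(split(rows, rows$seed), function(d) {
    y0 <- d$sauroc[d$rep == 0]
    y1 <- d$sauroc[d$rep == 1]
    if (length(y0) == 0 || length(y1) == 0)
      stop("seed ", d$seed[1], " is missing an endpoint proportion (0 or 1)")
    mid <- d[d$rep > 0 & d$rep < 1, , drop = FALSE]
    if (nrow(mid) == 0)
      stop("no intermediate proportions to validate against")
    pred <- interpolate_from_extremes(mean(y0), mean(y1), mid$rep)
    mean(abs(mid$sauroc - pred))
  }, numeric(1))
  list(mean = mean(per_seed),
       sd = if (length(per_seed) >= 2) stats::sd(per_seed) else NA_real_,
       per_seed = per_seed)
}

#' Fit a subgroup's fairness law
#'
#' Ordinary least squares of sAUROC on the category's own training
#' representation, over all per-(proportion, seed) points, with the Pearson
#' correlation on the same points, per-seed slope/intercept confidence
#' intervals via [gaussian_ci()], and the two-point interpolation MAE when
#' both endpoints are present.
#'
#' @param sweep A [composition_sweep()].
#' @param category Category whose law to fit.
#' @param level Confidence level for the per-seed CIs; default 0.95.
#' @return A `law_fit` object: `slope`, `intercept`, `pearson_r`,
#'   `degenerate` (TRUE when the response has zero variance, in which case
#'   `pearson_r` is reported as 0), `interpolation_mae`,
#'   `interpolation_mae_sd`, and `ci` (a list with `slope` and `intercept`
#'   intervals when at least two seeds are available).
#' @export
fit_law <- function(sweep, category, level = 0.95) {
  stopifnot(inherits(sweep, "composition_sweep"))
  sel <- sweep$category == category
  if (!any(sel)) stop("no sweep rows for category '", category, "'")
  x <- sweep_representation(sweep)[sel]
  y <- sweep$sauroc[sel]
  seeds <- sweep$seed[sel]
  if (length(unique(x)) < 2)
    stop("all proportions identical: slope undefined")

  fit <- stats::lm(y ~ x)
  degenerate <- isTRUE(all.equal(stats::var(y), 0))
  pearson_r <- if (degenerate) 0 else stats::cor(x, y)

  per_seed <- lapply(split(data.frame(x = x, y = y), seeds), function(d) {
    if (length(unique(d$x)) < 2) return(NULL)
    stats::coef(stats::lm(y ~ x, data = d))
  })
  per_seed <- per_seed[!vapply(per_seed, is.null, logical(1))]
  ci <- NULL
  if (length(per_seed) >= 2) {
    slopes <- vapply(per_seed, `[[`, numeric(1), "x")
    intercepts <- vapply(per_seed, `[[`, numeric(1), "(Intercept)")
    ci <- list(slope = gaussian_ci(slopes, level),
               intercept = gaussian_ci(intercepts, level))
  }

  mae <- tryCatch(interpolation_mae(sweep, category), error = function(e) NULL)
  structure(list(category = category,
                 slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 pearson_r = pearson_r,
                 degenerate = degenerate,
                 interpolation_mae = if (is.null(mae)) NA_real_ else mae$mean,
                 interpolation_mae_sd = if (is.null(mae)) NA_real_ else mae$sd,
                 ci = ci,
                 n_points = length(y),
                 n_seeds = length(unique(seeds))),
            class = "law_fit")
}

#' @export
print.law_fit <- function(x, ...) {
  cat(sprintf("Fairness law for '%s': sAUROC = %.4f + %.4f * representation\n",
              x$category, x$intercept, x$slope))
  cat(sprintf("  Pearson r = %.3f%s; interpolation MAE = %s (sd %s); %d points, %d seeds\n",
              x$pearson_r, if (x$degenerate) " (degenerate: flat response)" else "",
              formatC(x$interpolation_mae, digits = 4, format = "f"),
              formatC(x$interpolation_mae_sd, digits = 4, format = "f"),
              x$n_points, x$n_seeds))
  invisible(x)
}

#' Gaussian confidence interval over repeated runs
#'
#' `mean +/- z(level) * sd / sqrt(n)` with the sample standard deviation —
#' the normal approximation used to summarize a metric over independent
#' seeded runs.
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric `c(low, high)`, symmetric about the mean.
#' @export
gaussian_ci <- function(values, level = 0.95) {
  if (length(values) < 2) stop("need at least 2 values for a confidence interval")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  m <- mean(values)
  half <- z * stats::sd(values) / sqrt(length(values))
  c(low = m - half, high = m + half)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom, the
#' significance test used for seed-wise metric comparisons between two
#' subgroups. When both groups are constant the test statistic is undefined;
#' by convention equal constants give `t = 0, p = 1` and unequal constants
#' `p = 0`, both flagged `degenerate`.
#'
#' @param values_a,values_b Numeric vectors, length >= 2 each.
#' @return List with `statistic`, `dof`, `p_value`, `degenerate`.
#' @export
welch_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  eps <- .Machine$double.eps
  if (stats::sd(values_a) <= eps && stats::sd(values_b) <= eps) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(statistic = if (same) 0 else sign(mean(values_a) - mean(values_b)) * Inf,
                dof = NA_real_,
                p_value = if (same) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic),
       dof = unname(tt$parameter),
       p_value = tt$p.value,
       degenerate = FALSE)
}

#' Disparity under balanced training composition
#'
#' At the 50/50 training composition, compares the two categories' sAUROC
#' distributions over seeds: per-category means, their difference
#' (`g1 - g0`), and a Welch test, flagged at the configured alpha. A
#' significant result demonstrates residual unfairness that balanced
#' representation alone cannot remove.
#'
#' @param sweep A [composition_sweep()] containing the 0.5 proportion.
#' @param alpha Significance level; default 0.01.
#' @return A `balanced_disparity` list: `means` (named per category),
#'   `difference`, `test` (see [welch_test()]), `alpha`, `significant`.
#' @export
balanced_disparity_report <- function(sweep, alpha = 0.01) {
  stopifnot(inherits(sweep, "composition_sweep"))
  cats <- attr(sweep, "categories")
  at_half <- sweep[abs(sweep$proportion - 0.5) < 1e-9, , drop = FALSE]
  if (nrow(at_half) == 0)
    stop("sweep does not contain the 0.5 proportion")
  vals <- lapply(cats, function(cat)
    at_half$sauroc[at_half$category == cat][order(at_half$seed[at_half$category == cat])])
  names(vals) <- cats
  means <- vapply(vals, mean, numeric(1))
  test <- welch_test(vals[[cats[2]]], vals[[cats[1]]])
  structure(list(categories = cats,
                 means = means,
                 difference = unname(means[cats[2]] - means[cats[1]]),
                 test = test,
                 alpha = alpha,
                 significant = test$p_value < alpha,
                 n_seeds = length(vals[[1]])),
            class = "balanced_disparity")
}

#' @export
print.balanced_disparity <- function(x, ...) {
  cat(sprintf("Balanced-composition disparity (%s vs %s, %d seeds):\n",
              x$categories[2], x$categories[1], x$n_seeds))
  cat(sprintf("  mean sAUROC: %s = %.4f, %s = %.4f; difference = %+.4f\n",
              x$categories[2], x$means[x$categories[2]],
              x$categories[1], x$means[x$categories[1]], x$difference))
  cat(sprintf("  Welch t = %.3f, dof = %.2f, p = %.4g -> %ssignificant at alpha %.3g\n",
              x$test$statistic, x$test$dof, x$test$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Most group-fair training composition on the grid
#'
#' Returns the grid proportion minimizing the absolute gap between the two
#' categories' mean sAUROC, ties broken toward 0.5 (the balanced
#' composition), then toward the smaller proportion.
#'
#' @param sweep A [composition_sweep()] with at least 2 proportions.
#' @return A single proportion from the sweep's grid.
#' @export
fairest_composition <- function(sweep) {
  stopifnot(inherits(sweep, "composition_sweep"))
  cats <- attr(sweep, "categories")
  grid <- sort(unique(sweep$proportion))
  if (length(grid) < 2) stop("need at least 2 proportions")
  gap <- vapply(grid, function(p) {
    rows <- sweep[abs(sweep$proportion - p) < 1e-12, , drop = FALSE]
    abs(mean(rows$sauroc[rows$category == cats[2]]) -
          mean(rows$sauroc[rows$category == cats[1]]))
  }, numeric(1))
  ord <- order(gap, abs(grid - 0.5), grid)
  grid[ord[1]]
}
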