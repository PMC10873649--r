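# Subgroup ROC, sAUROC, naive AUROC, FPR@minTPR, score summaries.

test_that("subgroup ROC traces the hand-derived operating points", {
  # population positives {0.9, 0.8, 0.4}; subgroup-a negatives {0.7, 0.3}
  co <- make_cohort(scores = c(0.9, 0.8, 0.4, 0.7, 0.3),
                    labels = c(1, 1, 1, 0, 0),
                    categories = c("b", "a", "a", "a", "a"))
  cv <- subgroup_roc(co, "g", "a")
  pts <- cbind(cv$fpr_subgroup, cv$tpr_population)
  for (expected in list(c(0, 0), c(0, 2 / 3), c(1 / 2, 2 / 3),
                        c(1 / 2, 1), c(1, 1))) {
    hit <- any(abs(pts[, 1] - expected[1]) < 1e-12 &
                 abs(pts[, 2] - expected[2]) < 1e-12)
    expect_true(hit, label = sprintf("curve passes through (%g, %g)",
                                     expected[1], expected[2]))
  }
  expect_equal(sauroc(cv), 5 / 6, tolerance = 1e-12)
  expect_equal(cv$n_pop_positives, 3L)
  expect_equal(cv$n_sub_negatives, 2L)
  # non-decreasing along the sweep, anchored on [0, 1]
  expect_true(all(diff(cv$tpr_population) >= 0))
  expect_true(all(diff(cv$fpr_subgroup) >= 0))
  expect_true(all(diff(cv$thresholds) < 0))
})

test_that("all-tied scores collapse the curve to its two anchors", {
  co <- make_cohort(scores = rep(0.5, 6), labels = c(1, 1, 0, 0, 1, 0))
  cv <- subgroup_roc(co, "g", "a")
  expect_equal(length(cv$thresholds), 2L)
  expect_equal(cv$fpr_subgroup, c(0, 1))
  expect_equal(cv$tpr_population, c(0, 1))
  expect_equal(sauroc(cv), 0.5)
})

test_that("sAUROC equals the pairwise Mann-Whitney statistic on tied cohorts", {
  set.seed(101)
  for (k in 1:200) {
    co <- random_tied_cohort()
    got <- sauroc(subgroup_roc(co, "g", "a"))
    want <- mw_statistic(co$score[co$label == 1],
                         co$score[co$label == 0 & co$g == "a"])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("perfect separation gives sAUROC 1 and ties-only gives 0.5", {
  co <- make_cohort(scores = c(0.9, 0.8, 0.2, 0.1), labels = c(1, 1, 0, 0))
  expect_equal(sauroc(subgroup_roc(co, "g", "a")), 1)
})

test_that("naive AUROC matches hand-counted pair wins within the subgroup", {
  # subgroup positives {0.6, 0.2}, negatives {0.4, 0.5}: 2 of 4 pairs win
  co <- make_cohort(scores = c(0.6, 0.2, 0.4, 0.5), labels = c(1, 1, 0, 0))
  expect_equal(naive_auroc(co, "g", "a"), 0.5, tolerance = 1e-12)
  co2 <- make_cohort(scores = c(0.9, 0.1), labels = c(1, 0))
  expect_equal(naive_auroc(co2, "g", "a"), 1)
})

test_that("when the subgroup is the whole population, sAUROC and naive AUROC coincide", {
  set.seed(7)
  for (k in 1:50) {
    co <- random_tied_cohort()
    whole <- make_cohort(co$score, co$label)  # single category = whole cohort
    if (sum(whole$label == 1) == 0) next
    expect_identical(sauroc(subgroup_roc(whole, "g", "a")),
                     naive_auroc(whole, "g", "a"))
  }
})

test_that("metrics are invariant to strictly increasing score transforms", {
  set.seed(33)
  co <- random_tied_cohort()
  trans <- function(x) exp(2 * x) + x          # strictly increasing
  co2 <- make_cohort(trans(co$score), co$label, co$g)
  expect_equal(sauroc(subgroup_roc(co, "g", "a")),
               sauroc(subgroup_roc(co2, "g", "a")), tolerance = 1e-12)
  expect_equal(fpr_at_min_tpr(co, "g", 0.9), fpr_at_min_tpr(co2, "g", 0.9),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("negating scores complements sAUROC; negate-and-swap is the identity", {
  set.seed(91)
  for (k in 1:25) {
    n <- 30
    sc <- stats::runif(n)                      # continuous: no ties
    lab <- stats::rbinom(n, 1, 0.5)
    if (sum(lab) == 0 || sum(lab == 0) == 0) next
    whole <- make_cohort(sc, lab)
    base <- sauroc(subgroup_roc(whole, "g", "a"))
    # reversing the score direction turns every pair win into a loss
    negated <- make_cohort(-sc, lab)
    expect_equal(sauroc(subgroup_roc(negated, "g", "a")), 1 - base,
                 tolerance = 1e-12)
    # negating AND swapping labels composes two complements: the identity
    both <- make_cohort(-sc, 1 - lab)
    expect_equal(sauroc(subgroup_roc(both, "g", "a")), base,
                 tolerance = 1e-12)
  }
})

test_that("FPR at a minimum population TPR uses one shared threshold", {
  # min_tpr = 1: positives {0.9, 0.2} force t* = 0.2
  co <- make_cohort(scores = c(0.9, 0.2, 0.5, 0.1, 0.1),
                    labels = c(1, 1, 0, 0, 0),
                    categories = c("A", "B", "A", "A", "B"))
  f <- fpr_at_min_tpr(co, "g", min_tpr = 1.0)
  expect_equal(attr(f, "threshold"), 0.2)
  expect_equal(unname(f["A"]), 0.5)
  expect_equal(unname(f["B"]), 0.0)

  # tiny min_tpr with a unique maximal positive: nothing else is flagged
  co2 <- make_cohort(scores = c(0.99, 0.5, 0.4, 0.3),
                     labels = c(1, 0, 0, 0),
                     categories = c("A", "A", "B", "B"))
  f2 <- fpr_at_min_tpr(co2, "g", min_tpr = 0.01)
  expect_equal(unname(f2), c(0, 0), ignore_attr = TRUE)
})

test_that("raising a subgroup's negative scores cannot lower its FPR at fixed threshold", {
  set.seed(5)
  co <- random_tied_cohort()
  f1 <- fpr_at_min_tpr(co, "g", 0.9)
  t_star <- attr(f1, "threshold")
  shifted <- co$score
  bump <- co$label == 0 & co$g == "a"
  shifted[bump] <- shifted[bump] + 0.25
  co2 <- make_cohort(shifted, co$label, co$g)
  fpr_a_after <- mean(co2$score[bump] >= t_star)
  expect_gte(fpr_a_after, f1[["a"]])
})

test_that("score summaries report per-cell means and omit empty cells", {
  co <- make_cohort(scores = c(1, 3, 2, 5),
                    labels = c(0, 0, 0, 1),
                    categories = c("x", "x", "y", "x"))
  s <- score_summary(co, "g")
  expect_equal(s$mean_score[s$category == "x" & s$label == 0], 2)
  expect_equal(s$mean_score[s$category == "y" & s$label == 0], 2)
  expect_false(any(s$category == "y" & s$label == 1))  # absent, not zero
})

test_that("empty strata raise errors that name the stratum", {
  co <- make_cohort(scores = c(0.2, 0.4), labels = c(0, 0),
                    categories = c("a", "a"))
  expect_error(subgroup_roc(co, "g", "a"), "no positive samples")
  co2 <- make_cohort(scores = c(0.2, 0.4), labels = c(1, 1),
                     categories = c("a", "a"))
  expect_error(subgroup_roc(co2, "g", "a"), "g=a")
  expect_error(naive_auroc(co, "g", "a"), "no positive")
  expect_error(fpr_at_min_tpr(co2, "g", 0.9), "no negative")
  expect_error(subgroup_roc(co, "nope", "a"), "not a declared")
})

test_that("subgroup_metrics assembles one consistent row per category", {
  set.seed(12)
  cfg <- generator_config(n_per_cell = 150, seed = 4)
  co <- generate_cohort(cfg, c(female = 0.5, male = 0.5))
  tab <- subgroup_metrics(co, "sex", min_tpr = 0.95)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$sauroc >= 0 & tab$sauroc <= 1))
  expect_true(all(tab$fpr_at_min_tpr >= 0 & tab$fpr_at_min_tpr <= 1))
  expect_equal(tab$n_sub_neg, c(150L, 150L))
  for (i in 1:2)
    expect_equal(tab$sauroc[i],
                 sauroc(subgroup_roc(co, "sex", tab$category[i])))
})
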