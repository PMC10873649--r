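# Independent oracles and fixture builders used across the suite.

# Tie-corrected Mann-Whitney statistic: fraction of (positive, negative)
# pairs with positive > negative, ties counting 1/2. Brute-force over all
# pairs; deliberately independent of the package's threshold-sweep path.
mw_statistic <- function(pos, neg) {
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# Standard AUROC via the rank-sum formula; independent of the trapezoid path.
rank_auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

# Small random cohort with heavy ties (scores on a 0.1 grid), guaranteed to
# have >= 1 population positive and >= 1 negative in category "a".
random_tied_cohort <- function(n_max = 40) {
  repeat {
    n <- sample(5:n_max, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    lab <- stats::rbinom(n, 1, 0.4)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (sum(lab) >= 1 && sum(lab == 0 & g == "a") >= 1) break
  }
  scored_cohort(data.frame(sample_id = seq_len(n), patient_id = seq_len(n),
                           score = sc, label = lab, g = g),
                attributes = "g")
}

# Cohort from explicit score vectors; category defaults to one group.
make_cohort <- function(scores, labels, categories = NULL,
                        attribute = "g") {
  n <- length(scores)
  if (is.null(categories)) categories <- rep("a", n)
  d <- data.frame(sample_id = seq_len(n), patient_id = seq_len(n),
                  score = scores, label = labels)
  d[[attribute]] <- categories
  scored_cohort(d, attributes = attribute)
}

# Toy metadata pool: `per_cell` single-image patients for every
# (category x label) cell of a binary attribute.
toy_metadata <- function(per_cell, categories = c("g0", "g1"),
                         attribute = "grp") {
  grid <- expand.grid(category = categories, label = c(0L, 1L),
                      idx = seq_len(per_cell), stringsAsFactors = FALSE)
  d <- data.frame(
    sample_id = sprintf("s%04d", seq_len(nrow(grid))),
    patient_id = sprintf("p%04d", seq_len(nrow(grid))),
    label = grid$label, stringsAsFactors = FALSE)
  d[[attribute]] <- grid$category
  d
}

# Toy metadata over two binary attributes, `per_cell` single-image patients
# per (comboA x comboB x label) cell.
toy_metadata2 <- function(per_cell,
                          cats_a = c("a1", "a2"), cats_b = c("b1", "b2")) {
  grid <- expand.grid(A = cats_a, B = cats_b, label = c(0L, 1L),
                      idx = seq_len(per_cell), stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%04d", seq_len(nrow(grid))),
             patient_id = sprintf("p%04d", seq_len(nrow(grid))),
             label = grid$label, A = grid$A, B = grid$B,
             stringsAsFactors = FALSE)
}

# Long-format sweep rows for a pair of categories whose sAUROC follows
# given functions of the g1 proportion, plus optional noise.
synthetic_sweep <- function(props, seeds, f_g0, f_g1, noise_sd = 0,
                            categories = c("g0", "g1")) {
  rows <- expand.grid(proportion = props, seed = seeds,
                      stringsAsFactors = FALSE)
  out <- rbind(
    data.frame(category = categories[1], proportion = rows$proportion,
               seed = rows$seed,
               sauroc = f_g0(rows$proportion) +
                 stats::rnorm(nrow(rows), 0, noise_sd)),
    data.frame(category = categories[2], proportion = rows$proportion,
               seed = rows$seed,
               sauroc = f_g1(rows$proportion) +
                 stats::rnorm(nrow(rows), 0, noise_sd)))
  composition_sweep(out, categories)
}
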