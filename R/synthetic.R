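# Synthetic anomaly-score generator.
#
# Emulates the statistical signature of an anomaly detector trained on a
# composition-controlled cohort: a subgroup's scores rise linearly as its
# training representation shrinks. Each sample of category s with disease
# label y receives
#
#     score = sum_attributes [ mu_s + beta_s * (1 - r_s) ] + delta * y + eps,
#     eps ~ Normal(0, sigma^2),
#
# where r_s is the subgroup's share of the training data, mu_s its baseline
# score level ("hardness"), beta_s >= 0 its sensitivity to missing
# representation, delta > 0 the disease shift and sigma the noise scale.
# The Gaussian noise buys closed-form oracles: with a single attribute,
# equal mu and beta = 0, every subgroup's expected sAUROC is
# Phi(delta / (sigma * sqrt(2))).

#' Configuration of the synthetic score generator
#'
#' Defaults define the package's reference simulation conditions: one binary
#' attribute, equal baseline means, representation sensitivity `beta = 0.5`,
#' disease shift and noise scale 1 (so score shifts are expressed in noise
#' units), 2000 normal samples per category cell, prevalence 0.5.
#'
#' @param attributes Named list of category vectors, e.g.
#'   `list(sex = c("female", "male"))`; at least 2 categories per attribute.
#' @param base_mean Named per-category baseline score `mu_s`; unnamed scalar
#'   recycles to every category; default 0.
#' @param sensitivity Named per-category representation sensitivity
#'   `beta_s >= 0` (score units per unit of *missing* representation);
#'   unnamed scalar recycles; default 0.5.
#' @param disease_shift Additive score shift `delta > 0` for diseased
#'   samples; default 1.
#' @param noise_sd Gaussian noise sd `sigma > 0`; default 1.
#' @param n_per_cell Normal samples per category-combination cell; diseased
#'   samples per cell are `round_half_up(n_per_cell * prevalence /
#'   (1 - prevalence))`, so prevalence 0.5 gives equal cells; default 2000.
#' @param prevalence Diseased fraction, in (0, 1); default 0.5.
#' @param seed Integer seed; identical config and seed reproduce the cohort
#'   byte-for-byte.
#' @return A `generator_config` object.
#' @export
generator_config <- function(attributes = list(sex = c("female", "male")),
                             base_mean = 0, sensitivity = 0.5,
                             disease_shift = 1, noise_sd = 1,
                             n_per_cell = 2000, prevalence = 0.5,
                             seed = 1L) {
  if (!is.list(attributes) || is.null(names(attributes)) ||
      any(names(attributes) == ""))
    stop("`attributes` must be a named list of category vectors")
  if (any(lengths(attributes) < 2))
    stop("every attribute needs at least 2 categories")
  cats <- unlist(attributes, use.names = FALSE)
  if (anyDuplicated(cats))
    stop("category names must be unique across attributes")

  expand_param <- function(x, what, lower_ok) {
    if (is.null(names(x)) && length(x) == 1)
      x <- stats::setNames(rep(x, length(cats)), cats)
    missing_cats <- setdiff(cats, names(x))
    if (length(missing_cats))
      stop(what, " missing for categories: ",
           paste(missing_cats, collapse = ", "))
    if (!lower_ok && any(x[cats] < 0)) stop(what, " must be >= 0")
    x[cats]
  }
  base_mean <- expand_param(base_mean, "base_mean", lower_ok = TRUE)
  sensitivity <- expand_param(sensitivity, "sensitivity", lower_ok = FALSE)

  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (disease_shift < 0) stop("disease_shift must be >= 0")
  if (n_per_cell < 1) stop("n_per_cell must be >= 1")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")

  structure(list(attributes = attributes,
                 base_mean = base_mean,
                 sensitivity = sensitivity,
                 disease_shift = disease_shift,
                 noise_sd = noise_sd,
                 n_per_cell = as.integer(n_per_cell),
                 prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a scored cohort from the linear representation-shift mechanism
#'
#' @param config A [generator_config()].
#' @param training_proportions Named numeric vector mapping every category to
#'   its training representation `r` in \[0, 1\]; within each attribute the
#'   proportions must sum to 1.
#' @return A [scored_cohort()] with one row per sample (one sample per
#'   synthetic patient) and the configured attributes as columns.
#' @examples
#' cfg <- generator_config(n_per_cell = 100, seed = 7)
#' cohort <- generate_cohort(cfg, c(female = 0.3, male = 0.7))
#' @export
generate_cohort <- function(config, training_proportions) {
  stopifnot(inherits(config, "generator_config"))
  cats <- unlist(config$attributes, use.names = FALSE)
  missing_cats <- setdiff(cats, names(training_proportions))
  if (length(missing_cats))
    stop("training_proportions missing for categories: ",
         paste(missing_cats, collapse = ", "))
  if (any(training_proportions < 0 | training_proportions > 1))
    stop("training proportions must lie in [0, 1]")
  for (a in names(config$attributes)) {
    s <- sum(training_proportions[config$attributes[[a]]])
    if (abs(s - 1) > 1e-8)
      stop("training proportions for attribute '", a, "' sum to ", s,
           ", not 1")
  }

  combos <- expand.grid(config$attributes, stringsAsFactors = FALSE)
  n_neg <- config$n_per_cell
  n_pos <- as.integer(round_half_up(
    config$n_per_cell * config$prevalence / (1 - config$prevalence)))

  rows <- list()
  for (i in seq_len(nrow(combos))) {
    combo <- combos[i, , drop = FALSE]
    shift <- sum(vapply(names(config$attributes), function(a) {
      cat <- combo[[a]]
      config$base_mean[[cat]] +
        config$sensitivity[[cat]] * (1 - training_proportions[[cat]])
    }, numeric(1)))
    cell <- data.frame(label = rep(c(0L, 1L), c(n_neg, n_pos)))
    cell$mean <- shift + config$disease_shift * cell$label
    for (a in names(config$attributes)) cell[[a]] <- combo[[a]]
    rows[[i]] <- cell
  }
  df <- do.call(rbind, rows)
  df$score <- withr::with_seed(config$seed,
                               stats::rnorm(nrow(df), df$mean,
                                            config$noise_sd))
  df$sample_id <- sprintf("S%07d", seq_len(nrow(df)))
  df$patient_id <- df$sample_id
  df$mean <- NULL
  scored_cohort(df, attributes = names(config$attributes))
}

# deterministic per-(grid point, seed) stream seed below 2^31
.derive_seed <- function(base, i, j) {
  as.integer((as.numeric(base) * 100003 + i * 1009 + j * 97) %% 2147483647)
}

#' Run a composition sweep through the generator and the sAUROC metric
#'
#' For every proportion `p` on the grid and every run seed, generates a
#' cohort whose two categories carry training representations `(1 - p, p)`,
#' evaluates each category's sAUROC, and assembles the results into a
#' [composition_sweep()]. Per-run seeds are derived deterministically from
#' the config's base seed, so grid points are independent yet reproducible.
#'
#' @param config A [generator_config()] with exactly one binary attribute.
#' @param proportions Grid of `g1` training fractions; default
#'   `seq(0, 1, by = 0.1)`.
#' @param n_seeds Number of independent runs per grid point; default 10.
#' @return A [composition_sweep()].
#' @export
run_sweep <- function(config, proportions = seq(0, 1, by = 0.1),
                      n_seeds = 10) {
  stopifnot(inherits(config, "generator_config"))
  if (length(config$attributes) != 1 || length(config$attributes[[1]]) != 2)
    stop("run_sweep needs a config with exactly one binary attribute")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  attr_name <- names(config$attributes)
  cats <- config$attributes[[1]]

  rows <- list()
  for (i in seq_along(proportions)) {
    p <- proportions[i]
    props <- stats::setNames(c(1 - p, p), cats)
    for (j in seq_len(n_seeds)) {
      cfg <- config
      cfg$seed <- .derive_seed(config$seed, i, j)
      cohort <- generate_cohort(cfg, props)
      for (cat in cats) {
        rows[[length(rows) + 1]] <- data.frame(
          attribute = attr_name, category = cat, proportion = p,
          seed = j,
          sauroc = sauroc(subgroup_roc(cohort, attr_name, cat)),
          stringsAsFactors = FALSE)
      }
    }
  }
  composition_sweep(do.call(rbind, rows), categories = cats,
                    attribute = attr_name)
}
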