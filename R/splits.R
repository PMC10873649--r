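# Composition-controlled, patient-disjoint dataset construction.
#
# Workflow mirrors the screening-study design the package audits: consolidate
# diagnostic labels into normal/diseased, bin continuous age into two
# well-separated groups, carve out balanced prevalence-corrected validation
# and test sets first, then draw constant-size training sets from the
# remaining normal data at every requested composition of the protected
# attribute. All sampling is at patient granularity, so no patient ever
# appears in more than one of {train, val, test}.

# deterministic round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Consolidate raw diagnostic labels into a binary disease label
#'
#' A sample is normal (0) iff its label set contains only the no-finding
#' marker(s); it is diseased (1) iff at least one other diagnostic label is
#' present. A sample with no labels at all is ambiguous and raises an error
#' rather than being silently assigned.
#'
#' @param raw_labels Either a list with one character vector of label names
#'   per sample, or a character vector in which each element holds one
#'   sample's labels separated by `sep`.
#' @param normal_markers Label names (case-insensitive) marking the absence
#'   of findings. Default `c("no finding", "normal")`.
#' @param sep Separator used when `raw_labels` is a character vector.
#' @return Integer vector of 0/1 labels.
#' @examples
#' consolidate_label(list(c("no finding"), c("pneumonia", "edema")))
#' consolidate_label(c("normal", "pneumonia|edema"))
#' @export
consolidate_label <- function(raw_labels,
                              normal_markers = c("no finding", "normal"),
                              sep = "|") {
  if (is.character(raw_labels))
    raw_labels <- strsplit(raw_labels, sep, fixed = TRUE)
  if (!is.list(raw_labels))
    stop("`raw_labels` must be a list of character vectors or a character vector")
  markers <- tolower(trimws(normal_markers))
  vapply(seq_along(raw_labels), function(i) {
    labs <- tolower(trimws(as.character(raw_labels[[i]])))
    labs <- labs[labs != ""]
    if (length(labs) == 0)
      stop("sample ", i, " carries neither a normal marker nor any ",
           "diagnostic label: ambiguous record")
    if (any(!labs %in% markers)) 1L else 0L
  }, integer(1))
}

#' Bin age into young / old / excluded
#'
#' Ages up to 31 years are `young`, ages of 61 years and above are `old`;
#' the centre group is `excluded` so that the two retained groups are
#' separated by a clear age gap.
#'
#' @param age Numeric vector of ages in years (non-negative).
#' @return Character vector in `{"young", "old", "excluded"}`.
#' @export
bin_age <- function(age) {
  if (any(is.na(age)) || any(age < 0))
    stop("ages must be non-negative and non-missing")
  ifelse(age <= 31, "young", ifelse(age >= 61, "old", "excluded"))
}

#' Declarative specification of a composition-controlled split
#'
#' @param attribute Protected-attribute column name.
#' @param categories Ordered pair `c(g0, g1)`; `proportions` refer to the
#'   `g1` fraction of the training set.
#' @param proportions Grid of `g1` training fractions in \[0, 1\];
#'   default `seq(0, 1, by = 0.1)`.
#' @param n_train Training-set size, held constant across the whole grid.
#' @param n_val,n_test Validation / test set sizes.
#' @param prevalence Diseased fraction of val and test sets, in (0, 1);
#'   default 0.5 so that threshold-based metrics are not confounded by
#'   prevalence shifts between subgroups.
#' @param seed Integer seed; the same spec and seed reproduce the split
#'   byte-for-byte.
#' @return A `split_spec` object.
#' @export
split_spec <- function(attribute, categories,
                       proportions = seq(0, 1, by = 0.1),
                       n_train, n_val, n_test,
                       prevalence = 0.5, seed = 1L) {
  stopifnot(length(categories) == 2, !anyDuplicated(categories))
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  stopifnot(n_train >= 1, n_val >= 0, n_test >= 1)
  structure(list(attribute = attribute,
                 categories = as.character(categories),
                 proportions = as.numeric(proportions),
                 n_train = as.integer(n_train),
                 n_val = as.integer(n_val),
                 n_test = as.integer(n_test),
                 prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# per-(category x label) cell size for an evaluation set of n samples
.cell_need <- function(n, prevalence, n_categories, label) {
  share <- if (label == 1L) prevalence else 1 - prevalence
  need <- n * share / n_categories
  if (abs(need - round(need)) > 1e-9)
    stop("set size ", n, " with prevalence ", prevalence,
         " does not divide evenly over ", n_categories,
         " categories for label ", label)
  as.integer(round(need))
}

# Greedily take `need` samples from the rows of `pool` (already restricted to
# one cell), at patient granularity: patients are drawn in random order and
# every drawn patient is retired globally, with the last patient's images
# capped at the remaining need. Relies on the caller's RNG state.
.take_cell <- function(pool, need, used_patients, cell_name) {
  avail <- pool[!(pool$patient_id %in% used_patients), , drop = FALSE]
  avail <- avail[order(avail$patient_id, avail$sample_id), , drop = FALSE]
  patients <- unique(avail$patient_id)
  if (length(patients)) patients <- sample(patients)
  taken <- character(0)
  for (p in patients) {
    if (length(taken) >= need) break
    imgs <- avail$sample_id[avail$patient_id == p]
    taken <- c(taken, imgs[seq_len(min(length(imgs), need - length(taken)))])
    used_patients <- c(used_patients, p)
  }
  if (length(taken) < need)
    stop("cell ", cell_name, ": need ", need, " samples but only ",
         length(taken), " available at patient granularity")
  list(ids = taken, used_patients = used_patients)
}

.check_metadata <- function(metadata, attribute) {
  required <- c("sample_id", "patient_id", "label", attribute)
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$patient_id <- as.character(metadata$patient_id)
  metadata$label <- as.integer(metadata$label)
  metadata
}

#' Build balanced validation and test sets
#'
#' Validation and test sets are drawn first, each with exactly
#' `prevalence * n` diseased and `(1 - prevalence) * n` normal samples and
#' equal counts per protected category within each label class. Sampling is
#' at patient granularity: all retained images of a chosen patient go to the
#' same set, and used patients are retired from the remaining pool. Samples
#' whose attribute value falls outside the spec's two categories are dropped
#' before splitting.
#'
#' @param metadata Data frame with `sample_id`, `patient_id`, consolidated
#'   binary `label`, and the spec's attribute column.
#' @param spec A [split_spec()].
#' @return List with `val_ids`, `test_ids` (character vectors of sample ids)
#'   and `pool` (the remaining metadata rows, patient-disjoint from both).
#' @export
make_eval_sets <- function(metadata, spec) {
  stopifnot(inherits(spec, "split_spec"))
  metadata <- .check_metadata(metadata, spec$attribute)
  metadata <- metadata[metadata[[spec$attribute]] %in% spec$categories, ,
                       drop = FALSE]
  withr::with_seed(spec$seed, {
    used <- character(0)
    sets <- list()
    for (set_name in c("val", "test")) {
      n_set <- if (set_name == "val") spec$n_val else spec$n_test
      ids <- character(0)
      if (n_set > 0) {
        for (cat in spec$categories) {
          for (lab in c(1L, 0L)) {
            need <- .cell_need(n_set, spec$prevalence, 2L, lab)
            cell <- metadata[metadata[[spec$attribute]] == cat &
                               metadata$label == lab, , drop = FALSE]
            res <- .take_cell(cell, need, used,
                              paste0(set_name, " ", spec$attribute, "=", cat,
                                     " label=", lab))
            ids <- c(ids, res$ids)
            used <- res$used_patients
          }
        }
      }
      sets[[set_name]] <- sort(ids)
    }
    pool <- metadata[!(metadata$patient_id %in% used), , drop = FALSE]
    rownames(pool) <- NULL
    list(val_ids = sets$val, test_ids = sets$test, pool = pool)
  })
}

#' Draw the composition-swept training sets
#'
#' For every proportion `p` in the spec's grid, draws a training set of
#' exactly `n_train` normal samples with `round_half_up(p * n_train)` from
#' category `g1` and the remainder from `g0`, sampled at patient granularity
#' from the pool left over by [make_eval_sets()]. The pool is filtered to
#' consolidated-normal samples internally, so training sets are always
#' label-pure. Each proportion draws independently from the pool (training
#' sets of different proportions may share patients with each other, never
#' with val/test).
#'
#' @param pool Metadata data frame (e.g. `$pool` from [make_eval_sets()]).
#' @param spec A [split_spec()].
#' @return Named list mapping each proportion (formatted via `format()`) to a
#'   sorted character vector of sample ids.
#' @export
make_train_sweep <- function(pool, spec) {
  stopifnot(inherits(spec, "split_spec"))
  pool <- .check_metadata(pool, spec$attribute)
  pool <- pool[pool$label == 0L &
                 pool[[spec$attribute]] %in% spec$categories, , drop = FALSE]
  g0 <- spec$categories[1]
  g1 <- spec$categories[2]
  out <- vector("list", length(spec$proportions))
  names(out) <- vapply(spec$proportions, format, character(1))
  for (i in seq_along(spec$proportions)) {
    p <- spec$proportions[i]
    n1 <- as.integer(round_half_up(p * spec$n_train))
    n0 <- spec$n_train - n1
    seed_i <- as.integer((as.numeric(spec$seed) + 7919 * i) %% 2147483647)
    out[[i]] <- withr::with_seed(seed_i, {
      used <- character(0)
      ids <- character(0)
      for (cfg in list(list(cat = g0, need = n0), list(cat = g1, need = n1))) {
        if (cfg$need == 0) next
        cell <- pool[pool[[spec$attribute]] == cfg$cat, , drop = FALSE]
        res <- .take_cell(cell, cfg$need, used,
                          paste0("train p=", p, " ", spec$attribute, "=",
                                 cfg$cat))
        ids <- c(ids, res$ids)
        used <- res$used_patients
      }
      sort(ids)
    })
  }
  out
}

#' Build intersectional test sets and the leftover training pool
#'
#' One test set per combination of categories of the two attributes, each
#' internally balanced in labels at the requested prevalence and sampled at
#' patient granularity (patients retired globally across all sets). The
#' remaining normal samples form the uncontrolled training pool, which
#' therefore approximates the source population's attribute composition.
#'
#' @param metadata Data frame with `sample_id`, `patient_id`, `label`, and
#'   both attribute columns.
#' @param attributes Character pair of attribute names.
#' @param n_per_set Samples per intersectional test set.
#' @param prevalence Diseased fraction of each test set; default 0.5.
#' @param seed Integer seed.
#' @return List with `test_sets` (named list, one sorted id vector per
#'   `catA.catB` combination) and `train_pool` (remaining normal metadata
#'   rows).
#' @export
make_intersectional_test_sets <- function(metadata, attributes, n_per_set,
                                          prevalence = 0.5, seed = 1L) {
  stopifnot(length(attributes) == 2)
  metadata <- .check_metadata(metadata, attributes[1])
  metadata <- .check_metadata(metadata, attributes[2])
  cats_a <- sort(unique(metadata[[attributes[1]]]))
  cats_b <- sort(unique(metadata[[attributes[2]]]))
  n_pos <- as.integer(round_half_up(prevalence * n_per_set))
  n_neg <- as.integer(n_per_set) - n_pos
  withr::with_seed(as.integer(seed), {
    used <- character(0)
    test_sets <- list()
    for (a in cats_a) {
      for (b in cats_b) {
        ids <- character(0)
        for (cfg in list(list(lab = 1L, need = n_pos),
                         list(lab = 0L, need = n_neg))) {
          cell <- metadata[metadata[[attributes[1]]] == a &
                             metadata[[attributes[2]]] == b &
                             metadata$label == cfg$lab, , drop = FALSE]
          res <- .take_cell(cell, cfg$need, used,
                            paste0(attributes[1], "=", a, " ",
                                   attributes[2], "=", b,
                                   " label=", cfg$lab))
          ids <- c(ids, res$ids)
          used <- res$used_patients
        }
        test_sets[[paste(a, b, sep = ".")]] <- sort(ids)
      }
    }
    pool <- metadata[metadata$label == 0L &
                       !(metadata$patient_id %in% used), , drop = FALSE]
    rownames(pool) <- NULL
    list(test_sets = test_sets, train_pool = pool)
  })
}

#' Realized composition of a set of splits
#'
#' Counts samples per category and label in each emitted set; useful for the
#' JSON provenance summary written next to split manifests.
#'
#' @param metadata The metadata the splits were drawn from.
#' @param sets Named list of sample-id vectors.
#' @param attribute Attribute to tabulate.
#' @return Data frame with columns `set`, `category`, `label`, `n`.
#' @export
split_composition <- function(metadata, sets, attribute) {
  metadata <- .check_metadata(metadata, attribute)
  rows <- lapply(names(sets), function(nm) {
    sub <- metadata[metadata$sample_id %in% sets[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    agg <- stats::aggregate(sub$sample_id,
                            by = list(category = sub[[attribute]],
                                      label = sub$label),
                            FUN = length)
    data.frame(set = nm, category = agg$category, label = agg$label,
               n = as.integer(agg$x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
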