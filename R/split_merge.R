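#' Split a labelled reference into training and test halves
#'
#' When two or more subjects are present, whole subjects are assigned to each
#' half so that the achieved training-cell fraction is as close as possible to
#' `fraction` — subject-level splitting preserves the between-donor expression
#' heterogeneity that makes deconvolution hard, which cell-level splitting
#' would average away. With a single subject, cells are split stratified by
#' cell type instead.
#'
#' @param data a `LabeledCounts` object with at least 2 cells.
#' @param fraction target fraction of cells in the training half, in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return A list of class `SplitResult` with `LabeledCounts` elements
#'   `train` and `test`; cell sets are disjoint and exhaustive, gene sets
#'   identical.
#' @examples
#' lc <- make_synthetic(synthetic_spec(n_genes = 40, seed = 1))$data
#' sp <- split_train_test(lc, 0.5, seed = 7)
#' c(train = n_cells(sp$train), test = n_cells(sp$test))
#' @export
split_train_test <- function(data, fraction = 0.5, seed = 1) {
  stopifnot(inherits(data, "LabeledCounts"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n_cells(data) < 2) stop("need at least 2 cells to split")

  subjects <- unique(data$subject)
  with_local_seed(seed, {
    if (length(subjects) >= 2) {
      train_cells <- subject_level_split(data, fraction, subjects)
    } else {
      train_cells <- stratified_cell_split(data, fraction)
    }
  })
  test_cells <- setdiff(cell_ids(data), train_cells)
  if (length(train_cells) == 0 || length(test_cells) == 0)
    stop("fraction yields an empty train or test half")
  res <- list(train = subset_counts(data, cells = train_cells),
              test = subset_counts(data, cells = test_cells))
  class(res) <- "SplitResult"
  res
}

# Assign whole subjects to train, matching the target cell fraction as
# closely as possible. Subsets are enumerated when few subjects exist;
# ties are broken by a seeded random preference so the choice is unbiased
# but reproducible.
subject_level_split <- function(data, fraction, subjects) {
  sizes <- table(data$subject)[subjects]
  total <- sum(sizes)
  ns <- length(subjects)
  pref <- sample(ns)  # seeded tie-break order
  if (ns <= 16) {
    best <- NULL; best_err <- Inf
    for (code in seq_len(2^ns - 2)) {
      take <- as.logical(bitwAnd(code, 2^(seq_len(ns) - 1)))
      err <- abs(sum(sizes[take]) / total - fraction)
      key <- sum(2^(pref[take] - 1))  # deterministic random tie-break
      if (err < best_err - 1e-12 ||
          (abs(err - best_err) <= 1e-12 && !is.null(best) && key < best$key)) {
        best <- list(take = take, key = key); best_err <- err
      }
    }
    chosen <- subjects[best$take]
  } else {
    ord <- order(pref)
    cum <- cumsum(sizes[ord]) / total
    k <- which.min(abs(cum - fraction))
    k <- max(1, min(ns - 1, k))
    chosen <- subjects[ord][seq_len(k)]
  }
  cell_ids(data)[data$subject %in% chosen]
}

# Per-cell-type stratified split for single-subject data.
stratified_cell_split <- function(data, fraction) {
  ids <- cell_ids(data)
  train <- character(0)
  for (ty in unique(data$cell_type)) {
    pool <- ids[data$cell_type == ty]
    k <- round(fraction * length(pool))
    k <- max(0, min(length(pool), k))
    train <- c(train, sample(pool, k))
  }
  # keep original cell order within the halves
  ids[ids %in% train]
}

#' Append generated cells to a reference as a new case
#'
#' Generated cells are appended to the reference matrix as an additional,
#' independent reference subject. Gene sets must be identical and in the same
#' order; colliding cell identifiers in the generated set are uniquified.
#'
#' @param reference,generated `LabeledCounts` over the same ordered gene set.
#' @param case_label subject label for the generated cells; must not collide
#'   with an existing subject.
#' @return A `LabeledCounts` with the generated cells appended.
#' @export
merge_references <- function(reference, generated, case_label = "augmented") {
  stopifnot(inherits(reference, "LabeledCounts"),
            inherits(generated, "LabeledCounts"))
  if (!identical(gene_ids(reference), gene_ids(generated)))
    stop("gene sets differ or are ordered differently")
  if (case_label %in% unique(reference$subject))
    stop("case_label collides with an existing subject: ", case_label)
  if (n_cells(generated) == 0) return(reference)

  gen_ids <- make.unique(c(cell_ids(reference), cell_ids(generated)))[
    n_cells(reference) + seq_len(n_cells(generated))]
  gm <- generated$counts
  colnames(gm) <- gen_ids
  gen <- labeled_counts(gm, cell_type = unname(generated$cell_type),
                        subject = rep(case_label, n_cells(generated)),
                        normalized = reference$normalized)
  cbind_counts(reference, gen)
}
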