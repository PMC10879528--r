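#' sc-CMGAN configuration
#'
#' Hyperparameters of the stepwise cell-marker GAN. The marker fraction used
#' at step k is `t0 - (k - 1) * t_step` percent of all genes; with the default
#' `(n_steps, t0, t_step) = (2, 40, 20)` the two steps use the top 40% and the
#' top 20% of genes by ridge importance. Every scheduled fraction must stay in
#' (0, 100].
#'
#' @param n_steps number of generation cycles (default 2).
#' @param t0 initial marker percentage (default 40).
#' @param t_step percentage decrement per step (default 20).
#' @param ridge_alpha ridge penalty used for marker importance (default 1).
#' @param generator a [generator_config()] for the per-step generator fitted
#'   on the marker submatrix (default: the GAN backend).
#' @param cells_per_type total generated cells per cell type, split as evenly
#'   as possible across steps (remainder to the earliest steps).
#' @param seed integer seed.
#' @return A list of class `CMGANConfig`.
#' @export
cmgan_config <- function(n_steps = 2, t0 = 40, t_step = 20,
                         ridge_alpha = 1,
                         generator = generator_config("gan"),
                         cells_per_type = 100, seed = 1) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  fr <- t0 - (seq_len(n_steps) - 1) * t_step
  if (any(fr <= 0) || any(fr > 100))
    stop("marker schedule leaves (0, 100]: fractions ",
         paste(fr, collapse = ", "))
  if (ridge_alpha <= 0) stop("ridge_alpha must be positive")
  if (cells_per_type < 1) stop("cells_per_type must be >= 1")
  structure(list(n_steps = n_steps, t0 = t0, t_step = t_step,
                 ridge_alpha = ridge_alpha, generator = generator,
                 cells_per_type = cells_per_type, seed = as.integer(seed)),
            class = "CMGANConfig")
}

#' Ridge-based marker-gene importance
#'
#' Ranks genes by how strongly they discriminate cell types. Expression is
#' log1p-transformed and standardized per gene, then one ridge-penalized
#' one-vs-rest linear model is fitted per cell type (centered 0/1 indicator
#' response, closed-form penalized solve). A gene's importance is the maximum
#' absolute coefficient it attains across cell types.
#'
#' @param train a `LabeledCounts` with at least 2 cell types, normally the
#'   preprocessed (normalized) training half.
#' @param ridge_alpha positive ridge penalty.
#' @return Named non-negative numeric vector of scores, one per gene, in the
#'   input gene order.
#' @export
rank_gene_importance <- function(train, ridge_alpha = 1) {
  stopifnot(inherits(train, "LabeledCounts"))
  types <- sort(unique(train$cell_type))
  if (length(types) < 2) stop("need >= 2 cell types to rank markers")
  if (ridge_alpha <= 0) stop("ridge_alpha must be positive")

  X <- t(log1p(train$counts))        # cells x genes
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("degenerate design: all genes constant")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")

  G <- ncol(Xs)
  A <- crossprod(Xs) + diag(ridge_alpha, G)
  ch <- chol(A)
  score_kept <- rep(0, G)
  for (ty in types) {
    y <- as.numeric(train$cell_type == ty)
    y <- y - mean(y)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, y)))
    score_kept <- pmax(score_kept, abs(beta))
  }
  score <- stats::setNames(rep(0, n_genes(train)), gene_ids(train))
  score[keep] <- score_kept
  score
}

#' Stepwise marker schedule
#'
#' Converts importance scores into the nested marker sets used by the
#' generation cycles: step k keeps the top `round(fraction_k / 100 * n_genes)`
#' genes, `fraction_k = t0 - (k - 1) * t_step`. Scores are fixed once, so the
#' sets are nested by construction; ties are broken by original gene order.
#'
#' @param config a [cmgan_config()].
#' @param n_genes total number of genes.
#' @param importance named score vector as from [rank_gene_importance()].
#' @return A list of class `MarkerSelection` with `importance`, `fractions`
#'   and `steps` (list of marker-gene id vectors, one per step).
#' @export
marker_schedule <- function(config, n_genes, importance) {
  stopifnot(inherits(config, "CMGANConfig"))
  if (length(importance) != n_genes)
    stop("importance must have one score per gene")
  fractions <- config$t0 - (seq_len(config$n_steps) - 1) * config$t_step
  if (any(fractions <= 0))
    stop("marker schedule reaches a zero or negative fraction")
  ord <- order(-importance, seq_along(importance))
  steps <- lapply(fractions, function(fr) {
    k <- round(fr / 100 * n_genes)
    if (k < 1) stop("marker fraction selects zero genes")
    names(importance)[ord[seq_len(k)]]
  })
  structure(list(importance = importance, fractions = fractions,
                 steps = steps),
            class = "MarkerSelection")
}

#' One sc-CMGAN generation step
#'
#' Fits the configured generator on the marker-gene submatrix only, samples
#' `n_cells_per_type` cells per cell type for the marker genes, and imputes
#' every non-marker gene of a generated cell with the per-cell-type median of
#' the training expression (on the expression scale). The full training gene
#' order is restored.
#'
#' @param train a `LabeledCounts`.
#' @param markers character vector of marker gene ids (subset of the training
#'   genes).
#' @param generator a [generator_config()].
#' @param n_cells_per_type cells to generate per type in this step.
#' @param seed integer seed for both fitting and sampling.
#' @return A `LabeledCounts` of generated cells over all training genes.
#' @export
generate_step <- function(train, markers, generator, n_cells_per_type,
                          seed = 1) {
  stopifnot(inherits(train, "LabeledCounts"))
  if (length(markers) == 0) stop("empty marker set")
  if (!all(markers %in% gene_ids(train)))
    stop("markers must be a subset of the training genes")

  cfg <- generator
  cfg$seed <- as.integer(seed)
  sub <- subset_counts(train, genes = match(markers, gene_ids(train)))
  model <- fit_generator(sub, cfg)
  gen <- sample_cells(model, cells_per_type = n_cells_per_type, seed = seed)

  full <- matrix(0, n_genes(train), n_cells(gen),
                 dimnames = list(gene_ids(train), cell_ids(gen)))
  full[markers, ] <- gen$counts
  non_markers <- setdiff(gene_ids(train), markers)
  if (length(non_markers)) {
    for (ty in model$cell_types) {
      med <- apply(train$counts[non_markers,
                                train$cell_type == ty, drop = FALSE],
                   1, stats::median)
      full[non_markers, gen$cell_type == ty] <- med
    }
  }
  labeled_counts(full, cell_type = unname(gen$cell_type),
                 subject = unname(gen$subject),
                 normalized = train$normalized)
}

#' Generate augmented cells with sc-CMGAN
#'
#' The full stepwise method: gene importance is ranked once by ridge
#' regression, the shrinking marker schedule is laid out, each step trains a
#' generator on its marker submatrix and imputes non-markers with per-type
#' medians, and the per-step outputs are combined. The total of
#' `config$cells_per_type` generated cells per type is split as evenly as
#' possible across steps, remainder to the earliest steps.
#'
#' @param train a preprocessed `LabeledCounts` with >= 2 cell types.
#' @param config a [cmgan_config()].
#' @return A `LabeledCounts` of generated cells carrying a single new
#'   synthetic subject label, plus attribute `"markers"` (the
#'   `MarkerSelection` used).
#' @examples
#' \donttest{
#' lc <- make_synthetic(synthetic_spec(n_genes = 60, seed = 4))$data
#' pp <- preprocess(lc)$data
#' gen <- sc_cmgan_generate(pp, cmgan_config(cells_per_type = 10,
#'   generator = generator_config("gan", epochs = 5), seed = 1))
#' table(gen$cell_type)
#' }
#' @export
sc_cmgan_generate <- function(train, config = cmgan_config()) {
  stopifnot(inherits(train, "LabeledCounts"),
            inherits(config, "CMGANConfig"))
  importance <- rank_gene_importance(train, config$ridge_alpha)
  sel <- marker_schedule(config, n_genes(train), importance)

  n <- config$n_steps
  base <- config$cells_per_type %/% n
  per_step <- rep(base, n) + as.integer(seq_len(n) <= config$cells_per_type %% n)

  parts <- vector("list", n)
  for (k in seq_len(n)) {
    parts[[k]] <- generate_step(train, sel$steps[[k]], config$generator,
                                per_step[k],
                                seed = child_seed(config$seed, k))
  }
  m <- do.call(cbind, lapply(parts, function(p) p$counts))
  colnames(m) <- paste0("cmgan_", seq_len(ncol(m)))
  out <- labeled_counts(
    m,
    cell_type = unlist(lapply(parts, function(p) unname(p$cell_type))),
    subject = rep("scCMGAN_generated", ncol(m)),
    normalized = train$normalized)
  attr(out, "markers") <- sel
  out
}
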