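#' Build a cell-type signature matrix
#'
#' Per cell type, the mean of the CPM-scaled cell profiles pooled over all
#' subjects (real and generated alike). This is the reference the NNLS
#' baseline deconvolver regresses bulk profiles onto.
#'
#' @param reference a `LabeledCounts` with at least 2 cell types.
#' @return An object of class `SignatureMatrix`: list with `values`
#'   (genes x cell types, columns summing to 1e6), `cell_types` and
#'   `scale = "cpm"`.
#' @export
build_signature <- function(reference) {
  stopifnot(inherits(reference, "LabeledCounts"))
  types <- sort(unique(reference$cell_type))
  if (length(types) < 2) stop("need >= 2 cell types for a signature")
  cpm <- cpm_scale(reference$counts)
  vals <- vapply(types, function(ty)
    rowMeans(cpm[, reference$cell_type == ty, drop = FALSE]),
    numeric(n_genes(reference)))
  if (any(colSums(vals) == 0))
    stop("cell type with zero total expression: ",
         paste(types[colSums(vals) == 0], collapse = ", "))
  structure(list(values = vals, cell_types = types, scale = "cpm"),
            class = "SignatureMatrix")
}

#' Non-negative least squares deconvolution
#'
#' The baseline proportion estimator: per bulk sample, solves
#' `min || S w - b ||_2` subject to `w >= 0` on the gene intersection of
#' signature and bulk (both CPM-scaled), then renormalizes `w` to the
#' simplex. Deterministic.
#'
#' @param bulk numeric vector or genes x samples matrix with gene ids as
#'   (row)names.
#' @param signature a [build_signature()] result.
#' @return Matrix cell types x samples of estimated proportions; every column
#'   is non-negative and sums to 1.
#' @export
nnls_deconvolve <- function(bulk, signature) {
  stopifnot(inherits(signature, "SignatureMatrix"))
  if (is.vector(bulk)) bulk <- matrix(bulk, ncol = 1,
                                      dimnames = list(names(bulk), "bulk1"))
  common <- intersect(rownames(signature$values), rownames(bulk))
  if (length(common) == 0) stop("empty gene intersection")
  if (any(colSums(bulk) == 0)) stop("all-zero bulk column")
  S <- signature$values[common, , drop = FALSE]
  B <- cpm_scale(bulk[common, , drop = FALSE])
  est <- apply(B, 2, function(b) {
    w <- pracma::lsqnonneg(S, b)$x
    if (sum(w) == 0) stop("NNLS returned the zero solution")
    w / sum(w)
  })
  est <- matrix(est, nrow = ncol(S),
                dimnames = list(signature$cell_types, colnames(bulk)))
  est
}

#' Root-mean-square error of estimated proportions
#'
#' @param true,est cell types x mixtures proportion matrices of equal shape.
#' @param axis `"per_mixture"` (RMSE over cell types, one value per column)
#'   or `"overall"` (one value over all entries).
#' @return Numeric vector or scalar, >= 0.
#' @export
prop_rmse <- function(true, est, axis = c("per_mixture", "overall")) {
  axis <- match.arg(axis)
  if (!all(dim(true) == dim(est))) stop("shape mismatch")
  sq <- (true - est)^2
  if (axis == "per_mixture") sqrt(colMeans(sq)) else sqrt(mean(sq))
}

#' Pearson correlation of estimated proportions
#'
#' Per cell type (the usual convention: correlation across mixtures for each
#' type) or overall on the flattened matrices. A zero-variance vector makes
#' the correlation undefined; it is reported as `NA` with a warning, never
#' coerced to 0.
#'
#' @inheritParams prop_rmse
#' @param axis `"per_type"` or `"overall"`.
#' @return Named vector of per-type r, or a scalar.
#' @export
prop_pearson <- function(true, est, axis = c("per_type", "overall")) {
  axis <- match.arg(axis)
  if (!all(dim(true) == dim(est))) stop("shape mismatch")
  if (ncol(true) < 2) stop("need >= 2 mixtures for a correlation")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance vector: correlation undefined, reported as NA")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  if (axis == "overall") return(safe_cor(as.vector(true), as.vector(est)))
  r <- vapply(seq_len(nrow(true)), function(i)
    safe_cor(true[i, ], est[i, ]), numeric(1))
  stats::setNames(r, rownames(true))
}

#' Paired t-test between two metric vectors
#'
#' Two-sided paired t-test on the elementwise differences, `df = n - 1`.
#' Zero-variance differences are a hard error ("degenerate pairing") rather
#' than a spurious p-value.
#'
#' @param metric_a,metric_b equal-length numeric vectors (paired by index);
#'   pairs with a missing value are dropped.
#' @param pairing_unit free-text record of what one pair is (e.g.
#'   `"per_mixture_rmse"`).
#' @return List with `t_statistic`, `p_value`, `n_pairs`, `pairing_unit`.
#' @export
paired_ttest <- function(metric_a, metric_b, pairing_unit = "per_mixture") {
  if (length(metric_a) != length(metric_b)) stop("unequal lengths")
  ok <- is.finite(metric_a) & is.finite(metric_b)
  a <- metric_a[ok]; b <- metric_b[ok]
  if (length(a) < 2) stop("need >= 2 complete pairs")
  d <- a - b
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + max(abs(d)) + 1e-300))
    stop("degenerate pairing: zero-variance differences")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       n_pairs = length(a), pairing_unit = pairing_unit)
}

#' Run one augmentation-vs-control benchmark
#'
#' Closes the loop: builds pseudo-bulk mixtures from the test half, deconvolves
#' them against the control reference signature and — when a generator
#' configuration is supplied — against the signature of the reference
#' augmented with generated cells, then compares the two runs.
#'
#' @param reference a `LabeledCounts` used as deconvolution reference
#'   (typically the preprocessed training half).
#' @param test a `LabeledCounts` supplying cells for the pseudo-bulk mixtures
#'   (raw counts; must share genes with the reference).
#' @param generator `NULL` for a control-only run, a [generator_config()] for
#'   a benchmark backend, or a [cmgan_config()] for sc-CMGAN.
#' @param n_mixtures,cells_per_mixture,concentration pseudo-bulk parameters
#'   passed to [make_mixtures()].
#' @param seed integer seed driving mixtures, fitting and sampling.
#' @return An object of class `EvalReport`: list with `estimated`,
#'   `per_mixture_rmse`, `per_type_pearson`, `overall_pearson`,
#'   `overall_rmse` for the primary (augmented if available, else control)
#'   run, a nested `control` block, and `comparison`
#'   (`delta_rmse`, `delta_pearson`, `t_statistic`, `p_value`,
#'   `pairing_unit`) when a generator was given.
#' @export
run_benchmark <- function(reference, test, generator = NULL,
                          n_mixtures = 1000, cells_per_mixture = 100,
                          concentration = 1, seed = 1) {
  stopifnot(inherits(reference, "LabeledCounts"),
            inherits(test, "LabeledCounts"))
  pb <- make_mixtures(test, n_mixtures = n_mixtures,
                      cells_per_mixture = cells_per_mixture,
                      seed = child_seed(seed, 1), concentration = concentration)
  truth <- mixture_ground_truth(pb)

  eval_arm <- function(ref) {
    sig <- build_signature(ref)
    est <- nnls_deconvolve(pb$mixtures, sig)
    est <- est[rownames(truth), , drop = FALSE]
    list(estimated = est,
         per_mixture_rmse = prop_rmse(truth, est, "per_mixture"),
         per_type_pearson = prop_pearson(truth, est, "per_type"),
         overall_pearson = prop_pearson(truth, est, "overall"),
         overall_rmse = prop_rmse(truth, est, "overall"))
  }
  control <- eval_arm(reference)

  if (is.null(generator)) {
    out <- c(control, list(control = NULL, comparison = NULL,
                           truth = truth, seed = seed))
    class(out) <- "EvalReport"
    return(out)
  }

  generated <- if (inherits(generator, "CMGANConfig")) {
    cfg <- generator
    cfg$seed <- child_seed(seed, 2)
    sc_cmgan_generate(reference, cfg)
  } else {
    cfg <- generator
    cfg$seed <- child_seed(seed, 2)
    model <- fit_generator(reference, cfg)
    sample_cells(model, cells_per_type = cfg$cells_per_type,
                 seed = child_seed(seed, 3))
  }
  augmented_ref <- merge_references(reference, generated,
                                    case_label = "augmented_case")
  augmented <- eval_arm(augmented_ref)

  tt <- paired_ttest(augmented$per_mixture_rmse, control$per_mixture_rmse,
                     pairing_unit = "per_mixture_rmse")
  comparison <- list(
    delta_rmse = mean(augmented$per_mixture_rmse) -
      mean(control$per_mixture_rmse),
    delta_pearson = augmented$overall_pearson - control$overall_pearson,
    t_statistic = tt$t_statistic, p_value = tt$p_value,
    pairing_unit = tt$pairing_unit)

  out <- c(augmented, list(control = control, comparison = comparison,
                           truth = truth, seed = seed))
  class(out) <- "EvalReport"
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d mixtures, overall RMSE %.4f, Pearson %.4f\n",
              ncol(x$estimated), x$overall_rmse, x$overall_pearson))
  if (!is.null(x$comparison))
    cat(sprintf("  vs control: delta RMSE %+.4f, delta Pearson %+.4f, p = %.3g\n",
                x$comparison$delta_rmse, x$comparison$delta_pearson,
                x$comparison$p_value))
  invisible(x)
}

#' Grid search over epochs and generated-cell counts
#'
#' One [run_benchmark()] per grid point, reporting the improvement over the
#' control arm. Defaults follow the usual search: epochs 50-300 in steps of
#' 50, generated cells 100-1000 per type in steps of 100. A failing grid
#' point yields an `NA` row instead of aborting the search.
#'
#' @param reference,test as in [run_benchmark()].
#' @param generator_template a [generator_config()] or [cmgan_config()] whose
#'   epochs / cells-per-type fields are overridden per grid point.
#' @param epochs_grid,cells_grid numeric vectors of grid values.
#' @param seed integer seed (shared across grid points so mixtures coincide).
#' @param ... further arguments passed to [run_benchmark()].
#' @return data.frame with columns `epochs`, `cells`, `delta_rmse`,
#'   `delta_pearson`, `p_value`.
#' @export
grid_search <- function(reference, test, generator_template,
                        epochs_grid = seq(50, 300, by = 50),
                        cells_grid = seq(100, 1000, by = 100),
                        seed = 1, ...) {
  if (length(epochs_grid) == 0 || length(cells_grid) == 0)
    stop("grids must be non-empty")
  grid <- expand.grid(epochs = epochs_grid, cells = cells_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- generator_template
    if (inherits(cfg, "CMGANConfig")) {
      cfg$generator$epochs <- grid$epochs[i]
      cfg$cells_per_type <- grid$cells[i]
    } else {
      cfg$epochs <- grid$epochs[i]
      cfg$cells_per_type <- grid$cells[i]
    }
    tryCatch({
      rep <- run_benchmark(reference, test, generator = cfg, seed = seed, ...)
      data.frame(epochs = grid$epochs[i], cells = grid$cells[i],
                 delta_rmse = rep$comparison$delta_rmse,
                 delta_pearson = rep$comparison$delta_pearson,
                 p_value = rep$comparison$p_value)
    }, error = function(e) {
      warning("grid point (", grid$epochs[i], ", ", grid$cells[i],
              ") failed: ", conditionMessage(e))
      data.frame(epochs = grid$epochs[i], cells = grid$cells[i],
                 delta_rmse = NA_real_, delta_pearson = NA_real_,
                 p_value = NA_real_)
    })
  })
  do.call(rbind, res)
}
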