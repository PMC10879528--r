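#' Build artificial pseudo-bulk mixtures with known proportions
#'
#' Simulates bulk RNA-seq samples by summing raw counts of individually drawn
#' single cells, so that the true cell-type composition of every mixture is
#' known exactly. For each mixture a cell-type proportion vector is drawn from
#' a symmetric Dirichlet, `cells_per_mixture` cell slots are allocated to
#' types multinomially, and that many cells per type are sampled with
#' replacement from the test set. The recorded ground truth is the realized
#' fraction of drawn cells, not the Dirichlet draw.
#'
#' @param test a `LabeledCounts` holding the (raw-count) test half.
#' @param n_mixtures number of pseudo-bulk mixtures; default 1000.
#' @param cells_per_mixture cells summed into each mixture; default 100, the
#'   minimum used for every dataset.
#' @param seed integer seed; the whole set is deterministic given the seed.
#' @param concentration symmetric Dirichlet concentration; 1 (default) is
#'   uniform on the simplex, larger values pull compositions toward equality.
#' @return A list of class `PseudoBulkSet` with elements `mixtures`
#'   (genes x mixtures summed counts), `proportions` (cell types x mixtures,
#'   columns summing to 1), `cells_per_mixture` and `seed`.
#' @examples
#' lc <- make_synthetic(synthetic_spec(n_genes = 50, seed = 2))$data
#' pb <- make_mixtures(lc, n_mixtures = 10, seed = 5)
#' colSums(pb$proportions)
#' @export
make_mixtures <- function(test, n_mixtures = 1000, cells_per_mixture = 100,
                          seed = 1, concentration = 1) {
  stopifnot(inherits(test, "LabeledCounts"))
  if (cells_per_mixture < 1) stop("cells_per_mixture must be >= 1")
  if (n_mixtures < 1) stop("n_mixtures must be >= 1")
  if (concentration <= 0) stop("concentration must be positive")
  types <- sort(unique(test$cell_type))
  k <- length(types)
  cells_by_type <- lapply(types, function(ty)
    which(unname(test$cell_type) == ty))
  names(cells_by_type) <- types

  mixtures <- matrix(0, n_genes(test), n_mixtures,
                     dimnames = list(gene_ids(test),
                                     paste0("mix", seq_len(n_mixtures))))
  props <- matrix(0, k, n_mixtures,
                  dimnames = list(types, colnames(mixtures)))
  with_local_seed(seed, {
    for (j in seq_len(n_mixtures)) {
      p <- rdirichlet1(k, concentration)
      alloc <- as.vector(stats::rmultinom(1, cells_per_mixture, p))
      picked <- integer(0)
      for (i in seq_len(k)) {
        if (alloc[i] > 0) {
          pool <- cells_by_type[[i]]
          picked <- c(picked,
                      pool[sample.int(length(pool), alloc[i], replace = TRUE)])
        }
      }
      mixtures[, j] <- rowSums(test$counts[, picked, drop = FALSE])
      props[, j] <- alloc / cells_per_mixture
    }
  })
  structure(list(mixtures = mixtures, proportions = props,
                 cells_per_mixture = cells_per_mixture, seed = seed),
            class = "PseudoBulkSet")
}

#' Known cell-type proportions of a pseudo-bulk set
#'
#' Returns the realized (computed) cell-type proportion matrix against which
#' deconvolution estimates are scored.
#'
#' @param set a [make_mixtures()] result.
#' @return Matrix, cell types x mixtures; every column sums to 1.
#' @export
mixture_ground_truth <- function(set) {
  stopifnot(inherits(set, "PseudoBulkSet"))
  set$proportions
}

#' @export
print.PseudoBulkSet <- function(x, ...) {
  cat(sprintf("PseudoBulkSet: %d genes x %d mixtures, %d cells each, seed %d\n",
              nrow(x$mixtures), ncol(x$mixtures), x$cells_per_mixture,
              x$seed))
  invisible(x)
}
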