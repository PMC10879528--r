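#' Quality-control configuration
#'
#' Parameters of the single-cell QC pipeline: gene pre-filtering, 3-MAD
#' outlier-cell removal on library size / mitochondrial fraction / ribosomal
#' fraction, prevalence-based gene filtering and TMM normalization.
#'
#' @param n_mads number of (scaled) median absolute deviations beyond which a
#'   cell is an outlier; default 3.
#' @param prevalence_fraction minimum fraction of cells in which a gene must
#'   be detected; default 0.05.
#' @param detection_threshold a gene counts as detected in a cell when its
#'   value is strictly greater than this; default 1 (UMI/read count > 1).
#' @param mito_prefixes,ribo_prefixes gene-name prefixes (matched
#'   case-insensitively) defining the mitochondrial and ribosomal families.
#' @param scaled_mad use the 1.4826 consistency constant in the MAD (the
#'   standard single-cell convention); set `FALSE` for the raw MAD.
#' @return A list of class `QCConfig`.
#' @export
qc_config <- function(n_mads = 3,
                      prevalence_fraction = 0.05,
                      detection_threshold = 1,
                      mito_prefixes = c("MT-"),
                      ribo_prefixes = c("RPS", "RPL"),
                      scaled_mad = TRUE) {
  if (n_mads <= 0) stop("n_mads must be > 0")
  if (prevalence_fraction <= 0 || prevalence_fraction > 1)
    stop("prevalence_fraction must be in (0, 1]")
  structure(list(n_mads = n_mads,
                 prevalence_fraction = prevalence_fraction,
                 detection_threshold = detection_threshold,
                 mito_prefixes = mito_prefixes,
                 ribo_prefixes = ribo_prefixes,
                 scaled_mad = isTRUE(scaled_mad)),
            class = "QCConfig")
}

#' Remove all-zero and zero-variance genes
#'
#' Drops genes with zero total expression or with identical values across all
#' cells (no variability). Surviving genes keep their order.
#'
#' @param data a `LabeledCounts`.
#' @return A list with `data` (filtered `LabeledCounts`) and `removed`
#'   (character vector of removed gene ids).
#' @export
filter_genes_basic <- function(data) {
  stopifnot(inherits(data, "LabeledCounts"))
  m <- data$counts
  zero <- rowSums(m) == 0
  constant <- apply(m, 1, function(r) all(r == r[1]))
  drop <- zero | constant
  if (all(drop)) stop("empty matrix: every gene is zero or constant")
  list(data = subset_counts(data, genes = which(!drop)),
       removed = rownames(m)[drop])
}

#' Per-cell QC metrics
#'
#' Library size (column sum), mitochondrial fraction and ribosomal fraction
#' per cell, with family membership decided by case-insensitive gene-name
#' prefix matching. Cells with zero library size get `NA` fractions and are
#' flagged for removal.
#'
#' @param data a `LabeledCounts`.
#' @param config a [qc_config()].
#' @return A data.frame with columns `cell_id`, `library_size`,
#'   `mito_fraction`, `ribo_fraction`, `zero_library`.
#' @export
cell_qc_metrics <- function(data, config = qc_config()) {
  stopifnot(inherits(data, "LabeledCounts"))
  m <- data$counts
  libs <- colSums(m)
  mito <- prefix_match(gene_ids(data), config$mito_prefixes)
  ribo <- prefix_match(gene_ids(data), config$ribo_prefixes)
  msum <- if (any(mito)) colSums(m[mito, , drop = FALSE]) else rep(0, ncol(m))
  rsum <- if (any(ribo)) colSums(m[ribo, , drop = FALSE]) else rep(0, ncol(m))
  zero <- libs == 0
  data.frame(cell_id = colnames(m),
             library_size = libs,
             mito_fraction = ifelse(zero, NA_real_, msum / libs),
             ribo_fraction = ifelse(zero, NA_real_, rsum / libs),
             zero_library = zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

prefix_match <- function(ids, prefixes) {
  if (length(prefixes) == 0) return(rep(FALSE, length(ids)))
  up <- toupper(ids)
  Reduce(`|`, lapply(toupper(prefixes), function(p) startsWith(up, p)))
}

#' Remove outlier cells by the MAD rule
#'
#' For each of the three QC metrics — library size (assessed on log10 scale),
#' mitochondrial fraction and ribosomal fraction — a cell is discarded when it
#' lies strictly more than `n_mads` scaled median absolute deviations from the
#' median in any metric. Zero-library cells are always removed. When every
#' deviation is zero (all cells identical) nothing is removed.
#'
#' @inheritParams cell_qc_metrics
#' @return A list with `data` (filtered), `removed` (cell ids) and `metrics`
#'   (the per-cell table with a `violated` column naming the failed metric).
#' @export
filter_cells_mad <- function(data, config = qc_config()) {
  stopifnot(inherits(data, "LabeledCounts"))
  if (n_cells(data) < 3) stop("need at least 3 cells for MAD-based QC")
  met <- cell_qc_metrics(data, config)
  const <- if (config$scaled_mad) 1.4826 else 1

  vals <- list(log_library = log10(pmax(met$library_size, .Machine$double.xmin)),
               mito_fraction = met$mito_fraction,
               ribo_fraction = met$ribo_fraction)
  violated <- rep("", nrow(met))
  out <- met$zero_library
  violated[out] <- "zero_library"
  for (nm in names(vals)) {
    x <- vals[[nm]]
    ok <- !met$zero_library
    md <- stats::median(x[ok])
    sc <- stats::mad(x[ok], constant = const)
    bad <- ok & abs(x - md) > config$n_mads * sc
    violated[bad & violated == ""] <- nm
    out <- out | bad
  }
  if (all(out)) stop("MAD filter removed every cell")
  met$violated <- violated
  list(data = subset_counts(data, cells = which(!out)),
       removed = met$cell_id[out],
       metrics = met)
}

#' Prevalence-based gene filter
#'
#' Keeps genes detected (count strictly greater than `detection_threshold`)
#' in at least `ceiling(prevalence_fraction * n_cells)` cells, regardless of
#' cell type.
#'
#' @inheritParams cell_qc_metrics
#' @return A list with `data` (filtered) and `removed` (gene ids).
#' @export
filter_genes_prevalence <- function(data, config = qc_config()) {
  stopifnot(inherits(data, "LabeledCounts"))
  need <- ceiling(config$prevalence_fraction * n_cells(data))
  detected <- rowSums(data$counts > config$detection_threshold)
  keep <- detected >= need
  if (!any(keep)) stop("prevalence filter removed every gene")
  list(data = subset_counts(data, genes = which(keep)),
       removed = gene_ids(data)[!keep])
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors, one per cell (each cell treated
#' as a sample). The reference cell is the one whose 75th-percentile CPM is
#' closest to the mean 75th percentile; per pair, genes zero in either sample
#' are excluded, log-ratios are doubly trimmed (30% on M, 5% on A) and
#' averaged with precision weights; factors are rescaled to geometric mean 1.
#'
#' @param data a `LabeledCounts` with at least 2 cells and positive library
#'   sizes.
#' @return Named numeric vector of positive factors, one per cell, with
#'   geometric mean 1.
#' @export
tmm_factors <- function(data) {
  stopifnot(inherits(data, "LabeledCounts"))
  if (n_cells(data) < 2) stop("TMM needs at least 2 cells")
  if (any(colSums(data$counts) == 0)) stop("TMM needs positive library sizes")
  f <- edgeR::calcNormFactors(data$counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05,
                              doWeighting = TRUE)
  stats::setNames(f, cell_ids(data))
}

#' Apply per-cell normalization factors
#'
#' Divides each column by its effective library size relative to the mean:
#' `counts[, j] / (lib[j] * factor[j] / mean(lib))`. The result keeps the
#' overall scale of the input and is flagged as normalized.
#'
#' @param data a `LabeledCounts`.
#' @param factors named factor vector as returned by [tmm_factors()]; must
#'   cover every cell.
#' @return A normalized `LabeledCounts`.
#' @export
apply_normalization <- function(data, factors) {
  stopifnot(inherits(data, "LabeledCounts"))
  miss <- setdiff(cell_ids(data), names(factors))
  if (length(miss)) stop("missing factor for cells: ",
                         paste(miss, collapse = ", "))
  f <- factors[cell_ids(data)]
  libs <- colSums(data$counts)
  eff <- libs * f / mean(libs)
  m <- sweep(data$counts, 2, eff, "/")
  labeled_counts(m, cell_type = unname(data$cell_type),
                 subject = unname(data$subject), normalized = TRUE)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: the basic gene filter, MAD-based outlier-cell removal,
#' the prevalence gene filter and TMM normalization.
#'
#' @inheritParams cell_qc_metrics
#' @param tmm apply TMM normalization after filtering; default `TRUE`.
#' @return A list with `data` (the preprocessed `LabeledCounts`), `raw` (the
#'   same cells and genes but unnormalized counts, the right input for
#'   pseudo-bulk summation) and `report` (class `QCReport`: removal counts
#'   and ids, per-cell metrics, TMM factors).
#' @examples
#' lc <- make_synthetic(synthetic_spec(n_genes = 60, seed = 3))$data
#' pp <- preprocess(lc)
#' pp$report$cells_removed_qc
#' @export
preprocess <- function(data, config = qc_config(), tmm = TRUE) {
  s1 <- filter_genes_basic(data)
  s2 <- filter_cells_mad(s1$data, config)
  s3 <- filter_genes_prevalence(s2$data, config)
  factors <- if (tmm) tmm_factors(s3$data) else
    stats::setNames(rep(1, n_cells(s3$data)), cell_ids(s3$data))
  out <- if (tmm) apply_normalization(s3$data, factors) else s3$data
  raw <- s3$data
  report <- structure(list(
    genes_removed_zero = length(s1$removed),
    genes_removed_zero_ids = s1$removed,
    cells_removed_qc = length(s2$removed),
    cells_removed_qc_ids = s2$removed,
    cell_metrics = s2$metrics,
    genes_removed_prevalence = length(s3$removed),
    genes_removed_prevalence_ids = s3$removed,
    tmm_factors = factors
  ), class = "QCReport")
  list(data = out, raw = raw, report = report)
}
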