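#' Labelled single-cell count matrix
#'
#' The central container of the package: a dense genes x cells matrix of
#' non-negative expression values together with one cell-type label and one
#' subject (donor) label per cell. Gene and cell identifiers are opaque
#' strings and must be unique; duplicates are a hard error.
#'
#' @param counts numeric matrix, genes in rows and cells in columns. If it
#'   carries dimnames they are used as identifiers unless `gene_ids` /
#'   `cell_ids` are given explicitly.
#' @param cell_type character vector of cell-type labels, one per column.
#' @param subject character vector of subject labels, one per column.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#' @param normalized logical flag; `TRUE` once between-cell normalization has
#'   been applied (see [apply_normalization()]).
#'
#' @return An object of class `LabeledCounts`: a list with elements
#'   `counts` (matrix with identifiers as dimnames), `cell_type` and
#'   `subject` (character vectors named by cell id) and `normalized`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' lc <- labeled_counts(m, cell_type = rep(c("A", "B"), 2),
#'                      subject = rep("S1", 4))
#' n_cells(lc)
#' @export
labeled_counts <- function(counts, cell_type, subject,
                           gene_ids = NULL, cell_ids = NULL,
                           normalized = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- colnames(counts)
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell%d", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (length(cell_type) != ncol(counts))
    stop("cell_type must have one entry per cell")
  if (length(subject) != ncol(counts))
    stop("subject must have one entry per cell")
  if (anyNA(cell_type) || anyNA(subject))
    stop("every cell needs a cell_type and a subject label")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)
  cell_type <- stats::setNames(as.character(cell_type), cell_ids)
  subject <- stats::setNames(as.character(subject), cell_ids)
  structure(
    list(counts = counts, cell_type = cell_type, subject = subject,
         normalized = isTRUE(normalized)),
    class = "LabeledCounts"
  )
}

#' @export
print.LabeledCounts <- function(x, ...) {
  cat(sprintf("LabeledCounts: %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  cell types: %s\n",
              paste(names(table(x$cell_type)), collapse = ", ")))
  cat(sprintf("  subjects:   %s\n",
              paste(unique(x$subject), collapse = ", ")))
  invisible(x)
}

#' @rdname labeled_counts
#' @param x a `LabeledCounts` object.
#' @export
n_genes <- function(x) nrow(x$counts)

#' @rdname labeled_counts
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname labeled_counts
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname labeled_counts
#' @export
cell_ids <- function(x) colnames(x$counts)

#' Subset a LabeledCounts object
#'
#' Row (gene) and column (cell) subsetting that keeps labels in step with the
#' matrix. Order of surviving genes and cells is preserved.
#'
#' @param x a `LabeledCounts` object.
#' @param genes,cells index, logical or character selectors; `NULL` keeps all.
#' @return A `LabeledCounts` with the selected genes and cells.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "LabeledCounts"))
  if (is.null(genes)) genes <- seq_len(n_genes(x))
  if (is.null(cells)) cells <- seq_len(n_cells(x))
  m <- x$counts[genes, cells, drop = FALSE]
  labeled_counts(m, cell_type = unname(x$cell_type[colnames(m)]),
                 subject = unname(x$subject[colnames(m)]),
                 normalized = x$normalized)
}

#' Combine two LabeledCounts objects column-wise
#'
#' Internal helper: gene sets must be identical and identically ordered.
#' @noRd
cbind_counts <- function(a, b) {
  stopifnot(identical(gene_ids(a), gene_ids(b)))
  labeled_counts(cbind(a$counts, b$counts),
                 cell_type = c(unname(a$cell_type), unname(b$cell_type)),
                 subject = c(unname(a$subject), unname(b$subject)),
                 normalized = a$normalized)
}
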