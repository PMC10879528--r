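#' Read a labelled count matrix
#'
#' Reads a genes x cells count matrix plus a cell label table into a
#' [labeled_counts()] object. Three on-disk layouts are supported:
#'
#' * `mtx` — MatrixMarket sparse matrix; gene and cell identifiers come from
#'   `genes.tsv` and `cells.tsv` sidecar files (one identifier per line) in
#'   the same directory as the `.mtx` file.
#' * `csv` / `tsv` — dense table, genes as rows, cells as columns; the first
#'   column holds gene identifiers and the header row holds cell identifiers.
#'
#' The label table is a TSV with header `cell_id`, `cell_type`, `subject` and
#' one row per cell. Every cell in the matrix must be labelled; extra label
#' rows are ignored.
#'
#' @param path path to the matrix file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param labels_path path to the labels TSV.
#' @return A `LabeledCounts` object.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("mtx", "csv", "tsv"), labels_path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)

  if (format == "mtx") {
    dir <- dirname(path)
    gfile <- file.path(dir, "genes.tsv")
    cfile <- file.path(dir, "cells.tsv")
    if (!file.exists(gfile) || !file.exists(cfile))
      stop("mtx format requires genes.tsv and cells.tsv sidecars in ", dir)
    m <- as.matrix(Matrix::readMM(path))
    g <- readLines(gfile)
    cl <- readLines(cfile)
    if (length(g) != nrow(m) || length(cl) != ncol(m))
      stop("sidecar identifier counts do not match matrix dimensions")
    dimnames(m) <- list(g, cl)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, colClasses = NA,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 1) stop("malformed matrix table")
    g <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (nrow(m) > 0 && !is.numeric(m)) stop("malformed matrix: non-numeric entries")
    storage.mode(m) <- "double"
    rownames(m) <- g
  }

  lab <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cell_id", "cell_type", "subject")
  if (!all(need %in% names(lab)))
    stop("labels table must have columns cell_id, cell_type, subject")
  idx <- match(colnames(m), lab$cell_id)
  if (anyNA(idx))
    stop("unlabeled cell: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  labeled_counts(m, cell_type = lab$cell_type[idx],
                 subject = lab$subject[idx])
}

#' Write a labelled count matrix
#'
#' Inverse of [read_counts()]: emits the matrix in the requested format plus
#' the labels TSV, such that reading the files back reproduces the object
#' exactly (dense formats use full `%.17g` precision; MatrixMarket output is
#' written by `Matrix::writeMM`, which round-trips doubles).
#'
#' @param data a `LabeledCounts` object.
#' @param path destination for the matrix file. For `mtx`, `genes.tsv`,
#'   `cells.tsv` sidecars are written next to it.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param labels_path destination for the labels TSV; defaults to
#'   `<path>.labels.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(data, path, format = c("mtx", "csv", "tsv"),
                         labels_path = paste0(path, ".labels.tsv")) {
  stopifnot(inherits(data, "LabeledCounts"))
  format <- match.arg(format)
  m <- data$counts

  if (format == "mtx") {
    dir <- dirname(path)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "cells.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    body <- cbind(gene_id = rownames(m),
                  matrix(formatC(m, format = "g", digits = 17),
                         nrow(m), ncol(m)))
    colnames(body) <- c("gene_id", colnames(m))
    utils::write.table(body, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }

  lab <- data.frame(cell_id = colnames(m),
                    cell_type = unname(data$cell_type),
                    subject = unname(data$subject),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(matrix = path, labels = labels_path))
}
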