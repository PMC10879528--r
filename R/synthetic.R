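#' Specification of a synthetic labelled scRNA-seq dataset
#'
#' Describes a negative-binomial multi-cell-type, multi-subject dataset that
#' emulates the data regime the pipeline targets: per-gene base means drawn
#' log-uniformly, planted marker genes with a per-type fold-change, per-subject
#' multiplicative log-normal expression heterogeneity, mitochondrial and
#' ribosomal gene families for QC, and optional planted library-size outlier
#' cells.
#'
#' Defaults mirror the benchmark's study conditions: 500 genes, 5 cell types
#' with 40 cells per type per subject, 4 subjects (two intended for training,
#' two for testing), marker fold 4 and between-subject sigma 0.6.
#'
#' @param n_genes total genes.
#' @param cell_types named integer vector: cells per type per subject.
#' @param subjects subject labels.
#' @param nb_mean_range range for the log-uniform per-gene base means.
#' @param nb_dispersion negative-binomial `size` parameter (smaller = noisier).
#' @param marker_fraction fraction of genes planted as cell-type markers
#'   (split evenly across types).
#' @param marker_fold multiplicative up-shift of a marker in its own type.
#' @param subject_sigma standard deviation of per-subject per-gene log-normal
#'   fold effects; 0 disables heterogeneity.
#' @param mito_fraction_genes,ribo_fraction_genes fractions of genes named
#'   with "MT-" and "RPS"/"RPL" prefixes.
#' @param outlier_cells number of planted library-size outlier cells.
#' @param outlier_fold count multiplier applied to outlier cells.
#' @param seed integer seed.
#' @return A list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_genes = 500,
                           cell_types = c(A = 40, B = 40, C = 40,
                                          D = 40, E = 40),
                           subjects = c("S1", "S2", "S3", "S4"),
                           nb_mean_range = c(0.5, 50),
                           nb_dispersion = 2,
                           marker_fraction = 0.1,
                           marker_fold = 4,
                           subject_sigma = 0.6,
                           mito_fraction_genes = 0.02,
                           ribo_fraction_genes = 0.04,
                           outlier_cells = 0,
                           outlier_fold = 50,
                           seed = 1) {
  if (n_genes < 1 || any(cell_types < 1)) stop("counts must be >= 1")
  if (is.null(names(cell_types))) stop("cell_types must be named")
  stopifnot(marker_fraction >= 0, marker_fraction <= 1,
            mito_fraction_genes >= 0, mito_fraction_genes <= 1,
            ribo_fraction_genes >= 0, ribo_fraction_genes <= 1,
            subject_sigma >= 0, nb_dispersion > 0,
            all(nb_mean_range > 0), length(nb_mean_range) == 2)
  if (round(marker_fraction * n_genes) +
      ceiling(mito_fraction_genes * n_genes) +
      ceiling(ribo_fraction_genes * n_genes) > n_genes)
    stop("impossible spec: marker + mito + ribo genes exceed n_genes")
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 subjects = subjects, nb_mean_range = nb_mean_range,
                 nb_dispersion = nb_dispersion,
                 marker_fraction = marker_fraction,
                 marker_fold = marker_fold, subject_sigma = subject_sigma,
                 mito_fraction_genes = mito_fraction_genes,
                 ribo_fraction_genes = ribo_fraction_genes,
                 outlier_cells = outlier_cells, outlier_fold = outlier_fold,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Simulate a labelled scRNA-seq dataset with known ground truth
#'
#' Draws counts from `NB(mu, size = nb_dispersion)` with
#' `mu[g, cell] = base[g] * marker_fold^[g is a marker of type(cell)] *
#' subject_effect[g, subject(cell)]`, where subject effects are i.i.d.
#' log-normal(0, subject_sigma^2) per gene and subject. The first genes are
#' given mitochondrial ("MT-") and ribosomal ("RPS"/"RPL") names so QC has
#' families to work on; marker genes are planted outside those families.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `data` (a `LabeledCounts`) and `truth` (class
#'   `GroundTruth`): base means, the marker map (gene -> type), subject-effect
#'   matrix, expected mean array, planted outlier cell ids and the spec.
#' @examples
#' sim <- make_synthetic(synthetic_spec(n_genes = 50, seed = 1))
#' sim$data
#' head(names(sim$truth$markers))
#' @export
make_synthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_local_seed(spec$seed, {
    G <- spec$n_genes
    types <- names(spec$cell_types)
    K <- length(types)
    n_mito <- ceiling(spec$mito_fraction_genes * G)
    n_ribo <- ceiling(spec$ribo_fraction_genes * G)
    gene_names <- character(G)
    if (n_mito > 0) gene_names[seq_len(n_mito)] <- paste0("MT-", seq_len(n_mito))
    if (n_ribo > 0)
      gene_names[n_mito + seq_len(n_ribo)] <-
        paste0(rep(c("RPS", "RPL"), length.out = n_ribo), seq_len(n_ribo))
    plain <- (n_mito + n_ribo + 1):G
    gene_names[plain] <- paste0("G", seq_along(plain))

    base <- exp(stats::runif(G, log(spec$nb_mean_range[1]),
                             log(spec$nb_mean_range[2])))

    n_markers <- round(spec$marker_fraction * G)
    markers <- character(0)
    if (n_markers > 0) {
      mk_genes <- sample(gene_names[plain], n_markers)
      markers <- stats::setNames(rep(types, length.out = n_markers), mk_genes)
    }

    subj_eff <- matrix(1, G, length(spec$subjects),
                       dimnames = list(gene_names, spec$subjects))
    if (spec$subject_sigma > 0)
      subj_eff[] <- exp(stats::rnorm(G * length(spec$subjects),
                                     0, spec$subject_sigma))

    # expected means: genes x types x subjects
    fold <- matrix(1, G, K, dimnames = list(gene_names, types))
    if (length(markers))
      fold[cbind(match(names(markers), gene_names),
                 match(unname(markers), types))] <- spec$marker_fold
    mu <- array(NA_real_, c(G, K, length(spec$subjects)),
                dimnames = list(gene_names, types, spec$subjects))
    for (s in seq_along(spec$subjects))
      mu[, , s] <- base * fold * subj_eff[, s]

    cell_type <- character(0); subject <- character(0)
    cols <- list(); i <- 0
    for (s in spec$subjects) {
      for (ty in types) {
        n <- spec$cell_types[[ty]]
        m <- matrix(stats::rnbinom(G * n, mu = mu[, ty, s],
                                   size = spec$nb_dispersion), G, n)
        i <- i + 1; cols[[i]] <- m
        cell_type <- c(cell_type, rep(ty, n))
        subject <- c(subject, rep(s, n))
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- gene_names
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))

    outlier_ids <- character(0)
    if (spec$outlier_cells > 0) {
      pick <- sample(ncol(counts), spec$outlier_cells)
      counts[, pick] <- counts[, pick] * spec$outlier_fold
      outlier_ids <- colnames(counts)[pick]
    }

    truth <- structure(list(base_mean = stats::setNames(base, gene_names),
                            markers = markers, fold = fold,
                            subject_effect = subj_eff, expected_mean = mu,
                            outlier_cells = outlier_ids, spec = spec),
                       class = "GroundTruth")
    list(data = labeled_counts(counts, cell_type = cell_type,
                               subject = subject),
         truth = truth)
  })
}

#' Expected CPM signature implied by the simulation ground truth
#'
#' The exact expected cell-type profiles (CPM scale) for one subject — the
#' linear-algebra oracle for deconvolution-recovery tests.
#'
#' @param truth the `GroundTruth` from [make_synthetic()].
#' @param subject a subject label present in the spec.
#' @return A `SignatureMatrix` over the simulated genes.
#' @export
ground_truth_signature <- function(truth, subject) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (!subject %in% dimnames(truth$expected_mean)[[3]])
    stop("unknown subject: ", subject)
  m <- truth$expected_mean[, , subject]
  vals <- sweep(m, 2, colSums(m), "/") * 1e6
  structure(list(values = vals, cell_types = colnames(m), scale = "cpm"),
            class = "SignatureMatrix")
}
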