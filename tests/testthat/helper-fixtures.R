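# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Small deterministic labelled counts: 3 genes x 4 cells, 2 types, 1 subject.
tiny_lc <- function() {
  m <- matrix(c(0, 5, 1,
                2, 5, 0,
                0, 5, 3,
                1, 5, 2), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
  labeled_counts(m, cell_type = c("A", "A", "B", "B"),
                 subject = rep("S1", 4))
}

# Continuous ("smooth") expression fixture for copula marginal tests:
# lognormal values, no ties.
smooth_lc <- function(n_genes = 30, n_cells = 200, seed = 99) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_genes * n_cells, mean = 2, sd = 1)),
              n_genes, n_cells,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  labeled_counts(m, cell_type = rep("A", n_cells),
                 subject = rep("S1", n_cells))
}

# Random small fixture for property loops.
random_lc <- function(seed, n_genes = 8, n_subjects = sample(1:4, 1)) {
  set.seed(seed)
  n_types <- sample(2:3, 1)
  n_cells <- sample(6:20, 1)
  m <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  labeled_counts(m,
                 cell_type = sample(LETTERS[seq_len(n_types)], n_cells,
                                    replace = TRUE),
                 subject = sample(paste0("S", seq_len(n_subjects)), n_cells,
                                  replace = TRUE))
}

# Independent brute-force TMM implementation (trim-and-weight formula),
# used as the oracle for tmm_factors().
tmm_oracle <- function(m) {
  lib <- colSums(m)
  f75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- sapply(seq_len(ncol(m)), function(j) {
    obs <- m[, j]; refv <- m[, ref]; nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE))
  })
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

# Exhaustive simplex grid search (step 0.01) for 2-type NNLS problems:
# the independent oracle for nnls_deconvolve(). For each candidate simplex
# composition the overall scale is profiled out analytically, matching the
# scale-free renormalization of the NNLS solution.
nnls_grid_oracle <- function(S, b) {
  w1 <- seq(0, 1, by = 0.01)
  err <- sapply(w1, function(w) {
    sw <- S %*% c(w, 1 - w)
    sum(b^2) - sum(sw * b)^2 / sum(sw^2)
  })
  best <- w1[which.min(err)]
  c(best, 1 - best)
}

# Split preprocessed (normalized) data but return the matching raw-count halves
# for pseudo-bulk construction.
prepped_split <- function(spec, split_seed) {
  sim <- make_synthetic(spec)
  pp <- preprocess(sim$data)
  sp <- split_train_test(pp$data, 0.5, seed = split_seed)
  raw_test <- subset_counts(pp$raw,
                            cells = match(cell_ids(sp$test), cell_ids(pp$raw)))
  list(train = sp$train, test = sp$test, raw_test = raw_test,
       truth = sim$truth)
}
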