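test_that("basic gene filter removes zero and constant genes only", {
  m <- rbind(zero = c(0, 0, 0, 0),
             const = c(5, 5, 5, 5),
             keep = c(0, 1, 0, 2))
  colnames(m) <- paste0("c", 1:4)
  lc <- labeled_counts(m, rep("A", 4), rep("S", 4))
  f <- filter_genes_basic(lc)
  expect_setequal(f$removed, c("zero", "const"))
  expect_equal(gene_ids(f$data), "keep")

  allbad <- labeled_counts(m[1:2, ], rep("A", 4), rep("S", 4))
  expect_error(filter_genes_basic(allbad), "empty matrix")
})

test_that("cell QC metrics compute library size and family fractions", {
  m <- rbind("MT-CO1" = c(10, 0), "ACTB" = c(90, 0), "RPS1" = c(0, 0))
  colnames(m) <- c("c1", "c2")
  lc <- labeled_counts(m, rep("A", 2), rep("S", 2))
  met <- cell_qc_metrics(lc)
  expect_equal(met$library_size, c(100, 0))
  expect_equal(met$mito_fraction[1], 0.10)
  expect_equal(met$ribo_fraction[1], 0)
  expect_true(met$zero_library[2])
  expect_true(is.na(met$mito_fraction[2]))

  # no mito genes in the panel -> fraction 0 everywhere
  lc2 <- labeled_counts(m[2:3, , drop = FALSE] + 1, rep("A", 2), rep("S", 2))
  expect_equal(cell_qc_metrics(lc2)$mito_fraction, c(0, 0))
})

test_that("QC metrics match the generator's spiked ground truth", {
  spec <- synthetic_spec(n_genes = 100, cell_types = c(A = 30),
                         subjects = "S1", subject_sigma = 0, seed = 8)
  sim <- make_synthetic(spec)
  met <- cell_qc_metrics(sim$data)
  mito <- startsWith(gene_ids(sim$data), "MT-")
  expect_equal(met$library_size, unname(colSums(sim$data$counts)))
  expect_equal(met$mito_fraction,
               unname(colSums(sim$data$counts[mito, ]) /
                        colSums(sim$data$counts)))
})

test_that("MAD filter removes planted outliers and respects the boundary", {
  # all cells identical -> no outliers even though MAD = 0
  m <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  lc <- labeled_counts(m, rep("A", 6), rep("S", 6))
  expect_length(filter_cells_mad(lc)$removed, 0)

  # one cell with a 100x library in an otherwise homogeneous fixture
  m2 <- m; m2[, 3] <- m2[, 3] * 100
  lc2 <- labeled_counts(m2, rep("A", 6), rep("S", 6))
  expect_equal(filter_cells_mad(lc2)$removed, "c3")

  # a metric exactly at median + 3 * MAD is retained (strict inequality).
  # dyadic mito fractions make the boundary exact in floating point:
  # {.125, .25, .25, .4375} -> median .25, unscaled MAD .0625,
  # boundary .25 + 3 * .0625 = .4375.
  L <- 4096
  f <- c(0.125, 0.25, 0.25, 0.4375)
  m3 <- rbind("MT-1" = f * L, "B" = (1 - f) * L)
  colnames(m3) <- paste0("c", 1:4)
  lc3 <- labeled_counts(m3, rep("A", 4), rep("S", 4))
  expect_length(filter_cells_mad(lc3, qc_config(scaled_mad = FALSE))$removed,
                0)
  # one step beyond the boundary is removed
  f4 <- c(0.125, 0.25, 0.25, 0.46875)
  m4 <- rbind("MT-1" = f4 * L, "B" = (1 - f4) * L)
  colnames(m4) <- paste0("c", 1:4)
  lc4 <- labeled_counts(m4, rep("A", 4), rep("S", 4))
  expect_equal(filter_cells_mad(lc4, qc_config(scaled_mad = FALSE))$removed,
               "c4")
})

test_that("MAD filter agrees with a direct evaluation of the rule", {
  spec <- synthetic_spec(n_genes = 300, cell_types = c(A = 20, B = 20),
                         subjects = "S1", subject_sigma = 0,
                         outlier_cells = 3, outlier_fold = 50, seed = 1)
  sim <- make_synthetic(spec)
  dat <- filter_genes_basic(sim$data)$data
  got <- filter_cells_mad(dat)$removed

  met <- cell_qc_metrics(dat)
  flag <- rep(FALSE, nrow(met))
  for (x in list(log10(met$library_size), met$mito_fraction,
                 met$ribo_fraction)) {
    flag <- flag | abs(x - stats::median(x)) >
      3 * stats::mad(x, constant = 1.4826)
  }
  expect_setequal(got, met$cell_id[flag])
  expect_true(all(sim$truth$outlier_cells %in% got))
})

test_that("prevalence filter applies count > threshold in >= 5% of cells", {
  n <- 100
  m <- rbind(boundary = c(rep(2, 5), rep(0, n - 5)),   # kept: 5 >= 5
             ones = c(rep(1, n - 1), 0),               # removed: never > 1
             rare = c(rep(10, 4), rep(0, n - 4)),      # removed: 4 < 5
             common = c(rep(3, 50), rep(0, n - 50)))   # kept
  colnames(m) <- paste0("c", seq_len(n))
  lc <- labeled_counts(m, rep("A", n), rep("S", n))
  f <- filter_genes_prevalence(lc)
  expect_setequal(gene_ids(f$data), c("boundary", "common"))
  expect_setequal(f$removed, c("ones", "rare"))
})

test_that("TMM factors satisfy the scaling identities", {
  set.seed(7)
  base <- rpois(200, 20) + 1
  m <- matrix(base, 200, 4, dimnames = list(paste0("g", 1:200),
                                            paste0("c", 1:4)))
  lc <- labeled_counts(m, rep("A", 4), rep("S", 4))
  expect_equal(unname(tmm_factors(lc)), rep(1, 4))

  # column B = 2 x column A: pure library-size effect, factors stay 1
  m2 <- cbind(a = base, b = 2 * base)
  rownames(m2) <- paste0("g", 1:200)
  lc2 <- labeled_counts(m2, rep("A", 2), rep("S", 2))
  expect_equal(unname(tmm_factors(lc2)), c(1, 1))

  # geometric mean is 1 to numerical precision
  sim <- make_synthetic(synthetic_spec(n_genes = 150, seed = 5))
  f <- tmm_factors(filter_genes_basic(sim$data)$data)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
})

test_that("TMM matches an independent brute-force trim/weight oracle", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rnbinom(300 * 2, mu = runif(300, 1, 60), size = 2), 300, 2,
                dimnames = list(paste0("g", 1:300), c("c1", "c2")))
    keep <- rowSums(m) > 0 & apply(m, 1, function(r) !all(r == r[1]))
    m <- m[keep, ]
    lc <- labeled_counts(m, c("A", "A"), c("S", "S"))
    expect_lt(max(abs(tmm_factors(lc) - tmm_oracle(m))), 1e-9)
  }
})

test_that("normalization is an identity/scale-invariant operation", {
  lc <- tiny_lc()
  f1 <- stats::setNames(rep(1, 4), cell_ids(lc))
  # equal library sizes + unit factors -> output equals input
  m <- matrix(c(1, 2, 3, 3, 2, 1, 2, 2, 2, 1, 3, 2), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  eq <- labeled_counts(m, rep("A", 4), rep("S", 4))
  expect_equal(apply_normalization(eq, f1)$counts, eq$counts)

  # doubling a column's counts is undone up to the shared mean-library scale
  sim <- make_synthetic(synthetic_spec(n_genes = 80, seed = 2))
  dat <- filter_genes_basic(sim$data)$data
  doubled <- dat
  doubled$counts[, 1] <- doubled$counts[, 1] * 2
  fa <- tmm_factors(dat); fb <- tmm_factors(doubled)
  na <- apply_normalization(dat, fa)$counts
  nb <- apply_normalization(doubled, fb)$counts
  expect_lt(max(abs(na[, 1] / sum(na[, 1]) - nb[, 1] / sum(nb[, 1]))), 1e-9)
  expect_error(apply_normalization(dat, fa[-1]), "missing factor")
})

test_that("normalized column means equalize on a no-DE fixture", {
  set.seed(13)
  n <- 40
  m <- matrix(rpois(300 * n, lambda = rep(runif(300, 2, 40), n)), 300, n,
              dimnames = list(paste0("g", 1:300), paste0("c", 1:n)))
  depth <- runif(n, 0.5, 2)   # depth differences only, no DE
  m <- round(sweep(m, 2, depth, "*"))
  lc <- labeled_counts(m, rep("A", n), rep("S", n))
  norm <- apply_normalization(lc, tmm_factors(lc))
  cm <- colMeans(norm$counts)
  expect_lt(max(abs(cm / mean(cm) - 1)), 0.05)
})

test_that("the filtering pipeline is idempotent and order-preserving", {
  sim <- make_synthetic(synthetic_spec(seed = 6))
  p1 <- preprocess(sim$data, tmm = FALSE)
  p2 <- preprocess(p1$data, tmm = FALSE)
  expect_equal(p2$report$genes_removed_zero, 0)
  expect_equal(p2$report$cells_removed_qc, 0)
  expect_equal(p2$report$genes_removed_prevalence, 0)
  # filtering never reorders survivors
  expect_identical(gene_ids(p2$data), gene_ids(p1$data))
  expect_identical(cell_ids(p2$data), cell_ids(p1$data))

  # the gene filters are also idempotent across TMM normalization, which
  # rescales library sizes and hence intentionally re-centres the
  # library-size QC metric
  full <- preprocess(sim$data, tmm = TRUE)
  g2 <- filter_genes_basic(full$data)
  expect_length(g2$removed, 0)
})
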