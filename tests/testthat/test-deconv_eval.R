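test_that("signature columns are per-type means of CPM profiles", {
  m <- cbind(c1 = c(10, 0, 10), c2 = c(30, 10, 10), c3 = c(0, 40, 10))
  rownames(m) <- paste0("g", 1:3)
  lc <- labeled_counts(m, c("A", "A", "B"), rep("S", 3))
  sig <- build_signature(lc)
  cpm <- cpm_scale(m)
  expect_equal(sig$values[, "A"], (cpm[, 1] + cpm[, 2]) / 2)
  expect_equal(sig$values[, "B"], cpm[, 3])
  expect_equal(unname(colSums(sig$values)), rep(1e6, 2))
})

test_that("augmentation changes only the columns it contributes cells to", {
  sim <- make_synthetic(synthetic_spec(n_genes = 40, seed = 2))
  lc <- sim$data
  gen_a <- subset_counts(lc, cells = which(lc$cell_type == "A")[1:5])
  merged <- merge_references(lc, gen_a, "aug")
  s0 <- build_signature(lc)
  s1 <- build_signature(merged)
  expect_false(identical(s0$values[, "A"], s1$values[, "A"]))
  for (ty in c("B", "C", "D", "E"))
    expect_identical(s0$values[, ty], s1$values[, ty])
})

test_that("NNLS solves the worked examples and recovers noiseless mixtures", {
  sig <- structure(list(values = matrix(c(10, 0, 0, 10), 2,
                                        dimnames = list(c("g1", "g2"),
                                                        c("A", "B"))),
                        cell_types = c("A", "B"), scale = "cpm"),
                   class = "SignatureMatrix")
  est <- nnls_deconvolve(c(g1 = 5, g2 = 5), sig)
  expect_equal(unname(est[, 1]), c(0.5, 0.5))

  sig2 <- sig
  sig2$values[] <- c(8, 2, 2, 8)
  est2 <- nnls_deconvolve(c(g1 = 6, g2 = 4), sig2)
  expect_lt(max(abs(est2[, 1] - c(2 / 3, 1 / 3))), 1e-9)

  # noiseless identifiability on a well-conditioned random system
  set.seed(5)
  S <- matrix(runif(100 * 4, 1, 50), 100, 4,
              dimnames = list(paste0("g", 1:100), LETTERS[1:4]))
  sigr <- structure(list(values = S, cell_types = LETTERS[1:4],
                         scale = "cpm"), class = "SignatureMatrix")
  for (i in 1:5) {
    w <- rdir <- stats::rgamma(4, 1); w <- w / sum(w)
    b <- as.vector(S %*% w); names(b) <- rownames(S)
    est <- nnls_deconvolve(b, sigr)
    expect_lt(max(abs(est[, 1] - w)), 1e-6)
  }
  expect_error(nnls_deconvolve(c(x1 = 1, x2 = 2), sig), "empty gene")
  expect_error(nnls_deconvolve(c(g1 = 0, g2 = 0), sig), "all-zero")
})

test_that("NNLS agrees with the exhaustive simplex grid on 2-type problems", {
  set.seed(17)
  for (i in 1:50) {
    S <- matrix(runif(30 * 2, 0, 100), 30, 2,
                dimnames = list(paste0("g", 1:30), c("A", "B")))
    w <- runif(1)
    b <- as.vector(S %*% c(w, 1 - w)) +
      abs(rnorm(30, sd = 5))
    names(b) <- rownames(S)
    sig <- structure(list(values = S, cell_types = c("A", "B"),
                          scale = "cpm"), class = "SignatureMatrix")
    est <- nnls_deconvolve(b, sig)
    oracle <- nnls_grid_oracle(cpm_scale(S) * 0 + S, cpm_scale(
      matrix(b, ncol = 1, dimnames = list(names(b), "b")))[, 1])
    expect_lt(max(abs(est[, 1] - oracle)), 0.011)
  }
})

test_that("RMSE follows its definition and symmetries", {
  true <- rbind(A = c(0.5, 0.3), B = c(0.5, 0.7))
  expect_equal(prop_rmse(true, true, "overall"), 0)
  est <- rbind(A = c(0.6, 0.3), B = c(0.4, 0.7))
  expect_equal(prop_rmse(true, est, "per_mixture"),
               stats::setNames(c(0.1, 0), colnames(true)))
  perm <- c(2, 1)
  expect_equal(prop_rmse(true[, perm], est[, perm], "per_mixture"),
               prop_rmse(true, est, "per_mixture")[perm])
  expect_error(prop_rmse(true, est[, 1, drop = FALSE]), "shape")
})

test_that("Pearson metrics respect affine invariance and report NA safely", {
  true <- rbind(A = c(0.2, 0.5, 0.8), B = c(0.8, 0.5, 0.2))
  expect_equal(unname(prop_pearson(true, true, "per_type")), c(1, 1))
  expect_equal(prop_pearson(true, 0.5 * true + 0.1, "overall"), 1)
  # closed-form check on a hand-sized example
  est <- rbind(A = c(0.3, 0.4, 0.9), B = c(0.7, 0.6, 0.1))
  x <- true["A", ]; y <- est["A", ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(prop_pearson(true, est, "per_type")["A"]), r_hand)
  const <- rbind(A = c(0.5, 0.5, 0.5), B = c(0.5, 0.5, 0.5))
  expect_warning(r <- prop_pearson(const, est, "per_type"), "zero-variance")
  expect_true(all(is.na(r)))
})

test_that("paired t-test matches the closed form and rejects degeneracy", {
  a <- c(0.2, 0.1, 0.4)
  b <- a - c(-0.1, -0.2, 0.0)
  res <- paired_ttest(a, b)
  expect_lt(abs(res$t_statistic - (-sqrt(3))), 1e-9)
  expect_lt(abs(res$p_value - 2 * stats::pt(-sqrt(3), df = 2)), 1e-12)
  expect_equal(res$n_pairs, 3)
  # doubling all differences leaves t unchanged (sd doubles too)
  res2 <- paired_ttest(2 * a, 2 * b)
  expect_equal(res2$t_statistic, res$t_statistic)
  expect_error(paired_ttest(a, a - 0.1), "degenerate pairing")
  expect_error(paired_ttest(a, a), "degenerate pairing")
})

test_that("run_benchmark control arm has no comparison block", {
  ps <- prepped_split(synthetic_spec(n_genes = 60, seed = 3), split_seed = 3)
  rep0 <- run_benchmark(ps$train, ps$raw_test, NULL, n_mixtures = 20, seed = 1)
  expect_null(rep0$comparison)
  expect_equal(unname(colSums(rep0$estimated)), rep(1, 20))
  expect_true(all(rep0$estimated >= 0))
  expect_true(all(rep0$per_mixture_rmse >= 0))
})

test_that("duplicating the reference as 'generated' leaves metrics unchanged", {
  sim <- make_synthetic(synthetic_spec(n_genes = 50, seed = 4))
  lc <- sim$data
  copy <- subset_counts(lc)  # exact copies of all training cells
  merged <- merge_references(lc, copy, "dup")
  s0 <- build_signature(lc)
  s1 <- build_signature(merged)
  expect_lt(max(abs(s0$values - s1$values)), 1e-9)
  pb <- make_mixtures(lc, 20, 100, seed = 5)
  e0 <- nnls_deconvolve(pb$mixtures, s0)
  e1 <- nnls_deconvolve(pb$mixtures, s1)
  expect_lt(max(abs(e0 - e1)), 1e-9)
})

test_that("grid search is consistent with single runs and copula ignores epochs", {
  ps <- prepped_split(synthetic_spec(n_genes = 50, seed = 6), split_seed = 6)
  tmpl <- cmgan_config(cells_per_type = 20,
                       generator = generator_config("copula"), seed = 1)
  g <- grid_search(ps$train, ps$raw_test, tmpl, epochs_grid = 50,
                   cells_grid = 20, seed = 2, n_mixtures = 15)
  expect_equal(nrow(g), 1)
  direct <- run_benchmark(ps$train, ps$raw_test, tmpl, n_mixtures = 15,
                          seed = 2)
  expect_equal(g$delta_rmse, direct$comparison$delta_rmse)

  g2 <- grid_search(ps$train, ps$raw_test, tmpl,
                    epochs_grid = c(50, 100, 150), cells_grid = c(10, 20),
                    seed = 2, n_mixtures = 15)
  expect_equal(nrow(g2), 6)
  for (cells in c(10, 20)) {
    d <- g2$delta_rmse[g2$cells == cells]
    expect_true(all(d == d[1]))  # copula has no epoch parameter
  }
  # default grid dimensions
  eg <- seq(50, 300, by = 50); cg <- seq(100, 1000, by = 100)
  expect_equal(length(eg) * length(cg), 60)
})
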