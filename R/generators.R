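#' Generative-backend configuration
#'
#' Settings shared by the three benchmark generators. The grid the
#' hyperparameter search explores by default is 50-300 training epochs in
#' steps of 50 and 100-1000 generated cells per type in steps of 100.
#'
#' @param backend `"copula"`, `"gan"` or `"vae"`.
#' @param epochs training epochs for gan/vae (ignored by copula); default 100.
#' @param cells_per_type default number of cells to generate per cell type.
#' @param latent_dim latent (noise) dimension for gan/vae.
#' @param hidden_dims integer vector of hidden-layer widths.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate (gan default 2e-4, vae 1e-3 if
#'   left `NULL`).
#' @param seed integer seed; fitting and sampling are deterministic given it.
#' @return A list of class `GeneratorConfig`.
#' @export
generator_config <- function(backend = c("copula", "gan", "vae"),
                             epochs = 100, cells_per_type = 100,
                             latent_dim = 16, hidden_dims = c(64),
                             batch_size = 64, learning_rate = NULL,
                             seed = 1) {
  backend <- match.arg(backend)
  if (backend != "copula" && epochs < 1) stop("epochs must be >= 1")
  if (cells_per_type < 1) stop("cells_per_type must be >= 1")
  if (is.null(learning_rate))
    learning_rate <- if (backend == "gan") 2e-4 else 1e-3
  structure(list(backend = backend, epochs = epochs,
                 cells_per_type = cells_per_type, latent_dim = latent_dim,
                 hidden_dims = hidden_dims, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Fit a generative model on labelled single-cell data
#'
#' Three desk-scale backends behind one fit/sample contract:
#'
#' * `copula` — per cell type, a Gaussian copula: empirical per-gene marginals
#'   (midpoint ranks) coupled through the normal-scores correlation matrix,
#'   repaired to positive definite by eigenvalue clipping at 1e-6.
#' * `gan` — one conditional generator/discriminator pair over all types;
#'   condition is the one-hot cell type, data are log1p-transformed then
#'   per-gene min-max scaled to [-1, 1]; non-saturating GAN loss, Adam.
#' * `vae` — conditional encoder/decoder on the same transform, Gaussian
#'   latent, ELBO (squared-error reconstruction + KL) objective.
#'
#' @param train a `LabeledCounts`; every cell type needs at least 2 cells.
#' @param config a [generator_config()].
#' @return An object of class `GeneratorModel` holding the backend id, fitted
#'   state, the training gene ids and metadata (epochs, seed, loss trace).
#' @seealso [sample_cells()]
#' @export
fit_generator <- function(train, config) {
  stopifnot(inherits(train, "LabeledCounts"),
            inherits(config, "GeneratorConfig"))
  tab <- table(train$cell_type)
  if (any(tab < 2))
    stop("every cell type needs >= 2 cells; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (any(!is.finite(train$counts))) stop("non-finite expression values")
  types <- sort(names(tab))

  state <- with_local_seed(config$seed, switch(
    config$backend,
    copula = fit_copula_state(train, types),
    gan = fit_gan_state(train, types, config),
    vae = fit_vae_state(train, types, config)
  ))
  structure(list(backend = config$backend, state = state$state,
                 gene_ids = gene_ids(train), cell_types = types,
                 meta = list(epochs = config$epochs, seed = config$seed,
                             loss = state$loss, config = config)),
            class = "GeneratorModel")
}

#' @export
print.GeneratorModel <- function(x, ...) {
  cat(sprintf("GeneratorModel [%s]: %d genes, %d cell types (seed %d)\n",
              x$backend, length(x$gene_ids), length(x$cell_types),
              x$meta$seed))
  invisible(x)
}

#' Sample generated cells from a fitted model
#'
#' Draws `cells_per_type` new cells for every cell type the model was trained
#' on. Values are mapped back to the expression scale (inverse min-max, then
#' `expm1`) and clamped at zero; gene order equals the training order.
#'
#' @param model a [fit_generator()] result.
#' @param cells_per_type cells to generate per type.
#' @param seed integer seed.
#' @param round round generated values to integers (off by default: the
#'   downstream deconvolver treats the reference as expression levels).
#' @return A `LabeledCounts` of generated cells labelled with their cell type
#'   and a synthetic subject label.
#' @export
sample_cells <- function(model, cells_per_type = 100, seed = 1,
                         round = FALSE) {
  stopifnot(inherits(model, "GeneratorModel"))
  if (cells_per_type < 1) stop("cells_per_type must be >= 1")
  G <- length(model$gene_ids)
  types <- model$cell_types
  out <- with_local_seed(seed, {
    cols <- lapply(types, function(ty)
      switch(model$backend,
             copula = sample_copula_type(model$state, ty, cells_per_type),
             gan = sample_gan(model$state, ty, cells_per_type),
             vae = sample_vae(model$state, ty, cells_per_type)))
    do.call(cbind, cols)
  })
  out <- pmax(out, 0)
  if (round) out <- base::round(out)
  rownames(out) <- model$gene_ids
  colnames(out) <- paste0("gen_", model$backend, "_",
                          rep(types, each = cells_per_type), "_",
                          rep(seq_len(cells_per_type), length(types)))
  labeled_counts(out,
                 cell_type = rep(types, each = cells_per_type),
                 subject = rep(paste0("generated_", model$backend),
                               ncol(out)))
}

## ---- Gaussian copula ------------------------------------------------------

fit_copula_state <- function(train, types) {
  per_type <- lapply(types, function(ty) {
    x <- t(train$counts[, train$cell_type == ty, drop = FALSE])  # cells x genes
    n <- nrow(x)
    marg <- apply(x, 2, sort)
    if (is.vector(marg)) marg <- matrix(marg, nrow = n)
    constant <- apply(x, 2, function(v) all(v == v[1]))
    z <- apply(x, 2, function(v) {
      if (all(v == v[1])) return(rep(0, n))
      stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
    })
    R <- suppressWarnings(stats::cor(z))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    R <- nearest_pd_corr(R)
    list(chol = chol(R), marg = marg, n = n, constant = constant)
  })
  names(per_type) <- types
  list(state = list(per_type = per_type), loss = NULL)
}

# Eigenvalue clipping at 1e-6, rescaled back to unit diagonal.
nearest_pd_corr <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > 1e-6) return(R)
  v <- pmax(e$values, 1e-6)
  R2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(R2)
}

sample_copula_type <- function(state, ty, n) {
  st <- state$per_type[[ty]]
  G <- ncol(st$marg)
  z <- matrix(stats::rnorm(n * G), n, G) %*% st$chol
  u <- stats::pnorm(z)
  m <- st$n
  probs <- (seq_len(m) - 0.5) / m
  out <- matrix(0, G, n)
  for (g in seq_len(G)) {
    vals <- st$marg[, g]
    if (st$constant[g]) {
      out[g, ] <- vals[1]
    } else if (m == 1) {
      out[g, ] <- vals
    } else {
      out[g, ] <- stats::approx(probs, vals, xout = u[, g], rule = 2)$y
    }
  }
  out
}

## ---- shared GAN/VAE transform --------------------------------------------

# log1p then per-gene min-max to [-1, 1]; degenerate genes map to 0 and are
# restored to their constant on inversion.
make_transform <- function(counts) {
  lg <- log1p(counts)  # genes x cells
  mn <- apply(lg, 1, min)
  mx <- apply(lg, 1, max)
  rng <- mx - mn
  list(min = mn, range = rng)
}

transform_apply <- function(tr, counts) {
  lg <- log1p(counts)
  s <- (lg - tr$min) / ifelse(tr$range == 0, 1, tr$range)
  t(2 * s - ifelse(tr$range == 0, 0, 1))  # cells x genes in [-1, 1]
}

transform_invert <- function(tr, scaled) {
  # scaled: cells x genes in [-1, 1] -> genes x cells expression
  s <- (t(scaled) + 1) / 2
  lg <- s * tr$range + tr$min
  lg[tr$range == 0, ] <- tr$min[tr$range == 0]
  pmax(expm1(lg), 0)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## ---- conditional GAN ------------------------------------------------------

fit_gan_state <- function(train, types, config) {
  tr <- make_transform(train$counts)
  X <- transform_apply(tr, train$counts)          # cells x genes
  C <- t(one_hot(unname(train$cell_type), types)) # cells x K
  n <- nrow(X); G <- ncol(X); K <- length(types)
  ld <- config$latent_dim; hd <- config$hidden_dims

  gen <- mlp_new(c(ld + K, hd, G), c(rep("relu", length(hd)), "tanh"))
  dis <- mlp_new(c(G + K, hd, 1), c(rep("lrelu", length(hd)), "linear"))
  st_g <- adam_new(gen); st_d <- adam_new(dis)
  lr <- config$learning_rate
  bs <- min(config$batch_size, n)
  loss <- data.frame(epoch = seq_len(config$epochs), d_loss = NA_real_,
                     g_loss = NA_real_)

  for (ep in seq_len(config$epochs)) {
    idx <- sample(n)
    dl <- gl <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1, n)]
      b <- length(rows)
      Xr <- X[rows, , drop = FALSE]
      Cr <- C[rows, , drop = FALSE]
      Z <- matrix(stats::rnorm(b * ld), b, ld)
      fg <- mlp_forward(gen, cbind(Z, Cr))
      Xf <- fg$out

      # discriminator update: real -> 1, fake -> 0
      Din <- rbind(cbind(Xr, Cr), cbind(Xf, Cr))
      fd <- mlp_forward(dis, Din)
      logit <- fd$out[, 1]
      target <- c(rep(1, b), rep(0, b))
      dlogit <- matrix(1 / (1 + exp(-logit)) - target, ncol = 1)
      gd <- mlp_backward(dis, fd, dlogit)
      up <- adam_step(dis, gd, st_d, lr)
      dis <- up$net; st_d <- up$state
      dl <- dl + mean(softplus(-logit[1:b])) +
        mean(softplus(logit[(b + 1):(2 * b)]))

      # generator update (non-saturating): push D(fake) -> 1
      Z <- matrix(stats::rnorm(b * ld), b, ld)
      fg <- mlp_forward(gen, cbind(Z, Cr))
      fd <- mlp_forward(dis, cbind(fg$out, Cr))
      logit <- fd$out[, 1]
      dlogit <- matrix(1 / (1 + exp(-logit)) - 1, ncol = 1)
      gdd <- mlp_backward(dis, fd, dlogit)
      dFake <- gdd$dX[, seq_len(G), drop = FALSE]
      gg <- mlp_backward(gen, fg, dFake)
      up <- adam_step(gen, gg, st_g, lr)
      gen <- up$net; st_g <- up$state
      gl <- gl + mean(softplus(-logit))
      nb <- nb + 1
    }
    loss$d_loss[ep] <- dl / nb
    loss$g_loss[ep] <- gl / nb
    if (!is.finite(loss$d_loss[ep]) || !is.finite(loss$g_loss[ep]))
      stop("non-finite GAN loss at epoch ", ep)
  }
  list(state = list(gen = gen, transform = tr, latent_dim = ld,
                    types = types),
       loss = loss)
}

sample_gan <- function(state, ty, n) {
  K <- length(state$types)
  C <- t(one_hot(rep(ty, n), state$types))
  Z <- matrix(stats::rnorm(n * state$latent_dim), n, state$latent_dim)
  out <- mlp_forward(state$gen, cbind(Z, C))$out
  transform_invert(state$transform, out)
}

## ---- conditional VAE ------------------------------------------------------

fit_vae_state <- function(train, types, config) {
  tr <- make_transform(train$counts)
  X <- transform_apply(tr, train$counts)
  C <- t(one_hot(unname(train$cell_type), types))
  n <- nrow(X); G <- ncol(X); K <- length(types)
  ld <- config$latent_dim; hd <- config$hidden_dims

  enc <- mlp_new(c(G + K, hd, 2 * ld), c(rep("relu", length(hd)), "linear"))
  dec <- mlp_new(c(ld + K, hd, G), c(rep("relu", length(hd)), "tanh"))
  st_e <- adam_new(enc); st_d <- adam_new(dec)
  lr <- config$learning_rate
  bs <- min(config$batch_size, n)
  loss <- data.frame(epoch = seq_len(config$epochs), elbo_loss = NA_real_)

  for (ep in seq_len(config$epochs)) {
    idx <- sample(n)
    tot <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      rows <- idx[start:min(start + bs - 1, n)]
      b <- length(rows)
      Xb <- X[rows, , drop = FALSE]
      Cb <- C[rows, , drop = FALSE]

      fe <- mlp_forward(enc, cbind(Xb, Cb))
      mu <- fe$out[, seq_len(ld), drop = FALSE]
      logvar <- pmin(pmax(fe$out[, ld + seq_len(ld), drop = FALSE], -10), 10)
      epsm <- matrix(stats::rnorm(b * ld), b, ld)
      zc <- mu + epsm * exp(0.5 * logvar)
      fd <- mlp_forward(dec, cbind(zc, Cb))
      Xhat <- fd$out

      recon <- sum((Xhat - Xb)^2) / b
      kl <- sum(-0.5 * (1 + logvar - mu^2 - exp(logvar))) / b
      tot <- tot + recon + kl; nb <- nb + 1

      dXhat <- 2 * (Xhat - Xb)             # d(per-sample loss)/d out
      gd <- mlp_backward(dec, fd, dXhat)
      dz <- gd$dX[, seq_len(ld), drop = FALSE]
      dmu <- dz + mu
      dlogvar <- dz * epsm * 0.5 * exp(0.5 * logvar) +
        0.5 * (exp(logvar) - 1)
      ge <- mlp_backward(enc, fe, cbind(dmu, dlogvar))
      up <- adam_step(dec, gd, st_d, lr, beta1 = 0.9)
      dec <- up$net; st_d <- up$state
      up <- adam_step(enc, ge, st_e, lr, beta1 = 0.9)
      enc <- up$net; st_e <- up$state
    }
    loss$elbo_loss[ep] <- tot / nb
    if (!is.finite(loss$elbo_loss[ep]))
      stop("non-finite ELBO loss at epoch ", ep)
  }
  list(state = list(dec = dec, transform = tr, latent_dim = ld,
                    types = types),
       loss = loss)
}

sample_vae <- function(state, ty, n) {
  C <- t(one_hot(rep(ty, n), state$types))
  Z <- matrix(stats::rnorm(n * state$latent_dim), n, state$latent_dim)
  out <- mlp_forward(state$dec, cbind(Z, C))$out
  transform_invert(state$transform, out)
}
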