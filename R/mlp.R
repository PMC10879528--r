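# Minimal dense feed-forward network with manual backprop and Adam.
# Used by the conditional GAN and VAE backends; sized for desk-scale
# single-cell work (hundreds of cells, hundreds of genes), all in
# vectorised base-R matrix algebra.

# sizes: layer widths c(in, hidden..., out); act: one activation per
# non-input layer ("relu", "lrelu", "tanh", "sigmoid", "linear").
mlp_new <- function(sizes, act) {
  stopifnot(length(act) == length(sizes) - 1)
  L <- length(act)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- sqrt(2 / fan_in)  # He init; fine for tanh/linear at these widths
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, act = act)
}

act_fun <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         lrelu = ifelse(z > 0, z, 0.2 * z),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

act_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         lrelu = ifelse(z > 0, 1, 0.2),
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         linear = array(1, dim(z)))
}

# X: n x d. Returns activations (h[[1]] = X) and pre-activations.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  h <- vector("list", L + 1); z <- vector("list", L)
  h[[1]] <- X
  for (l in seq_len(L)) {
    z[[l]] <- sweep(h[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    h[[l + 1]] <- act_fun(z[[l]], net$act[l])
  }
  list(h = h, z = z, out = h[[L + 1]])
}

# dOut: gradient of the loss w.r.t. the network output (n x out).
# Returns per-parameter gradients (averaged over the batch is the caller's
# choice: gradients here are sums / n) and the gradient w.r.t. the input.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  n <- nrow(cache$h[[1]])
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    delta <- delta * act_grad(cache$z[[l]], cache$h[[l + 1]], net$act[l])
    dW[[l]] <- crossprod(cache$h[[l]], delta) / n
    db[[l]] <- colSums(delta) / n
    if (l > 1) delta <- delta %*% t(net$W[[l]])
    else dX <- delta %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = dX)
}

adam_new <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
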