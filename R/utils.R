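# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed, kept within 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k) %% 2147483647L)
}

#' Counts-per-million scaling
#'
#' Scales each column of a genes x samples matrix to a common depth of one
#' million. Columns with zero total are left at zero with a warning.
#'
#' @param m numeric matrix, genes x samples.
#' @return Matrix of the same shape with column sums equal to 1e6 (or 0).
#' @export
cpm_scale <- function(m) {
  libs <- colSums(m)
  zero <- libs == 0
  if (any(zero)) {
    warning("columns with zero total left at zero: ",
            paste(colnames(m)[zero], collapse = ", "))
    libs[zero] <- 1
  }
  sweep(m, 2, libs, "/") * 1e6
}

# Dirichlet draw via normalized gamma variates.
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)  # degenerate tiny-alpha guard
  g / sum(g)
}

# One-hot encode a factor-like vector against a fixed level set (rows = levels).
one_hot <- function(labels, levels) {
  m <- matrix(0, length(levels), length(labels),
              dimnames = list(levels, NULL))
  m[cbind(match(labels, levels), seq_along(labels))] <- 1
  m
}
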