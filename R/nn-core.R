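# Minimal neural-network plumbing: parameter trees (nested named lists of
# numeric arrays), analytic gradients, and Adam. Everything is plain base-R
# matrix algebra; gradients are verified against central finite differences
# in the test suite.

xavier_init <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Row-wise layer normalization with affine parameters.
layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv_sd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv_sd
  list(Y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv_sd = inv_sd)
}

layernorm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv_sd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Numerically stable row softmax; columns where keep == FALSE get weight 0.
# Rows must contain at least one kept column.
softmax_rows <- function(E, keep = NULL) {
  if (!is.null(keep)) E[, !keep] <- -Inf
  m <- apply(E, 1L, max)
  if (any(!is.finite(m))) stop("softmax over fully masked row")
  W <- exp(E - m)
  W / rowSums(W)
}

# dL/dE for A = softmax_rows(E): dE = A * (dA - rowSums(dA * A)).
softmax_backward <- function(dA, A) A * (dA - rowSums(dA * A))

# ---- parameter-tree utilities ------------------------------------------

# Apply f elementwise over the leaves of one or two parameter trees.
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(k) {
      tree_map(f, a[[k]], if (is.null(b)) NULL else b[[k]])
    })
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)
tree_add <- function(a, b) tree_map(`+`, a, b)
tree_scale <- function(p, s) tree_map(function(x) x * s, p)

# Accumulate grads g into acc, tolerating missing leaves in g (parameters
# untouched by a given loss simply receive no gradient).
tree_accumulate <- function(acc, g) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      acc[[nm]] <- tree_accumulate(acc[[nm]], g[[nm]])
    } else {
      acc[[nm]] <- acc[[nm]] + g[[nm]]
    }
  }
  acc
}

tree_has_nan <- function(p) {
  if (is.list(p)) any(vapply(p, tree_has_nan, NA)) else any(!is.finite(p))
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# One Adam update; lr may already include any warmup scaling.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  list(params = tree_map(`-`, params, upd), state = state)
}

# Linear warmup to `lr` over warmup steps, then constant.
lr_at_step <- function(step, lr, warmup) {
  if (warmup > 0 && step <= warmup) lr * step / warmup else lr
}
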