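#' Relative molecule self-attention encoder
#'
#' Each attention head scores a pair (i, j) with five terms: the vanilla
#' query-key product, query- and key-side content-dependent positional
#' biases against the projected relation embedding `b_ij^K`, a global
#' content bias `u' (x_j W^K)` and a global positional bias `v' b_ij^K`.
#' The softmax-weighted sum then aggregates `x_j W^V + b_ij^V`. Relation
#' embeddings are projected by two-layer networks `phi_K`, `phi_V` whose
#' hidden layer is shared across heads, with per-head output slices.
#'
#' Relation matrices use the row-major pair layout of [build_relations()]:
#' pair (i, j) is row `(i-1)*N + j`. Per-head key/value biases are stored as
#' `N^2 x (h * d_z)` matrices with head t in columns `(t-1)*d_z + 1 .. t*d_z`.
#'
#' @name rmat_encoder
NULL

addb <- function(M, b) sweep(M, 2L, b, `+`)

# x indexed (i-1)*N + j  ->  N x N matrix M[i, j]
rowmajor <- function(x, n) matrix(x, n, n, byrow = TRUE)

init_linear <- function(n_in, n_out, bias = TRUE) {
  l <- list(W = xavier_init(n_in, n_out))
  if (bias) l$b <- numeric(n_out)
  l
}

init_attention_params <- function(cfg, d_rel) {
  D <- cfg$d_model
  list(WQ = xavier_init(D, D), WK = xavier_init(D, D),
       WV = xavier_init(D, D), WO = xavier_init(D, D),
       u = matrix(0, cfg$n_heads, D %/% cfg$n_heads),
       v = matrix(0, cfg$n_heads, D %/% cfg$n_heads),
       phiK = list(W1 = xavier_init(d_rel, cfg$phi_hidden),
                   b1 = numeric(cfg$phi_hidden),
                   W2 = xavier_init(cfg$phi_hidden, D), b2 = numeric(D)),
       phiV = list(W1 = xavier_init(d_rel, cfg$phi_hidden),
                   b1 = numeric(cfg$phi_hidden),
                   W2 = xavier_init(cfg$phi_hidden, D), b2 = numeric(D)))
}

init_block_params <- function(cfg, d_rel) {
  D <- cfg$d_model
  list(ln1 = list(g = rep(1, D), b = numeric(D)),
       attn = init_attention_params(cfg, d_rel),
       ln2 = list(g = rep(1, D), b = numeric(D)),
       ffn = list(W1 = xavier_init(D, cfg$d_ffn), b1 = numeric(cfg$d_ffn),
                  W2 = xavier_init(cfg$d_ffn, D), b2 = numeric(D)))
}

# ---- relation projections ------------------------------------------------

phi_forward <- function(Bm, phi, slope) {
  pre <- addb(Bm %*% phi$W1, phi$b1)
  list(pre = pre, out = addb(leaky_relu(pre, slope) %*% phi$W2, phi$b2))
}

phi_backward <- function(dOut, Bm, fwd, phi, slope) {
  hidden <- leaky_relu(fwd$pre, slope)
  dHidden <- dOut %*% t(phi$W2)
  dPre <- dHidden * leaky_relu_grad(fwd$pre, slope)
  list(W1 = crossprod(Bm, dPre), b1 = colSums(dPre),
       W2 = crossprod(hidden, dOut), b2 = colSums(dOut))
}

#' Project relation embeddings into per-head key/value biases
#'
#' Applies the two-layer networks `phi_K` and `phi_V` (shared hidden layer,
#' per-head output slices) to every pair's relation embedding.
#'
#' @param b `N^2 x D'` relation matrix from [build_relations()] (or any
#'   matrix in the same pair layout).
#' @param params Attention parameter list containing `phiK` and `phiV`.
#' @param cfg An [rmat_config()].
#' @return List with 4-D arrays `bK` and `bV` of shape `(N, N, heads, d_z)`.
#' @export
relation_projections <- function(b, params, cfg) {
  N2 <- nrow(b)
  N <- as.integer(sqrt(N2))
  stopifnot(N * N == N2)
  if (ncol(b) != nrow(params$phiK$W1)) {
    stop("relation width ", ncol(b), " does not match phi input width ",
         nrow(params$phiK$W1))
  }
  dz <- cfg$d_model %/% cfg$n_heads
  to_array <- function(M) {
    aperm(array(M, c(N, N, dz, cfg$n_heads)), c(2L, 1L, 4L, 3L))
  }
  list(bK = to_array(phi_forward(b, params$phiK, cfg$leaky_slope)$out),
       bV = to_array(phi_forward(b, params$phiV, cfg$leaky_slope)$out))
}

# ---- single attention layer ---------------------------------------------

# Core forward for one layer on normalized inputs Xn (N x D) with relation
# matrix Bm (N^2 x D') and keep mask. Returns output before residual.
attn_core_forward <- function(Xn, Bm, keep, ap, cfg) {
  N <- nrow(Xn)
  h <- cfg$n_heads
  dz <- cfg$d_model %/% h
  Q <- Xn %*% ap$WQ
  K <- Xn %*% ap$WK
  V <- Xn %*% ap$WV
  fK <- phi_forward(Bm, ap$phiK, cfg$leaky_slope)
  fV <- phi_forward(Bm, ap$phiV, cfg$leaky_slope)
  BK <- fK$out
  BV <- fV$out
  ii <- rep(seq_len(N), each = N)
  jj <- rep.int(seq_len(N), N)
  O <- matrix(0, N, cfg$d_model)
  Alist <- vector("list", h)
  for (t in seq_len(h)) {
    cols <- ((t - 1L) * dz + 1L):(t * dz)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    BKh <- BK[, cols, drop = FALSE]
    BVh <- BV[, cols, drop = FALSE]
    e <- Qh %*% t(Kh) +
      rowmajor(rowSums(Qh[ii, , drop = FALSE] * BKh), N) +
      rowmajor(rowSums(Kh[jj, , drop = FALSE] * BKh), N) +
      matrix(as.vector(Kh %*% ap$u[t, ]), N, N, byrow = TRUE) +
      rowmajor(as.vector(BKh %*% ap$v[t, ]), N)
    A <- softmax_rows(e / sqrt(dz), keep)
    Alist[[t]] <- A
    aflat <- as.vector(t(A))
    O[, cols] <- A %*% Vh + rowsum(BVh * aflat, ii)
  }
  list(out = O %*% ap$WO,
       cache = list(Xn = Xn, Q = Q, K = K, V = V, BK = BK, BV = BV,
                    fK_pre = fK$pre, fV_pre = fV$pre, A = Alist, O = O,
                    ii = ii, jj = jj))
}

attn_core_backward <- function(dOut, cache, Bm, ap, cfg) {
  N <- nrow(cache$Xn)
  h <- cfg$n_heads
  dz <- cfg$d_model %/% h
  ii <- cache$ii
  jj <- cache$jj
  dO <- dOut %*% t(ap$WO)
  gWO <- crossprod(cache$O, dOut)
  dQ <- matrix(0, N, cfg$d_model)
  dK <- dQ
  dV <- dQ
  dBK <- matrix(0, N * N, cfg$d_model)
  dBV <- dBK
  gu <- matrix(0, h, dz)
  gv <- matrix(0, h, dz)
  for (t in seq_len(h)) {
    cols <- ((t - 1L) * dz + 1L):(t * dz)
    Qh <- cache$Q[, cols, drop = FALSE]
    Kh <- cache$K[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    BKh <- cache$BK[, cols, drop = FALSE]
    BVh <- cache$BV[, cols, drop = FALSE]
    A <- cache$A[[t]]
    aflat <- as.vector(t(A))
    dHead <- dO[, cols, drop = FALSE]
    dHead_ii <- dHead[ii, , drop = FALSE]
    # out_t = A V_h + sum_j a_ij bV_ij
    dA <- dHead %*% t(Vh) + rowmajor(rowSums(dHead_ii * BVh), N)
    dV[, cols] <- crossprod(A, dHead)
    dBV[, cols] <- dHead_ii * aflat
    dE <- softmax_backward(dA, A) / sqrt(dz)
    deflat <- as.vector(t(dE))
    csE <- colSums(dE)
    dQ[, cols] <- dE %*% Kh + rowsum(deflat * BKh, ii)
    dK[, cols] <- crossprod(dE, Qh) + rowsum(deflat * BKh, jj) +
      outer(csE, ap$u[t, ])
    dBK[, cols] <- deflat * (Qh[ii, , drop = FALSE] + Kh[jj, , drop = FALSE]) +
      outer(deflat, ap$v[t, ])
    gu[t, ] <- as.vector(crossprod(Kh, csE))
    gv[t, ] <- colSums(BKh * deflat)
  }
  gphiK <- phi_backward(dBK, Bm, list(pre = cache$fK_pre), ap$phiK,
                        cfg$leaky_slope)
  gphiV <- phi_backward(dBV, Bm, list(pre = cache$fV_pre), ap$phiV,
                        cfg$leaky_slope)
  dXn <- dQ %*% t(ap$WQ) + dK %*% t(ap$WK) + dV %*% t(ap$WV)
  grads <- list(WQ = crossprod(cache$Xn, dQ), WK = crossprod(cache$Xn, dK),
                WV = crossprod(cache$Xn, dV), WO = gWO, u = gu, v = gv,
                phiK = gphiK, phiV = gphiV)
  list(dXn = dXn, grads = grads)
}

#' Unnormalized relative attention logits
#'
#' The five-term pair score of each head, before scaling by `1/sqrt(d_z)`
#' and the softmax: vanilla query-key product, query- and key-side
#' content-dependent positional biases, global content bias and global
#' positional bias.
#'
#' @param X `N x D` input hidden states.
#' @param bK Projected key relation biases, either the `(N, N, h, d_z)`
#'   array from [relation_projections()] or the internal matrix layout.
#' @param params Attention parameters (`WQ`, `WK`, `u`, `v`).
#' @param cfg An [rmat_config()].
#' @return Array `(N, N, heads)` of logits `e_ij`.
#' @export
attention_logits <- function(X, bK, params, cfg) {
  N <- nrow(X)
  h <- cfg$n_heads
  dz <- cfg$d_model %/% h
  BK <- flatten_bias(bK, N, h, dz)
  Q <- X %*% params$WQ
  K <- X %*% params$WK
  ii <- rep(seq_len(N), each = N)
  jj <- rep.int(seq_len(N), N)
  out <- array(0, c(N, N, h))
  for (t in seq_len(h)) {
    cols <- ((t - 1L) * dz + 1L):(t * dz)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    BKh <- BK[, cols, drop = FALSE]
    out[, , t] <- Qh %*% t(Kh) +
      rowmajor(rowSums(Qh[ii, , drop = FALSE] * BKh), N) +
      rowmajor(rowSums(Kh[jj, , drop = FALSE] * BKh), N) +
      matrix(as.vector(Kh %*% params$u[t, ]), N, N, byrow = TRUE) +
      rowmajor(as.vector(BKh %*% params$v[t, ]), N)
  }
  out
}

# Accept either the exported (N, N, h, d_z) array form or the internal
# N^2 x (h * d_z) matrix form of a projected relation bias.
flatten_bias <- function(bK, N, h, dz) {
  if (is.matrix(bK)) return(bK)
  stopifnot(length(dim(bK)) == 4L)
  M <- matrix(0, N * N, h * dz)
  for (t in seq_len(h)) {
    for (k in seq_len(dz)) {
      M[, (t - 1L) * dz + k] <- as.vector(t(bK[, , t, k]))
    }
  }
  M
}

#' One relative self-attention layer
#'
#' Projects the relation tensor, computes the five-term logits, softmax
#' (masked positions excluded), aggregates `x_j W^V + b_ij^V` per head,
#' concatenates heads and applies the output projection. This is the bare
#' sublayer: no residual or normalization.
#'
#' @param X `N x D` hidden states.
#' @param b `N^2 x D'` relation matrix from [build_relations()].
#' @param params Attention parameter list (see [relation_projections()]).
#' @param cfg An [rmat_config()].
#' @param mask Logical vector, `TRUE` for positions that participate
#'   (default all).
#' @return List with `out` (`N x D`) and `attn` (`(N, N, heads)` array of
#'   attention weights; rows sum to 1 over unmasked positions).
#' @export
relative_attention <- function(X, b, params, cfg, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  if (!any(mask)) stop("all positions are masked")
  fw <- attn_core_forward(X, b, mask, params, cfg)
  h <- cfg$n_heads
  N <- nrow(X)
  attn <- array(0, c(N, N, h))
  for (t in seq_len(h)) attn[, , t] <- fw$cache$A[[t]]
  list(out = fw$out, attn = attn)
}

# ---- encoder block and stack --------------------------------------------

block_forward <- function(X, Bm, keep, lp, cfg, train = FALSE) {
  ln1 <- layernorm_forward(X, lp$ln1$g, lp$ln1$b)
  at <- attn_core_forward(ln1$Y, Bm, keep, lp$attn, cfg)
  attn_out <- at$out
  drop1 <- NULL
  if (train && cfg$dropout > 0) {
    drop1 <- matrix(stats::rbinom(length(attn_out), 1L, 1 - cfg$dropout) /
                      (1 - cfg$dropout), nrow(attn_out), ncol(attn_out))
    attn_out <- attn_out * drop1
  }
  X1 <- X + attn_out
  ln2 <- layernorm_forward(X1, lp$ln2$g, lp$ln2$b)
  pre <- addb(ln2$Y %*% lp$ffn$W1, lp$ffn$b1)
  hid <- leaky_relu(pre, cfg$leaky_slope)
  drop2 <- NULL
  if (train && cfg$dropout > 0) {
    drop2 <- matrix(stats::rbinom(length(hid), 1L, 1 - cfg$dropout) /
                      (1 - cfg$dropout), nrow(hid), ncol(hid))
    hid <- hid * drop2
  }
  ffn_out <- addb(hid %*% lp$ffn$W2, lp$ffn$b2)
  list(X = X1 + ffn_out,
       cache = list(ln1 = ln1, attn = at$cache, ln2 = ln2, pre = pre,
                    hid = hid, drop1 = drop1, drop2 = drop2))
}

block_backward <- function(dX, cache, Bm, lp, cfg) {
  dHid <- (dX %*% t(lp$ffn$W2))
  gW2 <- crossprod(cache$hid, dX)
  gb2 <- colSums(dX)
  if (!is.null(cache$drop2)) dHid <- dHid * cache$drop2
  dPre <- dHid * leaky_relu_grad(cache$pre, cfg$leaky_slope)
  gW1 <- crossprod(cache$ln2$Y, dPre)
  gb1 <- colSums(dPre)
  dLn2Y <- dPre %*% t(lp$ffn$W1)
  ln2b <- layernorm_backward(dLn2Y, cache$ln2, lp$ln2$g)
  dX1 <- dX + ln2b$dX
  dAttnOut <- dX1
  if (!is.null(cache$drop1)) dAttnOut <- dAttnOut * cache$drop1
  ab <- attn_core_backward(dAttnOut, cache$attn, Bm, lp$attn, cfg)
  ln1b <- layernorm_backward(ab$dXn, cache$ln1, lp$ln1$g)
  list(dX = dX1 + ln1b$dX,
       grads = list(ln1 = list(g = ln1b$dg, b = ln1b$db), attn = ab$grads,
                    ln2 = list(g = ln2b$dg, b = ln2b$db),
                    ffn = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)))
}

#' One encoder block: attention plus position-wise feed-forward
#'
#' Pre-norm residual arrangement: `X + Attn(LN(X))`, then
#' `X + FFN(LN(X))`, where the FFN is two linear layers with a leaky-ReLU
#' between them.
#'
#' @param X `N x D` hidden states.
#' @param b `N^2 x D'` relation matrix.
#' @param params Block parameter list (`ln1`, `attn`, `ln2`, `ffn`).
#' @param cfg An [rmat_config()].
#' @param mask Logical participation mask (default all `TRUE`).
#' @return `N x D` matrix of updated hidden states.
#' @export
encoder_block <- function(X, b, params, cfg, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  block_forward(X, b, mask, params, cfg)$X
}

encoder_forward <- function(params, cfg, Fmat, Bm, keep, train = FALSE) {
  X <- addb(Fmat %*% params$emb$W, params$emb$b)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    bf <- block_forward(X, Bm, keep, params$layers[[l]], cfg, train)
    X <- bf$X
    caches[[l]] <- bf$cache
  }
  lnf <- layernorm_forward(X, params$lnf$g, params$lnf$b)
  list(H = lnf$Y, caches = caches, lnf = lnf, Fmat = Fmat)
}

encoder_backward <- function(dH, fwd, params, cfg, Bm) {
  lnfb <- layernorm_backward(dH, fwd$lnf, params$lnf$g)
  dX <- lnfb$dX
  gl <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    bb <- block_backward(dX, fwd$caches[[l]], Bm, params$layers[[l]], cfg)
    dX <- bb$dX
    gl[[l]] <- bb$grads
  }
  list(grads = list(emb = list(W = crossprod(fwd$Fmat, dX), b = colSums(dX)),
                    layers = gl,
                    lnf = list(g = lnfb$dg, b = lnfb$db)),
       dF = dX %*% t(params$emb$W))
}
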