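#' Self-attention pooling to a graph embedding
#'
#' Pools the encoder hidden states `H` into a fixed-size graph embedding:
#' `P = softmax(W2 tanh(W1 H'))` row-wise over unmasked atoms, then
#' `g = flatten(P H)`. Each of the S pooling heads selects its own soft
#' subset of atoms; `g` has length `S * D`.
#'
#' @param H `N x D` hidden states from the encoder.
#' @param params Pooling parameters: `W1` (`pool_dim x D`) and `W2`
#'   (`pool_heads x pool_dim`).
#' @param mask Logical vector; `FALSE` positions get zero pooling weight.
#' @return List with `g` (length `S * D`, head-major) and `P`
#'   (`S x N` pooling weights, rows summing to 1 over unmasked atoms).
#' @export
attention_pool <- function(H, params, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(H))
  if (!any(mask)) stop("all atoms are masked; nothing to pool")
  fw <- pool_forward(H, mask, params)
  list(g = fw$g, P = fw$P)
}

pool_forward <- function(H, keep, pp) {
  Tpre <- pp$W1 %*% t(H)
  Tact <- tanh(Tpre)
  L <- pp$W2 %*% Tact
  P <- softmax_rows(L, keep)
  G <- P %*% H
  list(g = as.vector(t(G)), P = P, Tact = Tact, H = H)
}

pool_backward <- function(dg, cache, pp) {
  S <- nrow(cache$P)
  D <- ncol(cache$H)
  dG <- matrix(dg, S, D, byrow = TRUE)
  dH <- crossprod(cache$P, dG)
  dP <- dG %*% t(cache$H)
  dL <- softmax_backward(dP, cache$P)
  gW2 <- dL %*% t(cache$Tact)
  dT <- crossprod(pp$W2, dL)
  dTpre <- dT * (1 - cache$Tact^2)
  gW1 <- dTpre %*% cache$H
  dH <- dH + t(crossprod(pp$W1, dTpre))
  list(dH = dH, grads = list(W1 = gW1, W2 = gW2))
}

#' Physicochemical descriptor block
#'
#' The canonical RDKit descriptor list, ordered alphabetically and truncated
#' to `n` entries, evaluated on the molecule. Non-finite values are replaced
#' by 0. These raw values are z-normalized with train-fold statistics before
#' entering the model (see [descriptor_normalizer()]).
#'
#' @param mol An [rmat_molecule] or a single SMILES string.
#' @param n Number of descriptors (default 200).
#' @return Named numeric vector of length `n`.
#' @export
global_descriptors <- function(mol, n = 200L) {
  smiles <- if (inherits(mol, "rmat_molecule")) {
    if (!is.null(mol$descriptors) && length(mol$descriptors) == n) {
      return(mol$descriptors)
    }
    mol$canonical
  } else {
    mol
  }
  res <- rdkit_query(smiles, descriptors = n)
  check_descriptor_count(res, n)
  out <- unlist(res$mols[[1]]$descriptors)
  names(out) <- unlist(res$descriptor_names)
  out
}

#' Fit / apply train-fold descriptor normalization
#'
#' @param X Matrix of raw descriptor values (rows = molecules).
#' @return `descriptor_normalizer`: list with per-descriptor `center` and
#'   `scale` (zero-variance descriptors get scale 1).
#' @export
descriptor_normalizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' @rdname descriptor_normalizer
#' @param norm A normalizer from [descriptor_normalizer()].
#' @export
apply_normalizer <- function(X, norm) {
  out <- sweep(sweep(X, 2L, norm$center), 2L, norm$scale, `/`)
  out[!is.finite(out)] <- 0
  out
}

head_forward <- function(g, hp, slope) {
  g <- matrix(g, 1L)
  pre <- addb(g %*% hp$W1, hp$b1)
  hid <- leaky_relu(pre, slope)
  list(y = as.vector(addb(hid %*% hp$W2, hp$b2)), pre = pre, hid = hid, g = g)
}

head_backward <- function(dy, cache, hp, slope) {
  dy <- matrix(dy, 1L)
  gW2 <- crossprod(cache$hid, dy)
  gb2 <- as.vector(dy)
  dHid <- dy %*% t(hp$W2)
  dPre <- dHid * leaky_relu_grad(cache$pre, slope)
  gW1 <- crossprod(cache$g, dPre)
  gb1 <- as.vector(dPre)
  list(dg = as.vector(dPre %*% t(hp$W1)),
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}
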