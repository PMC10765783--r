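# Independent oracles and shared fixtures. Oracles are deliberately written
# as naive loops, never reusing the package's vectorized code paths.

# ---- graph oracle ---------------------------------------------------------

floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# ---- attention oracles ----------------------------------------------------

# Two-layer relation network applied to a single pair's embedding.
oracle_phi <- function(b_row, phi, slope) {
  h <- as.vector(t(phi$W1) %*% b_row) + phi$b1
  h <- ifelse(h > 0, h, slope * h)
  as.vector(t(phi$W2) %*% h) + phi$b2
}

# Five-term logits, one scalar at a time. bK is the (N, N, h, d_z) array.
oracle_logits <- function(X, bK, params, cfg) {
  N <- nrow(X)
  h <- cfg$n_heads
  dz <- cfg$d_model / h
  out <- array(0, c(N, N, h))
  for (t in seq_len(h)) {
    cols <- ((t - 1) * dz + 1):(t * dz)
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        q <- as.vector(X[i, ] %*% params$WQ)[cols]
        k <- as.vector(X[j, ] %*% params$WK)[cols]
        b <- bK[i, j, t, ]
        out[i, j, t] <- sum(q * k) + sum(q * b) + sum(k * b) +
          sum(params$u[t, ] * k) + sum(params$v[t, ] * b)
      }
    }
  }
  out
}

# Full relative attention layer by explicit per-position loops.
oracle_relative_attention <- function(X, bK, bV, params, cfg, mask = NULL) {
  N <- nrow(X)
  if (is.null(mask)) mask <- rep(TRUE, N)
  h <- cfg$n_heads
  dz <- cfg$d_model / h
  e <- oracle_logits(X, bK, params, cfg)
  O <- matrix(0, N, cfg$d_model)
  for (t in seq_len(h)) {
    cols <- ((t - 1) * dz + 1):(t * dz)
    for (i in seq_len(N)) {
      w <- exp(e[i, , t] / sqrt(dz) - max(e[i, mask, t] / sqrt(dz)))
      w[!mask] <- 0
      w <- w / sum(w)
      acc <- numeric(dz)
      for (j in seq_len(N)) {
        v <- as.vector(X[j, ] %*% params$WV)[cols] + bV[i, j, t, ]
        acc <- acc + w[j] * v
      }
      O[i, cols] <- acc
    }
  }
  O %*% params$WO
}

# Vanilla multi-head attention (no relation terms) on the same weights.
oracle_vanilla_mha <- function(X, params, cfg) {
  N <- nrow(X)
  h <- cfg$n_heads
  dz <- cfg$d_model / h
  Q <- X %*% params$WQ
  K <- X %*% params$WK
  V <- X %*% params$WV
  O <- matrix(0, N, cfg$d_model)
  for (t in seq_len(h)) {
    cols <- ((t - 1) * dz + 1):(t * dz)
    E <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dz)
    W <- exp(E - apply(E, 1, max))
    W <- W / rowSums(W)
    O[, cols] <- W %*% V[, cols, drop = FALSE]
  }
  O %*% params$WO
}

# Per-head pooling by explicit loops.
oracle_pool <- function(H, pp, mask = NULL) {
  N <- nrow(H)
  if (is.null(mask)) mask <- rep(TRUE, N)
  S <- nrow(pp$W2)
  g <- numeric(0)
  for (s in seq_len(S)) {
    l <- numeric(N)
    for (i in seq_len(N)) {
      l[i] <- sum(pp$W2[s, ] * tanh(as.vector(pp$W1 %*% H[i, ])))
    }
    w <- exp(l - max(l[mask]))
    w[!mask] <- 0
    w <- w / sum(w)
    g <- c(g, as.vector(t(H) %*% w))
  }
  g
}

# ---- shared fixtures ------------------------------------------------------

STD_SMILES <- c(co2 = "C(=O)=O", methane = "C", benzene = "c1ccccc1",
                ethane = "CC", ethanol = "CCO", chain8 = "CCCCCCCC",
                toluene = "Cc1ccccc1", pyridine = "c1ccncc1",
                acetone = "CC(=O)C", phenol = "Oc1ccccc1")

std_mols <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- parse_smiles_batch(unname(STD_SMILES), scaffold = TRUE)
      names(m) <- names(STD_SMILES)
      cache <<- m
    }
    cache
  }
})

# Fully featurized standard set under a given config (coords, dummy, F, B).
std_featurized <- local({
  cache <- list()
  function(cfg) {
    key <- paste(cfg$max_order, cfg$n_emb, cfg$cutoff, cfg$use_distance,
                 cfg$use_bond, cfg$use_neighborhood, sep = "|")
    if (is.null(cache[[key]])) {
      fx <- featurize_molecules(unname(STD_SMILES), cfg, seed = 1)
      names(fx$mols) <- names(STD_SMILES)
      names(fx$items) <- names(STD_SMILES)
      cache[[key]] <<- fx
    }
    cache[[key]]
  }
})

test_cfg <- function(...) rmat_small_config(...)

# Random rotation (det +1) in 3D.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Re-featurize an augmented molecule after transforming the real-atom
# coordinates; the dummy row keeps the cutoff distance.
item_with_coords <- function(mol, cfg, transform) {
  real <- !mol$atoms$is_dummy
  C2 <- transform(mol$coords[real, , drop = FALSE])
  D <- mol$D
  D[real, real] <- as.matrix(dist(C2))
  mol$coords[real, ] <- C2
  mol$D <- D
  list(F = atom_features(mol), B = build_relations(mol, cfg),
       keep = rep(TRUE, nrow(mol$atoms)))
}

# Permute the real atoms of a featurized item (dummy stays last).
permute_item <- function(item, perm) {
  n <- nrow(item$F)
  stopifnot(length(perm) == n)
  Bp <- matrix(0, n * n, ncol(item$B))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      Bp[(a - 1) * n + b, ] <- item$B[(perm[a] - 1) * n + perm[b], ]
    }
  }
  list(F = item$F[perm, , drop = FALSE], B = Bp, keep = item$keep[perm])
}
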