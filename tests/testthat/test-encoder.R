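# Random small instances for oracle comparisons.
random_instance <- function(N, cfg, seed) {
  set.seed(seed)
  d_rel <- rmat:::relation_width(cfg)
  params <- rmat:::with_seed(seed + 1, {
    p <- rmat:::init_attention_params(cfg, d_rel)
    p$u <- matrix(rnorm(length(p$u), sd = 0.3), nrow(p$u))
    p$v <- matrix(rnorm(length(p$v), sd = 0.3), nrow(p$v))
    p
  })
  list(X = matrix(rnorm(N * cfg$d_model), N),
       B = matrix(rnorm(N * N * d_rel, sd = 0.5), N * N),
       params = params)
}

test_that("relation projections match a per-pair two-layer oracle", {
  cfg <- test_cfg(n_emb = 8L)
  inst <- random_instance(4L, cfg, 11)
  pr <- relation_projections(inst$B, inst$params, cfg)
  dz <- cfg$d_model / cfg$n_heads
  expect_equal(dim(pr$bK), c(4L, 4L, cfg$n_heads, dz))
  for (i in 1:4) for (j in 1:4) {
    bk <- oracle_phi(inst$B[(i - 1) * 4 + j, ], inst$params$phiK, cfg$leaky_slope)
    bv <- oracle_phi(inst$B[(i - 1) * 4 + j, ], inst$params$phiV, cfg$leaky_slope)
    for (t in seq_len(cfg$n_heads)) {
      cols <- ((t - 1) * dz + 1):(t * dz)
      expect_equal(pr$bK[i, j, t, ], bk[cols], tolerance = 1e-6)
      expect_equal(pr$bV[i, j, t, ], bv[cols], tolerance = 1e-6)
    }
  }
  # zero relations through a bias-free network give zero projections
  p0 <- inst$params
  p0$phiK$b1[] <- 0; p0$phiK$b2[] <- 0
  pr0 <- relation_projections(inst$B * 0, p0, cfg)
  expect_equal(max(abs(pr0$bK)), 0)
  # width mismatch is a config error
  expect_error(relation_projections(inst$B[, 1:5], inst$params, cfg), "width")
})

test_that("attention logits reproduce the five printed terms", {
  cfg <- test_cfg(d_model = 8L, phi_hidden = 8L, n_emb = 4L)
  inst <- random_instance(5L, cfg, 21)
  pr <- relation_projections(inst$B, inst$params, cfg)
  e <- attention_logits(inst$X, pr$bK, inst$params, cfg)
  expect_equal(e, oracle_logits(inst$X, pr$bK, inst$params, cfg),
               tolerance = 1e-6)
  # with relations and u, v zeroed the logits reduce to vanilla QK^T
  p0 <- inst$params
  p0$u[] <- 0; p0$v[] <- 0
  e0 <- attention_logits(inst$X, pr$bK * 0, p0, cfg)
  dz <- cfg$d_model / cfg$n_heads
  for (t in seq_len(cfg$n_heads)) {
    cols <- ((t - 1) * dz + 1):(t * dz)
    Q <- (inst$X %*% p0$WQ)[, cols]
    K <- (inst$X %*% p0$WK)[, cols]
    expect_equal(e0[, , t], Q %*% t(K), tolerance = 1e-10)
  }
  # zero inputs and zero v kill all five terms
  ez <- attention_logits(inst$X * 0, pr$bK, p0, cfg)
  # terms with bK survive via x-independent pieces only when u,v nonzero;
  # here only (x W^Q) b and (x W^K) b and v' b remain, all zero
  expect_equal(max(abs(ez)), 0)
})

test_that("relative attention matches the brute-force loop oracle", {
  for (seed in c(5, 17)) {
    cfg <- test_cfg(d_model = 16L, phi_hidden = 12L, n_emb = 6L)
    N <- 5L
    inst <- random_instance(N, cfg, seed)
    pr <- relation_projections(inst$B, inst$params, cfg)
    res <- relative_attention(inst$X, inst$B, inst$params, cfg)
    expect_equal(res$out,
                 oracle_relative_attention(inst$X, pr$bK, pr$bV, inst$params, cfg),
                 tolerance = 1e-6)
    # attention rows are stochastic over unmasked positions
    for (t in seq_len(cfg$n_heads)) {
      expect_equal(rowSums(res$attn[, , t]), rep(1, N), tolerance = 1e-12)
    }
    # masked positions receive zero weight
    mask <- c(rep(TRUE, N - 1L), FALSE)
    resm <- relative_attention(inst$X, inst$B, inst$params, cfg, mask)
    expect_true(all(resm$attn[, N, ] == 0))
    expect_error(relative_attention(inst$X, inst$B, inst$params, cfg,
                                    rep(FALSE, N)), "mask")
  }
})

test_that("zeroed relations and biases reduce to a vanilla transformer layer", {
  cfg <- test_cfg(d_model = 16L)
  inst <- random_instance(6L, cfg, 33)
  p0 <- inst$params
  p0$u[] <- 0; p0$v[] <- 0
  p0$phiK$W1[] <- 0; p0$phiK$b1[] <- 0; p0$phiK$W2[] <- 0; p0$phiK$b2[] <- 0
  p0$phiV$W1[] <- 0; p0$phiV$b1[] <- 0; p0$phiV$W2[] <- 0; p0$phiV$b2[] <- 0
  res <- relative_attention(inst$X, inst$B, p0, cfg)
  expect_equal(res$out, oracle_vanilla_mha(inst$X, p0, cfg), tolerance = 1e-6)
})

test_that("encoder blocks preserve shape, respect residuals and stack", {
  cfg <- test_cfg(n_emb = 8L)
  d_rel <- rmat:::relation_width(cfg)
  N <- 5L
  set.seed(9)
  X <- matrix(rnorm(N * cfg$d_model), N)
  B <- matrix(rnorm(N * N * d_rel, sd = 0.3), N * N)
  lp <- rmat:::with_seed(10, rmat:::init_block_params(cfg, d_rel))
  X1 <- encoder_block(X, B, lp, cfg)
  expect_equal(dim(X1), dim(X))
  # zero output projections make both sublayers identity via the residuals
  lp0 <- lp
  lp0$attn$WO[] <- 0
  lp0$ffn$W2[] <- 0; lp0$ffn$b2[] <- 0
  expect_equal(encoder_block(X, B, lp0, cfg), X)
  # the stacked encoder is the iterated application of its blocks
  model <- rmat_model(cfg, seed = 4)
  item <- std_featurized(cfg)$items$ethanol
  enc <- rmat:::encoder_forward(model$params, cfg, item$F, item$B, item$keep)
  Xi <- rmat:::addb(item$F %*% model$params$emb$W, model$params$emb$b)
  for (l in seq_len(cfg$n_layers)) {
    Xi <- encoder_block(Xi, item$B, model$params$layers[[l]], cfg)
  }
  lnf <- rmat:::layernorm_forward(Xi, model$params$lnf$g, model$params$lnf$b)
  expect_equal(enc$H, lnf$Y, tolerance = 1e-10)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- test_cfg(d_model = 8L, d_ffn = 16L, phi_hidden = 8L, n_emb = 4L,
                  pool_dim = 8L)
  fx <- std_featurized(cfg)
  item <- fx$items$acetone
  model <- rmat_model(cfg, seed = 12)
  target <- 1.7
  loss_of <- function(params) {
    m2 <- model
    m2$params <- params
    (rmat:::model_forward(m2, item)$y - target)^2
  }
  fw <- rmat:::model_forward(model, item)
  gr <- rmat:::model_backward(2 * (fw$y - target), fw, model, item)
  pluck <- function(x, path) {
    for (p in path) x <- x[[p]]
    x
  }
  poke <- function(x, path, value) {
    if (length(path) == 1L) {
      x[[path[[1L]]]] <- value
    } else {
      x[[path[[1L]]]] <- poke(x[[path[[1L]]]], path[-1L], value)
    }
    x
  }
  paths <- list(
    list("layers", 1L, "attn", "WQ"), list("layers", 1L, "attn", "WK"),
    list("layers", 1L, "attn", "WV"), list("layers", 1L, "attn", "WO"),
    list("layers", 2L, "attn", "u"), list("layers", 2L, "attn", "v"),
    list("layers", 2L, "attn", "phiK", "W2"),
    list("layers", 1L, "attn", "phiV", "W1"),
    list("layers", 1L, "ln1", "g"), list("layers", 2L, "ln2", "b"),
    list("layers", 2L, "ffn", "W1"), list("layers", 1L, "ffn", "b2"),
    list("emb", "W"), list("lnf", "g"), list("pool", "W1"), list("pool", "W2"),
    list("head", "W1"), list("head", "b2"))
  eps <- 1e-5
  set.seed(77)
  for (path in paths) {
    leaf <- pluck(model$params, path)
    k <- sample.int(length(leaf), 1L)
    bump <- function(delta) {
      leaf2 <- leaf
      leaf2[k] <- leaf2[k] + delta
      poke(model$params, path, leaf2)
    }
    num <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
    ana <- pluck(gr, path)[k]
    expect_lt(abs(ana - num), 1e-6 + 1e-4 * abs(num),
              label = paste("grad gap at", paste(unlist(path), collapse = "/")))
  }
})

test_that("encoding is permutation-equivariant and batch-independent", {
  cfg <- test_cfg()
  fx <- std_featurized(cfg)
  model <- rmat_model(cfg, seed = 3)
  item <- fx$items$toluene
  n <- nrow(item$F)
  H <- encode_molecules(model, list(item))[[1]]$H
  set.seed(8)
  perm <- c(sample(n - 1L), n)       # dummy stays last
  Hp <- encode_molecules(model, list(permute_item(item, perm)))[[1]]$H
  expect_equal(Hp, H[perm, ], tolerance = 1e-6)
  # identical output alone and inside a padded batch
  padded <- pad_item(item, 3L)
  Hpad <- encode_molecules(model, list(padded))[[1]]$H
  expect_equal(Hpad[seq_len(n), ], H, tolerance = 1e-6)
  y1 <- predict(model, list(item))
  y2 <- predict(model, list(padded))
  expect_equal(y1, y2, tolerance = 1e-6)
  expect_error(encode_molecules(model, list()), "empty")
})

test_that("the forward pass is blind to rigid motions and mirror images", {
  cfg <- test_cfg()
  fx <- std_featurized(cfg)
  model <- rmat_model(cfg, seed = 6)
  mol <- fx$mols$phenol
  base <- predict(model, fx$items["phenol"])
  set.seed(13)
  R <- random_rotation()
  moved <- item_with_coords(mol, cfg, function(C) sweep(C %*% R, 2L, c(3, -2, 1), `+`))
  mirrored <- item_with_coords(mol, cfg, function(C) C %*% diag(c(-1, 1, 1)))
  expect_equal(predict(model, list(moved)), base, tolerance = 1e-10)
  expect_equal(predict(model, list(mirrored)), base, tolerance = 1e-10)
})
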