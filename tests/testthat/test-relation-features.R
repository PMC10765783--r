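test_that("atom features are 36-wide with one-hot blocks", {
  cfg <- test_cfg()
  fx <- std_featurized(cfg)
  f <- fx$items$benzene$F
  expect_equal(ncol(f), 36L)
  # atom-type block is one-hot for every atom including the dummy
  expect_true(all(rowSums(f[, 1:12]) == 1))
  carbon <- f[1, ]
  expect_equal(unname(carbon["type_C"]), 1)
  expect_equal(unname(carbon["degree_2"]), 1)
  expect_equal(unname(carbon["numH_1"]), 1)
  expect_equal(unname(carbon["ring_6"]), 1)
  expect_equal(unname(carbon["aromatic"]), 1)
  expect_equal(unname(carbon["in_ring"]), 1)
  dummy <- f[7, ]
  expect_equal(unname(dummy["type_dummy"]), 1)
  expect_true(all(dummy[setdiff(seq_len(36), 11L)] == 0))
})

test_that("unsupported elements fall back to the 'other' slot with a warning", {
  m <- parse_smiles("C[Se]C")
  m <- add_dummy_node(embed_conformer(m, seed = 1), 20)
  expect_warning(f <- atom_features(m), "other")
  expect_equal(unname(f[2, "type_other"]), 1)
})

test_that("neighborhood embedding buckets hop counts per the class table", {
  fx <- std_featurized(test_cfg())
  co2 <- fx$mols$co2
  nb <- neighborhood_embedding(co2$hops, co2$atoms$is_dummy)
  expect_equal(ncol(nb), 6L)
  n <- 4L
  cls <- function(i, j) which(nb[(i - 1L) * n + j, ] == 1) - 1L
  expect_equal(cls(1, 1), 0L)          # self
  expect_equal(cls(1, 2), 1L)          # bonded
  expect_equal(cls(2, 3), 2L)          # one atom between (O..O)
  expect_equal(cls(4, 1), 5L)          # dummy overrides everything
  expect_equal(cls(4, 4), 5L)
  # exactly one class per pair, symmetric under i <-> j
  expect_true(all(rowSums(nb) == 1))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(nb[(i - 1L) * n + j, ], nb[(j - 1L) * n + i, ])
  }
  chain8 <- fx$mols$chain8
  nb8 <- neighborhood_embedding(chain8$hops, chain8$atoms$is_dummy)
  expect_equal(which(nb8[(1 - 1L) * 9L + 8L, ] == 1) - 1L, 4L)  # 7 hops -> top
})

test_that("maximum-order variants collapse classes and shrink the one-hot", {
  chain8 <- std_featurized(test_cfg())$mols$chain8
  nb1 <- neighborhood_embedding(chain8$hops, chain8$atoms$is_dummy, max_order = 1L)
  expect_equal(ncol(nb1), 3L)          # self / bonded-or-farther / dummy
  expect_equal(which(nb1[(1 - 1L) * 9L + 2L, ] == 1), 2L)  # bonded
  expect_equal(which(nb1[(1 - 1L) * 9L + 8L, ] == 1), 2L)  # far away, same class
  nb2 <- neighborhood_embedding(chain8$hops, chain8$atoms$is_dummy, max_order = 2L)
  r <- function(i, j) which(nb2[(i - 1L) * 9L + j, ] == 1)
  expect_equal(r(1, 3), r(1, 8))       # hops >= 2 share one class
  expect_true(r(1, 2) != r(1, 3))
  cfg1 <- max_order_variant(test_cfg(), 1L)
  expect_equal(ncol(std_featurized(cfg1)$items$chain8$B), 3L + 7L + cfg1$n_emb)
  expect_error(max_order_variant(test_cfg(), 5L), "1..4")
})

test_that("bond embedding encodes order, aromaticity, conjugation and rings", {
  fx <- std_featurized(test_cfg())
  benz <- fx$mols$benzene
  be <- bond_embedding(benz)
  n <- nrow(benz$atoms)
  expect_equal(ncol(be), 7L)
  expect_equal(be[(1 - 1L) * n + 2L, ], c(0, 1, 0, 0, 1, 1, 1))  # aromatic ring bond
  expect_equal(be[(1 - 1L) * n + 3L, ], rep(0, 7))               # non-bonded
  expect_equal(be[(n - 1L) * n + 1L, ], rep(0, 7))               # dummy pair
  eth <- fx$mols$ethane
  expect_equal(bond_embedding(eth)[(1 - 1L) * 3L + 2L, ],
               c(1, 0, 0, 0, 0, 0, 0))                           # plain single bond
})

test_that("distance embedding analytics: cutoff, envelope and zero limit", {
  c_ <- 20
  p <- 6L
  n_emb <- 16L
  # all basis values vanish at d = c
  expect_equal(as.vector(distance_embedding(c_, c_, n_emb, p)), rep(0, n_emb))
  expect_equal(as.vector(distance_embedding(c_ + 3, c_, n_emb, p)), rep(0, n_emb))
  # envelope boundary values; at d = c the printed polynomial gives 1-28+48-21
  expect_equal(rbf_envelope(0, c_, p), 1)
  expect_equal(1 - 28 + 48 - 21, 0)
  expect_equal(rbf_envelope(c_, c_, p), 0)
  # smooth cutoff: finite-difference derivative at d = c is 0
  hstep <- 1e-5
  du <- (rbf_envelope(c_ - hstep, c_, p) - rbf_envelope(c_ - 2 * hstep, c_, p)) / hstep
  expect_lt(abs(du), 1e-4)
  # d -> 0 analytic limit sqrt(2/c) * n pi / c
  lim <- sqrt(2 / c_) * (1:n_emb) * pi / c_
  expect_equal(as.vector(distance_embedding(0, c_, n_emb, p)), lim)
  expect_equal(as.vector(distance_embedding(1e-8, c_, n_emb, p)), lim,
               tolerance = 1e-8)
  # continuity spot check inside [0, c)
  d1 <- distance_embedding(5, c_, n_emb, p)
  d2 <- distance_embedding(5 + 1e-7, c_, n_emb, p)
  expect_lt(max(abs(d1 - d2)), 1e-5)
})

test_that("distance block is invariant under rigid motions and reflections", {
  cfg <- test_cfg()
  fx <- std_featurized(cfg)
  mol <- fx$mols$toluene
  base <- fx$items$toluene$B
  set.seed(42)
  R <- random_rotation()
  shift <- rnorm(3)
  moved <- item_with_coords(mol, cfg, function(C) {
    sweep(C %*% R, 2L, shift, `+`)
  })$B
  expect_lt(max(abs(moved - base)), 1e-10)
  mirrored <- item_with_coords(mol, cfg, function(C) {
    C %*% diag(c(-1, 1, 1))
  })$B
  expect_lt(max(abs(mirrored - base)), 1e-10)
})

test_that("relation tensor layout and ablation switches", {
  cfg <- test_cfg()
  fx <- std_featurized(cfg)
  B <- fx$items$co2$B
  expect_equal(ncol(B), 6L + 7L + cfg$n_emb)
  expect_equal(nrow(B), 16L)
  blocks <- attr(B, "blocks")
  # dummy pairs: class 5 and an all-zero bond block
  drow <- (4L - 1L) * 4L + 1L
  expect_equal(which(B[drow, blocks$neighborhood] == 1), 6L)
  expect_true(all(B[drow, blocks$bond] == 0))
  # distance block of the dummy pair vanishes (it sits at the cutoff)
  expect_true(all(B[drow, blocks$distance] == 0))
  for (block in names(blocks)) {
    cfg_off <- test_cfg()
    cfg_off[[paste0("use_", block)]] <- FALSE
    B_off <- build_relations(fx$mols$co2, cfg_off)
    expect_equal(ncol(B_off), ncol(B))                 # D' unchanged
    expect_true(all(B_off[, blocks[[block]]] == 0))    # block zeroed
    others <- setdiff(unlist(blocks), blocks[[block]])
    expect_equal(B_off[, others], B[, others], ignore_attr = TRUE)
  }
})
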