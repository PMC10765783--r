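test_that("metrics match hand-computed values", {
  y <- c(1, 2, 3)
  expect_equal(eval_metric(y, y, "rmse"), 0)
  expect_equal(eval_metric(y, y, "mae"), 0)
  expect_equal(eval_metric(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), "roc_auc"), 1)
  # 4-point hand case: 3 of 4 pairs concordant
  expect_equal(eval_metric(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), "roc_auc"), 0.75)
  expect_equal(eval_metric(c(2, 4), c(3, 6), "rmse"), sqrt(mean(c(1, 4))))
  expect_error(eval_metric(c(1, 1, 1), c(0.2, 0.3, 0.4), "roc_auc"), "single")
})

test_that("scaffold splits respect fractions and never leak scaffolds", {
  # 10 molecules with all-distinct scaffolds: counts 8/1/1
  scaff10 <- paste0("ring", 1:10)
  f10 <- scaffold_split(scaff10, seed = 1)
  expect_equal(unname(table(f10)[c("train", "valid", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  # structural analogues always share a fold
  mols <- std_mols()[c("toluene", "phenol", "benzene", "pyridine", "co2",
                       "ethanol", "acetone")]
  scaff <- vapply(mols, function(m) m$scaffold, "")
  expect_equal(scaff[["toluene"]], scaff[["phenol"]])  # both benzene-cored
  for (s in 1:5) {
    fold <- scaffold_split(unname(scaff), fractions = c(0.6, 0.2, 0.2), seed = s)
    expect_equal(fold[[1]], fold[[2]])
    # no scaffold appears in two folds
    leak <- tapply(fold, unname(scaff), function(x) length(unique(x)))
    expect_true(all(leak == 1L))
  }
  # random mode is a reproducible permutation
  r1 <- scaffold_split(rep("x", 20), seed = 3, mode = "random")
  r2 <- scaffold_split(rep("x", 20), seed = 3, mode = "random")
  expect_identical(r1, r2)
  expect_equal(sum(r1 == "test"), 2L)
  expect_error(scaffold_split(rep(c("a", "b"), 5)), "random")
})

test_that("fixture generation is deterministic, valid and size-bounded", {
  f1 <- generate_fixtures(40, seed = 7, labels = FALSE)
  f2 <- generate_fixtures(40, seed = 7, labels = FALSE)
  expect_identical(f1$smiles, f2$smiles)
  expect_equal(f1$smiles[1], "C(=O)=O")
  lab <- generate_fixtures(40, seed = 7, max_atoms = 12L)
  expect_true(all(lab$embed_ok))                 # every fixture embeds
  expect_true(all(lab$heavy_atoms <= 12L))
  expect_true(all(lab$heavy_atoms >= 1L))
  expect_equal(lab$heavy_atoms[1], 3L)           # carbon dioxide
  expect_equal(lab$bond_order_sum[1], 4)         # two double bonds
  expect_true(all(lab$inv_dist_sum[lab$heavy_atoms > 1] > 0))
})

test_that("a one-point learning-rate grid reduces finetune to plain training", {
  cfg <- test_cfg(n_emb = 16L)
  fix <- generate_fixtures(40, seed = 21)
  fx <- featurize_molecules(fix$smiles, cfg, seed = 21)
  exp_cfg <- rmat_experiment(task = "regression", lr_grid = 1e-3, epochs = 3L,
                             split_seeds = 1L, split_mode = "random",
                             init_seed = 11L)
  run <- finetune(cfg, list(items = fx$items, y = fix$heavy_atoms,
                            scaffolds = fx$scaffolds), exp_cfg)
  # replicate by hand: same split, same standardization, same training seed
  fold <- scaffold_split(rep("", 40), exp_cfg$fractions, seed = 1L,
                         mode = "random")
  tr <- fold == "train"
  te <- fold == "test"
  mu <- mean(fix$heavy_atoms[tr])
  sd_ <- sd(fix$heavy_atoms[tr])
  model <- rmat_model(cfg, seed = 11L)
  fit <- train_rmat(model, fx$items[tr], (fix$heavy_atoms[tr] - mu) / sd_,
                    lr = 1e-3, epochs = 3L, batch_size = exp_cfg$batch_size,
                    seed = 1L * 1000L + 1L)
  pred <- predict(fit$model, fx$items[te]) * sd_ + mu
  expect_equal(run$mean_test,
               eval_metric(fix$heavy_atoms[te], as.vector(pred), "rmse"),
               tolerance = 1e-10)
  expect_equal(nrow(run$results), 1L)
  expect_equal(run$results$lr, 1e-3)
})

test_that("model selection consults validation only; test is scored once", {
  cfg <- test_cfg(n_emb = 8L)
  fix <- generate_fixtures(30, seed = 22)
  fx <- featurize_molecules(fix$smiles, cfg, seed = 22)
  exp_cfg <- rmat_experiment(task = "regression", lr_grid = c(5e-4, 2e-3),
                             epochs = 2L, split_seeds = c(1L, 2L),
                             split_mode = "random")
  run <- finetune(cfg, list(items = fx$items, y = fix$heavy_atoms,
                            scaffolds = fx$scaffolds), exp_cfg)
  audit <- do.call(rbind, lapply(run$audit, as.data.frame))
  # per seed: one validation evaluation per grid point, exactly one test
  for (s in c(1L, 2L)) {
    a <- audit[audit$seed == s, ]
    expect_equal(sum(a$fold == "valid"), 2L)
    expect_equal(sum(a$fold == "test"), 1L)
    # the test evaluation used the validation-chosen learning rate
    expect_equal(a$lr[a$fold == "test"],
                 run$results$lr[run$results$seed == s])
  }
  expect_equal(run$mean_test, mean(run$results$test))
})

test_that("training reports divergence instead of propagating NaNs", {
  cfg <- test_cfg(n_emb = 8L)
  fx <- std_featurized(cfg)
  model <- rmat_model(cfg, seed = 1)
  model$params$head$W2[] <- 1e150   # force an overflow on the first step
  res <- train_rmat(model, fx$items[1:4], rep(1, 4), lr = 1e200, epochs = 2L,
                    seed = 1)
  expect_true(res$diverged)
})

test_that("end-to-end determinism: same seeds and config, same metrics", {
  cfg <- test_cfg(n_emb = 8L)
  fix <- generate_fixtures(20, seed = 5)
  fx <- featurize_molecules(fix$smiles, cfg, seed = 5)
  fit1 <- train_rmat(rmat_model(cfg, seed = 2), fx$items, fix$heavy_atoms,
                     lr = 1e-3, epochs = 2L, seed = 9)
  fit2 <- train_rmat(rmat_model(cfg, seed = 2), fx$items, fix$heavy_atoms,
                     lr = 1e-3, epochs = 2L, seed = 9)
  expect_identical(fit1$history, fit2$history)
  expect_equal(predict(fit1$model, fx$items[1:3]),
               predict(fit2$model, fx$items[1:3]), tolerance = 1e-12)
})
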