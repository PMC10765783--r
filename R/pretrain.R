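#' Pretraining tasks
#'
#' Two desk-scale self-supervised objectives: (1) contextual property
#' prediction — selected atoms AND their graph neighbors are masked in the
#' atom feature matrix (the relation tensor is left untouched) and the model
#' must classify each selected atom's radius-1 chemical environment key;
#' (2) graph-level prediction — regression of a vector of physicochemical
#' descriptors from the pooled graph embedding. The stages run sequentially
#' (contextual first) or jointly.
#'
#' @name pretrain_tasks
NULL

order_letter <- c("1" = "S", "1.5" = "A", "2" = "D", "3" = "T")

#' Radius-1 chemical environment key of an atom
#'
#' The key is the atom's element followed by the sorted multiset of its
#' bonds, each written as `<order letter>-<neighbor element><count>` with
#' S/A/D/T for single/aromatic/double/triple. The central carbon of carbon
#' dioxide gives `"C_D-O2"`; an atom with no heavy neighbors gives just its
#' element.
#'
#' @param mol An [rmat_molecule].
#' @param atom_i 1-based atom index (must not be the dummy node).
#' @return The context key string.
#' @export
context_key <- function(mol, atom_i) {
  stopifnot(inherits(mol, "rmat_molecule"))
  if (mol$atoms$is_dummy[atom_i]) stop("context key of the dummy node is undefined")
  b <- mol$bonds
  hit <- b$i == atom_i | b$j == atom_i
  el <- mol$atoms$element[atom_i]
  if (!any(hit)) return(el)
  nbr <- ifelse(b$i[hit] == atom_i, b$j[hit], b$i[hit])
  term <- paste0(order_letter[as.character(b$order[hit])], "-",
                 mol$atoms$element[nbr])
  tab <- table(term)
  key_terms <- sort(paste0(names(tab), as.integer(tab)))
  paste(c(el, key_terms), collapse = "_")
}

#' Build the context vocabulary over a corpus
#'
#' Collects the radius-1 environment keys of every real atom, drops keys
#' rarer than `min_count`, and assigns dense indices in sorted key order
#' (so the vocabulary is reproducible given the corpus and threshold).
#' Index `size` (= number of kept keys + 1) is the "unknown" class.
#'
#' @param mols List of [rmat_molecule] objects.
#' @param min_count Minimum corpus frequency for a key to get its own class.
#' @return List with `keys`, `index` (named integer vector), `unknown` and
#'   `size`.
#' @export
build_context_vocab <- function(mols, min_count = 1L) {
  keys <- unlist(lapply(mols, function(m) {
    real <- which(!m$atoms$is_dummy)
    vapply(real, function(i) context_key(m, i), "")
  }))
  if (!length(keys)) stop("empty corpus: no atoms to build a vocabulary from")
  tab <- table(keys)
  kept <- sort(names(tab)[tab >= min_count])
  list(keys = kept, index = stats::setNames(seq_along(kept), kept),
       unknown = length(kept) + 1L, size = length(kept) + 1L)
}

vocab_lookup <- function(vocab, keys) {
  idx <- vocab$index[keys]
  idx[is.na(idx)] <- vocab$unknown
  unname(idx)
}

#' Mask atoms and their neighbors for contextual pretraining
#'
#' Samples `max(1, floor(fraction * n_real))` real atoms; the selected atoms
#' and all their bonded neighbors have their atom features replaced by the
#' mask vector (all zeros except the dedicated mask flag). The dummy node is
#' never selected or masked, and the relation tensor is left unchanged.
#' Labels are the pre-masking context keys of the selected atoms.
#'
#' @param mol An [rmat_molecule] (dummy-augmented).
#' @param item Its featurized item from [featurize_molecules()].
#' @param fraction Fraction of real atoms to select, in (0, 1].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with `F_masked`, `selected` (atom indices), `masked`
#'   (selected plus neighbors), and `labels` (context keys).
#' @export
mask_for_context <- function(mol, item, fraction = 0.15, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  real <- which(!mol$atoms$is_dummy)
  if (length(real) < 2L) stop("contextual masking needs at least 2 real atoms")
  draw <- function() {
    n_sel <- max(1L, floor(fraction * length(real)))
    sel <- real[sample.int(length(real), n_sel)]
    sort(sel)
  }
  sel <- if (is.null(seed)) draw() else with_seed(seed, draw())
  b <- mol$bonds
  nbrs <- unique(c(b$j[b$i %in% sel], b$i[b$j %in% sel]))
  masked <- sort(union(sel, nbrs))
  masked <- masked[!mol$atoms$is_dummy[masked]]
  Fm <- item$F
  Fm[masked, ] <- 0
  Fm[masked, MASK_COLUMN] <- 1
  list(F_masked = Fm, selected = sel, masked = masked,
       labels = vapply(sel, function(i) context_key(mol, i), ""))
}

#' Graph-level descriptor targets
#'
#' The descriptor machinery of [global_descriptors()], used as regression
#' targets: deterministic per molecule, identical for identical graphs.
#' Normalize across the pretraining corpus with [descriptor_normalizer()].
#'
#' @param mol An [rmat_molecule] or SMILES string.
#' @param n Number of descriptors.
#' @param normalizer Optional normalizer to apply.
#' @return Numeric vector of length `n`.
#' @export
graph_level_targets <- function(mol, n = 200L, normalizer = NULL) {
  v <- global_descriptors(mol, n)
  if (!is.null(normalizer)) {
    v <- as.vector(apply_normalizer(matrix(v, 1L), normalizer))
  }
  v
}

# Contextual cross-entropy at the selected positions of a masked item.
contextual_loss <- function(model, item, Fm, sel, label_idx, train = FALSE) {
  cfg <- model$config
  enc <- encoder_forward(model$params, cfg, Fm, item$B, item$keep, train)
  Hs <- enc$H[sel, , drop = FALSE]
  Z <- addb(Hs %*% model$params$ctx$W, model$params$ctx$b)
  P <- softmax_rows(Z)
  n_sel <- length(sel)
  picked <- cbind(seq_len(n_sel), label_idx)
  loss <- -mean(log(P[picked] + 1e-12))
  dZ <- P
  dZ[picked] <- dZ[picked] - 1
  dZ <- dZ / n_sel
  dH <- matrix(0, nrow(enc$H), ncol(enc$H))
  dH[sel, ] <- dZ %*% t(model$params$ctx$W)
  eb <- encoder_backward(dH, enc, model$params, cfg, item$B)
  grads <- eb$grads
  grads$ctx <- list(W = crossprod(Hs, dZ), b = colSums(dZ))
  list(loss = loss, grads = grads, pred = max.col(P))
}

# Graph-level descriptor regression from the pooled embedding.
graph_loss <- function(model, item, target, train = FALSE) {
  cfg <- model$config
  enc <- encoder_forward(model$params, cfg, item$F, item$B, item$keep, train)
  pool <- pool_forward(enc$H, item$keep, model$params$pool)
  hd <- head_forward(pool$g, model$params$gdesc, cfg$leaky_slope)
  r <- hd$y - target
  loss <- mean(r^2)
  hb <- head_backward(2 * r / length(r), hd, model$params$gdesc, cfg$leaky_slope)
  pb <- pool_backward(hb$dg, pool, model$params$pool)
  eb <- encoder_backward(pb$dH, enc, model$params, cfg, item$B)
  grads <- eb$grads
  grads$pool <- pb$grads
  grads$gdesc <- hb$grads
  list(loss = loss, grads = grads)
}

#' Compute the pretraining losses on one batch
#'
#' @param model An `rmat_model` built with `vocab_size` (and, for the graph
#'   stage, `n_graph_targets`).
#' @param batch List of entries, each a list with `mol`, `item`, and for the
#'   graph stage a `graph_targets` vector; contextual masking uses
#'   `fraction` and `seed`.
#' @param vocab Context vocabulary from [build_context_vocab()].
#' @param stage `"contextual"`, `"graph"` or `"both"`.
#' @param fraction Masking fraction.
#' @param seed Masking seed (per batch).
#' @return List with the mean `contextual` cross-entropy, mean `graph` MSE
#'   (NA for stages not run) and their `total`.
#' @export
pretrain_step <- function(model, batch, vocab = NULL,
                          stage = c("both", "contextual", "graph"),
                          fraction = 0.15, seed = 1L) {
  stage <- match.arg(stage)
  ce <- NA_real_
  mse <- NA_real_
  if (stage %in% c("both", "contextual")) {
    if (is.null(vocab) || is.null(model$params$ctx)) {
      stop("contextual stage needs a vocabulary and a model built with vocab_size")
    }
    ce <- mean(vapply(seq_along(batch), function(k) {
      entry <- batch[[k]]
      mk <- mask_for_context(entry$mol, entry$item, fraction,
                             seed = seed + k)
      contextual_loss(model, entry$item, mk$F_masked, mk$selected,
                      vocab_lookup(vocab, mk$labels))$loss
    }, 0))
  }
  if (stage %in% c("both", "graph")) {
    if (is.null(model$params$gdesc)) {
      stop("graph stage needs a model built with n_graph_targets")
    }
    mse <- mean(vapply(batch, function(entry) {
      graph_loss(model, entry$item, entry$graph_targets)$loss
    }, 0))
  }
  list(contextual = ce, graph = mse, total = sum(c(ce, mse), na.rm = TRUE))
}

#' Run the two-step pretraining procedure
#'
#' Stage 1 trains the contextual environment classifier on freshly drawn
#' masks every presentation; stage 2 trains graph-level descriptor
#' regression. Either stage can be skipped by setting its epochs to 0.
#'
#' @param model An `rmat_model` with the required heads.
#' @param mols,items Corpus from [featurize_molecules()].
#' @param vocab Context vocabulary.
#' @param graph_targets Matrix of normalized descriptor targets (rows =
#'   molecules), required when `epochs_graph > 0`.
#' @param epochs_contextual,epochs_graph Epochs per stage.
#' @param lr Learning rate (Adam, linear warmup then constant).
#' @param fraction Masking fraction.
#' @param batch_size Molecules per update.
#' @param seed Seed controlling shuffling and mask draws.
#' @return List with the trained `model` and per-stage loss `history`.
#' @export
pretrain <- function(model, mols, items, vocab, graph_targets = NULL,
                     epochs_contextual = 30L, epochs_graph = 10L,
                     lr = 1e-3, fraction = 0.15, batch_size = 16L, seed = 1L) {
  hist_ctx <- numeric(0)
  hist_graph <- numeric(0)
  if (epochs_contextual > 0L) {
    entries <- Map(function(m, it) list(mol = m, item = it), mols, items)
    # single-heavy-atom molecules have no maskable context
    entries <- Filter(function(e) sum(!e$mol$atoms$is_dummy) >= 2L, entries)
    loss_fn <- function(mod, entry, target, train) {
      mk <- mask_for_context(entry$mol, entry$item, fraction)
      cl <- contextual_loss(mod, entry$item, mk$F_masked, mk$selected,
                            vocab_lookup(vocab, mk$labels), train)
      list(loss = cl$loss, grads = cl$grads)
    }
    res <- sgd_train(model, entries, vector("list", length(entries)), loss_fn,
                     lr, epochs_contextual, batch_size, seed)
    model <- res$model
    hist_ctx <- res$history
  }
  if (epochs_graph > 0L) {
    if (is.null(graph_targets)) stop("graph stage needs graph_targets")
    targets <- lapply(seq_len(nrow(graph_targets)),
                      function(i) graph_targets[i, ])
    loss_fn <- function(mod, item, target, train) {
      graph_loss(mod, item, target, train)
    }
    res <- sgd_train(model, items, targets, loss_fn, lr, epochs_graph,
                     batch_size, seed + 1L)
    model <- res$model
    hist_graph <- res$history
  }
  list(model = model, history = list(contextual = hist_ctx, graph = hist_graph))
}

#' Masked-context prediction accuracy
#'
#' Draws deterministic masks over the corpus, predicts each selected atom's
#' environment class, and reports the accuracy together with the
#' majority-class baseline of the same evaluation labels.
#'
#' @inheritParams pretrain
#' @param seed Seed for the evaluation mask draws.
#' @return List with `accuracy`, `majority_baseline` and `n_labels`.
#' @export
eval_context_accuracy <- function(model, mols, items, vocab,
                                  fraction = 0.15, seed = 99L) {
  preds <- integer(0)
  labels <- integer(0)
  for (k in seq_along(mols)) {
    if (sum(!mols[[k]]$atoms$is_dummy) < 2L) next
    mk <- mask_for_context(mols[[k]], items[[k]], fraction, seed = seed + k)
    lab <- vocab_lookup(vocab, mk$labels)
    cl <- contextual_loss(model, items[[k]], mk$F_masked, mk$selected, lab)
    preds <- c(preds, cl$pred)
    labels <- c(labels, lab)
  }
  list(accuracy = mean(preds == labels),
       majority_baseline = max(table(labels)) / length(labels),
       n_labels = length(labels))
}
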