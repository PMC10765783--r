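#' Construct a relative molecule self-attention transformer
#'
#' Builds the full parameter tree: atom-feature embedding, `n_layers`
#' encoder blocks, final layer normalization, self-attention pooling and the
#' two-layer prediction MLP, plus optional heads for the pretraining tasks
#' (a context classifier over masked-atom environment keys and a
#' graph-level descriptor regressor).
#'
#' @param cfg An [rmat_config()].
#' @param n_outputs Number of prediction targets.
#' @param task `"regression"` (linear output) or `"classification"`
#'   (logit output; probabilities via `predict(..., type = "response")`).
#' @param vocab_size Context-vocabulary size; adds the contextual
#'   pretraining head when non-`NULL`.
#' @param n_graph_targets Number of graph-level descriptor targets; adds the
#'   graph-level pretraining head when non-`NULL`.
#' @param seed Seed for parameter initialization.
#' @return An object of class `rmat_model`.
#' @export
rmat_model <- function(cfg, n_outputs = 1L, task = c("regression", "classification"),
                       vocab_size = NULL, n_graph_targets = NULL, seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(cfg, "rmat_config"), n_outputs >= 1L)
  d_rel <- relation_width(cfg)
  g_dim <- cfg$pool_heads * cfg$d_model
  head_in <- g_dim + if (cfg$use_descriptors) cfg$n_descriptors else 0L
  params <- with_seed(seed, {
    p <- list(
      emb = list(W = xavier_init(ATOM_FEATURE_WIDTH, cfg$d_model),
                 b = numeric(cfg$d_model)),
      layers = lapply(seq_len(cfg$n_layers),
                      function(l) init_block_params(cfg, d_rel)),
      lnf = list(g = rep(1, cfg$d_model), b = numeric(cfg$d_model)),
      pool = list(W1 = xavier_init(cfg$pool_dim, cfg$d_model),
                  W2 = xavier_init(cfg$pool_heads, cfg$pool_dim)),
      head = list(W1 = xavier_init(head_in, cfg$head_hidden),
                  b1 = numeric(cfg$head_hidden),
                  W2 = xavier_init(cfg$head_hidden, n_outputs),
                  b2 = numeric(n_outputs)))
    if (!is.null(vocab_size)) {
      p$ctx <- list(W = xavier_init(cfg$d_model, vocab_size),
                    b = numeric(vocab_size))
    }
    if (!is.null(n_graph_targets)) {
      p$gdesc <- list(W1 = xavier_init(g_dim, cfg$head_hidden),
                      b1 = numeric(cfg$head_hidden),
                      W2 = xavier_init(cfg$head_hidden, n_graph_targets),
                      b2 = numeric(n_graph_targets))
    }
    p
  })
  structure(list(params = params, config = cfg, n_outputs = as.integer(n_outputs),
                 task = task, vocab_size = vocab_size,
                 n_graph_targets = n_graph_targets),
            class = "rmat_model")
}

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' @export
print.rmat_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(unlist(tree_map(length, x$params)))
  cat("<rmat_model> ", cfg$n_layers, " layers, ", cfg$n_heads, " heads, D = ",
      cfg$d_model, ", D' = ", relation_width(cfg), ", ", n_par,
      " parameters\n", sep = "")
  invisible(x)
}

# ---- full forward / backward ---------------------------------------------

# item: list(F = N x 36 atom features, B = N^2 x D' relations, keep = logical
# participation mask, desc = normalized descriptor vector (optional)).
model_forward <- function(model, item, train = FALSE) {
  cfg <- model$config
  enc <- encoder_forward(model$params, cfg, item$F, item$B, item$keep, train)
  pool <- pool_forward(enc$H, item$keep, model$params$pool)
  g <- pool$g
  if (cfg$use_descriptors) {
    if (is.null(item$desc)) stop("configuration uses descriptors but item has none")
    g <- c(g, item$desc)
  }
  hd <- head_forward(g, model$params$head, cfg$leaky_slope)
  list(y = hd$y, enc = enc, pool = pool, head = hd)
}

model_backward <- function(dy, fw, model, item) {
  cfg <- model$config
  hb <- head_backward(dy, fw$head, model$params$head, cfg$leaky_slope)
  g_dim <- cfg$pool_heads * cfg$d_model
  dg <- hb$dg[seq_len(g_dim)]        # descriptor block carries no gradient
  pb <- pool_backward(dg, fw$pool, model$params$pool)
  eb <- encoder_backward(pb$dH, fw$enc, model$params, cfg, item$B)
  grads <- eb$grads
  grads$pool <- pb$grads
  grads$head <- hb$grads
  grads
}

#' Predict properties for featurized molecules
#'
#' @param object An `rmat_model`.
#' @param items Featurized items from [featurize_molecules()].
#' @param type `"link"` returns raw outputs (regression values or logits);
#'   `"response"` applies the sigmoid for classification models.
#' @param ... Unused.
#' @return Numeric matrix, one row per molecule.
#' @export
predict.rmat_model <- function(object, items, type = c("link", "response"), ...) {
  type <- match.arg(type)
  out <- t(vapply(items, function(it) model_forward(object, it)$y,
                  numeric(object$n_outputs)))
  if (object$n_outputs == 1L) out <- matrix(out, ncol = 1L)
  if (type == "response") {
    if (object$task == "classification") {
      out <- 1 / (1 + exp(-out))
    } else if (!is.null(object$label_scale)) {
      # undo the train-fold label standardization recorded by finetune()
      out <- sweep(sweep(out, 2L, object$label_scale, `*`), 2L,
                   object$label_center, `+`)
    }
  }
  out
}

#' Run the encoder and collect hidden states and attention maps
#'
#' @param model An `rmat_model`.
#' @param items Featurized items from [featurize_molecules()] (non-empty).
#' @return List per molecule: `H` (`N x D` hidden states) and `attn`, a list
#'   over layers of `(N, N, heads)` attention-weight arrays suitable for
#'   attention-map inspection.
#' @export
encode_molecules <- function(model, items) {
  if (length(items) == 0L) stop("empty batch")
  cfg <- model$config
  lapply(items, function(it) {
    enc <- encoder_forward(model$params, cfg, it$F, it$B, it$keep)
    attn <- lapply(enc$caches, function(cc) {
      N <- nrow(it$F)
      a <- array(0, c(N, N, cfg$n_heads))
      for (t in seq_len(cfg$n_heads)) a[, , t] <- cc$attn$A[[t]]
      a
    })
    list(H = enc$H, attn = attn)
  })
}

# ---- losses ---------------------------------------------------------------

# Squared-error loss with NA-masked labels; returns d(loss)/dy as well.
loss_regression <- function(y, target) {
  obs <- which(!is.na(target))
  if (!length(obs)) return(list(loss = 0, dy = numeric(length(y))))
  r <- y[obs] - target[obs]
  dy <- numeric(length(y))
  dy[obs] <- 2 * r / length(obs)
  list(loss = mean(r^2), dy = dy)
}

loss_classification <- function(y, target) {
  obs <- which(!is.na(target))
  if (!length(obs)) return(list(loss = 0, dy = numeric(length(y))))
  p <- 1 / (1 + exp(-y[obs]))
  eps <- 1e-12
  loss <- -mean(target[obs] * log(p + eps) + (1 - target[obs]) * log(1 - p + eps))
  dy <- numeric(length(y))
  dy[obs] <- (p - target[obs]) / length(obs)
  list(loss = loss, dy = dy)
}

supervised_loss_fn <- function(task) {
  lf <- if (task == "classification") loss_classification else loss_regression
  function(model, item, target, train) {
    fw <- model_forward(model, item, train)
    l <- lf(fw$y, target)
    grads <- if (any(l$dy != 0)) model_backward(l$dy, fw, model, item) else NULL
    list(loss = l$loss, grads = grads)
  }
}

# ---- generic training loop ------------------------------------------------

# loss_fn(model, item, target, train) -> list(loss, grads or NULL).
# Returns the trained model, per-epoch mean losses, and a divergence flag.
sgd_train <- function(model, items, targets, loss_fn, lr, epochs,
                      batch_size = 16L, seed = 1L, warmup_frac = 0.1,
                      on_epoch = NULL) {
  n <- length(items)
  stopifnot(n >= 1L, length(targets) == n)
  state <- adam_init(model$params)
  total_steps <- epochs * ceiling(n / batch_size)
  warmup <- max(1L, floor(warmup_frac * total_steps))
  step <- 0L
  history <- numeric(epochs)
  diverged <- FALSE
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (batch in batches) {
        acc <- tree_zeros_like(model$params)
        bl <- 0
        for (k in batch) {
          # numerical overflow in a forward pass (exploded parameters) is a
          # divergence of this run, not a usage error
          lg <- tryCatch(loss_fn(model, items[[k]], targets[[k]], TRUE),
                         error = function(e) e)
          if (inherits(lg, "error")) {
            message("training run diverged: ", conditionMessage(lg))
            diverged <- TRUE
            break
          }
          bl <- bl + lg$loss
          if (!is.null(lg$grads)) acc <- tree_accumulate(acc, lg$grads)
        }
        ep_loss <- ep_loss + bl
        grads <- tree_scale(acc, 1 / length(batch))
        if (diverged || !is.finite(bl) || tree_has_nan(grads)) {
          diverged <- TRUE
          break
        }
        step <- step + 1L
        upd <- adam_step(model$params, grads, state,
                         lr_at_step(step, lr, warmup))
        model$params <- upd$params
        state <- upd$state
      }
      history[ep] <- ep_loss / n
      if (diverged) {
        history <- history[seq_len(ep)]
        break
      }
      if (!is.null(on_epoch)) on_epoch(ep, history[ep], model)
    }
  })
  list(model = model, history = history, diverged = diverged)
}

# ---- checkpoints (plain-text JSON) ----------------------------------------

serialize_tree <- function(p) {
  if (is.list(p)) return(lapply(p, serialize_tree))
  list(.dim = if (is.matrix(p)) dim(p) else length(p), .data = as.vector(p))
}

deserialize_tree <- function(s) {
  if (!is.null(s$.data)) {
    x <- as.numeric(unlist(s$.data))
    d <- as.integer(unlist(s$.dim))
    if (length(d) == 2L) x <- matrix(x, d[1L], d[2L])
    return(x)
  }
  lapply(s, deserialize_tree)
}

#' Save / load a model checkpoint as JSON
#'
#' The checkpoint is a flat text file: a config header plus every named
#' parameter array with its dimensions, so weights survive refactors.
#'
#' @param model An `rmat_model`.
#' @param path Output file.
#' @param vocab Optional context vocabulary ([build_context_vocab()]) stored
#'   alongside the weights.
#' @export
save_checkpoint <- function(model, path, vocab = NULL) {
  obj <- list(config = unclass(model$config), n_outputs = model$n_outputs,
              task = model$task, vocab_size = model$vocab_size,
              n_graph_targets = model$n_graph_targets,
              label_center = model$label_center,
              label_scale = model$label_scale,
              vocab = vocab$keys,
              params = serialize_tree(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with elements `model` and
#'   (possibly `NULL`) `vocab`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(rmat_config, obj$config[names(obj$config) %in%
                                           names(formals(rmat_config))])
  model <- structure(list(params = deserialize_tree(obj$params), config = cfg,
                          n_outputs = as.integer(obj$n_outputs),
                          task = obj$task,
                          vocab_size = if (!is.null(obj$vocab_size))
                            as.integer(obj$vocab_size),
                          n_graph_targets = if (!is.null(obj$n_graph_targets))
                            as.integer(obj$n_graph_targets),
                          label_center = if (!is.null(obj$label_center))
                            as.numeric(unlist(obj$label_center)),
                          label_scale = if (!is.null(obj$label_scale))
                            as.numeric(unlist(obj$label_scale))),
                     class = "rmat_model")
  vocab <- NULL
  if (!is.null(obj$vocab)) {
    keys <- unlist(obj$vocab)
    vocab <- list(keys = keys, index = stats::setNames(seq_along(keys), keys),
                  unknown = length(keys) + 1L, size = length(keys) + 1L)
  }
  list(model = model, vocab = vocab)
}
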