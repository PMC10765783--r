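#' Model and featurization configuration
#'
#' Collects every tunable of the encoder, the atom-pair relation
#' featurization and the readout in one validated list. Defaults are a
#' desk-scale configuration; [rmat_small_config()] is the reduced setting
#' used throughout the test suite.
#'
#' @param n_layers Number of stacked relative self-attention encoder blocks.
#' @param n_heads Attention heads per block; must divide `d_model`.
#' @param d_model Width of the atom hidden state (D).
#' @param d_ffn Hidden width of the position-wise feed-forward network.
#' @param phi_hidden Hidden width of the two-layer relation networks
#'   \eqn{\phi_K, \phi_V} that project the relation embedding \eqn{b_{ij}}
#'   into per-head key/value biases.
#' @param max_order Maximum neighborhood order kept as its own one-hot class
#'   (1-4). Shortest paths with more intervening atoms collapse into the top
#'   bucket; the one-hot width is `max_order + 2` (self + orders + dummy).
#' @param cutoff Radial-basis cutoff distance c, in Angstrom. Must exceed all
#'   intra-molecular distances so the dummy node sits exactly at the boundary
#'   where the distance embedding vanishes.
#' @param n_emb Number of radial basis functions in the distance embedding.
#' @param envelope_p Exponent p of the polynomial cutoff envelope (>= 2).
#' @param use_neighborhood,use_bond,use_distance Ablation switches; a
#'   disabled block is zeroed but keeps its width so the relation dimension
#'   D' = (max_order + 2) + 7 + n_emb is unchanged.
#' @param pool_dim Hidden width of the self-attention pooling layer.
#' @param pool_heads Number of pooling attention heads S; the graph embedding
#'   g has length `pool_heads * d_model` (+ `n_descriptors` when enabled).
#' @param head_hidden Hidden width of the two-layer prediction MLP.
#' @param use_descriptors Concatenate a block of physicochemical descriptors
#'   to the pooled graph embedding before the prediction MLP.
#' @param n_descriptors Number of descriptors in that block.
#' @param leaky_slope Negative slope of every leaky-ReLU in the model.
#' @param dropout Dropout rate applied after the attention output projection
#'   and inside the FFN during training (0 disables).
#' @return A validated list of class `rmat_config`.
#' @export
rmat_config <- function(n_layers = 4L, n_heads = 8L, d_model = 256L,
                        d_ffn = 4L * d_model, phi_hidden = 256L,
                        max_order = 4L, cutoff = 20, n_emb = 64L,
                        envelope_p = 6L,
                        use_neighborhood = TRUE, use_bond = TRUE,
                        use_distance = TRUE,
                        pool_dim = 128L, pool_heads = 4L,
                        head_hidden = d_model,
                        use_descriptors = FALSE, n_descriptors = 200L,
                        leaky_slope = 0.1, dropout = 0) {
  cfg <- list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              d_model = as.integer(d_model), d_ffn = as.integer(d_ffn),
              phi_hidden = as.integer(phi_hidden),
              max_order = as.integer(max_order), cutoff = as.numeric(cutoff),
              n_emb = as.integer(n_emb), envelope_p = as.integer(envelope_p),
              use_neighborhood = isTRUE(use_neighborhood),
              use_bond = isTRUE(use_bond), use_distance = isTRUE(use_distance),
              pool_dim = as.integer(pool_dim),
              pool_heads = as.integer(pool_heads),
              head_hidden = as.integer(head_hidden),
              use_descriptors = isTRUE(use_descriptors),
              n_descriptors = as.integer(n_descriptors),
              leaky_slope = as.numeric(leaky_slope),
              dropout = as.numeric(dropout))
  validate_config(cfg)
  structure(cfg, class = "rmat_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_layers >= 1L, cfg$n_heads >= 1L, cfg$d_model >= 1L,
            cfg$d_ffn >= 1L, cfg$phi_hidden >= 1L,
            cfg$pool_dim >= 1L, cfg$pool_heads >= 1L, cfg$head_hidden >= 1L,
            cfg$cutoff > 0, cfg$n_emb >= 1L, cfg$envelope_p >= 2L,
            cfg$leaky_slope >= 0, cfg$dropout >= 0, cfg$dropout < 1)
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("d_model (", cfg$d_model, ") must be divisible by n_heads (",
         cfg$n_heads, ")")
  }
  if (!cfg$max_order %in% 1:4) {
    stop("max_order must be in 1..4, got ", cfg$max_order)
  }
  invisible(cfg)
}

#' @rdname rmat_config
#' @param ... Overrides passed on to [rmat_config()].
#' @export
rmat_small_config <- function(...) {
  defaults <- list(n_layers = 2L, n_heads = 2L, d_model = 32L, d_ffn = 64L,
                   phi_hidden = 32L, pool_dim = 32L, pool_heads = 2L,
                   head_hidden = 32L)
  args <- utils::modifyList(defaults, list(...))
  do.call(rmat_config, args)
}

# Width of the neighborhood one-hot block (self + 1..max_order + dummy).
neighborhood_width <- function(cfg) cfg$max_order + 2L

# Total relation embedding width D' = neighborhood + bond(7) + distance.
relation_width <- function(cfg) neighborhood_width(cfg) + 7L + cfg$n_emb

#' Restrict the maximum neighborhood order of a configuration
#'
#' Returns a copy of `cfg` whose neighborhood one-hot keeps orders
#' `1..max_order` as separate classes, with larger orders collapsed into the
#' top bucket. The one-hot width (and hence D') shrinks accordingly:
#' `max_order = 4` is the default six-class scheme, `max_order = 1` keeps
#' only self / bonded-or-farther / dummy.
#'
#' @param cfg An `rmat_config`.
#' @param max_order Integer in 1..4.
#' @return The modified configuration.
#' @export
max_order_variant <- function(cfg, max_order) {
  if (length(max_order) != 1L || !max_order %in% 1:4) {
    stop("max_order must be a single integer in 1..4")
  }
  cfg$max_order <- as.integer(max_order)
  validate_config(cfg)
  cfg
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the arguments of [rmat_config()]; the nested spellings
#' `distance.cutoff`, `distance.n_emb`, `distance.p` and
#' `features.use_distance` / `use_neighborhood` / `use_bond` are also
#' accepted. Unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return An `rmat_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$distance)) {
    if (!is.null(raw$distance$cutoff)) raw$cutoff <- raw$distance$cutoff
    if (!is.null(raw$distance$n_emb)) raw$n_emb <- raw$distance$n_emb
    if (!is.null(raw$distance$p)) raw$envelope_p <- raw$distance$p
    raw$distance <- NULL
  }
  if (!is.null(raw$features)) {
    for (k in c("use_distance", "use_neighborhood", "use_bond")) {
      if (!is.null(raw$features[[k]])) raw[[k]] <- raw$features[[k]]
    }
    raw$features <- NULL
  }
  known <- names(formals(rmat_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(rmat_config, raw)
}
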