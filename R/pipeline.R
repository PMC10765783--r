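#' Featurize molecules end-to-end for the encoder
#'
#' Runs the full input pipeline: parse SMILES (heavy-atom graph), embed one
#' UFF conformer, append the dummy node at the cutoff distance, and build
#' the atom feature matrix and pair relation tensor. One batched RDKit
#' round-trip serves the whole input.
#'
#' @param x Character vector of SMILES, or a list of already parsed
#'   [rmat_molecule] objects (which are then embedded/augmented as needed).
#' @param cfg An [rmat_config()].
#' @param seed Conformer seed.
#' @return List with `mols` (augmented molecules) and `items`, where each
#'   item holds `F` (atom features), `B` (relation matrix), `keep`
#'   (participation mask) and `desc` (raw descriptor vector, when the
#'   configuration uses descriptors; normalize before prediction).
#' @export
featurize_molecules <- function(x, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "rmat_config"))
  if (is.character(x)) {
    mols <- parse_smiles_batch(x, coords = TRUE, seed = seed, scaffold = TRUE,
                               descriptors = if (cfg$use_descriptors)
                                 cfg$n_descriptors else 0L)
  } else {
    mols <- lapply(x, function(m) {
      if (is.null(m$D)) m <- embed_conformer(m, seed)
      m
    })
  }
  mols <- lapply(mols, function(m) {
    if (!m$has_dummy) m <- add_dummy_node(m, cfg$cutoff)
    m
  })
  items <- lapply(mols, function(m) {
    list(F = atom_features(m), B = build_relations(m, cfg),
         keep = rep(TRUE, nrow(m$atoms)),
         desc = if (cfg$use_descriptors) m$descriptors else NULL)
  })
  list(mols = mols, items = items,
       scaffolds = vapply(mols, function(m) m$scaffold, ""))
}

#' Write / read a featurized-molecule bundle
#'
#' Serializes featurized items (atom feature matrices, relation tensors,
#' masks and optional descriptor vectors) to a plain JSON archive. Arrays
#' are stored column-major with explicit dimensions.
#'
#' @param items Items from [featurize_molecules()].
#' @param path Output file.
#' @export
write_featurized <- function(items, path) {
  obj <- lapply(items, function(it) {
    list(F = serialize_tree(it$F), B = serialize_tree(unclass_attrs(it$B)),
         keep = it$keep, desc = it$desc)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_featurized
#' @export
read_featurized <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(it) {
    list(F = deserialize_tree(it$F), B = deserialize_tree(it$B),
         keep = vapply(it$keep, isTRUE, NA),
         desc = if (!is.null(it$desc)) as.numeric(unlist(it$desc)))
  })
}

unclass_attrs <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Pad a featurized item to a larger batch size
#'
#' Appends masked zero positions (zero atom features, zero relations),
#' leaving the molecule's own positions untouched; model outputs must be
#' identical for the padded and unpadded item.
#'
#' @param item A featurized item.
#' @param n_pad Number of padding positions to append.
#' @return The padded item.
#' @export
pad_item <- function(item, n_pad) {
  if (n_pad == 0L) return(item)
  n <- nrow(item$F)
  m <- n + n_pad
  Fp <- rbind(item$F, matrix(0, n_pad, ncol(item$F)))
  Bp <- matrix(0, m * m, ncol(item$B))
  old <- as.vector(t(outer((seq_len(n) - 1L) * n, seq_len(n), `+`)))
  new <- as.vector(t(outer((seq_len(n) - 1L) * m, seq_len(n), `+`)))
  Bp[new, ] <- item$B[old, ]
  list(F = Fp, B = Bp, keep = c(item$keep, rep(FALSE, n_pad)),
       desc = item$desc)
}
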