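#' Deterministic generator of small drug-like fixture molecules
#'
#' Assembles valence-valid SMILES from a small fragment grammar: an optional
#' ring core (benzene, pyridine, thiophene, furan, cyclohexane, ...) plus a
#' heteroatom chain with occasional branches (methyl, carbonyl, hydroxyl,
#' halogens). Every output parses and embeds; molecule 1 is always carbon
#' dioxide, `C(=O)=O`. Labels cover both graph-only quantities (heavy-atom
#' count, ring count, sum of bond orders) and a geometry-dependent target,
#' the sum of inverse pairwise 3D distances, which is only learnable through
#' the distance channel.
#'
#' @param n Number of molecules.
#' @param seed Seed; the SMILES list is byte-identical across calls.
#' @param max_atoms Maximum heavy atoms per molecule.
#' @param labels Also compute the label columns (requires conformer
#'   embedding; set `FALSE` for a SMILES-only list).
#' @return Data frame with column `smiles` and, when `labels = TRUE`,
#'   `heavy_atoms`, `n_rings`, `bond_order_sum`, `inv_dist_sum` and
#'   `embed_ok`.
#' @export
generate_fixtures <- function(n, seed = 1L, max_atoms = 12L, labels = TRUE) {
  stopifnot(n >= 1L, max_atoms >= 3L)
  cores <- data.frame(
    smi = c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1", "C1CCNC1",
            "c1ccsc1", "c1ccoc1", "C1CC1", "C1CCC1"),
    size = c(6L, 6L, 6L, 5L, 5L, 5L, 5L, 3L, 4L))
  chain_pool <- c("C", "C", "C", "C", "N", "O", "S")
  branch_pool <- c("(C)", "(=O)", "(O)", "(F)", "(Cl)", "(Br)")

  random_smiles <- function() {
    atoms <- 0L
    parts <- character(0)
    if (stats::runif(1) < 0.55) {
      fit <- cores[cores$size <= max_atoms, , drop = FALSE]
      k <- sample.int(nrow(fit), 1L)
      parts <- fit$smi[k]
      atoms <- fit$size[k]
    }
    room <- max_atoms - atoms
    min_len <- if (atoms == 0L) 1L else 0L
    len <- if (room > 0L) sample(min_len:min(room, 6L), 1L) else 0L
    for (a in seq_len(len)) {
      if (atoms >= max_atoms) break
      el <- sample(chain_pool, 1L)
      atoms <- atoms + 1L
      parts <- c(parts, el)
      # branches only on chain carbons, to stay valence-safe
      if (el == "C" && atoms < max_atoms && stats::runif(1) < 0.3) {
        parts <- c(parts, sample(branch_pool, 1L))
        atoms <- atoms + 1L
      }
    }
    paste(parts, collapse = "")
  }

  smiles <- with_seed(seed, {
    c("C(=O)=O", vapply(seq_len(max(0L, n - 1L)), function(k) random_smiles(), ""))
  })[seq_len(n)]

  out <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
  if (labels) {
    mols <- parse_smiles_batch(smiles, coords = TRUE, seed = seed)
    out$heavy_atoms <- vapply(mols, function(m) nrow(m$atoms), 0L)
    out$n_rings <- vapply(mols, function(m) m$n_rings, 0L)
    out$bond_order_sum <- vapply(mols, function(m) sum(m$bonds$order), 0)
    out$inv_dist_sum <- vapply(mols, function(m) {
      if (nrow(m$atoms) < 2L) return(0)
      sum(1 / m$D[upper.tri(m$D)])
    }, 0)
    out$embed_ok <- vapply(mols, function(m) isTRUE(m$embed_ok), NA)
  }
  out
}
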