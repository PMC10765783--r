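#' Atom and atom-pair featurization
#'
#' Every molecule is embedded as an `N_atom x 36` atom feature matrix plus a
#' pairwise relation tensor `b_ij` of width `D' = (max_order + 2) + 7 +
#' n_emb`, laid out as `[neighborhood one-hot | bond features | distance
#' embedding]`. Pairs are stored row-major: pair (i, j) of an N-atom
#' molecule lives in row `(i - 1) * N + j` of an `N^2 x D'` matrix.
#'
#' @name relation_features
NULL

# Column layout of the 36-dim atom feature vector. Exact composition is a
# package choice (the printed total and the one-hot structure are the
# contract): 12 atom-type slots, degree 0-5, formal charge -2..2,
# attached-H 0-4, ring-size flags 3-6, aromatic, in-ring, then a mask flag
# and one reserved zero column.
ATOM_TYPES <- c("B", "N", "C", "O", "F", "P", "S", "Cl", "Br", "I",
                "dummy", "other")
ATOM_FEATURE_WIDTH <- 36L
MASK_COLUMN <- 35L

atom_feature_names <- function() {
  c(paste0("type_", ATOM_TYPES), paste0("degree_", 0:5),
    paste0("charge_", -2:2), paste0("numH_", 0:4),
    paste0("ring_", 3:6), "aromatic", "in_ring", "mask", "reserved")
}

#' Build the 36-dimensional atom feature matrix
#'
#' One-hot atom type over \{B, N, C, O, F, P, S, Cl, Br, I\} plus dedicated
#' dummy and "other" slots, heavy-atom degree (0-5), formal charge (-2..+2,
#' clamped), attached hydrogen count (0-4, clamped), ring-size membership
#' flags (3-6), aromaticity and ring membership, one mask flag used by the
#' pretraining tasks, and one reserved zero column. The dummy atom activates
#' only its type slot. Elements outside the supported set map to the
#' "other" slot with a warning.
#'
#' @param mol An [rmat_molecule] (normally dummy-augmented).
#' @return `N_atom x 36` numeric matrix.
#' @export
atom_features <- function(mol) {
  stopifnot(inherits(mol, "rmat_molecule"))
  at <- mol$atoms
  n <- nrow(at)
  f <- matrix(0, n, ATOM_FEATURE_WIDTH,
              dimnames = list(NULL, atom_feature_names()))
  elem <- ifelse(at$is_dummy, "dummy", at$element)
  unknown <- !elem %in% ATOM_TYPES
  if (any(unknown)) {
    warning("element(s) outside the supported set mapped to 'other': ",
            paste(unique(elem[unknown]), collapse = ", "))
    elem[unknown] <- "other"
  }
  f[cbind(seq_len(n), match(elem, ATOM_TYPES))] <- 1
  real <- !at$is_dummy
  if (any(real)) {
    idx <- which(real)
    f[cbind(idx, 12L + pmin(at$degree[idx], 5L) + 1L)] <- 1
    f[cbind(idx, 18L + pmin(pmax(at$charge[idx], -2L), 2L) + 2L + 1L)] <- 1
    f[cbind(idx, 23L + pmin(at$num_h[idx], 4L) + 1L)] <- 1
    f[idx, 29L] <- as.numeric(at$ring3[idx])
    f[idx, 30L] <- as.numeric(at$ring4[idx])
    f[idx, 31L] <- as.numeric(at$ring5[idx])
    f[idx, 32L] <- as.numeric(at$ring6[idx])
    f[idx, 33L] <- as.numeric(at$aromatic[idx])
    f[idx, 34L] <- as.numeric(at$in_ring[idx])
  }
  f
}

#' Neighborhood-order one-hot embedding
#'
#' Buckets the shortest-path hop count of each atom pair: class 0 for
#' `i = j`, class k for k-bond paths up to `max_order` (k - 1 intervening
#' atoms), the top class for anything farther (including disconnected
#' pairs), and a final dummy class that takes precedence whenever either
#' atom is the dummy node.
#'
#' @param hops Hop-count matrix from [compute_hops()].
#' @param dummy_flags Logical vector marking dummy atoms.
#' @param max_order Maximum order kept as its own class (1-4).
#' @return `N^2 x (max_order + 2)` one-hot matrix, pairs row-major.
#' @export
neighborhood_embedding <- function(hops, dummy_flags, max_order = 4L) {
  n <- nrow(hops)
  stopifnot(ncol(hops) == n, length(dummy_flags) == n, max_order %in% 1:4)
  width <- max_order + 2L
  # row-major flattening: row (i-1)*N + j  <=>  t(hops)
  h <- as.vector(t(hops))
  cls <- pmin(h, max_order)            # 0 = self, 1..max_order, capped
  dummy_pair <- as.vector(t(outer(dummy_flags, dummy_flags, `|`)))
  cls[dummy_pair] <- max_order + 1L    # dummy class overrides all others
  out <- matrix(0, n * n, width)
  out[cbind(seq_len(n * n), cls + 1L)] <- 1
  out
}

#' Bond feature embedding
#'
#' For bonded pairs: one-hot bond order over \{1, 1.5, 2, 3\} (dims 1-4),
#' aromatic (5), conjugated (6), in-ring (7). All seven dimensions are zero
#' for pairs not joined by a chemical bond, including every pair involving
#' the dummy node.
#'
#' @param mol An [rmat_molecule].
#' @return `N^2 x 7` matrix, pairs row-major.
#' @export
bond_embedding <- function(mol) {
  stopifnot(inherits(mol, "rmat_molecule"))
  n <- nrow(mol$atoms)
  out <- matrix(0, n * n, 7L)
  b <- mol$bonds
  if (nrow(b)) {
    slot <- match(b$order, c(1, 1.5, 2, 3))
    if (anyNA(slot)) {
      bad <- which(is.na(slot))[1L]
      stop("unsupported bond order ", b$order[bad], " on bond ",
           b$i[bad], "-", b$j[bad])
    }
    rows <- c((b$i - 1L) * n + b$j, (b$j - 1L) * n + b$i)
    out[cbind(rows, rep(slot, 2L))] <- 1
    out[rows, 5L] <- rep(as.numeric(b$aromatic), 2L)
    out[rows, 6L] <- rep(as.numeric(b$conjugated), 2L)
    out[rows, 7L] <- rep(as.numeric(b$in_ring), 2L)
  }
  out
}

#' Polynomial cutoff envelope
#'
#' Degree-`p` polynomial `u(d) = 1 - (p+1)(p+2)/2 (d/c)^p + p(p+2)
#' (d/c)^(p+1) - p(p+1)/2 (d/c)^(p+2)`, clamped to zero beyond the cutoff.
#' It satisfies `u(0) = 1` and `u(c) = u'(c) = 0`, so the distance embedding
#' it multiplies decays smoothly to zero at the cutoff.
#'
#' @param d Distances (vector or matrix), Angstrom.
#' @param cutoff Cutoff distance c.
#' @param p Envelope exponent (>= 2).
#' @return Envelope values, same shape as `d`.
#' @export
rbf_envelope <- function(d, cutoff, p = 6L) {
  stopifnot(cutoff > 0, p >= 2)
  x <- d / cutoff
  u <- 1 - (p + 1) * (p + 2) / 2 * x^p + p * (p + 2) * x^(p + 1) -
    p * (p + 1) / 2 * x^(p + 2)
  u[x >= 1] <- 0
  u
}

#' Radial-basis distance embedding
#'
#' Sine radial basis `e_n(d) = sqrt(2/c) sin(n pi d / c) / d` for
#' `n = 1..n_emb`, multiplied by the cutoff envelope [rbf_envelope()]. The
#' `d = 0` diagonal uses the analytic limit `sqrt(2/c) n pi / c`, so
#' self-pairs carry a finite distance signature; values vanish identically
#' for `d >= c`.
#'
#' @param D Distance matrix (or vector of distances), Angstrom.
#' @param cutoff Cutoff c.
#' @param n_emb Number of basis functions.
#' @param p Envelope exponent.
#' @return `length(D) x n_emb` matrix; for a matrix `D`, rows are the
#'   row-major pair order used by [build_relations()].
#' @export
distance_embedding <- function(D, cutoff, n_emb = 64L, p = 6L) {
  stopifnot(all(D >= 0), n_emb >= 1)
  d <- if (is.matrix(D)) as.vector(t(D)) else as.numeric(D)
  n <- 1:n_emb
  arg <- outer(d, n * pi / cutoff)           # d * n pi / c
  base <- sin(arg) / d                       # 0/0 on the diagonal
  zero <- d == 0
  if (any(zero)) base[zero, ] <- matrix(n * pi / cutoff, sum(zero), n_emb,
                                        byrow = TRUE)
  sqrt(2 / cutoff) * base * rbf_envelope(d, cutoff, p)
}

#' Fuse the three relation channels into the pair embedding b_ij
#'
#' Concatenates, in fixed order, the neighborhood one-hot, the bond feature
#' block and the distance embedding of every atom pair. Ablation switches in
#' the configuration zero a block without changing the total width D'.
#'
#' @param mol A dummy-augmented [rmat_molecule] with distance matrix.
#' @param cfg An [rmat_config()].
#' @return `N^2 x D'` matrix (pairs row-major) with attributes `n_atoms` and
#'   `blocks` (column index ranges of the three channels).
#' @export
build_relations <- function(mol, cfg) {
  stopifnot(inherits(mol, "rmat_molecule"))
  if (!mol$has_dummy) stop("add the dummy node before building relations")
  nb <- neighborhood_embedding(mol$hops, mol$atoms$is_dummy, cfg$max_order)
  bd <- bond_embedding(mol)
  di <- distance_embedding(mol$D, cfg$cutoff, cfg$n_emb, cfg$envelope_p)
  if (!cfg$use_neighborhood) nb[] <- 0
  if (!cfg$use_bond) bd[] <- 0
  if (!cfg$use_distance) di[] <- 0
  b <- cbind(nb, bd, di)
  stopifnot(ncol(b) == relation_width(cfg))
  w <- neighborhood_width(cfg)
  structure(b, n_atoms = nrow(mol$atoms),
            blocks = list(neighborhood = 1:w, bond = (w + 1L):(w + 7L),
                          distance = (w + 8L):(w + 7L + cfg$n_emb)))
}
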