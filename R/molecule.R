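#' Molecule objects
#'
#' An `rmat_molecule` is the heavy-atom graph of one compound plus, once
#' [embed_conformer()] has run, a single 3D conformer and its Euclidean
#' distance matrix. Hydrogens are implicit: they are never graph vertices,
#' only a per-atom attached-H count. Fields:
#'
#' * `atoms`: data frame with `element`, `charge`, `degree`, `aromatic`,
#'   `in_ring`, `ring3`..`ring6`, `num_h`, `is_dummy`.
#' * `bonds`: data frame with 1-based `i`, `j`, `order` (1, 1.5, 2, 3),
#'   `aromatic`, `conjugated`, `in_ring`.
#' * `A`: binary adjacency matrix; `hops`: all-pairs shortest-path bond
#'   counts (sentinel 99 across disconnected parts and for the dummy node).
#' * `coords`: N x 3 matrix in Angstrom (the dummy row is `NA`; its
#'   distances are defined directly in `D`); `D`: symmetric distance matrix
#'   with zero diagonal.
#'
#' @name rmat_molecule
NULL

HOP_SENTINEL <- 99L

molecule_from_record <- function(rec, smiles) {
  if (!isTRUE(rec$ok)) stop(rec$error, call. = FALSE)
  if (isTRUE(rec$kept_fragment)) {
    warning("'", smiles, "' has multiple fragments; keeping the largest one")
  }
  at <- rec$atoms
  atoms <- data.frame(
    element = vapply(at$element, as.character, ""),
    charge = vapply(at$charge, as.integer, 0L),
    degree = vapply(at$degree, as.integer, 0L),
    aromatic = vapply(at$aromatic, isTRUE, NA),
    in_ring = vapply(at$in_ring, isTRUE, NA),
    ring3 = vapply(at$ring3, isTRUE, NA),
    ring4 = vapply(at$ring4, isTRUE, NA),
    ring5 = vapply(at$ring5, isTRUE, NA),
    ring6 = vapply(at$ring6, isTRUE, NA),
    num_h = vapply(at$num_h, as.integer, 0L),
    is_dummy = FALSE,
    stringsAsFactors = FALSE
  )
  n <- nrow(atoms)
  if (length(rec$bonds)) {
    bonds <- data.frame(
      i = vapply(rec$bonds, function(b) as.integer(b$i), 0L) + 1L,
      j = vapply(rec$bonds, function(b) as.integer(b$j), 0L) + 1L,
      order = vapply(rec$bonds, function(b) as.numeric(b$order), 0),
      aromatic = vapply(rec$bonds, function(b) isTRUE(b$aromatic), NA),
      conjugated = vapply(rec$bonds, function(b) isTRUE(b$conjugated), NA),
      in_ring = vapply(rec$bonds, function(b) isTRUE(b$in_ring), NA)
    )
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                        aromatic = logical(), conjugated = logical(),
                        in_ring = logical())
  }
  A <- matrix(0L, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds$i, bonds$j)] <- 1L
    A[cbind(bonds$j, bonds$i)] <- 1L
  }
  mol <- structure(list(
    smiles = smiles,
    canonical = rec$canonical,
    atoms = atoms, bonds = bonds, A = A,
    hops = NULL, coords = NULL, D = NULL,
    n_rings = as.integer(rec$n_rings),
    scaffold = if (!is.null(rec$scaffold)) rec$scaffold else NA_character_,
    descriptors = if (!is.null(rec$descriptors)) unlist(rec$descriptors) else NULL,
    embed_ok = NA, coord_fallback = FALSE, has_dummy = FALSE
  ), class = "rmat_molecule")
  mol$hops <- compute_hops(mol)
  if (!is.null(rec$coords)) {
    mol$coords <- do.call(rbind, lapply(rec$coords, unlist))
    mol$D <- as.matrix(stats::dist(mol$coords))
    dimnames(mol$D) <- NULL
    mol$embed_ok <- isTRUE(rec$embed_ok)
  }
  mol
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Aromaticity, ring membership and conjugation are perceived by RDKit.
#' Multi-fragment inputs (salts, `.`-separated species) keep only the
#' largest fragment, with a warning. Coordinates are not generated; see
#' [embed_conformer()].
#'
#' @param smiles A single SMILES string.
#' @param scaffold Also record the Bemis-Murcko scaffold SMILES.
#' @param descriptors Number of physicochemical descriptors to attach
#'   (0 = none).
#' @return An [rmat_molecule].
#' @export
parse_smiles <- function(smiles, scaffold = FALSE, descriptors = 0L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  res <- rdkit_query(smiles, coords = FALSE, scaffold = scaffold,
                     descriptors = descriptors)
  check_descriptor_count(res, descriptors)
  molecule_from_record(res$mols[[1]], smiles)
}

#' Parse a batch of SMILES in one round-trip
#'
#' @param smiles Character vector of SMILES.
#' @param coords Generate UFF conformers (see [embed_conformer()]).
#' @param seed Conformer seed, used when `coords = TRUE`.
#' @inheritParams parse_smiles
#' @return List of [rmat_molecule] objects.
#' @export
parse_smiles_batch <- function(smiles, coords = FALSE, seed = 1L,
                               scaffold = FALSE, descriptors = 0L) {
  res <- rdkit_query(smiles, seed = seed, coords = coords,
                     scaffold = scaffold, descriptors = descriptors)
  check_descriptor_count(res, descriptors)
  mols <- Map(molecule_from_record, res$mols, smiles)
  if (coords) mols <- lapply(mols, finish_coords)
  unname(mols)
}

check_descriptor_count <- function(res, requested) {
  if (requested > 0 && res$available_descriptors < requested) {
    stop("only ", res$available_descriptors,
         " descriptors available in the installed toolkit; ", requested,
         " requested")
  }
}

#' Generate a single UFF-optimized 3D conformer
#'
#' One conformer is embedded and optimized with the Universal Force Field;
#' the result is deterministic given `seed`. If embedding fails the molecule
#' falls back to classical-scaling coordinates derived from the hop matrix
#' (bonded pairs near 1.5 Angstrom) and is flagged via `coord_fallback`.
#'
#' @param mol An [rmat_molecule] without a dummy node.
#' @param seed Integer seed for the conformer generator.
#' @return The molecule with `coords` and distance matrix `D` filled in.
#' @export
embed_conformer <- function(mol, seed = 1L) {
  stopifnot(inherits(mol, "rmat_molecule"))
  if (mol$has_dummy) stop("embed the conformer before adding the dummy node")
  res <- rdkit_query(mol$smiles, seed = seed, coords = TRUE)
  rec <- res$mols[[1]]
  out <- molecule_from_record(rec, mol$smiles)
  out$scaffold <- mol$scaffold
  out$descriptors <- mol$descriptors
  finish_coords(out)
}

# Fallback coordinates when RDKit cannot embed the graph: classical scaling
# of the hop matrix with bonds at 1.5 A, padded to 3 dimensions.
finish_coords <- function(mol) {
  if (isTRUE(mol$embed_ok)) return(mol)
  n <- nrow(mol$atoms)
  if (n == 1L) {
    coords <- matrix(0, 1L, 3L)
  } else {
    hd <- mol$hops
    hd[hd >= HOP_SENTINEL] <- max(hd[hd < HOP_SENTINEL]) + 1
    k <- min(3L, n - 1L)
    coords <- suppressWarnings(stats::cmdscale(1.5 * hd, k = k))
    if (ncol(coords) < 3L) {
      coords <- cbind(coords, matrix(0, n, 3L - ncol(coords)))
    }
  }
  mol$coords <- coords
  mol$D <- as.matrix(stats::dist(coords))
  dimnames(mol$D) <- NULL
  mol$embed_ok <- FALSE
  mol$coord_fallback <- TRUE
  mol
}

#' All-pairs shortest-path bond counts
#'
#' Breadth-first geodesic distances on the heavy-atom bond graph. Pairs in
#' different connected components (and any pair involving the dummy node)
#' get the sentinel value 99, which downstream featurization buckets into
#' the top neighborhood class.
#'
#' @param mol An [rmat_molecule].
#' @return Integer matrix of hop counts with zero diagonal.
#' @export
compute_hops <- function(mol) {
  stopifnot(inherits(mol, "rmat_molecule"))
  real <- !mol$atoms$is_dummy
  n_real <- sum(real)
  n <- nrow(mol$atoms)
  bonds <- mol$bonds
  g <- igraph::make_empty_graph(n = n_real, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, as.vector(t(cbind(bonds$i, bonds$j))))
  }
  h <- igraph::distances(g)
  h[is.infinite(h)] <- HOP_SENTINEL
  out <- matrix(HOP_SENTINEL, n, n)
  out[real, real] <- h
  diag(out) <- 0L
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Append the artificial dummy node
#'
#' Adds one unbonded atom whose distance to every real atom equals the
#' radial-basis cutoff `cutoff_c`, so its distance embedding is identically
#' zero; pair relations involving it take the dedicated dummy neighborhood
#' class, and its atom feature vector activates only the dummy type slot.
#' The dummy node gives attention a position to park weight on.
#'
#' @param mol An [rmat_molecule] with coordinates and distance matrix.
#' @param cutoff_c Cutoff distance c in Angstrom.
#' @return The augmented molecule (`has_dummy = TRUE`).
#' @export
add_dummy_node <- function(mol, cutoff_c) {
  stopifnot(inherits(mol, "rmat_molecule"), is.numeric(cutoff_c),
            cutoff_c > 0)
  if (mol$has_dummy) stop("molecule already has a dummy node")
  if (is.null(mol$D)) stop("embed a conformer before adding the dummy node")
  n <- nrow(mol$atoms)
  mol$atoms <- rbind(mol$atoms, data.frame(
    element = "*", charge = 0L, degree = 0L, aromatic = FALSE,
    in_ring = FALSE, ring3 = FALSE, ring4 = FALSE, ring5 = FALSE,
    ring6 = FALSE, num_h = 0L, is_dummy = TRUE))
  rownames(mol$atoms) <- NULL
  mol$A <- rbind(cbind(mol$A, 0L), 0L)
  hops <- rbind(cbind(mol$hops, HOP_SENTINEL), HOP_SENTINEL)
  hops[n + 1L, n + 1L] <- 0L
  storage.mode(hops) <- "integer"
  dimnames(hops) <- NULL
  mol$hops <- hops
  mol$coords <- rbind(mol$coords, NA_real_)
  D <- rbind(cbind(mol$D, cutoff_c), cutoff_c)
  D[n + 1L, n + 1L] <- 0
  dimnames(D) <- NULL
  mol$D <- D
  mol$has_dummy <- TRUE
  mol
}

#' @export
print.rmat_molecule <- function(x, ...) {
  n_real <- sum(!x$atoms$is_dummy)
  cat("<rmat_molecule> ", x$smiles, "\n", sep = "")
  cat("  ", n_real, " heavy atoms, ", nrow(x$bonds), " bonds, ",
      x$n_rings, " rings", if (x$has_dummy) ", dummy node appended" else "",
      "\n", sep = "")
  if (!is.null(x$coords)) {
    cat("  3D conformer: ",
        if (isTRUE(x$coord_fallback)) "graph-layout fallback" else "UFF-optimized",
        "\n", sep = "")
  }
  invisible(x)
}

#' Read SMILES from a text or CSV file
#'
#' Plain files are read one SMILES per line (blank lines and `#` comments
#' skipped); `.csv` files must contain the named SMILES column.
#'
#' @param path Input file.
#' @param column SMILES column name for CSV input.
#' @return Character vector of SMILES.
#' @export
read_smiles_file <- function(path, column = "smiles") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!column %in% names(df)) {
      stop("column '", column, "' not found in ", path)
    }
    return(as.character(df[[column]]))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
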