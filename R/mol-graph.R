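# Molecule-to-graph encoding: M = {A, X, E} with a symmetric binary
# adjacency matrix A over heavy atoms, a one-hot atom feature matrix X and a
# bond feature map E. Hydrogens are implicit (heavy-atom graph).

#' Atom feature schema
#'
#' Defines the one-hot layout of the atom feature vectors: element (with an
#' OTHER bucket for out-of-vocabulary symbols), formal charge, hybridization
#' state, heavy-atom degree, plus a single aromaticity bit. The total width
#' `d_atom` is fixed per schema and recorded on every graph built with it.
#'
#' @param elements ordered element vocabulary; an `"OTHER"` bucket is
#'   appended automatically.
#' @param charges ordered formal charge levels; out-of-range charges hit an
#'   appended OTHER slot.
#' @param hybridizations ordered hybridization states; unknowns hit OTHER.
#' @param degrees ordered heavy-atom degree levels; larger degrees hit OTHER.
#' @return an `atom_feature_schema` object with a `d_atom` field.
#' @export
atom_feature_schema <- function(elements = c("C", "N", "O", "S", "F", "Cl",
                                             "Br", "I", "P", "B", "Si"),
                                charges = c(-1L, 0L, 1L),
                                hybridizations = c("sp", "sp2", "sp3"),
                                degrees = 0:4) {
  blocks <- list(element = c(elements, "OTHER"),
                 charge = c(as.character(charges), "OTHER"),
                 hybridization = c(hybridizations, "OTHER"),
                 degree = c(as.character(degrees), "OTHER"))
  widths <- vapply(blocks, length, 0L)
  structure(list(blocks = blocks, widths = widths,
                 d_atom = sum(widths) + 1L),  # +1 aromatic flag
            class = "atom_feature_schema")
}

.mf_one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  k <- match(as.character(value), levels)
  if (is.na(k)) k <- length(levels)  # OTHER bucket
  v[k] <- 1
  v
}

#' Encode one atom as a feature vector
#'
#' Concatenates one-hot element, formal charge, hybridization and heavy-atom
#' degree blocks plus an aromaticity bit. Out-of-vocabulary values land in
#' the corresponding OTHER bucket, so the encoding never fails.
#'
#' @param element atomic symbol.
#' @param charge formal charge.
#' @param hybridization one of `"sp"`, `"sp2"`, `"sp3"` (or other).
#' @param degree heavy-atom degree.
#' @param aromatic logical aromaticity flag.
#' @param schema an [atom_feature_schema()].
#' @return numeric vector of length `schema$d_atom`.
#' @export
atom_features <- function(element, charge, hybridization, degree, aromatic,
                          schema = atom_feature_schema()) {
  c(.mf_one_hot(element, schema$blocks$element),
    .mf_one_hot(charge, schema$blocks$charge),
    .mf_one_hot(hybridization, schema$blocks$hybridization),
    .mf_one_hot(degree, schema$blocks$degree),
    as.numeric(aromatic))
}

#' Encode one bond as a feature vector
#'
#' One-hot bond order over single/double/triple/aromatic plus conjugation
#' and in-ring flags (length 6, constant across a corpus).
#'
#' @param order integer bond order (1, 2, 3) or 4 for aromatic.
#' @param conjugated,in_ring logical flags.
#' @return numeric vector of length 6.
#' @export
bond_features <- function(order, conjugated = FALSE, in_ring = FALSE) {
  c(.mf_one_hot(min(as.integer(order), 4L), c("1", "2", "3", "4"))[1:4],
    as.numeric(conjugated), as.numeric(in_ring))
}

.mf_graph_from_parsed <- function(mol, schema, smiles = NA_character_,
                                  max_atoms = 256L) {
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms)
  if (n == 0L) stop("molecule has no heavy atoms", call. = FALSE)
  if (n > max_atoms)
    stop(sprintf("molecule has %d atoms (cap %d)", n, max_atoms),
         call. = FALSE)
  A <- matrix(0, n, n)
  degree <- integer(n)
  if (nrow(bonds)) {
    A[cbind(bonds$from, bonds$to)] <- 1
    A[cbind(bonds$to, bonds$from)] <- 1
    degree <- as.integer(rowSums(A))
  }
  # conjugation: aromatic bonds, multiple bonds adjacent to another multiple
  # bond, and single bonds joining two unsaturated atoms
  unsat <- rep(FALSE, n)
  if (nrow(bonds)) {
    multi <- bonds$order >= 2L
    unsat[unique(c(bonds$from[multi], bonds$to[multi]))] <- TRUE
    n_multi <- integer(n)
    for (b in which(multi)) {
      n_multi[bonds$from[b]] <- n_multi[bonds$from[b]] + 1L
      n_multi[bonds$to[b]] <- n_multi[bonds$to[b]] + 1L
    }
  }
  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to),
                                     directed = FALSE)
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  # vectorized one-hot assembly (equivalent to atom_features() per row)
  X <- matrix(0, n, schema$d_atom)
  off <- 0L
  slot <- function(vals, levels) {
    k <- match(as.character(vals), levels)
    k[is.na(k)] <- length(levels)
    k
  }
  blocks <- list(atoms$element, atoms$charge, atoms$hybridization, degree)
  for (bi in seq_along(blocks)) {
    lv <- schema$blocks[[bi]]
    X[cbind(seq_len(n), off + slot(blocks[[bi]], lv))] <- 1
    off <- off + length(lv)
  }
  X[, off + 1L] <- as.numeric(atoms$aromatic)
  E <- list()
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$from[b]; j <- bonds$to[b]
      conj <- bonds$aromatic[b] ||
        (bonds$order[b] >= 2L &&
           (n_multi[i] > 1L || n_multi[j] > 1L)) ||
        (bonds$order[b] == 1L && unsat[i] && unsat[j])
      E[[paste(min(i, j), max(i, j), sep = "-")]] <-
        bond_features(bonds$order[b], conj, in_ring_bond[b])
    }
  }
  structure(list(n_nodes = n, A = A, X = X, E = E,
                 elements = atoms$element, smiles = smiles,
                 d_atom = schema$d_atom),
            class = "molecular_graph")
}

#' Convert a SMILES string to a molecular graph
#'
#' Builds the graph representation `M = {A, X, E}` of the heavy-atom
#' skeleton: `A` is the symmetric binary adjacency matrix (zero diagonal),
#' `X` the atom feature matrix (one row per atom, `schema$d_atom` columns)
#' and `E` a map from unordered atom pairs `"i-j"` to bond feature vectors.
#' Node order follows the chemistry backend's atom order.
#'
#' @param smiles a single SMILES string.
#' @param schema an [atom_feature_schema()].
#' @param max_atoms molecules with more heavy atoms are rejected
#'   (default 256).
#' @return a `molecular_graph` object.
#' @examples
#' g <- smiles_to_graph("CC")
#' g$A
#' @export
smiles_to_graph <- function(smiles, schema = atom_feature_schema(),
                            max_atoms = 256L) {
  stopifnot(length(smiles) == 1L)
  mol <- .mf_parse_mol2(smiles)[[1L]]
  if (is.null(mol)) stop("unparseable SMILES: ", smiles, call. = FALSE)
  .mf_graph_from_parsed(mol, schema, smiles, max_atoms)
}

#' Convert many SMILES to molecular graphs
#'
#' Batch version of [smiles_to_graph()]. Unparseable or oversized molecules
#' are dropped with a warning naming the offending identifiers; the `ids`
#' of the surviving graphs are attached as names.
#'
#' @param smiles character vector of SMILES.
#' @param schema an [atom_feature_schema()].
#' @param ids identifiers used in warnings and as names (default indices).
#' @param max_atoms per-molecule heavy-atom cap (default 256).
#' @return named list of `molecular_graph` objects.
#' @export
graphs_from_smiles <- function(smiles, schema = atom_feature_schema(),
                               ids = as.character(seq_along(smiles)),
                               max_atoms = 256L) {
  stopifnot(length(ids) == length(smiles))
  mols <- .mf_parse_mol2(smiles)
  out <- vector("list", length(smiles))
  bad <- character(0)
  for (i in seq_along(mols)) {
    if (is.null(mols[[i]])) { bad <- c(bad, ids[i]); next }
    out[[i]] <- tryCatch(
      .mf_graph_from_parsed(mols[[i]], schema, smiles[i], max_atoms),
      error = function(e) NULL)
    if (is.null(out[[i]])) bad <- c(bad, ids[i])
  }
  if (length(bad))
    warning("dropped ", length(bad), " molecule(s): ",
            paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  keep <- !vapply(out, is.null, TRUE)
  stats::setNames(out[keep], ids[keep])
}
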