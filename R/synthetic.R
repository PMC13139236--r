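# Synthetic valence-valid SMILES corpus generator. Molecules are grown as
# random trees with per-element valence bookkeeping (C:4, N:3, O:2, S:2,
# halogens:1), optionally closed into rings between eligible atom pairs,
# and labelled by cheap structural predicates so ground truth is available
# to tests without running the pipeline.

.mf_synth_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L)

#' Registered structural label rules
#'
#' @return named list of predicates; each takes a parsed molecule
#'   (`list(atoms, bonds)`) and returns TRUE/FALSE.
#' @export
label_rules <- function() {
  list(
    "contains-nitrogen" = function(mol) "N" %in% mol$atoms$element,
    "contains-oxygen" = function(mol) "O" %in% mol$atoms$element,
    "contains-halogen" = function(mol)
      any(mol$atoms$element %in% c("F", "Cl", "Br", "I")),
    "contains-ring" = function(mol)
      nrow(mol$bonds) > nrow(mol$atoms) - 1L,
    "contains-aromatic-ring" = function(mol)
      isTRUE(any(mol$atoms$aromatic)),
    "heavy-atom-count-ge-15" = function(mol) nrow(mol$atoms) >= 15L)
}

#' Synthetic corpus specification
#'
#' Parameters of the generator. Defaults describe a small-molecule corpus
#' in the size range typical of screening benchmarks: 8-26 heavy atoms,
#' carbon-dominated element distribution, 30% of molecules carrying a ring,
#' labels from the contains-nitrogen predicate with 10% label noise and a
#' balanced target prevalence.
#'
#' @param n_molecules corpus size.
#' @param atom_budget `c(min, max)` heavy atoms per molecule.
#' @param element_weights named sampling weights over C, N, O, S, F, Cl.
#' @param ring_probability probability a molecule receives a ring closure.
#' @param label_rule name of a registered predicate (see [label_rules()]).
#' @param label_noise probability each label is flipped.
#' @param target_prevalence positive fraction before noise (`NULL` to leave
#'   the natural rate).
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 1000L, atom_budget = c(8L, 26L),
                           element_weights = c(C = 0.70, N = 0.10, O = 0.12,
                                               S = 0.03, F = 0.03,
                                               Cl = 0.02),
                           ring_probability = 0.3,
                           label_rule = "contains-nitrogen",
                           label_noise = 0.1, target_prevalence = 0.5,
                           seed = 1L) {
  stopifnot(n_molecules >= 1L, length(atom_budget) == 2L,
            atom_budget[1L] >= 1L, atom_budget[2L] >= atom_budget[1L],
            ring_probability >= 0, ring_probability <= 1,
            label_noise >= 0, label_noise <= 1)
  if (!all(names(element_weights) %in% names(.mf_synth_valence)))
    stop("element_weights must be over ",
         paste(names(.mf_synth_valence), collapse = ", "), call. = FALSE)
  if (!label_rule %in% names(label_rules()))
    stop("unknown label rule: ", label_rule, call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules),
                 atom_budget = as.integer(atom_budget),
                 element_weights = element_weights / sum(element_weights),
                 ring_probability = ring_probability,
                 label_rule = label_rule, label_noise = label_noise,
                 target_prevalence = target_prevalence,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Grow one random valence-valid molecule; returns list(atoms, bonds).
.mf_grow_molecule <- function(spec) {
  n_target <- if (spec$atom_budget[1L] == spec$atom_budget[2L])
    spec$atom_budget[1L]
  else sample(spec$atom_budget[1L]:spec$atom_budget[2L], 1L)
  elems <- names(spec$element_weights)
  pick <- function() sample(elems, 1L, prob = spec$element_weights)
  element <- character(0); free <- integer(0)
  bonds <- list()
  for (i in seq_len(n_target)) {
    e <- pick()
    if (i == 1L) {
      element <- e; free <- .mf_synth_valence[[e]]
      next
    }
    open <- which(free >= 1L)
    if (!length(open)) break  # saturated; accept a smaller molecule
    # monovalent caps would dead-end a growing chain; keep them as leaves
    if (length(element) < n_target - 1L && .mf_synth_valence[[e]] == 1L &&
        sum(free) <= 1L) e <- "C"
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    element <- c(element, e)
    free[parent] <- free[parent] - 1L
    free <- c(free, .mf_synth_valence[[e]] - 1L)
    bonds[[length(bonds) + 1L]] <- c(parent, length(element))
  }
  n <- length(element)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(0), 0L, 2L)
  if (n >= 3L && stats::runif(1L) < spec$ring_probability) {
    adj <- matrix(FALSE, n, n)
    if (nrow(bonds)) {
      adj[bonds] <- TRUE; adj[bonds[, c(2L, 1L)]] <- TRUE
    }
    cand <- which(free >= 1L)
    if (length(cand) >= 2L) {
      pairs <- which(outer(free >= 1L, free >= 1L, `&`) & !adj &
                       upper.tri(adj), arr.ind = TRUE)
      if (nrow(pairs)) {
        k <- if (nrow(pairs) == 1L) 1L else sample(nrow(pairs), 1L)
        bonds <- rbind(bonds, pairs[k, ])
      }
    }
  }
  list(atoms = data.frame(element = element, charge = 0L,
                          stringsAsFactors = FALSE),
       bonds = data.frame(from = bonds[, 1L], to = bonds[, 2L],
                          order = rep(1L, nrow(bonds))))
}

#' Generate a synthetic SMILES corpus
#'
#' Draws random chemically valid molecules under the spec's element and
#' size distributions. With a `target_prevalence`, generation continues
#' under per-class quotas until the requested prevalence (with respect to
#' the spec's label rule, before noise) is met within the corpus; the
#' emitted SMILES strings are unique and deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return character vector of `n_molecules` SMILES strings.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rule <- label_rules()[[spec$label_rule]]
  n <- spec$n_molecules
  withr::with_seed(spec$seed, {
    kept <- character(0)
    want_pos <- if (is.null(spec$target_prevalence)) NA_integer_ else
      round(n * spec$target_prevalence)
    n_pos <- 0L; n_neg <- 0L
    tries <- 0L; max_tries <- 200L * n
    while (length(kept) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not reach the requested corpus under the spec ",
             "(prevalence or uniqueness infeasible)", call. = FALSE)
      mol <- .mf_grow_molecule(spec)
      smi <- .mf_write_smiles(mol$atoms, mol$bonds)
      if (smi %in% kept) next
      if (!is.na(want_pos)) {
        pos <- isTRUE(rule(mol))
        if (pos && n_pos >= want_pos) next
        if (!pos && n_neg >= n - want_pos) next
        if (pos) n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
      }
      kept <- c(kept, smi)
    }
    # class quotas fill at different times; shuffle so corpus order carries
    # no label information
    kept[sample(length(kept))]
  })
}

#' Label molecules by a structural rule with optional noise
#'
#' Evaluates a registered predicate on each parsed molecule and flips each
#' resulting label independently with probability `noise`. Deterministic
#' under `seed`.
#'
#' @param smiles character vector of SMILES.
#' @param rule name of a registered predicate (see [label_rules()]).
#' @param noise flip probability in `[0, 1]`.
#' @param seed integer seed for the noise draws.
#' @return integer vector of binary labels.
#' @export
label_molecules <- function(smiles, rule = "contains-nitrogen", noise = 0,
                            seed = 1L) {
  rules <- label_rules()
  if (!rule %in% names(rules)) stop("unknown label rule: ", rule,
                                    call. = FALSE)
  mols <- .mf_parse_mol2(smiles)
  if (any(vapply(mols, is.null, TRUE)))
    stop("unparseable SMILES in input", call. = FALSE)
  base <- vapply(mols, function(m) as.integer(isTRUE(rules[[rule]](m))), 0L)
  if (noise <= 0) return(base)
  flips <- withr::with_seed(seed, stats::rbinom(length(base), 1L, noise))
  as.integer(xor(base, flips))
}

#' Generate a labelled synthetic record table
#'
#' Convenience wrapper: [generate_molecules()] then [label_molecules()]
#' (noise seed derived from the spec seed), returned as a
#' `molecule_records` table ready for the augmentation pipeline.
#'
#' @param spec a [synthetic_spec()].
#' @return a `molecule_records` table.
#' @export
synthetic_dataset <- function(spec) {
  smiles <- generate_molecules(spec)
  labels <- label_molecules(smiles, spec$label_rule, spec$label_noise,
                            seed = spec$seed + 1L)
  molecule_records(smiles, labels)
}
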