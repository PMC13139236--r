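# Kekule SMILES writer over a connection table (elements, formal charges,
# integer bond orders). Emitting the molecule along a caller-supplied atom
# ranking yields alternative, equally valid renderings of one molecule: the
# basis of seeded SMILES enumeration. Stereo annotations are not written
# (stereo-aware augmentation is out of scope). Every enumerated variant is
# validated downstream by round-trip canonicalization, so a rendering the
# writer cannot express faithfully is filtered out rather than emitted.

# organic subset: bare atoms whose implicit H count readers reconstruct
.mf_organic_valence <- list(B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L),
                            S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L,
                            I = 1L)

.mf_default_valence <- function(element, charge) {
  base <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
            F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, H = 1L)
  v <- unname(base[element])
  if (is.na(v)) return(0L)
  if (charge == 0L) return(v)
  # common charge adjustments for N/O/P/S-type donors and carbanions
  if (element %in% c("N", "O", "P", "S")) return(max(0L, v + charge))
  if (element == "C") return(max(0L, v - abs(charge)))
  max(0L, v - abs(charge))
}

.mf_atom_token <- function(element, charge, bondsum) {
  std <- .mf_organic_valence[[element]]
  if (!is.null(std) && charge == 0L && any(std >= bondsum)) {
    return(element)  # bare organic-subset atom, implicit H understood
  }
  nh <- max(0L, .mf_default_valence(element, charge) - bondsum)
  htok <- if (nh == 1L) "H" else if (nh > 1L) paste0("H", nh) else ""
  ctok <- if (charge == 0L) "" else {
    sign <- if (charge > 0L) "+" else "-"
    if (abs(charge) == 1L) sign else paste0(sign, abs(charge))
  }
  paste0("[", element, htok, ctok, "]")
}

.mf_bond_token <- function(order) {
  switch(as.character(order), `1` = "", `2` = "=", `3` = "#", `4` = "", "")
}

.mf_ring_digit <- function(k) if (k <= 9L) as.character(k) else sprintf("%%%02d", k)

# Write one SMILES string. `atoms`: data.frame(element, charge);
# `bonds`: data.frame(from, to, order); `ranking`: permutation of 1..n giving
# the DFS priority (lowest rank = start atom and first-visited neighbor).
.mf_write_smiles <- function(atoms, bonds, ranking = seq_len(nrow(atoms))) {
  n <- nrow(atoms)
  if (n == 0L) stop("molecule has no heavy atoms", call. = FALSE)
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$from[b]; j <- bonds$to[b]; o <- bonds$order[b]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  bondsum <- vapply(seq_len(n), function(i) {
    if (is.null(adj[[i]])) 0L else sum(pmin(adj[[i]][, 2L], 3L))
  }, 0L)

  visited <- rep(FALSE, n)
  children <- vector("list", n)   # per atom: matrix(child, order)
  closures <- vector("list", n)   # per atom: matrix(digit_id, order)
  ring_seen <- new.env(parent = emptyenv())
  ring_count <- 0L
  roots <- integer(0)

  order_of <- function(cands) cands[order(ranking[cands])]

  while (!all(visited)) {
    root <- order_of(which(!visited))[1L]
    roots <- c(roots, root)
    stack <- list(list(atom = root, parent = 0L))
    visited[root] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      u <- top$atom
      nb <- adj[[u]]
      if (is.null(nb)) next
      ord <- order(ranking[nb[, 1L]])
      tovisit <- list()
      for (k in ord) {
        v <- nb[k, 1L]; o <- nb[k, 2L]
        if (v == top$parent) next  # the bond we arrived through
        key <- paste(min(u, v), max(u, v), sep = "-")
        if (visited[v]) {
          if (!exists(key, envir = ring_seen)) {
            assign(key, TRUE, envir = ring_seen)
            ring_count <- ring_count + 1L
            closures[[u]] <- rbind(closures[[u]], c(ring_count, o))
            closures[[v]] <- rbind(closures[[v]], c(ring_count, o))
          }
        } else {
          visited[v] <- TRUE
          children[[u]] <- rbind(children[[u]], c(v, o))
          tovisit <- c(tovisit, list(list(atom = v, parent = u)))
        }
      }
      # push in reverse so the first-ranked child is emitted first
      for (item in rev(tovisit)) stack[[length(stack) + 1L]] <- item
    }
  }

  emit <- function(u) {
    tok <- .mf_atom_token(atoms$element[u], atoms$charge[u], bondsum[u])
    cls <- closures[[u]]
    if (!is.null(cls)) {
      for (r in seq_len(nrow(cls))) {
        tok <- paste0(tok, .mf_bond_token(cls[r, 2L]),
                      .mf_ring_digit(cls[r, 1L]))
      }
    }
    ch <- children[[u]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (r in seq_len(nc)) {
        sub <- paste0(.mf_bond_token(ch[r, 2L]), emit(ch[r, 1L]))
        tok <- if (r < nc) paste0(tok, "(", sub, ")") else paste0(tok, sub)
      }
    }
    tok
  }
  paste(vapply(roots, emit, ""), collapse = ".")
}

#' Enumerate randomized SMILES renderings of a molecule
#'
#' Generates alternative valid SMILES strings for one molecule by rewriting
#' it along random atom orderings (SMILES enumeration). Every returned
#' variant canonicalizes back to the same molecule as the input, no two
#' variants are equal, and none equals the input's canonical form. Small or
#' highly symmetric molecules exhaust their rendering space, in which case
#' fewer than `max_variants` strings (possibly none) are returned.
#'
#' @param smiles a single SMILES string.
#' @param max_variants maximum number of distinct variants to return.
#' @param seed integer seed; the returned list is deterministic given the
#'   seed and does not disturb the caller's RNG state.
#' @param attempts_per_variant how many random renderings to try per
#'   requested variant before accepting fewer (default 10).
#' @return character vector of at most `max_variants` distinct SMILES.
#' @examples
#' enumerate_smiles("c1ccccc1O", 5, seed = 7)
#' enumerate_smiles("C", 5, seed = 1)  # no variants exist for methane
#' @export
enumerate_smiles <- function(smiles, max_variants, seed,
                             attempts_per_variant = 10L) {
  stopifnot(length(smiles) == 1L, is.numeric(max_variants), max_variants >= 0)
  if (max_variants == 0L) return(character(0))
  mol <- .mf_parse_sdf(smiles)[[1L]]
  if (is.null(mol)) stop("unparseable SMILES: ", smiles, call. = FALSE)
  canon <- .mf_canonical(smiles)
  key <- .mf_canonical_key(smiles)
  cand <- withr::with_seed(seed, {
    n_att <- as.integer(attempts_per_variant * max_variants)
    unique(vapply(seq_len(n_att), function(a) {
      .mf_write_smiles(mol$atoms, mol$bonds, sample(nrow(mol$atoms)))
    }, ""))
  })
  cand <- setdiff(cand, canon)
  if (!length(cand)) return(character(0))
  keep <- !is.na(.mf_canonical_key(cand)) & .mf_canonical_key(cand) == key
  utils::head(cand[keep], max_variants)
}
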