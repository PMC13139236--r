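# Internal chemistry backend. All SMILES parsing, canonicalization and
# perception (aromaticity, hybridization, formal charge) go through Open
# Babel via ChemmineOB/ChemmineR. Batch conversions abort at the first
# invalid entry, so every input is tagged with an index title and the
# conversion is restarted after the offender; invalid entries come back NA.

# Run a batch converter over `items` (character SMILES, named with unique
# tags). `fn(tagged_lines)` must return a named list keyed by tag for the
# prefix of inputs it managed to convert. Entries never returned are invalid.
.mf_convert_recursive <- function(smiles, fn) {
  n <- length(smiles)
  out <- vector("list", n)
  tags <- sprintf("i%d", seq_len(n))
  clean <- trimws(smiles)
  ok <- !is.na(clean) & nzchar(clean) & !grepl("[[:space:]]", clean)
  idx <- which(ok)
  guard <- 0L
  while (length(idx) > 0L) {
    guard <- guard + 1L
    if (guard > n + 1L) break
    res <- fn(paste(clean[idx], tags[idx], sep = "\t"))
    got <- match(names(res), tags[idx])
    got <- got[!is.na(got)]
    if (length(got)) out[idx[got]] <- res[tags[idx[got]]]
    remaining <- setdiff(seq_along(idx), got)
    if (!length(remaining)) break
    # conversion stops at the first bad entry; skip it and resume after
    idx <- idx[remaining[-1L]]
  }
  out
}

# Canonical SMILES (Open Babel "CAN"); NA for unparseable input.
.mf_canonical <- function(smiles) {
  res <- .mf_convert_recursive(smiles, function(lines) {
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN",
                                paste0(paste(lines, collapse = "\n"), "\n")),
      error = function(e) "")
    rows <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    rows <- rows[nzchar(rows)]
    parts <- strsplit(rows, "\t", fixed = TRUE)
    vals <- vapply(parts, `[`, "", 1L)
    tags <- vapply(parts, function(p) if (length(p) > 1L) trimws(p[2L]) else "",
                   "")
    keep <- nzchar(vals) & nzchar(tags)
    as.list(stats::setNames(vals[keep], tags[keep]))
  })
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, "")
}

# Stereo-insensitive canonical key used for molecule-identity checks.
.mf_canonical_key <- function(smiles) {
  stripped <- gsub("@|/|\\\\", "", smiles)
  .mf_canonical(stripped)
}

.mf_charge_from_code <- function(code) {
  # MDL V2000 atom-block charge codes
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  out
}

# Kekule connection table (elements, formal charges, integer bond orders)
# via SDF. Returns a list per input: list(atoms = data.frame(element,
# charge), bonds = data.frame(from, to, order)) or NULL for invalid input.
.mf_parse_sdf <- function(smiles) {
  .mf_convert_recursive(smiles, function(lines) {
    nm <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 2L)
    smi <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi, nm))),
      error = function(e) NULL)
    if (is.null(sdfset) || length(sdfset) == 0L) return(list())
    out <- lapply(seq_along(sdfset), function(i) {
      sdf <- sdfset[[i]]
      ab <- ChemmineR::atomblock(sdf)
      if (is.null(ab) || nrow(ab) == 0L) return(NULL)
      element <- sub("_\\d+$", "", rownames(ab))
      charge <- if ("C6" %in% colnames(ab)) {
        .mf_charge_from_code(ab[, "C6"])
      } else rep(0L, nrow(ab))
      bb <- ChemmineR::bondblock(sdf)
      if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = 1L)
      bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
        data.frame(from = integer(0), to = integer(0), order = integer(0))
      } else {
        data.frame(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
                   order = as.integer(bb[, 3L]))
      }
      list(atoms = data.frame(element = element,
                              charge = as.integer(charge),
                              stringsAsFactors = FALSE),
           bonds = bonds)
    })
    stats::setNames(out, ChemmineR::sdfid(sdfset))
  })
}

.mf_hyb_from_sybyl <- function(type) {
  suffix <- ifelse(grepl(".", type, fixed = TRUE),
                   sub("^[^.]*\\.", "", type), "")
  out <- rep("sp3", length(type))
  out[suffix == "1"] <- "sp"
  out[suffix %in% c("2", "ar", "am", "co2", "pl3")] <- "sp2"
  out
}

# Perceived molecule via MOL2: SYBYL atom types give hybridization and
# aromaticity, bond records give orders (1/2/3, "ar", "am"), and the
# UNITY_ATOM_ATTR section carries formal charges. Returns per input
# list(atoms = data.frame(element, charge, hybridization, aromatic),
# bonds = data.frame(from, to, order, aromatic)) or NULL.
# The record parsing is vectorized across the whole corpus: one strsplit
# over the full conversion output, then grouped assembly by molecule index.
.mf_parse_mol2 <- function(smiles) {
  .mf_convert_recursive(smiles, function(inlines) {
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "MOL2",
                                paste0(paste(inlines, collapse = "\n"),
                                       "\n")),
      error = function(e) "")
    if (!nzchar(txt)) return(list())
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    is_marker <- startsWith(lines, "@<TRIPOS>")
    if (!any(is_marker)) return(list())
    mol_idx <- cumsum(lines == "@<TRIPOS>MOLECULE")
    mpos <- which(is_marker)
    labs <- substring(lines[mpos], 10L)
    section <- rep(NA_character_, length(lines))
    section[seq_along(lines) >= mpos[1L]] <-
      labs[findInterval(seq_along(lines)[seq_along(lines) >= mpos[1L]],
                        mpos)]
    body <- !is_marker & nzchar(trimws(lines)) & mol_idx > 0L
    tags <- trimws(lines[which(lines == "@<TRIPOS>MOLECULE") + 1L])

    parse_rows <- function(rows) {
      # rows with a constant whitespace-separated field count -> matrix
      sp <- strsplit(trimws(rows), "[[:space:]]+")
      len <- lengths(sp)
      if (length(unique(len)) == 1L) {
        matrix(unlist(sp, use.names = FALSE), nrow = length(sp),
               byrow = TRUE)
      } else {
        k <- max(len)
        t(vapply(sp, function(x) c(x, rep("", k - length(x))),
                 character(k)))
      }
    }

    a_sel <- body & section == "ATOM"
    b_sel <- body & section == "BOND"
    u_sel <- body & section == "UNITY_ATOM_ATTR"
    a_mol <- mol_idx[a_sel]
    AM <- if (any(a_sel)) parse_rows(lines[a_sel]) else NULL
    b_mol <- mol_idx[b_sel]
    BM <- if (any(b_sel)) parse_rows(lines[b_sel]) else NULL

    out <- stats::setNames(vector("list", length(tags)), tags)
    for (m in seq_along(tags)) {
      if (!nzchar(tags[m])) next
      arows <- which(a_mol == m)
      if (!length(arows)) next
      type <- AM[arows, 6L]
      atoms <- data.frame(
        element = sub("\\..*$", "", type),
        charge = rep(0L, length(type)),
        hybridization = .mf_hyb_from_sybyl(type),
        aromatic = endsWith(type, ".ar"),
        stringsAsFactors = FALSE)
      if (any(u_sel & mol_idx == m)) {
        urows <- lines[u_sel & mol_idx == m]
        i <- 1L
        while (i <= length(urows)) {
          head <- strsplit(trimws(urows[i]), "[[:space:]]+")[[1]]
          aid <- as.integer(head[1L]); nat <- as.integer(head[2L])
          for (j in seq_len(nat)) {
            kv <- strsplit(trimws(urows[i + j]), "[[:space:]]+")[[1]]
            if (identical(kv[1L], "charge"))
              atoms$charge[aid] <- as.integer(kv[2L])
          }
          i <- i + nat + 1L
        }
      }
      brows <- which(b_mol == m)
      bonds <- if (length(brows)) {
        from <- as.integer(BM[brows, 2L])
        to <- as.integer(BM[brows, 3L])
        btype <- BM[brows, 4L]
        arom_bond <- btype == "ar" & atoms$aromatic[from] &
          atoms$aromatic[to]
        order <- suppressWarnings(as.integer(btype))
        order[btype == "ar"] <- ifelse(arom_bond[btype == "ar"], 4L, 1L)
        order[is.na(order)] <- 1L
        data.frame(from = from, to = to, order = order,
                   aromatic = arom_bond)
      } else {
        data.frame(from = integer(0), to = integer(0), order = integer(0),
                   aromatic = logical(0))
      }
      out[[tags[m]]] <- list(atoms = atoms, bonds = bonds)
    }
    out[!vapply(out, is.null, TRUE)]
  })
}

#' Canonicalize SMILES strings
#'
#' Maps each SMILES string to the unique canonical form assigned by the Open
#' Babel canonicalization algorithm. Two renderings of the same molecule map
#' to the same output, and the function is idempotent, which makes the result
#' usable as a deduplication key.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- .mf_canonical(smiles)
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
         call. = FALSE)
  }
  out
}

# Validity mask without erroring.
.mf_valid_smiles <- function(smiles) !is.na(.mf_canonical(smiles))
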