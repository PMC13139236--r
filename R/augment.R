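# SMILES dataset handling: record construction, fivefold-style enumeration
# augmentation with duplicate control, K-fold labels and train/test splits.

#' Build a molecule record table
#'
#' The record table is the currency of the augmentation pipeline: one row per
#' labelled molecule with columns `record_id`, `smiles`, `label` (binary),
#' `fold_id` (`NA` until folds are assigned), `is_augmented` and `parent_id`
#' (equal to `record_id` for original records). Rows whose SMILES do not
#' parse are dropped with a message; the number dropped is available as
#' `attr(x, "n_dropped")`.
#'
#' @param smiles character vector of SMILES strings.
#' @param label binary labels (0/1), recycled if length 1.
#' @param fold_id optional fold assignments (non-negative integers).
#' @param record_id optional identifiers; defaults to `mol<i>`.
#' @return a `molecule_records` data frame.
#' @export
molecule_records <- function(smiles, label, fold_id = NA_integer_,
                             record_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary 0/1",
                                       call. = FALSE)
  if (is.null(record_id)) record_id <- sprintf("mol%d", seq_along(smiles))
  df <- data.frame(record_id = as.character(record_id), smiles = smiles,
                   label = rep_len(label, length(smiles)),
                   fold_id = rep_len(as.integer(fold_id), length(smiles)),
                   is_augmented = FALSE, parent_id = as.character(record_id),
                   stringsAsFactors = FALSE)
  ok <- .mf_valid_smiles(df$smiles)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(sprintf("dropping %d record(s) with unparseable SMILES",
                    n_dropped))
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (nrow(df) == 0L) stop("no valid records", call. = FALSE)
  structure(df, n_dropped = n_dropped,
            class = c("molecule_records", "data.frame"))
}

.mf_assert_records <- function(records) {
  need <- c("record_id", "smiles", "label", "fold_id", "is_augmented",
            "parent_id")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("expected a molecule_records table with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Augment a SMILES dataset by randomized enumeration
#'
#' Adds up to `factor` enumerated SMILES variants per original record.
#' Variants inherit the parent's label and fold id, carry `is_augmented =
#' TRUE` and a `parent_id` back-reference, and are subject to duplicate
#' control: no two records in the returned corpus share a raw SMILES string,
#' and every variant canonicalizes to the same molecule as its parent.
#' Deterministic under `seed`.
#'
#' @param records non-augmented `molecule_records`.
#' @param factor maximum number of variants per original (default 5).
#' @param seed integer seed.
#' @param attempts_per_variant random renderings tried per requested variant
#'   before accepting fewer (default 10).
#' @return a `molecule_records` table containing the originals followed by
#'   the augmented records.
#' @export
augment_dataset <- function(records, factor = 5L, seed = 1L,
                            attempts_per_variant = 10L) {
  .mf_assert_records(records)
  stopifnot(factor >= 1L)
  if (any(records$is_augmented))
    stop("input records must be non-augmented", call. = FALSE)
  if (anyDuplicated(records$record_id))
    stop("duplicate record_ids in input", call. = FALSE)
  n <- nrow(records)
  parsed <- .mf_parse_sdf(records$smiles)
  keys <- .mf_canonical_key(records$smiles)
  canons <- .mf_canonical(records$smiles)
  bad <- vapply(parsed, is.null, TRUE) | is.na(keys)
  if (any(bad)) stop("unparseable SMILES: ",
                     paste(records$smiles[bad], collapse = ", "),
                     call. = FALSE)

  taken <- new.env(parent = emptyenv())  # raw strings used corpus-wide
  for (s in records$smiles) assign(s, TRUE, envir = taken)
  kept <- vector("list", n)  # accepted variants per parent
  max_rounds <- max(1L, as.integer(attempts_per_variant))

  withr::with_seed(seed, {
    pending_cand <- vector("list", n)
    for (round in seq_len(max_rounds)) {
      need <- which(vapply(kept, length, 0L) < factor)
      if (!length(need)) break
      # draw a couple of spare renderings per parent still short of
      # variants: over-drawing slightly keeps most parents to one round
      draw <- factor + 2L
      for (i in need) {
        cand <- vapply(seq_len(draw), function(a) {
          .mf_write_smiles(parsed[[i]]$atoms, parsed[[i]]$bonds,
                           sample(nrow(parsed[[i]]$atoms)))
        }, "")
        cand <- setdiff(unique(cand), c(canons[i], kept[[i]]))
        cand <- cand[!vapply(cand, exists, TRUE, envir = taken)]
        pending_cand[[i]] <- cand
      }
      # one corpus-wide canonicalization call validates this round
      flat <- unlist(pending_cand[need], use.names = FALSE)
      if (!length(flat)) next
      flat_key <- .mf_canonical_key(flat)
      pos <- 0L
      for (i in need) {
        k <- length(pending_cand[[i]])
        if (k == 0L) next
        ck <- flat_key[pos + seq_len(k)]
        pos <- pos + k
        good <- !is.na(ck) & ck == keys[i]
        for (s in pending_cand[[i]][good]) {
          if (length(kept[[i]]) >= factor) break
          if (!exists(s, envir = taken)) {
            assign(s, TRUE, envir = taken)
            kept[[i]] <- c(kept[[i]], s)
          }
        }
      }
    }
  })

  counts <- vapply(kept, length, 0L)
  aug <- data.frame(
    record_id = sprintf("%s_aug%d", rep(records$record_id, counts),
                        unlist(lapply(counts, seq_len), use.names = FALSE)),
    smiles = unlist(kept, use.names = FALSE),
    label = rep(records$label, counts),
    fold_id = rep(records$fold_id, counts),
    is_augmented = TRUE,
    parent_id = rep(records$record_id, counts),
    stringsAsFactors = FALSE)
  if (nrow(aug) == 0L) aug <- records[0, , drop = FALSE]
  out <- rbind(as.data.frame(records), aug)
  rownames(out) <- NULL
  structure(out, class = c("molecule_records", "data.frame"))
}

#' Assign K-fold labels to a record table
#'
#' Shuffles the records with a seeded RNG and deals them round-robin into
#' `k` folds, so fold sizes differ by at most one. Augmentation applied
#' afterwards inherits these fold ids, preserving the original fold
#' distribution.
#'
#' @param records non-augmented `molecule_records`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return the records with `fold_id` filled in (0-based fold numbers).
#' @export
assign_folds <- function(records, k, seed = 1L) {
  .mf_assert_records(records)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (any(records$is_augmented))
    stop("assign folds before augmentation", call. = FALSE)
  n <- nrow(records)
  if (k > n) stop("k exceeds the number of records", call. = FALSE)
  perm <- withr::with_seed(seed, sample(n))
  fold <- integer(n)
  fold[perm] <- (seq_len(n) - 1L) %% k
  records$fold_id <- fold
  records
}

#' Split records into train and test sets
#'
#' Random, seeded, exhaustive and disjoint partition. With
#' `group_by_parent = TRUE` (the default) an original record and all of its
#' augmented variants land on the same side, so enumeration variants of a
#' test molecule can never leak into training.
#'
#' @param records `molecule_records` (augmented or not).
#' @param train_fraction fraction of parent groups (or records) assigned to
#'   training (default 0.7).
#' @param seed integer seed.
#' @param group_by_parent keep each parent group intact (default TRUE).
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(records, train_fraction = 0.7, seed = 1L,
                             group_by_parent = TRUE) {
  .mf_assert_records(records)
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (group_by_parent) {
    parents <- unique(records$parent_id)
    n_tr <- round(length(parents) * train_fraction)
    perm <- withr::with_seed(seed, sample(parents))
    tr_parents <- perm[seq_len(n_tr)]
    in_train <- records$parent_id %in% tr_parents
  } else {
    n <- nrow(records)
    n_tr <- round(n * train_fraction)
    perm <- withr::with_seed(seed, sample(n))
    in_train <- seq_len(n) %in% perm[seq_len(n_tr)]
  }
  list(train = structure(records[in_train, , drop = FALSE],
                         class = class(records)),
       test = structure(records[!in_train, , drop = FALSE],
                        class = class(records)))
}

#' Read a molecule dataset from CSV or .smi
#'
#' CSV files need a header with at least a SMILES column and a label column;
#' `.smi` files are read as tab-separated `smiles<TAB>label` lines without a
#' header. Invalid SMILES rows are dropped with a message.
#'
#' @param path input file.
#' @param smiles_col,label_col,fold_col column names (CSV only; `fold_col`
#'   optional).
#' @return a `molecule_records` table.
#' @export
read_molecule_csv <- function(path, smiles_col = "smiles",
                              label_col = "label", fold_col = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("smiles", "label"))
    return(molecule_records(df$smiles, df$label))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(smiles_col, label_col))
    if (!col %in% names(df)) stop("missing column: ", col, call. = FALSE)
  fold <- if (!is.null(fold_col) && fold_col %in% names(df))
    df[[fold_col]] else NA_integer_
  molecule_records(as.character(df[[smiles_col]]), df[[label_col]], fold)
}

#' Write a molecule record table to CSV
#'
#' @param records `molecule_records`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_molecule_csv <- function(records, path) {
  .mf_assert_records(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
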