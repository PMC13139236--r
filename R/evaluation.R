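# Ablation harness: train the identical classifier configuration on every
# requested subset of the three graph branches, with a shared featurization
# seed so only branch membership varies between variants.

#' Evaluation report
#'
#' Container for one trained variant: the branch set, feature width, final
#' and best-epoch metric records, the per-epoch history and the seeds used.
#'
#' @param branch_set character subset of `c("gin", "gcn", "gat")`.
#' @param model a fitted `bilstm_model`.
#' @param train_metrics,val_metrics metric lists from [evaluate_scores()].
#' @param feature_width fused feature width.
#' @param seed featurization/training seed record.
#' @param dataset optional dataset name.
#' @return an `eval_report` object.
#' @export
eval_report <- function(branch_set, model, train_metrics, val_metrics,
                        feature_width, seed, dataset = NA_character_) {
  structure(list(branch_set = branch_set,
                 feature_width = as.integer(feature_width),
                 train = train_metrics, validation = val_metrics,
                 history = model$history, best_epoch = model$best_epoch,
                 seed = seed, dataset = dataset),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> branches: %s | feature width %d\n",
              paste(toupper(x$branch_set), collapse = "+"),
              x$feature_width))
  fm <- function(m) sprintf(
    "loss %.4f  ROC-AUC %.4f  PRC-AUC %.4f  recall %.4f  zero-one %.4f",
    m$loss, m$roc_auc, m$prc_auc, m$recall, m$zero_one_loss)
  cat("  train:      ", fm(x$train), "\n")
  if (!is.null(x$validation))
    cat("  validation: ", fm(x$validation), "\n")
  invisible(x)
}

# Featurize a record table: graphs + fused features for the given branches.
.mf_featurize_records <- function(records, weights,
                                  branches = c("gin", "gcn", "gat"),
                                  schema = atom_feature_schema()) {
  graphs <- graphs_from_smiles(records$smiles, schema,
                               ids = records$record_id)
  keep <- records$record_id %in% names(graphs)
  list(features = extract_features(graphs, weights, branches),
       records = structure(records[keep, , drop = FALSE],
                           class = class(records)))
}

#' Run the branch ablation study
#'
#' Featurizes the corpus once with a shared weight seed, then trains the
#' same classifier configuration on each requested branch subset by slicing
#' the fused feature matrix, so the only difference between variants is
#' branch membership. A failing variant is reported and skipped; the
#' remaining variants still run.
#'
#' @param records a `molecule_records` table with labels (typically already
#'   augmented).
#' @param branch_sets list of branch subsets; default all 7 non-empty
#'   subsets of `c("gin", "gcn", "gat")`.
#' @param config a [classifier_config()].
#' @param seed integer seed for weights and the train/test split.
#' @param train_fraction train share of the grouped split (default 0.7).
#' @param schema an [atom_feature_schema()].
#' @param dataset optional dataset name recorded in the reports.
#' @return named list of `eval_report` objects (names like `"gin+gcn"`).
#' @export
run_ablation <- function(records,
                         branch_sets = list(c("gin"), c("gcn"), c("gat"),
                                            c("gin", "gcn"),
                                            c("gin", "gat"),
                                            c("gcn", "gat"),
                                            c("gin", "gcn", "gat")),
                         config = classifier_config(), seed = 1L,
                         train_fraction = 0.7,
                         schema = atom_feature_schema(),
                         dataset = NA_character_) {
  .mf_assert_records(records)
  weights <- init_branch_weights(schema$d_atom, branch_config(), seed = seed)
  fz <- .mf_featurize_records(records, weights, c("gin", "gcn", "gat"),
                              schema)
  feats <- fz$features; recs <- fz$records
  spans <- attr(feats, "column_spans")
  split <- split_train_test(recs, train_fraction, seed = seed,
                            group_by_parent = TRUE)
  tr_idx <- match(split$train$record_id, recs$record_id)
  te_idx <- match(split$test$record_id, recs$record_id)
  out <- list()
  for (bs in branch_sets) {
    bs <- intersect(c("gin", "gcn", "gat"), bs)
    nm <- paste(bs, collapse = "+")
    cols <- unlist(spans[bs], use.names = FALSE)
    rep <- tryCatch({
      model <- train_bilstm(feats[tr_idx, cols, drop = FALSE],
                            split$train$label, config,
                            feats[te_idx, cols, drop = FALSE],
                            split$test$label)
      tr_m <- evaluate_scores(
        predict(model, feats[tr_idx, cols, drop = FALSE]),
        split$train$label)
      va_m <- evaluate_scores(
        predict(model, feats[te_idx, cols, drop = FALSE]),
        split$test$label)
      eval_report(bs, model, tr_m, va_m, length(cols), seed, dataset)
    }, error = function(e) {
      warning("ablation variant ", nm, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(rep)) out[[nm]] <- rep
  }
  out
}
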