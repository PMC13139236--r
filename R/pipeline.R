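# End-to-end orchestration: augment -> graph encoding -> untrained branch
# feature extraction -> BiLSTM training -> evaluation, with every stage's
# artifacts written to an output directory and all randomness funnelled
# through three named seeds.

#' Pipeline run configuration
#'
#' @param input path to a CSV/.smi dataset, a `molecule_records` table, or
#'   `NULL` to use `synthetic`.
#' @param synthetic a [synthetic_spec()] used when `input` is `NULL`.
#' @param smiles_col,label_col,fold_col CSV column names.
#' @param augment_factor enumeration variants per molecule (default 5; 0
#'   disables augmentation).
#' @param train_fraction train share of the grouped split (default 0.7).
#' @param branches branch subset to extract (default all three).
#' @param classifier a [classifier_config()].
#' @param schema an [atom_feature_schema()].
#' @param seed_augment,seed_weights,seed_train the three named seeds.
#' @param group_by_parent keep augmented variants on their parent's side of
#'   the split (default TRUE).
#' @param out_dir output directory for artifacts (`NULL` to skip writing).
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_spec(),
                       smiles_col = "smiles", label_col = "label",
                       fold_col = NULL, augment_factor = 5L,
                       train_fraction = 0.7,
                       branches = c("gin", "gcn", "gat"),
                       classifier = classifier_config(),
                       schema = atom_feature_schema(),
                       seed_augment = 1L, seed_weights = 1L,
                       seed_train = 1L, group_by_parent = TRUE,
                       out_dir = NULL) {
  structure(list(input = input, synthetic = synthetic,
                 smiles_col = smiles_col, label_col = label_col,
                 fold_col = fold_col,
                 augment_factor = as.integer(augment_factor),
                 train_fraction = train_fraction, branches = branches,
                 classifier = classifier, schema = schema,
                 seed_augment = as.integer(seed_augment),
                 seed_weights = as.integer(seed_weights),
                 seed_train = as.integer(seed_train),
                 group_by_parent = isTRUE(group_by_parent),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Loads or generates the dataset, augments it by SMILES enumeration,
#' encodes molecules as graphs, extracts fused untrained-branch features,
#' trains the BiLSTM classifier on a grouped train/test split and evaluates
#' the metric suite. When `config$out_dir` is set, writes the augmented
#' corpus, the feature matrix, the model checkpoint, the training history
#' and a JSON manifest of seeds and counts.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return an `eval_report`, with the fitted model attached as
#'   `attr(, "model")` and the featurized records as `attr(, "records")`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  records <- stage("load", {
    if (is.null(config$input)) synthetic_dataset(config$synthetic)
    else if (is.character(config$input))
      read_molecule_csv(config$input, config$smiles_col, config$label_col,
                        config$fold_col)
    else .mf_assert_records(config$input)
  })
  say("loaded %d records", nrow(records))

  if (config$augment_factor >= 1L) {
    records <- stage("augment",
                     augment_dataset(records, config$augment_factor,
                                     seed = config$seed_augment))
    say("augmented corpus: %d records", nrow(records))
  }

  weights <- init_branch_weights(config$schema$d_atom, branch_config(),
                                 seed = config$seed_weights)
  fz <- stage("featurize",
              .mf_featurize_records(records, weights, config$branches,
                                    config$schema))
  feats <- fz$features; recs <- fz$records
  say("features: %d x %d", nrow(feats), ncol(feats))

  split <- split_train_test(recs, config$train_fraction,
                            seed = config$seed_train,
                            group_by_parent = config$group_by_parent)
  tr_idx <- match(split$train$record_id, recs$record_id)
  te_idx <- match(split$test$record_id, recs$record_id)

  model <- stage("train",
                 train_bilstm(feats[tr_idx, , drop = FALSE],
                              split$train$label, config$classifier,
                              feats[te_idx, , drop = FALSE],
                              split$test$label, verbose = verbose))
  tr_m <- evaluate_scores(predict(model, feats[tr_idx, , drop = FALSE]),
                          split$train$label)
  va_m <- evaluate_scores(predict(model, feats[te_idx, , drop = FALSE]),
                          split$test$label)
  report <- eval_report(attr(feats, "branches"), model, tr_m, va_m,
                        ncol(feats),
                        seed = c(augment = config$seed_augment,
                                 weights = config$seed_weights,
                                 train = config$seed_train))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    write_molecule_csv(recs, fp("augmented.csv"))
    write_features_csv(feats, fp("features.csv"))
    saveRDS(model, fp("model.rds"))
    utils::write.csv(model$history, fp("history.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seeds = list(augment = config$seed_augment,
                        weights = config$seed_weights,
                        train = config$seed_train),
           augment_factor = config$augment_factor,
           train_fraction = config$train_fraction,
           branches = config$branches,
           n_records = nrow(recs), n_train = length(tr_idx),
           n_test = length(te_idx), feature_width = ncol(feats),
           metrics = list(train = tr_m, validation = va_m),
           r_version = as.character(getRversion())),
      fp("manifest.json"), auto_unbox = TRUE, digits = NA)
    say("artifacts written to %s", config$out_dir)
  }
  attr(report, "model") <- model
  attr(report, "records") <- recs
  report
}
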