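# SMILES canonicalization, randomized enumeration and dataset augmentation

test_that("canonicalization maps renderings of one molecule together and is idempotent", {
  # ethanol written two ways
  can <- canonicalize_smiles(c("OCC", "CCO"))
  expect_identical(can[1], can[2])
  # benzene, aromatic and Kekule notation
  benz <- canonicalize_smiles(c("c1ccccc1", "C1=CC=CC=C1"))
  expect_identical(benz[1], benz[2])
  # idempotence on a mixed bag
  mix <- c("CC(=O)Oc1ccccc1C(=O)O", "C[N+](C)(C)C", "N#Cc1ccncc1")
  once <- canonicalize_smiles(mix)
  expect_identical(canonicalize_smiles(once), once)
})

test_that("canonicalization errors identify the offending string", {
  expect_error(canonicalize_smiles(c("CCO", "C1CC")), "C1CC")
})

test_that("enumeration returns distinct molecule-preserving variants, deterministically", {
  v <- enumerate_smiles("c1ccccc1O", 5, seed = 7)
  expect_gte(length(v), 1)
  expect_lte(length(v), 5)
  expect_false(anyDuplicated(v) > 0)
  can <- canonicalize_smiles("c1ccccc1O")
  expect_false(can %in% v)
  expect_true(all(canonicalize_smiles(v) == can))
  expect_identical(v, enumerate_smiles("c1ccccc1O", 5, seed = 7))
  # a different seed explores a different part of the rendering space
  expect_false(identical(v, enumerate_smiles("c1ccccc1O", 5, seed = 8)))
})

test_that("single-atom molecules admit no variants", {
  expect_identical(enumerate_smiles("C", 5, seed = 1), character(0))
})

test_that("augmentation preserves labels and folds, bounds the corpus and removes duplicates", {
  smis <- c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "CCCC", "CCOC", "CCCN",
            "CC(C)O", "CCS", "ClCCCl")
  recs <- molecule_records(smis, label = rep(c(0, 1), 5))
  recs <- assign_folds(recs, k = 5, seed = 2)
  aug <- augment_dataset(recs, factor = 5, seed = 3)
  expect_lte(nrow(aug), 6 * nrow(recs))
  expect_false(anyDuplicated(aug$smiles) > 0)
  kids <- aug[aug$is_augmented, ]
  expect_gt(nrow(kids), 0)
  par <- recs[match(kids$parent_id, recs$record_id), ]
  expect_identical(kids$label, par$label)
  expect_identical(kids$fold_id, par$fold_id)
  # variants canonicalize back to their parent
  expect_identical(canonicalize_smiles(kids$smiles),
                   canonicalize_smiles(par$smiles))
  # determinism: per-parent variant counts agree across runs
  aug2 <- augment_dataset(recs, factor = 5, seed = 3)
  expect_identical(aug$smiles, aug2$smiles)
  # label multiset of parents unchanged
  expect_identical(as.vector(table(aug$label[!aug$is_augmented])),
                   as.vector(table(recs$label)))
})

test_that("augmentation validates its input", {
  recs <- molecule_records(c("CCO", "CCN"), c(0, 1),
                           record_id = c("a", "a"))
  expect_error(augment_dataset(recs, 5, seed = 1), "duplicate")
  ok <- molecule_records(c("CCO", "CCN"), c(0, 1))
  aug <- augment_dataset(ok, 2, seed = 1)
  expect_error(augment_dataset(aug, 2, seed = 1), "non-augmented")
})

test_that("fold assignment balances folds and is deterministic", {
  recs <- molecule_records(sprintf("%sO", strrep("C", 1:11)),
                           label = rep_len(c(0, 1), 11))
  f5 <- assign_folds(recs[1:10, ], k = 5, seed = 1)
  expect_identical(as.integer(sort(table(f5$fold_id))), rep(2L, 5))
  f11 <- assign_folds(recs, k = 5, seed = 1)
  expect_identical(as.integer(sort(table(f11$fold_id))),
                   c(2L, 2L, 2L, 2L, 3L))
  expect_identical(assign_folds(recs, 5, seed = 9)$fold_id,
                   assign_folds(recs, 5, seed = 9)$fold_id)
  expect_error(assign_folds(recs, k = 12, seed = 1), "exceeds")
  expect_error(assign_folds(recs, k = 1, seed = 1), ">= 2")
})

test_that("train/test split partitions exactly and keeps parent groups intact", {
  smis <- sprintf("%sN", strrep("C", 2:21))
  recs <- molecule_records(smis, rep_len(c(0, 1), 20))
  aug <- augment_dataset(recs, factor = 3, seed = 4)
  sp <- split_train_test(aug, 0.7, seed = 5, group_by_parent = TRUE)
  expect_identical(sort(c(sp$train$record_id, sp$test$record_id)),
                   sort(aug$record_id))
  expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
  expect_identical(length(unique(sp$train$parent_id)), 14L)  # 0.7 * 20
  # leakage scan: no test record's parent appears on the train side
  expect_length(intersect(sp$test$parent_id, sp$train$parent_id), 0)
  # ungrouped mode splits records instead
  sp2 <- split_train_test(aug, 0.7, seed = 5, group_by_parent = FALSE)
  expect_identical(nrow(sp2$train), as.integer(round(0.7 * nrow(aug))))
})

test_that("the augment-fold-split pipeline is reproducible end to end", {
  smis <- c("CCO", "CCCO", "CCN", "CCCN", "c1ccccc1", "c1ccncc1",
            "CC(=O)O", "CCS")
  run <- function() {
    r <- molecule_records(smis, rep_len(c(0, 1), length(smis)))
    r <- assign_folds(r, 4, seed = 11)
    a <- augment_dataset(r, 3, seed = 12)
    split_train_test(a, 0.7, seed = 13)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$train, s2$train)
  expect_identical(s1$test, s2$test)
})

test_that("CSV round trip keeps records and drops invalid rows with a count", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(smiles = c("CCO", "notasmiles", "CCN"),
                   label = c(0, 1, 1))
  utils::write.csv(df, tmp, row.names = FALSE)
  expect_message(recs <- read_molecule_csv(tmp), "1 record")
  expect_identical(nrow(recs), 2L)
  expect_identical(attr(recs, "n_dropped"), 1L)
  out <- tempfile(fileext = ".csv")
  write_molecule_csv(recs, out)
  back <- utils::read.csv(out)
  expect_identical(back$smiles, recs$smiles)
})
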