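# Untrained graph branches: initialisation, forwards vs explicit-loop
# oracles, attention laws, readout, fusion and the frozen-weight law.

test_that("weight initialisation is seeded, shape-correct and seed-sensitive", {
  w1 <- init_branch_weights(27, seed = 5)
  w2 <- init_branch_weights(27, seed = 5)
  expect_identical(w1, w2)
  w3 <- init_branch_weights(27, seed = 6)
  expect_false(identical(w1$gcn$W1, w3$gcn$W1))
  expect_identical(dim(w1$gcn$W1), c(27L, 64L))
  expect_identical(dim(w1$gcn$W2), c(64L, 32L))
  expect_identical(dim(w1$gin$W1), c(27L, 64L))
  expect_length(w1$gat$layer1, 8L)
  expect_identical(dim(w1$gat$layer1[[1]]$W), c(27L, 8L))
  expect_length(w1$gat$layer1[[1]]$a, 16L)
  expect_identical(dim(w1$gat$layer2[[1]]$W), c(64L, 32L))
})

test_that("adjacency normalisation matches hand computations and stays symmetric", {
  expect_identical(gcn_normalize(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(gcn_normalize(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))
  withr::with_seed(42, {
    for (rep in 1:20) {
      A <- random_adjacency(sample(1:10, 1))
      Ah <- gcn_normalize(A)
      expect_equal(Ah, t(Ah))
      expect_equal(Ah, oracle_gcn_normalize(A))
    }
  })
})

test_that("branch forwards match explicit-loop oracles on random graphs", {
  w <- init_branch_weights(7, branch_config(hidden1 = 8, hidden2 = 4,
                                            heads = 2), seed = 3)
  withr::with_seed(7, {
    for (rep in 1:50) {
      g <- random_graph(sample(1:10, 1), 7)
      expect_equal(gcn_forward(g, w), oracle_gcn_forward(g, w),
                   tolerance = 1e-6)
      expect_equal(gin_forward(g, w), oracle_gin_forward(g, w),
                   tolerance = 1e-6)
      expect_equal(gat_forward(g, w), oracle_gat_forward(g, w),
                   tolerance = 1e-6)
    }
  })
})

test_that("all-zero features give all-zero convolutional output", {
  w <- init_branch_weights(5, branch_config(hidden1 = 4, hidden2 = 2,
                                            heads = 2), seed = 1)
  g <- random_graph(6, 5)
  g$X <- matrix(0, 6, 5)
  expect_identical(unname(gcn_forward(g, w)), matrix(0, 6, 2))
})

test_that("the isomorphism branch honours the epsilon self-weight", {
  w <- init_branch_weights(5, branch_config(hidden1 = 4, hidden2 = 2,
                                            heads = 2), seed = 2)
  # isolated node with epsilon 0: MLP sees the node's own features
  g <- list(n_nodes = 1L, A = matrix(0, 1, 1),
            X = matrix(rnorm(5), 1), E = list())
  expect_equal(gin_forward(g, w, epsilon = 0),
               oracle_gin_forward(g, w, 0), tolerance = 1e-10)
  # epsilon -1 cancels the self term: a 4-node star equals the plain
  # neighbor sum
  star <- list(n_nodes = 4L,
               A = rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                         c(1, 0, 0, 0), c(1, 0, 0, 0)),
               X = matrix(rnorm(20), 4), E = list())
  out <- gin_forward(star, w, epsilon = -1)
  M <- star$A %*% star$X  # plain neighbor sum, self term gone
  H1 <- pmax(sweep(M %*% w$gin$W1, 2, w$gin$b1, `+`), 0)
  expect_equal(out, pmax(sweep(H1 %*% w$gin$W2, 2, w$gin$b2, `+`), 0),
               tolerance = 1e-10)
})

test_that("attention rows are normalised softmaxes over neighborhoods", {
  withr::with_seed(11, {
    W <- matrix(rnorm(6 * 3), 6, 3)
    a <- rnorm(6)
    for (rep in 1:100) {
      n <- sample(2:10, 1)
      A <- random_adjacency(n)
      H <- matrix(rnorm(n * 6), n, 6)
      al <- gat_attention(H, A, W, a, self_loops = FALSE)
      expect_true(all(al >= 0))
      expect_identical(al[A == 0 & diag(n) == 0], rep(0, sum(A == 0) - n))
      has_nb <- rowSums(A) > 0
      expect_equal(unname(rowSums(al)[has_nb]),
                   rep(1, sum(has_nb)), tolerance = 1e-8)
      expect_identical(unname(rowSums(al)[!has_nb]),
                       rep(0, sum(!has_nb)))
      expect_equal(al, oracle_gat_attention(H, A, W, a, self_loops = FALSE),
                   tolerance = 1e-8)
    }
  })
})

test_that("attention degenerates correctly for single and identical neighbors", {
  W <- diag(3); a <- c(1, 0, 0, 0, 1, 0)
  # node 1 with the single neighbor 2
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  H <- matrix(rnorm(6), 2, 3)
  al <- gat_attention(H, A, W, a, self_loops = FALSE)
  expect_equal(al[1, 2], 1)
  expect_equal(al[2, 1], 1)
  # identical neighbor features: uniform attention over the neighborhood
  H3 <- rbind(c(5, 0, 0), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  A3 <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
  al3 <- gat_attention(H3, A3, W, a, self_loops = FALSE)
  expect_equal(unname(al3[1, 2:4]), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("a triangle's attention matches a brute-force exp/sum computation", {
  withr::with_seed(4, {
    W <- matrix(rnorm(12), 4, 3); a <- rnorm(6)
    H <- matrix(rnorm(12), 3, 4)
  })
  A <- matrix(1, 3, 3) - diag(3)
  al <- gat_attention(H, A, W, a, negative_slope = 0.2, self_loops = FALSE)
  HW <- H %*% W
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  for (i in 1:3) {
    nb <- setdiff(1:3, i)
    e <- sapply(nb, function(j) lrelu(sum(a * c(HW[i, ], HW[j, ]))))
    expect_equal(unname(al[i, nb]), unname(exp(e) / sum(exp(e))),
                 tolerance = 1e-8)
  }
})

test_that("single-head attention reduces the forward to one head and widths follow the config", {
  w <- init_branch_weights(27, seed = 9)
  g <- smiles_to_graph("CCOCC")
  full <- gat_forward(g, w)
  expect_identical(dim(full), c(5L, 32L))
  one <- gat_forward(g, w, heads = 1)
  expect_identical(dim(one), c(5L, 32L))
  expect_error(gat_forward(g, w, heads = 3), "divisible")
})

test_that("readout reduces correctly and is permutation-invariant", {
  v <- matrix(c(1, 2, 3), 1)
  expect_identical(readout(v), c(1, 2, 3))
  two <- rbind(c(1, 2), c(1, 2))
  expect_identical(readout(two), c(1, 2))
  expect_identical(readout(two, "sum"), c(2, 4))
  expect_identical(readout(two, "max"), c(1, 2))
  withr::with_seed(3, {
    H <- matrix(rnorm(40), 8, 5)
    perm <- sample(8)
    expect_equal(readout(H), readout(H[perm, ]), tolerance = 1e-12)
  })
  expect_error(readout(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("fusion concatenates in fixed order and slices recover the inputs", {
  gin <- rnorm(32); gcn <- rnorm(32); gat <- rnorm(32)
  f <- fuse_features(list(gat = gat, gin = gin, gcn = gcn))
  expect_length(f, 96)
  spans <- attr(f, "column_spans")
  expect_identical(names(spans), c("gin", "gcn", "gat"))
  expect_identical(f[spans$gin], gin)
  expect_identical(f[spans$gcn], gcn)
  expect_identical(f[spans$gat], gat)
  two <- fuse_features(list(gcn = gcn, gat = gat))
  expect_length(two, 64)
})

test_that("extracted features are deterministic, branch-selectable and permutation-invariant", {
  smis <- c("CCO", "c1ccccc1O", "CC(=O)NC", "ClCCBr")
  graphs <- graphs_from_smiles(smis)
  w <- init_branch_weights(27, seed = 21)
  f <- extract_features(graphs, w)
  expect_identical(dim(unclass(f)), c(4L, 96L))
  f2 <- extract_features(graphs, init_branch_weights(27, seed = 21))
  expect_identical(unclass(f), unclass(f2))
  fg <- extract_features(graphs, w, branches = "gcn")
  expect_identical(ncol(fg), 32L)
  # permutation invariance: relabel nodes of random molecular graphs
  withr::with_seed(31, {
    for (rep in 1:10) {
      g <- random_graph(sample(2:10, 1), 27)
      perm <- sample(g$n_nodes)
      gp <- list(n_nodes = g$n_nodes, A = g$A[perm, perm],
                 X = g$X[perm, , drop = FALSE], E = list())
      expect_equal(unclass(extract_features(list(g), w))[1, ],
                   unclass(extract_features(list(gp), w))[1, ],
                   tolerance = 1e-6)
    }
  })
})

test_that("feature extraction never mutates the frozen weights", {
  smis <- c("CCO", "CCCN", "c1ccncc1")
  graphs <- graphs_from_smiles(smis)
  w <- init_branch_weights(27, seed = 13)
  snapshot <- unserialize(serialize(w, NULL))
  invisible(extract_features(graphs, w))
  expect_identical(w, snapshot)
})
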