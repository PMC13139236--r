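# Independent explicit-loop oracles and random-structure generators used to
# validate the vectorized implementations. These are deliberately naive:
# every quantity is computed element by element from its definition.

# random symmetric binary adjacency (no self loops), guaranteed n >= 1
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
  }
  A
}

# random graph in molecular_graph form with arbitrary features
random_graph <- function(n, d, p = 0.4) {
  A <- random_adjacency(n, p)
  list(n_nodes = n, A = A, X = matrix(stats::rnorm(n * d), n, d), E = list())
}

oracle_gcn_normalize <- function(A) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- rowSums(At)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- At[i, j] / sqrt(D[i] * D[j])
  out
}

oracle_relu <- function(x) ifelse(x > 0, x, 0)

oracle_gcn_forward <- function(graph, weights) {
  Ah <- oracle_gcn_normalize(graph$A)
  H1 <- oracle_relu(Ah %*% graph$X %*% weights$gcn$W1)
  oracle_relu(Ah %*% H1 %*% weights$gcn$W2)
}

oracle_gin_forward <- function(graph, weights, eps = NULL) {
  if (is.null(eps)) eps <- weights$gin$epsilon
  n <- graph$n_nodes
  M <- matrix(0, n, ncol(graph$X))
  for (i in seq_len(n)) {
    acc <- (1 + eps) * graph$X[i, ]
    for (j in seq_len(n)) if (graph$A[i, j] == 1) acc <- acc + graph$X[j, ]
    M[i, ] <- acc
  }
  H1 <- oracle_relu(sweep(M %*% weights$gin$W1, 2, weights$gin$b1, `+`))
  oracle_relu(sweep(H1 %*% weights$gin$W2, 2, weights$gin$b2, `+`))
}

oracle_gat_attention <- function(H, A, W, a, slope = 0.2,
                                 self_loops = TRUE) {
  n <- nrow(A)
  HW <- H %*% W
  d <- ncol(HW)
  lrelu <- function(x) if (x > 0) x else slope * x
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (self_loops) nb <- sort(unique(c(nb, i)))
    if (!length(nb)) next
    e <- vapply(nb, function(j)
      lrelu(sum(a * c(HW[i, ], HW[j, ]))), 0)
    ex <- exp(e - max(e))
    alpha[i, nb] <- ex / sum(ex)
  }
  alpha
}

# full attention branch, head by head
oracle_gat_forward <- function(graph, weights, K = NULL) {
  cfg <- weights$config
  if (is.null(K)) K <- cfg$heads
  layer <- function(H, heads, combine) {
    outs <- lapply(heads, function(hd) {
      al <- oracle_gat_attention(H, graph$A, hd$W, hd$a,
                                 cfg$negative_slope, cfg$self_loops)
      HW <- H %*% hd$W
      agg <- matrix(0, nrow(H), ncol(HW))
      for (i in seq_len(nrow(H))) {
        if (sum(al[i, ]) == 0) { agg[i, ] <- HW[i, ]; next }
        for (j in seq_len(nrow(H)))
          agg[i, ] <- agg[i, ] + al[i, j] * HW[j, ]
      }
      agg
    })
    if (combine == "concat") oracle_relu(do.call(cbind, outs))
    else oracle_relu(Reduce(`+`, outs) / length(outs))
  }
  H1 <- layer(graph$X, weights$gat$layer1[seq_len(K)], "concat")
  l2 <- lapply(weights$gat$layer2, function(hd)
    list(W = hd$W[seq_len(ncol(H1)), , drop = FALSE], a = hd$a))
  layer(H1, l2, "mean")
}

# scalar LSTM step straight from the gate equations
oracle_lstm_step <- function(x, h_prev, c_prev, params) {
  h <- params$hidden_size
  hx <- c(h_prev, x)
  gate <- function(block, act) {
    z <- numeric(h)
    for (u in seq_len(h)) {
      col <- (block - 1) * h + u
      z[u] <- sum(hx * params$W[, col]) + params$b[col]
    }
    act(z)
  }
  sig <- function(z) 1 / (1 + exp(-z))
  i <- gate(1, sig); f <- gate(2, sig); g <- gate(3, tanh); o <- gate(4, sig)
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# average precision for distinct scores: mean over positives of the
# precision at that positive's rank
oracle_average_precision <- function(scores, labels) {
  stopifnot(!anyDuplicated(scores))
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  ranks_pos <- which(y == 1)
  mean(vapply(ranks_pos, function(r) sum(y[1:r]) / r, 0))
}

# small labelled feature set: two Gaussian blobs
blob_data <- function(n_per_class, d, shift = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * d), n_per_class),
               matrix(stats::rnorm(n_per_class * d, mean = shift),
                      n_per_class))
    list(x = x, y = rep(c(0L, 1L), each = n_per_class))
  })
}
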