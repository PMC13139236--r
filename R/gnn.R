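# Untrained, seeded, single-forward-pass graph feature extraction through
# three parallel branches (graph convolutional, graph isomorphism, graph
# attention), mean-pooling readout, and fusion by concatenation. No branch
# parameter is ever trained or mutated: the random projections act as fixed
# nonlinear descriptors and only the downstream classifier learns.

#' Branch configuration
#'
#' Layer widths and attention settings for the three graph branches. The
#' defaults are two message-passing layers of widths 64 and 32 per branch,
#' 8 attention heads, LeakyReLU slope 0.2, GIN epsilon 0 (fixed; nothing is
#' trained), and self-loops in the attention neighborhoods. Dropout rates
#' exist as stated configuration but inference-mode forwards apply none; a
#' deterministic feature extractor gains nothing from stochastic masking.
#'
#' @param hidden1,hidden2 widths of the two layers (default 64, 32).
#' @param heads attention heads in the first attention layer (default 8).
#' @param negative_slope LeakyReLU slope for attention scores (default 0.2).
#' @param gin_epsilon self-importance weight in the isomorphism branch
#'   (default 0).
#' @param self_loops include each node in its own attention neighborhood
#'   (default TRUE; guarantees the softmax is defined for isolated nodes).
#' @param readout graph-level pooling: `"mean"` (default), `"sum"` or
#'   `"max"`.
#' @return a `branch_config` list.
#' @export
branch_config <- function(hidden1 = 64L, hidden2 = 32L, heads = 8L,
                          negative_slope = 0.2, gin_epsilon = 0,
                          self_loops = TRUE, readout = "mean") {
  if (hidden1 %% heads != 0L)
    stop("hidden1 must be divisible by the number of heads", call. = FALSE)
  structure(list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 heads = as.integer(heads), negative_slope = negative_slope,
                 gin_epsilon = gin_epsilon, self_loops = self_loops,
                 readout = match.arg(readout, c("mean", "sum", "max"))),
            class = "branch_config")
}

.mf_glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize frozen branch weights
#'
#' Draws all parameters of the three branches from a seeded Glorot-uniform
#' generator. The weights are created once and never mutated; identical
#' `(d_atom, config, seed)` give elementwise-identical parameters.
#'
#' @param d_atom atom feature width the weights act on.
#' @param config a [branch_config()].
#' @param seed integer seed.
#' @return a `branch_weights` object with components `gcn` (W1, W2), `gin`
#'   (two affine layers and epsilon) and `gat` (per-head projection matrices
#'   and attention vectors for both layers).
#' @export
init_branch_weights <- function(d_atom, config = branch_config(), seed = 1L) {
  stopifnot(d_atom >= 1L)
  h1 <- config$hidden1; h2 <- config$hidden2; K <- config$heads
  head_dim <- h1 %/% K
  withr::with_seed(seed, {
    w <- list(
      gcn = list(W1 = .mf_glorot(d_atom, h1), W2 = .mf_glorot(h1, h2)),
      gin = list(W1 = .mf_glorot(d_atom, h1), b1 = numeric(h1),
                 W2 = .mf_glorot(h1, h2), b2 = numeric(h2),
                 epsilon = config$gin_epsilon),
      gat = list(
        layer1 = lapply(seq_len(K), function(k)
          list(W = .mf_glorot(d_atom, head_dim),
               a = stats::runif(2L * head_dim, -sqrt(6 / (2 * head_dim + 1)),
                                sqrt(6 / (2 * head_dim + 1))))),
        layer2 = lapply(seq_len(K), function(k)
          list(W = .mf_glorot(h1, h2),
               a = stats::runif(2L * h2, -sqrt(6 / (2 * h2 + 1)),
                                sqrt(6 / (2 * h2 + 1)))))),
      d_atom = as.integer(d_atom), config = config, seed = as.integer(seed))
  })
  structure(w, class = "branch_weights")
}

#' Symmetrically normalized adjacency
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of
#' `A + I`. Self-loops guarantee every degree is at least 1, so the result
#' is always defined, and symmetry of `A` carries over.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return the normalized adjacency, same dimensions as `A`.
#' @examples
#' gcn_normalize(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
gcn_normalize <- function(A) {
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

.mf_relu <- function(x) pmax(x, 0)

#' Graph convolutional forward pass
#'
#' Two rounds of normalized-adjacency mixing with frozen weights:
#' `H1 = ReLU(A_hat X W1)`, `H2 = ReLU(A_hat H1 W2)`. ReLU between layers
#' keeps the two-layer stack from collapsing to a single linear map; no
#' bias or dropout is applied.
#'
#' @param graph a `molecular_graph`.
#' @param weights a `branch_weights` object initialized for the graph's
#'   feature width.
#' @return node feature matrix of dimension `n_nodes x hidden2`.
#' @export
gcn_forward <- function(graph, weights) {
  if (ncol(graph$X) != nrow(weights$gcn$W1))
    stop("feature width mismatch: graph has ", ncol(graph$X),
         ", weights expect ", nrow(weights$gcn$W1), call. = FALSE)
  Ahat <- gcn_normalize(graph$A)
  H1 <- .mf_relu(Ahat %*% graph$X %*% weights$gcn$W1)
  .mf_relu(Ahat %*% H1 %*% weights$gcn$W2)
}

#' Graph isomorphism forward pass
#'
#' Sum aggregation with a weighted self term,
#' `(1 + epsilon) h_i + sum_{j in N(i)} h_j`, followed by a two-layer MLP
#' with ReLU. `epsilon` defaults to the frozen value in `weights`.
#'
#' @param graph a `molecular_graph`.
#' @param weights a `branch_weights` object.
#' @param epsilon optional override of the self-importance weight.
#' @return node feature matrix `n_nodes x hidden2`.
#' @export
gin_forward <- function(graph, weights, epsilon = NULL) {
  if (ncol(graph$X) != nrow(weights$gin$W1))
    stop("feature width mismatch", call. = FALSE)
  eps <- if (is.null(epsilon)) weights$gin$epsilon else epsilon
  M <- (1 + eps) * graph$X + graph$A %*% graph$X
  H1 <- .mf_relu(sweep(M %*% weights$gin$W1, 2L, weights$gin$b1, `+`))
  .mf_relu(sweep(H1 %*% weights$gin$W2, 2L, weights$gin$b2, `+`))
}

#' Attention coefficients for one attention head
#'
#' Scores every neighbor pair with
#' `e_ij = LeakyReLU(a' [W h_i || W h_j])` and normalizes each node's scores
#' over its neighborhood with a softmax. Rows of nodes with at least one
#' neighbor sum to one; non-neighbor entries are exactly zero; a node with
#' an empty neighborhood (only possible with `self_loops = FALSE`) gets an
#' all-zero row.
#'
#' @param H node feature matrix (one row per node).
#' @param A symmetric binary adjacency matrix.
#' @param W projection matrix (`ncol(H) x d'`).
#' @param a attention vector of length `2 d'`.
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @param self_loops include each node in its own neighborhood
#'   (default TRUE).
#' @return the `n x n` attention matrix alpha.
#' @export
gat_attention <- function(H, A, W, a, negative_slope = 0.2,
                          self_loops = TRUE) {
  .mf_gat_alpha(H %*% W, A, a, negative_slope, self_loops)
}

# attention coefficients from a precomputed projection HW
.mf_gat_alpha <- function(HW, A, a, negative_slope, self_loops) {
  n <- nrow(A)
  dprime <- ncol(HW)
  si <- drop(HW %*% a[seq_len(dprime)])          # a_left . W h_i
  sj <- drop(HW %*% a[dprime + seq_len(dprime)]) # a_right . W h_j
  E <- outer(si, sj, `+`)
  E[E < 0] <- negative_slope * E[E < 0]
  mask <- A > 0
  if (self_loops) diag(mask) <- TRUE
  E[!mask] <- -Inf
  # row-wise softmax over neighborhoods; empty rows come back all-zero
  rmax <- E[cbind(seq_len(n), max.col(E, ties.method = "first"))]
  rmax[!is.finite(rmax)] <- 0
  ex <- exp(E - rmax)  # column-major recycling subtracts rmax[i] in row i
  rs <- rowSums(ex)
  ex / ifelse(rs > 0, rs, 1)
}

.mf_gat_layer <- function(H, A, heads, negative_slope, self_loops, combine) {
  outs <- lapply(heads, function(hd) {
    HW <- H %*% hd$W
    alpha <- .mf_gat_alpha(HW, A, hd$a, negative_slope, self_loops)
    agg <- alpha %*% HW
    iso <- rowSums(alpha) == 0
    if (any(iso)) agg[iso, ] <- HW[iso, ]  # fall back to self term
    agg
  })
  if (combine == "concat") {
    .mf_relu(do.call(cbind, outs))
  } else {
    .mf_relu(Reduce(`+`, outs) / length(outs))
  }
}

#' Graph attention forward pass
#'
#' Two attention layers with frozen weights: the first runs `K` independent
#' heads whose ReLU outputs are concatenated (8 heads of width 8 by
#' default), the second runs `K` heads of full output width whose
#' aggregations are averaged before the ReLU, mirroring the standard
#' output-layer convention for multi-head attention.
#'
#' @param graph a `molecular_graph`.
#' @param weights a `branch_weights` object.
#' @param heads number of heads to use in layer 1 (default: all).
#' @return node feature matrix `n_nodes x hidden2`.
#' @export
gat_forward <- function(graph, weights, heads = NULL) {
  cfg <- weights$config
  K <- if (is.null(heads)) cfg$heads else as.integer(heads)
  if (K < 1L || K > cfg$heads)
    stop("heads must be between 1 and ", cfg$heads, call. = FALSE)
  if (cfg$hidden1 %% K != 0L)
    stop("layer width not divisible by the head count", call. = FALSE)
  if (ncol(graph$X) != nrow(weights$gat$layer1[[1]]$W))
    stop("feature width mismatch", call. = FALSE)
  H1 <- .mf_gat_layer(graph$X, graph$A, weights$gat$layer1[seq_len(K)],
                      cfg$negative_slope, cfg$self_loops, "concat")
  if (K < cfg$heads) {
    # reduced-head layer 1 shrinks the intermediate width; project with the
    # matching slice of the layer-2 weights
    l2 <- lapply(weights$gat$layer2, function(hd)
      list(W = hd$W[seq_len(ncol(H1)), , drop = FALSE], a = hd$a))
  } else l2 <- weights$gat$layer2
  .mf_gat_layer(H1, graph$A, l2, cfg$negative_slope, cfg$self_loops, "mean")
}

#' Graph-level readout
#'
#' Permutation-invariant reduction of node features to one graph-level
#' vector: arithmetic mean by default, sum or elementwise max selectable.
#'
#' @param H node feature matrix with at least one row.
#' @param method `"mean"`, `"sum"` or `"max"`.
#' @return numeric vector of length `ncol(H)`.
#' @export
readout <- function(H, method = c("mean", "sum", "max")) {
  method <- match.arg(method)
  if (is.null(dim(H)) || nrow(H) == 0L)
    stop("readout needs a non-empty node feature matrix", call. = FALSE)
  switch(method,
         mean = colMeans(H),
         sum = colSums(H),
         max = apply(H, 2L, max))
}

#' Fuse branch descriptors
#'
#' Concatenates graph-level branch vectors in the fixed order GIN, GCN, GAT
#' (ablation subsets keep that relative order). The output carries the
#' column span of every branch so slices recover the inputs exactly.
#'
#' @param vectors named list of branch vectors; names from
#'   `c("gin", "gcn", "gat")`.
#' @return fused numeric vector with a `column_spans` attribute.
#' @export
fuse_features <- function(vectors) {
  ord <- intersect(c("gin", "gcn", "gat"), names(vectors))
  if (!length(ord)) stop("no branch vectors to fuse", call. = FALSE)
  out <- unlist(vectors[ord], use.names = FALSE)
  widths <- vapply(vectors[ord], length, 0L)
  ends <- cumsum(widths)
  spans <- Map(function(s, e) s:e, ends - widths + 1L, ends)
  attr(out, "column_spans") <- stats::setNames(spans, ord)
  out
}

#' Extract fused graph-level features for a dataset
#'
#' Runs the selected untrained branches over every graph with a single
#' forward pass each, pools node features to graph level, and fuses the
#' branch descriptors row-wise into one feature matrix. No parameter is
#' modified; the result is deterministic given the weights' seed.
#'
#' @param graphs non-empty list of `molecular_graph` objects.
#' @param weights a `branch_weights` object.
#' @param branches subset of `c("gin", "gcn", "gat")`.
#' @return a `fused_features` matrix (`length(graphs)` rows) with
#'   attributes `column_spans`, `branches` and `seed`; row names come from
#'   the graph list names.
#' @export
extract_features <- function(graphs, weights,
                             branches = c("gin", "gcn", "gat")) {
  stopifnot(length(graphs) >= 1L)
  branches <- match.arg(branches, c("gin", "gcn", "gat"), several.ok = TRUE)
  branches <- intersect(c("gin", "gcn", "gat"), branches)
  method <- weights$config$readout
  rows <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    vecs <- tryCatch({
      v <- list()
      if ("gin" %in% branches) v$gin <- readout(gin_forward(g, weights),
                                                method)
      if ("gcn" %in% branches) v$gcn <- readout(gcn_forward(g, weights),
                                                method)
      if ("gat" %in% branches) v$gat <- readout(gat_forward(g, weights),
                                                method)
      v
    }, error = function(e) {
      id <- if (!is.null(names(graphs))) names(graphs)[i] else i
      stop("feature extraction failed for record ", id, ": ",
           conditionMessage(e), call. = FALSE)
    })
    rows[[i]] <- fuse_features(vecs)
  }
  spans <- attr(rows[[1L]], "column_spans")
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(graphs)
  colnames(mat) <- unlist(lapply(names(spans), function(b)
    sprintf("%s_%d", b, seq_along(spans[[b]]))), use.names = FALSE)
  structure(mat, column_spans = spans, branches = names(spans),
            seed = weights$seed, class = c("fused_features", "matrix"))
}

#' Write a fused feature matrix to CSV
#'
#' @param features a `fused_features` matrix.
#' @param path output path; the header row holds the branch column names.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(record_id = rownames(features) %||%
                     as.character(seq_len(nrow(features))),
                   as.data.frame(unclass(features)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
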