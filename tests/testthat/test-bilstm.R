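# LSTM cell and BiLSTM classifier: gate-equation fidelity, analytic
# gradients vs finite differences, training behaviour.

test_that("the zero-parameter cell is a fixed point and hidden states stay bounded", {
  p <- lstm_params(3, 2)  # all-zero parameters
  out <- lstm_cell_step(c(1, -2, 3), c(0, 0), c(0, 0), p)
  expect_identical(out$h, c(0, 0))
  expect_identical(out$c, c(0, 0))
  p2 <- lstm_params(4, 3, seed = 8)
  withr::with_seed(2, {
    for (rep in 1:25) {
      st <- lstm_cell_step(rnorm(4, sd = 5), rnorm(3), rnorm(3, sd = 2), p2)
      expect_true(all(abs(st$h) < 1))
    }
  })
})

test_that("lstm_cell_step matches a scalar evaluation of the gate equations", {
  withr::with_seed(5, {
    p <- lstm_params(3, 2, seed = 77)
    for (rep in 1:10) {
      x <- rnorm(3); h0 <- rnorm(2); c0 <- rnorm(2)
      got <- lstm_cell_step(x, h0, c0, p)
      want <- oracle_lstm_step(x, h0, c0, p)
      expect_equal(got$h, want$h, tolerance = 1e-10)
      expect_equal(got$c, want$c, tolerance = 1e-10)
    }
  })
})

test_that("lstm_cell_step validates shapes", {
  p <- lstm_params(3, 2, seed = 1)
  expect_error(lstm_cell_step(c(1, 2), c(0, 0), c(0, 0), p), "shape")
})

test_that("bilstm_forward concatenates directions and unrolls correctly", {
  fwd <- lstm_params(4, 3, seed = 1)
  bwd <- lstm_params(4, 3, seed = 2)
  x <- matrix(rnorm(4), 1, 4)
  out <- bilstm_forward(x, fwd, bwd)
  expect_identical(dim(out), c(1L, 6L))
  sf <- lstm_cell_step(drop(x), numeric(3), numeric(3), fwd)
  sb <- lstm_cell_step(drop(x), numeric(3), numeric(3), bwd)
  expect_equal(drop(out), c(sf$h, sb$h), tolerance = 1e-12)
  # identical parameters in both directions make the halves equal at T = 1
  sym <- bilstm_forward(x, fwd, fwd)
  expect_equal(sym[, 1:3], sym[, 4:6], tolerance = 1e-12)
  # manual two-step unroll
  x2 <- matrix(rnorm(8), 2, 4)
  out2 <- bilstm_forward(x2, fwd, bwd)
  f1 <- lstm_cell_step(x2[1, ], numeric(3), numeric(3), fwd)
  f2 <- lstm_cell_step(x2[2, ], f1$h, f1$c, fwd)
  b2 <- lstm_cell_step(x2[2, ], numeric(3), numeric(3), bwd)
  b1 <- lstm_cell_step(x2[1, ], b2$h, b2$c, bwd)
  expect_equal(out2[1, ], c(f1$h, b1$h), tolerance = 1e-8)
  expect_equal(out2[2, ], c(f2$h, b2$h), tolerance = 1e-8)
})

# finite-difference gradient check over every parameter of the stack
gradient_check <- function(timesteps) {
  cfg <- classifier_config(units_layer1 = 4, units_layer2 = 3, dropout = 0,
                           timesteps = timesteps, standardize = FALSE,
                           seed = 3)
  d <- 6 * timesteps
  withr::with_seed(10, {
    x <- matrix(rnorm(5 * d), 5, d)
    y <- c(0, 1, 1, 0, 1)
    p <- molfuse:::.mf_init_classifier(if (timesteps == 1) d else 6, cfg)
  })
  loss_of <- function(p) {
    prob <- molfuse:::.mf_predict_raw(p, x, cfg)
    -mean(y * log(prob) + (1 - y) * log(1 - prob))
  }
  fw_grad <- function(p) {
    if (timesteps == 1) {
      fw <- molfuse:::.mf_t1_stack_forward(x, p, 4, 3, keep_cache = TRUE)
      dz <- (fw$prob - y) / 5
      molfuse:::.mf_t1_stack_backward(fw, dz, p, 4, 3)
    } else {
      xt <- molfuse:::.mf_slice_timesteps(x, timesteps)
      fw <- molfuse:::.mf_stack_forward(xt, p, 4, 3, keep_cache = TRUE)
      dz <- (fw$prob - y) / 5
      molfuse:::.mf_stack_backward(fw, dz, p, 4, 3, timesteps)
    }
  }
  g <- fw_grad(p)
  eps <- 1e-6
  for (nm in names(g)) {
    ana <- as.matrix(g[[nm]])
    idx <- cbind(sample(nrow(ana), min(4, nrow(ana))),
                 sample(ncol(ana), min(4, ncol(ana))))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      pp <- p; pm <- p
      pp[[nm]] <- as.matrix(pp[[nm]]); pm[[nm]] <- as.matrix(pm[[nm]])
      pp[[nm]][i, j] <- pp[[nm]][i, j] + eps
      pm[[nm]][i, j] <- pm[[nm]][i, j] - eps
      if (is.null(dim(p[[nm]]))) {
        pp[[nm]] <- drop(pp[[nm]]); pm[[nm]] <- drop(pm[[nm]])
      }
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(ana[i, j], num, tolerance = 1e-4)
    }
  }
}

test_that("backpropagation matches finite differences (single timestep)", {
  withr::with_seed(1, gradient_check(1))
})

test_that("backpropagation matches finite differences (three timesteps)", {
  withr::with_seed(2, gradient_check(3))
})

test_that("training separates Gaussian blobs and predicts deterministically", {
  bd <- blob_data(100, 8, shift = 2, seed = 4)
  cfg <- classifier_config(units_layer1 = 16, units_layer2 = 8,
                           epochs = 40, seed = 5)
  m <- train_bilstm(bd$x, bd$y, cfg)
  expect_gte(utils::tail(m$history$train_roc_auc, 1), 0.99)
  expect_false(any(!is.finite(m$history$train_loss)))
  p1 <- predict(m, bd$x); p2 <- predict(m, bd$x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # thresholding reproduces the zero-one loss of the metric module
  expect_equal(mean(as.integer(p1 >= 0.5) != bd$y),
               zero_one_loss(p1, bd$y))
})

test_that("label-shuffled training scores near chance on validation data", {
  bd <- blob_data(150, 6, shift = 2, seed = 6)
  y_shuf <- withr::with_seed(7, sample(bd$y))
  tr <- 1:200; va <- 201:300
  cfg <- classifier_config(units_layer1 = 16, units_layer2 = 8,
                           epochs = 30, early_stopping_patience = 30,
                           seed = 8)
  m <- train_bilstm(bd$x[tr, ], y_shuf[tr], cfg, bd$x[va, ], y_shuf[va])
  auc <- m$history$val_roc_auc[nrow(m$history)]
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("early stopping returns the best validation epoch", {
  bd <- blob_data(80, 5, shift = 1, seed = 9)
  tr <- c(1:50, 81:130); va <- c(51:80, 131:160)  # both classes on each side
  cfg <- classifier_config(units_layer1 = 8, units_layer2 = 4,
                           epochs = 25, early_stopping_patience = 5,
                           seed = 10)
  m <- train_bilstm(bd$x[tr, ], bd$y[tr], cfg, bd$x[va, ], bd$y[va])
  expect_identical(m$best_epoch, which.max(m$history$val_roc_auc))
  # restored weights reproduce the best epoch's validation AUC
  expect_equal(roc_auc(predict(m, bd$x[va, ]), bd$y[va]),
               max(m$history$val_roc_auc), tolerance = 1e-10)
})

test_that("constant features give chance-level discrimination", {
  x <- matrix(1, 120, 6)
  y <- rep_len(c(0L, 1L), 120)
  cfg <- classifier_config(units_layer1 = 8, units_layer2 = 4, epochs = 5,
                           seed = 11)
  m <- train_bilstm(x[1:80, ], y[1:80], cfg, x[81:120, ], y[81:120])
  expect_equal(utils::tail(m$history$val_roc_auc, 1), 0.5)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(train_bilstm(x, rep(1, 10)), "single class")
  m <- train_bilstm(rbind(x, x + 2), rep(c(0, 1), each = 10),
                    classifier_config(units_layer1 = 4, units_layer2 = 2,
                                      epochs = 2, seed = 1))
  expect_error(predict(m, matrix(0, 2, 7)), "width")
})
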