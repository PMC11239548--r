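zeroed_gru <- function(d_in, d_h) {
  w <- gru_weights(d_in, d_h, seed = 1)
  for (nm in c("W_z", "W_r", "W_h", "U_z", "U_r", "U_h"))
    w[[nm]][] <- 0
  for (nm in c("b_z", "b_r", "b_h")) w[[nm]][] <- 0
  w
}

test_that("a zero-weight GRU cell halves its previous state", {
  w <- zeroed_gru(3, 4)
  p <- c(0.2, -0.4, 0.9, 0.1)
  # z = sigmoid(0) = 0.5, candidate = tanh(0) = 0 -> 0.5 * p
  expect_equal(gru_cell_step(c(1, 1, 1), p, w), 0.5 * p)
})

test_that("GRU states stay in (-1,1) and match a scalar oracle", {
  set.seed(8)
  for (k in 1:20) {
    w <- gru_weights(3, 5, seed = k)
    x <- rnorm(3); h <- runif(5, -0.99, 0.99)
    out <- gru_cell_step(x, h, w)
    expect_true(all(out > -1 & out < 1))
    expect_equal(out, gru_step_oracle(x, h, w), tolerance = 1e-12)
  }
  expect_error(gru_cell_step(c(1, 2), numeric(5), gru_weights(3, 5)),
               "dimension")
})

test_that("gru_layer runs the recurrence left to right", {
  w <- gru_weights(2, 3, seed = 2)
  x1 <- c(0.3, -0.7)
  expect_equal(gru_layer(rbind(x1), w), rbind(gru_cell_step(x1, numeric(3), w)))
  # zero input with zero weights keeps the zero state fixed
  wz <- zeroed_gru(2, 3)
  H <- gru_layer(matrix(0, 4, 2), wz)
  expect_equal(H, matrix(0, 4, 3))
  # per-step oracle on a random sequence
  set.seed(3)
  X <- matrix(rnorm(10), 5, 2)
  H <- gru_layer(X, w)
  h <- numeric(3)
  for (t in 1:5) {
    h <- gru_step_oracle(X[t, ], h, w)
    expect_equal(H[t, ], h, tolerance = 1e-12)
  }
  expect_error(gru_layer(matrix(0, 0, 2), w), "empty")
})

test_that("self-attention is row-stochastic and matches a double loop", {
  p <- attention_params(4, 3, seed = 5)
  # single timestep: softmax of a scalar is 1, context = its value row
  H1 <- matrix(rnorm(4), 1, 4)
  expect_equal(self_attention(H1, p), H1 %*% p$W_v)
  # identical rows: uniform attention
  H2 <- matrix(rep(rnorm(4), each = 6), 6, 4)
  A <- attr(self_attention(H2, p, return_weights = TRUE), "weights")
  expect_equal(A, matrix(1 / 6, 6, 6))
  # random case against the explicit oracle; weights positive, rows sum to 1
  set.seed(6)
  for (k in 1:10) {
    H <- matrix(rnorm(5 * 4), 5, 4)
    ctx <- self_attention(H, p, return_weights = TRUE)
    expect_equal(unclass(ctx), attention_oracle(H, p),
                 tolerance = 1e-10, ignore_attr = TRUE)
    W <- attr(ctx, "weights")
    expect_equal(rowSums(W), rep(1, 5), tolerance = 1e-9)
    expect_true(all(W > 0))
  }
})

test_that("the stacked extractor pools summed layer contexts", {
  w <- gru_weights(2, 4, seed = 1); p <- attention_params(4, 2, seed = 2)
  X <- matrix(rnorm(8), 4, 2)
  one <- stack_attention_gru(X, list(list(gru = w, attention = p)))
  expect_equal(one, colMeans(self_attention(gru_layer(X, w), p)))
  # two fully zeroed layers on zero input give a zero feature vector
  wz <- zeroed_gru(2, 4)
  pz <- attention_params(4, 2, seed = 1); for (nm in c("W_q", "W_k", "W_v")) pz[[nm]][] <- 0
  lz <- list(list(gru = wz, attention = pz),
             list(gru = zeroed_gru(2, 4), attention = pz))
  expect_equal(stack_attention_gru(matrix(0, 4, 2), lz), c(0, 0))
  # layer-by-layer oracle for a three-layer stack
  set.seed(9)
  layers <- list(
    list(gru = gru_weights(2, 4, seed = 11), attention = attention_params(4, 2, seed = 12)),
    list(gru = gru_weights(2, 4, seed = 13), attention = attention_params(4, 2, seed = 14)),
    list(gru = gru_weights(2, 4, seed = 15), attention = attention_params(4, 2, seed = 16)))
  X <- matrix(rnorm(12), 6, 2)
  inp <- X; acc <- 0
  for (l in layers) {
    ctx <- self_attention(gru_layer(inp, l$gru), l$attention)
    acc <- acc + ctx; inp <- ctx
  }
  expect_equal(stack_attention_gru(X, layers), colMeans(acc), tolerance = 1e-12)
  # concat aggregation returns one pooled block per layer
  expect_length(stack_attention_gru(X, layers, aggregate = "concat"), 6)
})

test_that("the batched forward pass agrees with the per-record path", {
  layers <- list(
    list(gru = gru_weights(4, 6, seed = 21), attention = attention_params(6, 4, seed = 22)),
    list(gru = gru_weights(4, 6, seed = 23), attention = attention_params(6, 4, seed = 24)))
  set.seed(10)
  X <- array(rnorm(7 * 5 * 4), c(7, 5, 4))
  batched <- cardiohawk:::forward_features(X, layers)
  for (i in 1:7)
    expect_equal(batched[i, ], stack_attention_gru(X[i, , ], layers),
                 tolerance = 1e-12)
  batched_c <- cardiohawk:::forward_features(X, layers, aggregate = "concat")
  for (i in 1:7)
    expect_equal(batched_c[i, ],
                 stack_attention_gru(X[i, , ], layers, aggregate = "concat"),
                 tolerance = 1e-12)
})

test_that("the ELM closed form interpolates, shrinks and matches ridge", {
  set.seed(12)
  # near-unregularized square system interpolates the targets
  h <- elm_head(6, 20, regularization = 1e12, seed = 1)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Y <- diag(20)[, 1:3]
  fit <- elm_fit(X, Y, h)
  expect_equal(elm_predict(X, fit), Y, tolerance = 1e-4, ignore_attr = TRUE)
  # kernel-form and primal-form solutions both satisfy the ridge oracle
  for (n in c(15, 60)) {   # n < d_elm and n > d_elm branches
    h2 <- elm_head(5, 30, regularization = 3, seed = 2)
    X2 <- matrix(rnorm(n * 5), n, 5)
    Y2 <- matrix(rnorm(n * 2), n, 2)
    fit2 <- elm_fit(X2, Y2, h2)
    H <- tanh(X2 %*% h2$hidden_proj +
                matrix(h2$hidden_bias, n, 30, byrow = TRUE))
    expect_equal(fit2$output_weights, ridge_oracle(H, Y2, 3),
                 tolerance = 1e-8, ignore_attr = TRUE)
    resid <- (crossprod(H) + diag(30) / 3) %*% fit2$output_weights -
      crossprod(H, Y2)
    expect_lt(max(abs(resid)), 1e-8)
  }
  # shrinkage: smaller C means smaller coefficient norm
  X3 <- matrix(rnorm(40 * 5), 40, 5); Y3 <- matrix(rnorm(40), 40, 1)
  norms <- sapply(c(0.01, 1, 100), function(C) {
    f <- elm_fit(X3, Y3, elm_head(5, 15, regularization = C, seed = 3))
    sqrt(sum(f$output_weights^2))
  })
  expect_true(all(diff(norms) >= 0))
  # permuting training rows leaves the solution unchanged
  perm <- sample(40)
  f1 <- elm_fit(X3, Y3, elm_head(5, 15, regularization = 2, seed = 4))
  f2 <- elm_fit(X3[perm, , drop = FALSE], Y3[perm, , drop = FALSE],
                elm_head(5, 15, regularization = 2, seed = 4))
  expect_equal(f1$output_weights, f2$output_weights, tolerance = 1e-10)
})

test_that("prediction requires a fit and respects the odd activation", {
  h <- elm_head(3, 8, seed = 5)
  expect_error(elm_predict(matrix(0, 1, 3), h), "not fitted")
  h$hidden_bias[] <- 0
  hf <- elm_fit(matrix(rnorm(30), 10, 3), matrix(rnorm(10), 10, 1), h)
  # tanh(0) = 0: a zero feature row scores exactly zero
  expect_equal(as.numeric(elm_predict(matrix(0, 1, 3), hf)), 0)
})

test_that("class decisions follow the ordinal staircase and the argmax", {
  expect_equal(decide_class(1, "ternary"), "normal")
  expect_equal(decide_class(1.5, "ternary"), "disease1")
  expect_equal(decide_class(2.5, "ternary"), "disease2")
  expect_equal(decide_class(3.5, "ternary"), "uncertain")
  expect_equal(decide_class(c(0.9, 0.1), "binary"), "normal")
  expect_equal(decide_class(c(0.2, 0.3), "binary"), "disease")
  expect_error(decide_class(c(NaN, 1), "binary"), "non-finite")
})
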