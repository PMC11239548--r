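#' GRU weight container
#'
#' Gate weights for a single gated recurrent unit layer. Matrices act on
#' column vectors: `W_*` are `d_h x d_in`, `U_*` are `d_h x d_h`, biases are
#' length `d_h`. Weights are drawn uniform on (-0.5, 0.5) under `seed`
#' (reservoir-style initialization: the layer is not gradient-trained, the
#' learnable capacity lives in the closed-form ELM head).
#'
#' @param d_in input dimension per timestep.
#' @param d_h hidden-state dimension.
#' @param seed integer seed for the draw.
#' @return object of class `gru_weights`.
#' @export
gru_weights <- function(d_in, d_h, seed = 1L) {
  stopifnot(d_in >= 1, d_h >= 1)
  with_seed(seed, {
    m <- function(r, c) matrix(stats::runif(r * c, -0.5, 0.5), r, c)
    structure(list(
      W_z = m(d_h, d_in), W_r = m(d_h, d_in), W_h = m(d_h, d_in),
      U_z = m(d_h, d_h), U_r = m(d_h, d_h), U_h = m(d_h, d_h),
      b_z = stats::runif(d_h, -0.5, 0.5),
      b_r = stats::runif(d_h, -0.5, 0.5),
      b_h = stats::runif(d_h, -0.5, 0.5),
      d_in = as.integer(d_in), d_h = as.integer(d_h)), class = "gru_weights")
  })
}

#' Single GRU cell step
#'
#' Update gate `z = sigmoid(W_z x + U_z h + b_z)`, reset gate
#' `r = sigmoid(W_r x + U_r h + b_r)`, candidate
#' `h~ = tanh(W_h x + U_h (r * h) + b_h)`, new state
#' `(1 - z) * h + z * h~`. With `h` componentwise in (-1, 1) the new state
#' stays in (-1, 1): it is a convex combination of `h` and a tanh value.
#'
#' @param x input vector (length `d_in`).
#' @param h_prev previous hidden state (length `d_h`).
#' @param weights a [gru_weights()].
#' @return the new hidden state.
#' @export
gru_cell_step <- function(x, h_prev, weights) {
  stopifnot(inherits(weights, "gru_weights"))
  if (length(x) != weights$d_in || length(h_prev) != weights$d_h)
    stop_numeric("gru_cell_step: dimension mismatch")
  z <- sigmoid(drop(weights$W_z %*% x + weights$U_z %*% h_prev) + weights$b_z)
  r <- sigmoid(drop(weights$W_r %*% x + weights$U_r %*% h_prev) + weights$b_r)
  h_cand <- tanh(drop(weights$W_h %*% x + weights$U_h %*% (r * h_prev)) +
                   weights$b_h)
  (1 - z) * h_prev + z * h_cand
}

#' Run a GRU layer over a sequence
#'
#' Left-to-right recurrence from `h0` (default zero state); returns every
#' hidden state.
#'
#' @param seq_matrix `T x d_in` matrix, one row per timestep.
#' @param weights a [gru_weights()].
#' @param h0 initial hidden state (default zeros).
#' @return `T x d_h` matrix of hidden states.
#' @export
gru_layer <- function(seq_matrix, weights, h0 = NULL) {
  seq_matrix <- as.matrix(seq_matrix)
  T_len <- nrow(seq_matrix)
  if (T_len < 1L) stop_numeric("gru_layer: empty sequence")
  h <- h0 %||% numeric(weights$d_h)
  H <- matrix(0, T_len, weights$d_h)
  for (t in seq_len(T_len)) {
    h <- gru_cell_step(seq_matrix[t, ], h, weights)
    H[t, ] <- h
  }
  H
}

#' Self-attention parameters
#'
#' Query/key/value projections (`d_h x d_k` each), drawn uniform on
#' (-0.5, 0.5) under `seed`.
#'
#' @param d_h hidden dimension of the incoming states.
#' @param d_k key/context dimension.
#' @param seed integer seed.
#' @export
attention_params <- function(d_h, d_k, seed = 1L) {
  stopifnot(d_h >= 1, d_k >= 1)
  with_seed(seed, {
    m <- function() matrix(stats::runif(d_h * d_k, -0.5, 0.5), d_h, d_k)
    structure(list(W_q = m(), W_k = m(), W_v = m(),
                   d_h = as.integer(d_h), d_k = as.integer(d_k)),
              class = "attention_params")
  })
}

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)      # shift rows for numerical stability
  E <- exp(S)
  E / rowSums(E)
}

#' Scaled dot-product self-attention over a state sequence
#'
#' `Q = H W_q`, `K = H W_k`, `V = H W_v`; context is
#' `softmax(Q K' / sqrt(d_k)) V` with row-wise softmax, so every attention
#' row is a probability vector (strictly positive, sums to one).
#'
#' @param hidden_states `T x d_h` matrix.
#' @param params an [attention_params()].
#' @param return_weights also attach the attention matrix as attribute
#'   `"weights"`.
#' @return `T x d_k` context matrix.
#' @export
self_attention <- function(hidden_states, params, return_weights = FALSE) {
  H <- as.matrix(hidden_states)
  stopifnot(inherits(params, "attention_params"), ncol(H) == params$d_h)
  Q <- H %*% params$W_q
  K <- H %*% params$W_k
  V <- H %*% params$W_v
  if (any(!is.finite(Q)) || any(!is.finite(K)) || any(!is.finite(V)))
    stop_numeric("self_attention: non-finite projections")
  A <- row_softmax(Q %*% t(K) / sqrt(params$d_k))
  ctx <- A %*% V
  if (return_weights) attr(ctx, "weights") <- A
  ctx
}

#' Stacked attention-evoked GRU feature extractor
#'
#' Each layer runs a GRU over its input sequence and applies self-attention
#' to the hidden states; the context sequence feeds the next layer. Layer
#' outputs are summed (or concatenated) and mean-pooled over time into one
#' feature vector per record.
#'
#' @param seq_matrix `T x d_in` input sequence.
#' @param layers list of `list(gru = gru_weights, attention =
#'   attention_params)` entries; layer `l+1` must accept `d_k` inputs of
#'   layer `l`.
#' @param aggregate `"sum"` (requires equal `d_k` across layers) or
#'   `"concat"`.
#' @return the pooled feature vector.
#' @export
stack_attention_gru <- function(seq_matrix, layers, aggregate = c("sum", "concat")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(layers) >= 1L)
  input <- as.matrix(seq_matrix)
  outputs <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    H <- gru_layer(input, layers[[l]]$gru)
    ctx <- self_attention(H, layers[[l]]$attention)
    outputs[[l]] <- ctx
    input <- ctx
  }
  if (aggregate == "sum") {
    Y <- Reduce(`+`, outputs)
    colMeans(Y)
  } else {
    unlist(lapply(outputs, colMeans), use.names = FALSE)
  }
}

# Batched forward pass: seqs is an n x T x d_in array; all records share the
# recurrence, so each timestep is a handful of n x d matrix products instead
# of n scalar loops. Attention still loops over records (T x T blocks).
# Agrees with stack_attention_gru record-by-record (tested).
forward_features <- function(seqs, layers, aggregate = "sum") {
  stopifnot(length(dim(seqs)) == 3L)
  n <- dim(seqs)[1]; T_len <- dim(seqs)[2]
  layer_pool <- vector("list", length(layers))
  acc <- NULL
  input <- seqs
  for (l in seq_along(layers)) {
    w <- layers[[l]]$gru
    p <- layers[[l]]$attention
    h <- matrix(0, n, w$d_h)
    H <- array(0, c(n, T_len, w$d_h))
    tWz <- t(w$W_z); tWr <- t(w$W_r); tWh <- t(w$W_h)
    tUz <- t(w$U_z); tUr <- t(w$U_r); tUh <- t(w$U_h)
    for (t in seq_len(T_len)) {
      xt <- matrix(input[, t, ], n)
      z <- sigmoid(xt %*% tWz + h %*% tUz +
                     matrix(w$b_z, n, w$d_h, byrow = TRUE))
      r <- sigmoid(xt %*% tWr + h %*% tUr +
                     matrix(w$b_r, n, w$d_h, byrow = TRUE))
      hc <- tanh(xt %*% tWh + (r * h) %*% tUh +
                   matrix(w$b_h, n, w$d_h, byrow = TRUE))
      h <- (1 - z) * h + z * hc
      H[, t, ] <- h
    }
    # project all records at once, then per-record softmax on T x T blocks
    flatH <- matrix(aperm(H, c(2, 1, 3)), n * T_len, w$d_h)
    Qa <- flatH %*% p$W_q; Ka <- flatH %*% p$W_k; Va <- flatH %*% p$W_v
    ctx <- array(0, c(n, T_len, p$d_k))
    sq <- sqrt(p$d_k)
    for (i in seq_len(n)) {
      idx <- ((i - 1) * T_len + 1):(i * T_len)
      A <- row_softmax(Qa[idx, , drop = FALSE] %*%
                         t(Ka[idx, , drop = FALSE]) / sq)
      ctx[i, , ] <- A %*% Va[idx, , drop = FALSE]
    }
    layer_pool[[l]] <- matrix(colMeans(aperm(ctx, c(2, 1, 3))), n)  # n x d_k
    acc <- if (is.null(acc)) ctx else acc + ctx
    input <- ctx
  }
  if (aggregate == "sum") {
    matrix(colMeans(aperm(acc, c(2, 1, 3))), n)
  } else {
    do.call(cbind, layer_pool)
  }
}
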