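#' Extreme learning machine head
#'
#' Single hidden layer with fixed random input weights and a tanh
#' activation; only the output weights are learned, in closed form, as the
#' ridge-regularized least-squares solution. With hidden activations
#' `H = tanh(X W + b)`, the fitted output weights are
#' `beta = H' (I/C + H H')^{-1} Y`, identical to the primal ridge solution
#' `(H'H + I/C)^{-1} H' Y`; the kernel form is used when `n <= d_elm`, the
#' primal form otherwise.
#'
#' @param d_feat incoming feature dimension.
#' @param d_elm hidden width.
#' @param regularization ridge constant C > 0 (larger C = less shrinkage).
#' @param seed integer seed for the fixed random hidden weights.
#' @return object of class `elm_head` (unfitted: `output_weights` is NULL).
#' @export
elm_head <- function(d_feat, d_elm, regularization = 1, seed = 1L) {
  stopifnot(d_feat >= 1, d_elm >= 1)
  if (regularization <= 0) stop_config("ELM regularization must be positive")
  with_seed(seed, {
    structure(list(
      hidden_proj = matrix(stats::runif(d_feat * d_elm, -1, 1), d_feat, d_elm),
      hidden_bias = stats::runif(d_elm, -1, 1),
      regularization = regularization,
      output_weights = NULL,
      d_feat = as.integer(d_feat), d_elm = as.integer(d_elm)),
      class = "elm_head")
  })
}

elm_hidden <- function(features, head) {
  X <- as.matrix(features)
  if (ncol(X) != head$d_feat) stop_numeric("ELM: feature dimension mismatch")
  tanh(X %*% head$hidden_proj +
         matrix(head$hidden_bias, nrow(X), head$d_elm, byrow = TRUE))
}

#' Fit the ELM output weights in closed form
#'
#' @param features `n x d_feat` matrix.
#' @param targets `n x k` target matrix (one-hot class indicators, or a
#'   single column of ordinal scores).
#' @param head an [elm_head()].
#' @return the head with `output_weights` filled in.
#' @export
elm_fit <- function(features, targets, head) {
  stopifnot(inherits(head, "elm_head"))
  H <- elm_hidden(features, head)
  Y <- as.matrix(targets)
  if (nrow(Y) != nrow(H)) stop_numeric("ELM: targets do not match features")
  n <- nrow(H); d <- ncol(H); C <- head$regularization
  beta <- tryCatch({
    if (n <= d) {
      t(H) %*% solve(diag(n) / C + H %*% t(H), Y)
    } else {
      solve(crossprod(H) + diag(d) / C, crossprod(H, Y))
    }
  }, error = function(e) stop_numeric("ELM: singular system: ", conditionMessage(e)))
  if (any(!is.finite(beta))) stop_numeric("ELM: non-finite output weights")
  head$output_weights <- beta
  head
}

#' Predict scores from a fitted ELM head
#'
#' @param features `n x d_feat` matrix.
#' @param head a fitted [elm_head()].
#' @return `n x k` score matrix.
#' @export
elm_predict <- function(features, head) {
  if (is.null(head$output_weights)) stop_numeric("ELM head is not fitted")
  elm_hidden(features, head) %*% head$output_weights
}

#' Map ELM scores to class labels
#'
#' Binary mode: argmax over the (normal, disease) score pair. Ternary mode
#' uses a single ordinal output `g` with the staircase thresholds
#' `g <= 1` normal, `1 < g <= 2` disease-1, `2 < g <= 3` disease-2, and
#' `g > 3` flagged `"uncertain"` (the re-evaluation branch surfaced as an
#' explicit label).
#'
#' @param score_row numeric vector: length 2 (binary) or 1 (ternary).
#' @param mode `"binary"` or `"ternary"`.
#' @return a character class label.
#' @export
decide_class <- function(score_row, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  if (any(!is.finite(score_row))) stop_numeric("decide_class: non-finite scores")
  if (mode == "binary") {
    stopifnot(length(score_row) == 2L)
    c("normal", "disease")[which.max(score_row)]
  } else {
    stopifnot(length(score_row) == 1L)
    g <- score_row
    if (g <= 1) "normal"
    else if (g <= 2) "disease1"
    else if (g <= 3) "disease2"
    else "uncertain"
  }
}
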