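#' Hyperparameter search space
#'
#' Bounds for every tunable of the classifier. The optimizer searches the
#' unit cube and positions are decoded affinely into these ranges, with
#' integral fields rounded half-up. In the default reservoir mode (no
#' gradient training) `epochs`, `learning_rate`, `batch_size` and `dropout`
#' are decoded and stored for fidelity but do not influence the forward
#' model; the active tunables are `gru_cells` (stacked layers),
#' `hidden_units` (GRU hidden width, also the ELM hidden width) and
#' `elm_regularization`.
#'
#' @param epochs,gru_cells,hidden_units,learning_rate,batch_size,dropout,elm_regularization
#'   length-2 numeric `c(lower, upper)` bounds per field.
#' @return object of class `hyperparam_space`.
#' @export
hyperparam_space <- function(epochs = c(50, 400),
                             gru_cells = c(1, 3),
                             hidden_units = c(4, 32),
                             learning_rate = c(1e-4, 1e-2),
                             batch_size = c(16, 128),
                             dropout = c(0, 0.5),
                             elm_regularization = c(0.1, 1000)) {
  fields <- list(epochs = epochs, gru_cells = gru_cells,
                 hidden_units = hidden_units, learning_rate = learning_rate,
                 batch_size = batch_size, dropout = dropout,
                 elm_regularization = elm_regularization)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (length(f) != 2 || !all(is.finite(f)) || f[1] >= f[2])
      stop_config("hyperparam_space: invalid bounds for ", nm)
  }
  if (fields$dropout[1] < 0 || fields$dropout[2] >= 1)
    stop_config("dropout bounds must lie in [0, 1)")
  if (fields$elm_regularization[1] <= 0)
    stop_config("elm_regularization must be positive")
  integral <- c(epochs = TRUE, gru_cells = TRUE, hidden_units = TRUE,
                learning_rate = FALSE, batch_size = TRUE, dropout = FALSE,
                elm_regularization = FALSE)
  structure(list(fields = fields, integral = integral), class = "hyperparam_space")
}

#' Decode an optimizer position into hyperparameters
#'
#' Affine map per coordinate from the unit cube onto the field range;
#' integral fields are rounded half-up and every decoded value is clamped
#' into its range.
#'
#' @param position numeric vector in `[0, 1]^7` (one coordinate per field).
#' @param space a [hyperparam_space()].
#' @return named list of decoded hyperparameter values.
#' @export
decode_position <- function(position, space) {
  stopifnot(inherits(space, "hyperparam_space"))
  if (length(position) != length(space$fields))
    stop_numeric("decode_position: dimension mismatch")
  out <- vector("list", length(space$fields))
  names(out) <- names(space$fields)
  for (j in seq_along(space$fields)) {
    f <- space$fields[[j]]
    v <- f[1] + min(max(position[j], 0), 1) * (f[2] - f[1])
    if (space$integral[[j]]) v <- round_half_up(v)
    out[[j]] <- min(max(v, f[1]), f[2])
  }
  out
}

# Build the layered attention-GRU extractor for decoded hyperparameters.
# d_k is fixed at the input feature count (4) so layers compose; the ELM
# hidden width is tied to hidden_units.
build_extractor <- function(hyper, d_in = 4L, seed = 1L,
                            attention_weights = NULL) {
  L <- as.integer(hyper$gru_cells)
  d_h <- as.integer(hyper$hidden_units)
  d_k <- d_in
  layers <- vector("list", L)
  din <- d_in
  for (l in seq_len(L)) {
    att <- attention_params(d_h, d_k, seed = derive_seed(seed, paste0("att", l)))
    if (!is.null(attention_weights))
      att[c("W_q", "W_k", "W_v")] <- attention_weights[[l]]
    layers[[l]] <- list(
      gru = gru_weights(din, d_h, seed = derive_seed(seed, paste0("gru", l))),
      attention = att)
    din <- d_k
  }
  layers
}

label_codes <- c(normal = 1, disease = 2, disease1 = 2, disease2 = 3)

# One-hot / ordinal targets per classification mode.
make_targets <- function(labels, mode) {
  if (mode == "binary") {
    y <- matrix(0, length(labels), 2)
    y[cbind(seq_along(labels), ifelse(labels == "normal", 1, 2))] <- 1
    y
  } else {
    matrix(label_codes[labels], ncol = 1)
  }
}

#' Fitness of one hyperparameter vector
#'
#' Builds the attention-GRU extractor and ELM head under `hyper` with
#' seeded initialization, fits the head on the training split, scores the
#' validation split, and returns the five performance measures together
#' with the scalar fitness — the mean of accuracy, precision, recall and
#' F1 (bounded in [0, 1]).
#'
#' @param hyper decoded hyperparameters ([decode_position()]).
#' @param train,validation lists with `x` (n x T x 4 array) and `labels`,
#'   as produced by [build_sequences()].
#' @param seed weight-initialization seed.
#' @param mode `"binary"` or `"ternary"`.
#' @return list: the five measures, `fitness`, and the fitted `layers` and
#'   `head`.
#' @export
evaluate_fitness <- function(hyper, train, validation, seed = 1L,
                             mode = "binary") {
  if (!length(train$labels) || !length(validation$labels) ||
      any(is.na(train$labels)) || any(is.na(validation$labels)))
    stop_config("evaluate_fitness: both splits must be non-empty and labeled")
  layers <- build_extractor(hyper, d_in = dim(train$x)[3], seed = seed)
  feat_tr <- forward_features(train$x, layers)
  head <- elm_head(ncol(feat_tr), as.integer(hyper$hidden_units),
                   regularization = hyper$elm_regularization,
                   seed = derive_seed(seed, "elm"))
  head <- elm_fit(feat_tr, make_targets(train$labels, mode), head)
  feat_va <- forward_features(validation$x, layers)
  scores <- elm_predict(feat_va, head)
  pred <- apply(scores, 1, decide_class, mode = mode)
  m <- classification_metrics(confusion(validation$labels, pred))
  c(m[c("accuracy", "recall", "specificity", "precision", "f1")],
    list(fitness = fitness_from_metrics(m), layers = layers, head = head))
}

#' Fit the chaotic-hawk cardiac classifier
#'
#' End-to-end training: studentized-residual imputation, a stratified
#' train/validation split, z-score normalization with training-fold
#' statistics, and Harris Hawks search (vanilla or logistic-chaotic) over
#' the hyperparameter space, maximizing the validation fitness (mean of
#' accuracy, precision, recall, F1). Early stopping halts the search when
#' the best validation fitness stalls for `optimizer$patience` iterations.
#' The selected model is refit on all supplied records before returning.
#'
#' In `tune = "weights"` mode the architecture is frozen mid-range and the
#' optimizer searches the attention projection entries directly instead of
#' the hyperparameters.
#'
#' @param records labeled cohort data.frame (columns patient_id, age,
#'   gender, ecg, bp, label; NAs allowed, they are imputed).
#' @param streams optional per-record sample stream matrix (rownames =
#'   patient ids).
#' @param space a [hyperparam_space()].
#' @param optimizer an [hho_config()]; its `seed` is ignored in favour of
#'   `seed`.
#' @param window sequence length fed to the GRU.
#' @param mode `"binary"` (normal vs disease) or `"ternary"` (ordinal
#'   staircase with an `"uncertain"` overflow label).
#' @param val_fraction fraction of the records held out internally for the
#'   fitness evaluations.
#' @param tune `"hyperparams"` (default) or `"weights"`.
#' @param seed master seed; the whole fit is deterministic given it.
#' @return object of class `cardiohawk`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_total = 120, n_healthy = 60))
#' fit <- cardiohawk(cohort$records, cohort$streams,
#'                   optimizer = hho_config(4, 3, variant = "lc_hhoa"),
#'                   seed = 7)
#' print(fit)
#' }
#' @export
cardiohawk <- function(records, streams = NULL,
                       space = hyperparam_space(),
                       optimizer = hho_config(population = 6,
                                              max_iterations = 10,
                                              variant = "lc_hhoa",
                                              patience = 3),
                       window = 16L, mode = c("binary", "ternary"),
                       val_fraction = 0.25,
                       tune = c("hyperparams", "weights"),
                       seed = 1L) {
  mode <- match.arg(mode)
  tune <- match.arg(tune)
  if (any(is.na(records$label))) stop_config("cardiohawk: unlabeled records")
  cl <- match.call()

  records <- impute_studentized(records)
  imput_fits <- attr(records, "imputation_fits")
  sp <- stratified_split(records, 1 - val_fraction,
                         derive_seed(seed, "valsplit"))
  norm_tr <- normalize_cohort(sp$train)
  norm_va <- normalize_cohort(sp$test, stats = norm_tr$stats)
  sub_str <- function(rec) {
    if (is.null(streams)) NULL else streams[rec$patient_id, , drop = FALSE]
  }
  train <- build_sequences(norm_tr, window, sub_str(sp$train))
  validation <- build_sequences(list(records = norm_va$records,
                                     stats = norm_tr$stats),
                                window, sub_str(sp$test))
  wseed <- derive_seed(seed, "weights")

  if (tune == "hyperparams") {
    dim_search <- length(space$fields)
    objective <- function(position) {
      hyper <- decode_position(position, space)
      -evaluate_fitness(hyper, train, validation, seed = wseed,
                        mode = mode)$fitness
    }
    bounds <- hho_bounds(rep(0, dim_search), rep(1, dim_search))
  } else {
    hyper_fixed <- decode_position(rep(0.5, length(space$fields)), space)
    L <- as.integer(hyper_fixed$gru_cells)
    d_h <- as.integer(hyper_fixed$hidden_units)
    d_k <- 4L
    slot <- d_h * d_k
    dim_search <- 3L * slot * L
    objective <- function(position) {
      aw <- lapply(seq_len(L), function(l) {
        off <- (l - 1) * 3 * slot
        lapply(0:2, function(j)
          matrix(position[off + j * slot + seq_len(slot)], d_h, d_k))
      })
      aw <- lapply(aw, function(ms) stats::setNames(ms, c("W_q", "W_k", "W_v")))
      -evaluate_weight_fitness(hyper_fixed, aw, train, validation,
                               seed = wseed, mode = mode)
    }
    bounds <- hho_bounds(rep(-0.5, dim_search), rep(0.5, dim_search))
  }

  optimizer$seed <- derive_seed(seed, "hho")
  result <- hho_optimize(objective, bounds, optimizer)

  # refit the selected configuration on everything supplied
  norm_all <- normalize_cohort(records)
  all_seq <- build_sequences(norm_all, window, sub_str(records))
  if (tune == "hyperparams") {
    hyper <- decode_position(result$best_position, space)
    attention_weights <- NULL
  } else {
    hyper <- hyper_fixed
    slot <- hyper$hidden_units * 4L
    attention_weights <- lapply(seq_len(hyper$gru_cells), function(l) {
      off <- (l - 1) * 3 * slot
      stats::setNames(lapply(0:2, function(j)
        matrix(result$best_position[off + j * slot + seq_len(slot)],
               hyper$hidden_units, 4L)), c("W_q", "W_k", "W_v"))
    })
  }
  layers <- build_extractor(hyper, d_in = 4L, seed = wseed,
                            attention_weights = attention_weights)
  feats <- forward_features(all_seq$x, layers)
  head <- elm_head(ncol(feats), as.integer(hyper$hidden_units),
                   regularization = hyper$elm_regularization,
                   seed = derive_seed(wseed, "elm"))
  head <- elm_fit(feats, make_targets(all_seq$labels, mode), head)

  structure(list(layers = layers, head = head,
                 normalization = norm_all$stats,
                 imputation_fits = imput_fits,
                 hyperparams = hyper,
                 fitness_trace = -result$trace,   # validation fitness, non-decreasing
                 optimizer_result = result,
                 validation_fitness = -result$best_fitness,
                 mode = mode, window = as.integer(window),
                 tune = tune, seed = as.integer(seed),
                 n_train = nrow(records), call = cl,
                 version = as.character(utils::packageVersion("cardiohawk"))),
            class = "cardiohawk")
}

# Weight-search fitness: fixed architecture, supplied attention projections.
evaluate_weight_fitness <- function(hyper, attention_weights, train,
                                    validation, seed, mode) {
  layers <- build_extractor(hyper, d_in = dim(train$x)[3], seed = seed,
                            attention_weights = attention_weights)
  feat_tr <- forward_features(train$x, layers)
  head <- elm_head(ncol(feat_tr), as.integer(hyper$hidden_units),
                   regularization = hyper$elm_regularization,
                   seed = derive_seed(seed, "elm"))
  head <- elm_fit(feat_tr, make_targets(train$labels, mode), head)
  scores <- elm_predict(forward_features(validation$x, layers), head)
  pred <- apply(scores, 1, decide_class, mode = mode)
  fitness_from_metrics(classification_metrics(confusion(validation$labels, pred)))
}

#' Predict cardiac class labels
#'
#' Applies the stored imputation regressions to any missing entries, the
#' stored normalization statistics, the forward path, and the class
#' decision. The model object is never modified.
#'
#' @param object a fitted [cardiohawk()] model.
#' @param records cohort record data.frame (label column optional).
#' @param streams optional stream matrix for the records.
#' @param type `"class"` for labels, `"score"` for the raw ELM scores.
#' @param ... unused.
#' @export
predict.cardiohawk <- function(object, records, streams = NULL,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (nrow(records) == 0)
    return(if (type == "class") character(0) else matrix(0, 0, 0))
  records <- apply_imputation_coefs(records, object$imputation_fits)
  records$label <- NA_character_
  norm <- normalize_cohort(records, stats = object$normalization)
  seqs <- build_sequences(list(records = norm$records,
                               stats = object$normalization),
                          object$window,
                          if (is.null(streams)) NULL
                          else streams[records$patient_id, , drop = FALSE])
  scores <- elm_predict(forward_features(seqs$x, object$layers), object$head)
  if (type == "score") return(scores)
  apply(scores, 1, decide_class, mode = object$mode)
}

# Fill missing entries of new records with the stored training-fold
# regression coefficients (no refitting, no outlier replacement).
apply_imputation_coefs <- function(records, fits) {
  if (is.null(fits)) return(records)
  me <- is.na(records$ecg)
  if (any(me)) {
    b <- fits$ecg
    bp <- records$bp[me]
    bp[is.na(bp)] <- mean(records$bp, na.rm = TRUE)
    records$ecg[me] <- b[1] + b["bp"] * bp + b["age"] * records$age[me]
  }
  mb <- is.na(records$bp)
  if (any(mb)) {
    b <- fits$bp
    records$bp[mb] <- b[1] + b["ecg"] * records$ecg[mb] +
      b["age"] * records$age[mb]
  }
  records
}

#' @export
print.cardiohawk <- function(x, ...) {
  cat("Chaotic-hawk cardiac classifier (", x$mode, " mode, ",
      x$optimizer_result$variant, ")\n", sep = "")
  cat("  records:", x$n_train, " window:", x$window, "\n")
  cat("  selected hyperparameters:\n")
  h <- x$hyperparams
  cat(sprintf("    gru_cells=%d hidden_units=%d C=%.4g\n",
              h$gru_cells, h$hidden_units, h$elm_regularization))
  cat(sprintf("  best validation fitness: %.4f after %d optimizer iterations\n",
              x$validation_fitness, x$optimizer_result$iterations))
  invisible(x)
}

#' @export
summary.cardiohawk <- function(object, ...) {
  out <- list(hyperparams = object$hyperparams,
              validation_fitness = object$validation_fitness,
              trace = object$fitness_trace,
              evaluations = object$optimizer_result$evaluations,
              mode = object$mode, tune = object$tune)
  class(out) <- "summary.cardiohawk"
  out
}

#' @export
print.summary.cardiohawk <- function(x, ...) {
  cat("cardiohawk model summary\n")
  cat("  mode:", x$mode, " tune:", x$tune, "\n")
  cat("  hyperparameters:\n")
  for (nm in names(x$hyperparams))
    cat(sprintf("    %-20s %s\n", nm, format(x$hyperparams[[nm]])))
  cat("  validation fitness:", round(x$validation_fitness, 4),
      "over", length(x$trace), "iterations,", x$evaluations,
      "model evaluations\n")
  invisible(x)
}

#' @export
coef.cardiohawk <- function(object, ...) {
  unlist(object$hyperparams)
}

#' Plot the optimizer convergence trace
#'
#' Best validation fitness (mean of accuracy, precision, recall, F1) per
#' optimizer iteration; non-decreasing by construction.
#'
#' @param x a fitted [cardiohawk()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cardiohawk <- function(x, ...) {
  graphics::plot(seq_along(x$fitness_trace), x$fitness_trace, type = "s",
                 xlab = "optimizer iteration",
                 ylab = "best validation fitness",
                 main = "Hyperparameter search convergence", ...)
  invisible(x)
}
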