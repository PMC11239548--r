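#' Save and load a fitted model bundle
#'
#' The bundle is a single JSON manifest holding every weight matrix, the
#' normalization and imputation statistics, hyperparameters, seeds and a
#' mandatory `version` field. Numeric payloads are written as 17
#' significant-digit decimal strings, which round-trip IEEE doubles
#' exactly, so a loaded model reproduces the saved model's outputs bit for
#' bit.
#'
#' @param model a fitted [cardiohawk()] object.
#' @param path file path for the JSON bundle.
#' @export
save_cardiohawk <- function(model, path) {
  stopifnot(inherits(model, "cardiohawk"))
  ser_num <- function(x) format_num(as.numeric(x))
  ser_mat <- function(m) list(dim = dim(m), data = ser_num(as.vector(m)))
  layers <- lapply(model$layers, function(l) list(
    gru = c(lapply(l$gru[c("W_z", "W_r", "W_h", "U_z", "U_r", "U_h")], ser_mat),
            lapply(l$gru[c("b_z", "b_r", "b_h")], ser_num),
            l$gru[c("d_in", "d_h")]),
    attention = c(lapply(l$attention[c("W_q", "W_k", "W_v")], ser_mat),
                  l$attention[c("d_h", "d_k")])))
  head <- list(hidden_proj = ser_mat(model$head$hidden_proj),
               hidden_bias = ser_num(model$head$hidden_bias),
               output_weights = ser_mat(model$head$output_weights),
               regularization = ser_num(model$head$regularization),
               d_feat = model$head$d_feat, d_elm = model$head$d_elm)
  imput <- lapply(model$imputation_fits, function(v)
    list(names = names(v), values = ser_num(v)))
  norm <- lapply(model$normalization, function(s)
    list(mean = ser_num(s$mean), sd = ser_num(s$sd)))
  bundle <- list(format = "cardiohawk-model", version = model$version,
                 mode = model$mode, window = model$window,
                 tune = model$tune, seed = model$seed,
                 n_train = model$n_train,
                 hyperparams = lapply(model$hyperparams, ser_num),
                 normalization = norm,
                 imputation_fits = imput,
                 fitness_trace = ser_num(model$fitness_trace),
                 validation_fitness = ser_num(model$validation_fitness),
                 variant = model$optimizer_result$variant,
                 layers = layers, head = head)
  tryCatch(
    jsonlite::write_json(bundle, path, auto_unbox = TRUE, pretty = FALSE),
    error = function(e) stop_io("cannot write model bundle: ",
                                conditionMessage(e)))
  invisible(path)
}

#' @rdname save_cardiohawk
#' @return `load_cardiohawk` returns the restored `cardiohawk` model.
#' @export
load_cardiohawk <- function(path) {
  if (!file.exists(path)) stop_io("model bundle not found: ", path)
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(b$format, "cardiohawk-model") || is.null(b$version))
    stop_io("not a cardiohawk model bundle: ", path)
  num <- function(x) as.numeric(unlist(x))
  de_mat <- function(s) matrix(num(s$data), s$dim[[1]], s$dim[[2]])
  layers <- lapply(b$layers, function(l) {
    gru <- structure(c(lapply(l$gru[c("W_z", "W_r", "W_h", "U_z", "U_r", "U_h")],
                              de_mat),
                       list(b_z = num(l$gru$b_z), b_r = num(l$gru$b_r),
                            b_h = num(l$gru$b_h),
                            d_in = as.integer(l$gru$d_in),
                            d_h = as.integer(l$gru$d_h))),
                     class = "gru_weights")
    att <- structure(c(lapply(l$attention[c("W_q", "W_k", "W_v")], de_mat),
                       list(d_h = as.integer(l$attention$d_h),
                            d_k = as.integer(l$attention$d_k))),
                     class = "attention_params")
    list(gru = gru, attention = att)
  })
  head <- structure(list(hidden_proj = de_mat(b$head$hidden_proj),
                         hidden_bias = num(b$head$hidden_bias),
                         regularization = num(b$head$regularization),
                         output_weights = de_mat(b$head$output_weights),
                         d_feat = as.integer(b$head$d_feat),
                         d_elm = as.integer(b$head$d_elm)),
                    class = "elm_head")
  norm <- lapply(b$normalization, function(s)
    list(mean = num(s$mean), sd = num(s$sd)))
  imput <- lapply(b$imputation_fits, function(v)
    stats::setNames(num(v$values), unlist(v$names)))
  structure(list(layers = layers, head = head, normalization = norm,
                 imputation_fits = imput,
                 hyperparams = lapply(b$hyperparams, function(v) as.numeric(v)),
                 fitness_trace = num(b$fitness_trace),
                 optimizer_result = list(variant = b$variant,
                                         iterations = length(b$fitness_trace),
                                         evaluations = NA_integer_,
                                         trace = -num(b$fitness_trace)),
                 validation_fitness = num(b$validation_fitness),
                 mode = b$mode, window = as.integer(b$window),
                 tune = b$tune, seed = as.integer(b$seed),
                 n_train = b$n_train, call = NULL, version = b$version),
            class = "cardiohawk")
}
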