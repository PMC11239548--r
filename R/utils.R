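# Internal helpers: seeded evaluation and deterministic child seeds.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Deterministic child seed from a master seed and a component tag; stays in
# [1, 2^31 - 2] so it is always a valid 32-bit integer seed.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) * 7919
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483646 + 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Round-half-up for decoding integral hyperparameters.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured conditions so the CLI can map failures to exit codes.
stop_config <- function(...) {
  stop(structure(class = c("cardiohawk_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_io <- function(...) {
  stop(structure(class = c("cardiohawk_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_numeric <- function(...) {
  stop(structure(class = c("cardiohawk_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
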