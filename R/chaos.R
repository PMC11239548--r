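#' Logistic chaotic map utilities
#'
#' The logistic map `x[n+1] = r * x[n] * (1 - x[n])` is fully chaotic at
#' control parameter `r = 4`, where it is conjugate to the doubling map:
#' iterates from `x0` equal `sin^2(2^n * asin(sqrt(x0)))`. The chaotic
#' optimizer variant draws its besiege positions and its initial population
#' from this sequence instead of uniform random numbers.
#'
#' @param value current map value, strictly inside (0, 1)
#' @param control map parameter in (0, 4]; 4 is the fully chaotic regime
#' @return `logistic_step` returns the next map value in `[0, 1]`.
#' @examples
#' logistic_step(0.2, 4)   # 0.64
#' @export
logistic_step <- function(value, control = 4) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0 || value >= 1)
    stop_numeric("invalid chaotic state: value must lie strictly in (0, 1)")
  if (!is.numeric(control) || length(control) != 1L || control <= 0 || control > 4)
    stop_numeric("invalid chaotic state: control must lie in (0, 4]")
  control * value * (1 - value)
}

#' @describeIn logistic_step Construct a chaotic state. Initial values on the
#'   absorbing/periodic orbit points {0, 0.25, 0.5, 0.75, 1} of the control-4
#'   map are rejected because their orbits collapse.
#' @export
chaotic_state <- function(value = 0.7, control = 4) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0 || value >= 1)
    stop_numeric("chaotic initial value must lie strictly in (0, 1)")
  if (any(abs(value - c(0.25, 0.5, 0.75)) < 1e-12))
    stop_numeric("chaotic initial value lies on a degenerate orbit of the map")
  if (control <= 0 || control > 4)
    stop_numeric("chaotic control parameter must lie in (0, 4]")
  structure(list(value = value, control = control), class = "chaotic_state")
}

# Advance the scalar chaotic stream n times; returns values and mutated state.
chaotic_draws <- function(state, n) {
  stopifnot(inherits(state, "chaotic_state"), n >= 1)
  v <- numeric(n)
  x <- state$value
  for (i in seq_len(n)) {
    x <- logistic_step(x, state$control)
    # Nudge off the absorbing endpoints that finite precision can reach.
    if (x <= 0) x <- .Machine$double.eps
    if (x >= 1) x <- 1 - .Machine$double.eps
    v[i] <- x
  }
  state$value <- x
  list(values = v, state = state)
}

#' Chaotic position inside a search box
#'
#' Advances the logistic stream once per coordinate and maps the values
#' affinely onto the box: `LB + c * (UB - LB)`.
#'
#' @param state a [chaotic_state()]
#' @param bounds an [hho_bounds()] search box
#' @return list with `position` (numeric vector) and the advanced `state`.
#' @export
chaotic_position <- function(state, bounds) {
  stopifnot(inherits(bounds, "hho_bounds"))
  d <- chaotic_draws(state, bounds$dim)
  list(position = bounds$lower + d$values * (bounds$upper - bounds$lower),
       state = d$state)
}
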