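#' Reward squashing transforms
#'
#' Backpropagated rewards are kept in \[-1, 1\]. Two strictly monotone
#' transforms are provided: `linear_unit` maps a known score range
#' linearly onto \[-1, 1\] (clamping outside values), the natural choice
#' for bounded scores such as QED; `tanh_scaled` maps unbounded scores
#' through `tanh(x / scale)`, the natural choice for penalized logP.
#' `-Inf` (a failed constraint) maps to -1.
#'
#' @param kind `"linear_unit"` or `"tanh_scaled"`.
#' @param lo,hi Score range for `linear_unit`.
#' @param scale Scale for `tanh_scaled`.
#' @return A `reward_transform` object.
#' @export
reward_transform <- function(kind = c("linear_unit", "tanh_scaled"),
                             lo = 0, hi = 1, scale = 10) {
  kind <- match.arg(kind)
  if (kind == "linear_unit") stopifnot(hi > lo)
  structure(list(kind = kind, lo = lo, hi = hi, scale = scale),
            class = "reward_transform")
}

#' Squash a raw score into \[-1, 1\]
#'
#' @param raw Numeric vector of raw scores (`-Inf` allowed).
#' @param transform A [reward_transform()].
#' @return Numeric vector in \[-1, 1\].
#' @export
squash <- function(raw, transform) {
  if (any(is.na(raw) | (is.infinite(raw) & raw > 0)))
    stop("non-finite score cannot be squashed", call. = FALSE)
  out <- if (transform$kind == "linear_unit") {
    2 * (raw - transform$lo) / (transform$hi - transform$lo) - 1
  } else {
    tanh(raw / transform$scale)
  }
  pmin(pmax(out, -1), 1)
}

# default transform for a score function: linear on a declared range,
# tanh otherwise
default_transform <- function(sf) {
  if (!is.null(sf$range))
    reward_transform("linear_unit", lo = sf$range[1], hi = sf$range[2])
  else
    reward_transform("tanh_scaled", scale = 10)
}

#' UCB1 selection score
#'
#' Upper confidence bound used by both tree searches:
#' `xbar + c * sqrt(2 * log(n_parent) / n)`. Unvisited nodes (`n = 0`)
#' return `Inf` so they are always selected first.
#'
#' @param xbar Mean reward of the node (`value_sum / visits`).
#' @param n Node visit count.
#' @param n_parent Parent visit count (`>= n`).
#' @param c_explore Exploration constant (default `sqrt(2)`).
#' @return Numeric (vectorized over the inputs).
#' @export
ucb1 <- function(xbar, n, n_parent, c_explore = sqrt(2)) {
  if (any(n < 0 | n_parent < 0))
    stop("visit counts must be non-negative", call. = FALSE)
  ifelse(n == 0, Inf,
         xbar + c_explore * sqrt(2 * log(pmax(n_parent, 1)) / pmax(n, 1)))
}
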