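# shared helpers

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (half-up), the
#' convention used when reporting percentages such as 3.125% -> 3.13%.
#' Base [round()] uses banker's rounding and would give 3.12.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' round_half_up(3.125, 2)  # 3.13
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# with seed = NULL the expression just uses the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_usage <- function(...) {
  stop(structure(class = c("meioscan_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
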