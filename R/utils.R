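# Internal helpers shared across modules.

# Deterministic child seeds. Keeps everything inside [0, 2^31 - 2] so the
# result is always a valid integer seed for set.seed().
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

#' Round half away from zero
#'
#' The rounding convention of the result tables; base [round()] rounds half
#' to even. Metrics are computed in full precision and only rounded for
#' presentation.
#'
#' @param x numeric (vector, matrix or data.frame).
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
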