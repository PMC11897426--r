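# Internal helpers shared across modules.

# Locale-independent lexicographic sort/order (radix = C locale), so matrix
# row/column orders are bit-stable across platforms.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp_prob <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
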