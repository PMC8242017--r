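# internal helpers: errors, seeded evaluation, pair-index arithmetic

`%||%` <- function(x, y) if (is.null(x)) y else x

bv_stop <- function(msg, class = "validation") {
  stop(errorCondition(
    msg,
    class = c(paste0("bionetval_", class, "_error"), "bionetval_error",
              "error", "condition")
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded package functions never clobber the user's random stream.
#' `seed = NULL` evaluates `code` with the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(abs(seed) %% 2147483647L))
  }
  force(code)
}

# counter-based derivation of per-replicate seeds from a master seed;
# order-insensitive (replicate i always gets the same seed) and kept inside
# 32-bit integer range. Constants are classic Lehmer multipliers; doubles
# stay below 2^53 so the arithmetic is exact.
derive_seed <- function(master, counter) {
  s <- (abs(as.double(master)) %% 2147483647) + 1
  as.integer((s * 48271 + (as.double(counter) + 1) * 69621) %% 2147483629) + 1L
}

# --- unordered-pair index arithmetic -----------------------------------------
# Pairs (i, j), 1 <= i < j <= n, are enumerated i-major:
# (1,2), (1,3), ..., (1,n), (2,3), ... Index range is 1..n(n-1)/2.

pair_count <- function(n) n * (n - 1) / 2

pair_index <- function(i, j, n) (i - 1) * n - i * (i + 1) / 2 + j

pair_decode <- function(k, n) {
  f <- function(t) t * n - t * (t + 1) / 2  # pairs with first element <= t
  t <- floor(((2 * n - 1) - sqrt(pmax((2 * n - 1)^2 - 8 * k, 0))) / 2)
  t <- pmax(pmin(t, n - 2), 0)
  bad <- f(t) >= k
  while (any(bad)) {
    t[bad] <- t[bad] - 1
    bad <- f(t) >= k
  }
  bad <- f(t + 1) < k
  while (any(bad)) {
    t[bad] <- t[bad] + 1
    bad <- f(t + 1) < k
  }
  i <- t + 1
  cbind(i = i, j = k - f(t) + i)
}

# small deterministic string hash (position-weighted code points)
string_hash <- function(s) {
  codes <- utf8ToInt(s)
  sum(codes * seq_along(codes)) %% 99991
}

# locale-independent sort/order for identifiers
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

# canonical unordered-pair keys for character endpoints
pair_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
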