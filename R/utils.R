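# Internal helpers: classed conditions, seed scoping, string hashing.

#' @keywords internal
"_PACKAGE"

# The 20 standard amino acids in alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

tb_stop <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "tcrbench_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

tb_warn <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "tcrbench_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  warning(cnd)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-bit string hash (polynomial rolling hash + Lehmer mixing).
# Exact-integer arithmetic in doubles; values stay below 2^31 - 1.
str_hash <- function(s, seed = 0L) {
  m <- 2147483647
  vapply(s, function(x) {
    h <- as.numeric(seed) %% m
    for (code in utf8ToInt(x)) h <- (h * 131 + code) %% m
    for (i in 1:3) h <- (h * 48271) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
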