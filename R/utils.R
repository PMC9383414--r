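# Internal utilities: seeded evaluation, nested-list (parameter tree)
# arithmetic, checksums, and a small string hash used for config fingerprints.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
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
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and an index, staying within the
# 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483563) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# ---- parameter trees -------------------------------------------------------
# Model parameters are nested lists whose leaves are numeric vectors/arrays.
# The optimizer and the checksum helpers walk these trees generically.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(el) tree_map(f, el)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_flatten), use.names = FALSE) else as.numeric(x)
}

#' Checksum of a parameter tree
#'
#' Deterministic fingerprint of every numeric value in a nested parameter
#' list, used by the phase-isolation (freeze) contracts: two trees have equal
#' checksums iff their flattened values are bit-identical in printed
#' 17-significant-digit form.
#'
#' @param x Nested list of numeric arrays (or a single array).
#' @return A character scalar.
#' @export
param_checksum <- function(x) {
  string_hash(paste(sprintf("%.17g", tree_flatten(x)), collapse = ","))
}

# FNV-1a style 32-bit string hash implemented in double arithmetic
# (products kept below 2^53 by splitting the accumulator into 16-bit halves).
string_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitxor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

bitxor32 <- function(a, b) {
  # xor of nonnegative doubles < 2^32 without integer overflow
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

is_symmetric_tol <- function(m, tol = 1e-9) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
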