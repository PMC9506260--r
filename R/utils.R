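#' Internal helpers: argument checks, seed derivation, reflective indexing
#'
#' @noRd
NULL

stop_rcm <- function(msg, class) {
  rlang::abort(msg, class = paste0("rcmseg_", class))
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_rcm(sprintf("`%s` must be a single finite number.", name), "bad_arg")
  }
  ok_lower <- if (strict_lower) x > lower else x >= lower
  if (!ok_lower || x > upper) {
    stop_rcm(sprintf("`%s` = %s is outside its allowed range.", name, x),
             "bad_arg")
  }
  invisible(x)
}

check_binary_matrix <- function(m, name) {
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    stop_rcm(sprintf("`%s` must be a binary (0/1) matrix.", name), "bad_mask")
  }
  invisible(m)
}

# Deterministic per-unit seed derived from a master seed; stays inside the
# 32-bit signed range so set.seed() accepts it on every platform.
derive_seed <- function(master, ...) {
  parts <- c(as.double(master), as.double(unlist(list(...))))
  primes <- c(7919, 104729, 1299709, 15485863, 32452843, 49979687)
  s <- 0
  for (i in seq_along(parts)) {
    s <- (s * 69069 + parts[i] * primes[((i - 1L) %% length(primes)) + 1L]) %%
      2147483647
  }
  as.integer(s)
}

# Reflect out-of-range 1-based indices back into [1, n] (symmetric reflection,
# edge pixel participates: ... 2 1 | 1 2 3 ... n | n n-1 ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((round(i) - 1L) %% period + period) %% period  # 0-based, in [0, 2n)
  j <- ifelse(j >= n, period - 1L - j, j)
  as.integer(j + 1L)
}

# TensorFlow-style "same" padding amounts for kernel k, stride s, length n.
same_pad <- function(n, k, s) {
  n <- as.integer(unname(n)); k <- as.integer(unname(k))
  s <- as.integer(unname(s))
  out <- as.integer(ceiling(n / s))
  total <- max((out - 1L) * s + k - n, 0L)
  c(beg = total %/% 2L, end = total - total %/% 2L, out = out)
}

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
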