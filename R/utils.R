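# Internal numeric helpers.

# Pairwise log(exp(a) + exp(b)), vectorised, tolerant of -Inf.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exact big integers (non-negative), base 1e4 digit vectors -------------
# Little-endian numeric digit vectors. Only what the state counter needs:
# construction from a small integer, multiplication, +1, log, decimal print.

BIG_BASE <- 1e4

big_from_int <- function(n) {
  stopifnot(n >= 0, n == floor(n))
  if (n == 0) return(0)
  d <- numeric(0)
  while (n > 0) {
    d <- c(d, n %% BIG_BASE)
    n <- n %/% BIG_BASE
  }
  d
}

big_carry <- function(d) {
  repeat {
    carry <- d %/% BIG_BASE
    if (all(carry == 0)) break
    d <- d %% BIG_BASE
    if (carry[length(carry)] > 0) { d <- c(d, 0); carry <- c(carry, 0) }
    d[-1] <- d[-1] + carry[-length(carry)]
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_mul <- function(a, b) {
  # convolution; products < 1e8 and short lengths keep sums well under 2^53
  n <- length(a) + length(b) - 1
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  big_carry(out)
}

big_add_small <- function(a, k) {
  a[1] <- a[1] + k
  big_carry(a)
}

big_log <- function(a) {
  # log of the represented integer; exact to double precision
  n <- length(a)
  if (n == 1) return(log(a[1]))
  # use the top few digits for the mantissa
  top <- min(n, 4)
  mant <- sum(a[(n - top + 1):n] * BIG_BASE^(0:(top - 1)))
  log(mant) + (n - top) * log(BIG_BASE)
}

big_to_string <- function(a) {
  n <- length(a)
  parts <- formatC(rev(a), width = 4, flag = "0", format = "d")
  parts[1] <- as.character(a[n])
  paste0(parts, collapse = "")
}

big_to_numeric <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))
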