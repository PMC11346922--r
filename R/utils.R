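# Internal helpers: seeded evaluation, seed fan-out, clipping, assertions.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic fan-out of one global seed into per-stage seeds. A small
# multiplicative hash keeps derived seeds inside the 32-bit signed range.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tok in c(...)) {
    for (ch in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_config <- function(...) {
  stop(structure(class = c("rascl_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_domain <- function(...) {
  stop(structure(class = c("rascl_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("rascl_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_config(name, " must be a single number in [", lower, ", ", upper, "]")
  x
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stop_config(name, " must be a numeric interval c(lower, upper) with lower <= upper")
  x
}

# Stable content hash (rolling polynomial hash mod a Mersenne prime over the
# serialized object), used for the pipeline's stage-idempotence guard and the
# frozen-encoder contract tests. All arithmetic stays below 2^53 so doubles
# are exact.
# exact (a * b) %% p for a, b < 2^31 using double arithmetic
mulmod <- function(a, b, p) {
  b1 <- b %/% 65536
  b0 <- b %% 65536
  (((a * b1) %% p) * 65536 + a * b0) %% p
}

content_hash <- function(object) {
  bytes <- as.double(serialize(object, NULL, version = 2))
  p <- 2147483647  # 2^31 - 1
  base <- 257
  chunk <- 1000L
  pow <- numeric(chunk)
  pow[chunk] <- 1
  for (k in seq(chunk - 1L, 1L)) pow[k] <- (pow[k + 1L] * base) %% p
  # base^chunk mod p
  bc <- (pow[1] * base) %% p
  h <- 0
  n <- length(bytes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    seg <- bytes[i:j]
    m <- length(seg)
    hseg <- sum((seg * pow[(chunk - m + 1L):chunk]) %% p) %% p
    # shift accumulated hash by base^m mod p
    shift <- if (m == chunk) bc else {
      s <- 1
      for (k in seq_len(m)) s <- (s * base) %% p
      s
    }
    h <- (mulmod(h, shift, p) + hseg) %% p
    i <- j + 1L
  }
  sprintf("%010.0f", h)
}
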