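# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream tag, kept < 2^31.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

l2norm <- function(x) sqrt(sum(x * x))

# Glorot-uniform weight matrix (n_out x n_in), drawn from the current RNG.
glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

is_finite_all <- function(x) all(is.finite(unlist(x, use.names = FALSE)))
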