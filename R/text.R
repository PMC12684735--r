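# Text branch: pluggable token-embedding providers, mean pooling, and
# L-layer transformer refinement of the pooled description vector.

#' Deterministic hash-based token embedder
#'
#' A context-independent stand-in for a pretrained language-model encoder:
#' each token maps to a fixed pseudo-random unit-norm vector derived from a
#' seeded hash of the token string. Identical tokens always receive
#' identical vectors; different seeds give different embeddings. Satisfies
#' the text-provider contract (`embed`, `d_t`, `deterministic`, `id`).
#'
#' @param d_t Embedding dimensionality.
#' @param seed Integer vocabulary seed.
#' @return A `text_provider` whose `embed(tokens)` returns an n x d_t
#'   matrix of unit-norm rows.
#' @export
#' @examples
#' p <- deterministic_text_embedder(d_t = 8, seed = 1)
#' e <- p$embed(c("benzene", "ring"))
#' sqrt(rowSums(e^2))  # both 1
deterministic_text_embedder <- function(d_t = 64L, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  embed_one <- function(token) {
    key <- paste0("t:", token)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- with_seed(derive_seed(seed, token), stats::rnorm(d_t))
    v <- v / l2norm(v)
    assign(key, v, envir = cache)
    v
  }
  provider <- list(
    embed = function(tokens) {
      if (length(tokens) == 0L) stopf("cannot embed an empty token sequence")
      out <- t(vapply(tokens, embed_one, numeric(d_t)))
      rownames(out) <- NULL
      out
    },
    d_t = as.integer(d_t),
    deterministic = TRUE,
    id = sprintf("hash-embedder-v1/seed=%d/d=%d", seed, d_t))
  class(provider) <- "text_provider"
  provider
}

#' @export
print.text_provider <- function(x, ...) {
  cat(sprintf("<text_provider> %s (deterministic=%s)\n", x$id, x$deterministic))
  invisible(x)
}

#' Embed tokens and mean-pool to the initial text vector
#'
#' The pooled vector z_t^(0) is the mean of all token embeddings; for a
#' context-independent provider it is invariant to token order.
#'
#' @param tokens Character vector of tokens (length >= 1).
#' @param provider A `text_provider`.
#' @return Numeric vector of length `provider$d_t`.
#' @export
embed_and_pool <- function(tokens, provider) {
  if (length(tokens) < 1L) stopf("need at least one token")
  E <- provider$embed(tokens)
  if (ncol(E) != provider$d_t)
    stopf("provider contract error: embed() returned %d dims, declared %d",
          ncol(E), provider$d_t)
  colMeans(E)
}

# Layer normalization over feature columns of a row-matrix; returns the
# normalized matrix plus the statistics needed for backprop.
layernorm_forward <- function(X, gain, bias, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(Y = sweep(xhat, 2L, gain, `*`) + rep(bias, each = nrow(X)),
       xhat = xhat, istd = istd)
}

layernorm_backward <- function(gY, cache, gain) {
  xhat <- cache$xhat; istd <- cache$istd
  d <- ncol(xhat)
  gxhat <- sweep(gY, 2L, gain, `*`)
  gg <- colSums(gY * xhat)
  gb <- colSums(gY)
  # standard layernorm input gradient
  gX <- istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
  list(gX = gX, g_gain = gg, g_bias = gb)
}

# One pre-norm transformer layer applied to pooled vectors (rows of Z).
# On a length-1 token sequence self-attention collapses to its value/output
# projections (the softmax over a single key is 1), so the attention branch
# is Wo(Wv(LN(z))).
text_layer_forward <- function(Z, lp) {
  ln1 <- layernorm_forward(Z, lp$ln1_g, lp$ln1_b)
  Xv <- ln1$Y %*% lp$Wv
  A <- Xv %*% lp$Wo
  Z1 <- Z + A
  ln2 <- layernorm_forward(Z1, lp$ln2_g, lp$ln2_b)
  F1 <- ln2$Y %*% lp$Wf1 + rep(lp$bf1, each = nrow(Z))
  R1 <- relu(F1)
  F2 <- R1 %*% lp$Wf2 + rep(lp$bf2, each = nrow(Z))
  Z2 <- Z1 + F2
  list(Z = Z2, ln1 = ln1, Xv = Xv, Z1 = Z1, ln2 = ln2, F1 = F1, R1 = R1,
       Zin = Z)
}

text_layer_backward <- function(gZ2, cache, lp) {
  g <- list()
  # FFN branch
  gF2 <- gZ2
  g$bf2 <- colSums(gF2)
  g$Wf2 <- t(cache$R1) %*% gF2
  gR1 <- gF2 %*% t(lp$Wf2)
  gF1 <- gR1 * (cache$F1 > 0)
  g$bf1 <- colSums(gF1)
  g$Wf1 <- t(cache$ln2$Y) %*% gF1
  gLN2 <- gF1 %*% t(lp$Wf1)
  ln2b <- layernorm_backward(gLN2, cache$ln2, lp$ln2_g)
  g$ln2_g <- ln2b$g_gain; g$ln2_b <- ln2b$g_bias
  gZ1 <- gZ2 + ln2b$gX
  # attention branch
  gA <- gZ1
  g$Wo <- t(cache$Xv) %*% gA
  gXv <- gA %*% t(lp$Wo)
  g$Wv <- t(cache$ln1$Y) %*% gXv
  gLN1 <- gXv %*% t(lp$Wv)
  ln1b <- layernorm_backward(gLN1, cache$ln1, lp$ln1_g)
  g$ln1_g <- ln1b$g_gain; g$ln1_b <- ln1b$g_bias
  g$gZ <- gZ1 + ln1b$gX
  g
}

#' Refine a pooled text vector through L transformer layers
#'
#' Applies L pre-norm transformer layers to the pooled description vector
#' (treated as a length-1 sequence) and collects the per-layer outputs
#' z_t^(1)..z_t^(L).
#'
#' @param z_t0 Numeric pooled vector (d_t).
#' @param layers List of L text-layer parameter sets (see
#'   [init_text_layer()]).
#' @return List of L numeric vectors, one per layer.
#' @export
refine_text <- function(z_t0, layers) {
  Z <- matrix(z_t0, nrow = 1L)
  out <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    Z <- text_layer_forward(Z, layers[[l]])$Z
    out[[l]] <- as.numeric(Z)
  }
  out
}

#' Initialize one transformer layer for the text branch
#'
#' Pre-norm self-attention (value/output projections) plus a two-layer
#' feed-forward block of width d_t. Draws weights from the current RNG;
#' `identity = TRUE` zeroes both residual branches so the layer is the
#' identity map.
#'
#' @param d_t Width of the layer.
#' @param identity Zero-initialize the residual branches.
#' @return Named list of layer parameters.
#' @export
init_text_layer <- function(d_t, identity = FALSE) {
  zero <- function(a, b) matrix(0, a, b)
  if (identity) {
    Wv <- zero(d_t, d_t); Wo <- zero(d_t, d_t)
    Wf1 <- zero(d_t, d_t); Wf2 <- zero(d_t, d_t)
  } else {
    Wv <- t(glorot(d_t, d_t)); Wo <- t(glorot(d_t, d_t))
    Wf1 <- t(glorot(d_t, d_t)); Wf2 <- t(glorot(d_t, d_t))
  }
  list(ln1_g = rep(1, d_t), ln1_b = rep(0, d_t),
       Wv = Wv, Wo = Wo,
       ln2_g = rep(1, d_t), ln2_b = rep(0, d_t),
       Wf1 = Wf1, bf1 = rep(0, d_t), Wf2 = Wf2, bf2 = rep(0, d_t))
}
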