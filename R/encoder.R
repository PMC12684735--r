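# Graph branch: GIN message passing with a per-layer readout producing the
# hierarchical representation set Z_g. The batched forward/backward used by
# the training engine lives here next to the single-graph operations.

#' Initialize atom states from raw features
#'
#' h_v^(0) = MLP(x_v); the input MLP is a single learnable linear map
#' d -> d_g (identity-initializable when d == d_g).
#'
#' @param X Atom feature matrix (n x d).
#' @param W Weight matrix (d x d_g).
#' @param b Bias vector (d_g).
#' @return n x d_g matrix of initial node states.
#' @export
init_node_embed <- function(X, W, b = rep(0, ncol(W))) {
  if (nrow(X) == 0L) stopf("empty graph: no atoms to embed")
  X %*% W + rep(b, each = nrow(X))
}

#' One GIN message-passing layer
#'
#' h_v^(l) = MLP((1 + eps) h_v^(l-1) + sum of neighbor states); isolated
#' atoms receive a zero aggregate. The layer MLP is linear-ReLU-linear.
#'
#' @param H Node-state matrix (n x d_g).
#' @param A Symmetric adjacency matrix (n x n), no self loops.
#' @param lp Layer parameters: `eps`, `W1`, `b1`, `W2`, `b2`.
#' @return Updated node-state matrix.
#' @export
message_pass_layer <- function(H, A, lp) {
  if (!all(is.finite(H))) stopf("non-finite node states")
  gin_layer_forward(H, A, lp)$H
}

gin_layer_forward <- function(H, A, lp) {
  S <- (1 + lp$eps) * H + as.matrix(A %*% H)
  F1 <- S %*% lp$W1 + rep(lp$b1, each = nrow(H))
  R1 <- relu(F1)
  Hn <- R1 %*% lp$W2 + rep(lp$b2, each = nrow(H))
  list(H = Hn, S = S, F1 = F1, R1 = R1, Hin = H)
}

gin_layer_backward <- function(gHn, cache, A, lp) {
  g <- list()
  g$b2 <- colSums(gHn)
  g$W2 <- t(cache$R1) %*% gHn
  gR1 <- gHn %*% t(lp$W2)
  gF1 <- gR1 * (cache$F1 > 0)
  g$b1 <- colSums(gF1)
  g$W1 <- t(cache$S) %*% gF1
  gS <- gF1 %*% t(lp$W1)
  g$eps <- sum(gS * cache$Hin)
  g$gH <- (1 + lp$eps) * gS + as.matrix(A %*% gS)  # A is symmetric
  g
}

#' Per-layer graph readout
#'
#' Permutation-invariant pooling of node states into one graph-level
#' vector.
#'
#' @param H Node-state matrix (n x d_g), n >= 1.
#' @param readout One of "sum", "mean", "max".
#' @return Numeric vector of length d_g.
#' @export
readout_layer <- function(H, readout = c("sum", "mean", "max")) {
  readout <- match.arg(readout)
  if (nrow(H) == 0L) stopf("readout of an empty graph")
  switch(readout,
         sum = colSums(H),
         mean = colMeans(H),
         max = apply(H, 2L, max))
}

#' Initialize a GIN layer
#'
#' @param d_g Hidden dimensionality.
#' @param identity Make the layer MLP the identity map (and eps = 0), for
#'   worked micro-examples.
#' @return Named parameter list (`eps`, `W1`, `b1`, `W2`, `b2`).
#' @export
init_gin_layer <- function(d_g, identity = FALSE) {
  if (identity) {
    list(eps = 0, W1 = diag(d_g), b1 = rep(0, d_g),
         W2 = diag(d_g), b2 = rep(0, d_g))
  } else {
    list(eps = 0, W1 = t(glorot(d_g, d_g)), b1 = rep(0, d_g),
         W2 = t(glorot(d_g, d_g)), b2 = rep(0, d_g))
  }
}

#' Encode a molecular graph into layer-wise embeddings
#'
#' Runs the input MLP (Eq. h^(0)), L GIN layers of message passing, and a
#' readout after every layer, returning the hierarchical set
#' Z_g = {z_g^(1), ..., z_g^(L)}.
#'
#' @param graph A `molecular_graph`, or a list with `features` and `bonds`.
#' @param params Graph-branch parameters: `win` (list W, b) and `gin`
#'   (list of L GIN layers).
#' @param readout Readout operator.
#' @return List of L numeric vectors (each d_g).
#' @export
encode_graph <- function(graph, params, readout = "sum") {
  A <- graph_adjacency(graph)
  H <- init_node_embed(graph$features, params$win$W, params$win$b)
  out <- vector("list", length(params$gin))
  for (l in seq_along(params$gin)) {
    H <- gin_layer_forward(H, A, params$gin[[l]])$H
    out[[l]] <- readout_layer(H, readout)
  }
  out
}
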