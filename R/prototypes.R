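# Unified prototype space: layer aggregation, modality projections, squared
# Euclidean distances, log-ratio similarity, top-K sparse distributions and
# the KL alignment loss.

#' Construct a learnable prototype space
#'
#' C*N prototypes of dimension d_p (class-major flat order: index
#' (c-1)*N + n), plus modality-specific linear projections into the space.
#' Prototypes are initialized i.i.d. normal scaled by 1/sqrt(d_p) from the
#' current RNG.
#'
#' @param C Number of classes (1 for regression).
#' @param N Prototypes per class.
#' @param d_p Prototype dimensionality.
#' @param d_g,d_t Input dimensionalities of the two modalities.
#' @param epsilon Small positive constant in the log-ratio similarity.
#' @param K Number of retained top-K entries (1 <= K <= C*N).
#' @return A `prototype_space`: list with `P` ((C*N) x d_p matrix), `Wgp`
#'   (d_p x d_g), `bgp`, `Wtp` (d_p x d_t), `btp`, and the scalars C, N,
#'   d_p, epsilon, K.
#' @export
prototype_space <- function(C, N, d_p, d_g, d_t, epsilon = 1e-6, K = min(5L, C * N)) {
  if (C < 1L || N < 1L) stopf("C and N must be >= 1")
  if (K < 1L || K > C * N) stopf("contract error: K must be in [1, C*N]")
  if (epsilon <= 0 || epsilon >= 1) stopf("epsilon must lie in (0, 1)")
  structure(list(
    P = matrix(stats::rnorm(C * N * d_p, sd = 1 / sqrt(d_p)), C * N, d_p),
    Wgp = glorot(d_p, d_g), bgp = rep(0, d_p),
    Wtp = glorot(d_p, d_t), btp = rep(0, d_p),
    C = as.integer(C), N = as.integer(N), d_p = as.integer(d_p),
    epsilon = epsilon, K = as.integer(K)), class = "prototype_space")
}

#' @export
print.prototype_space <- function(x, ...) {
  cat(sprintf("<prototype_space> C=%d, N=%d, d_p=%d, K=%d, epsilon=%g\n",
              x$C, x$N, x$d_p, x$K, x$epsilon))
  invisible(x)
}

#' Mean-pool layer-wise embeddings
#'
#' z_bar = (1/L) sum_l z_hat^(l).
#'
#' @param hat_layers Non-empty list of equal-length numeric vectors.
#' @return Numeric vector.
#' @export
aggregate_layers <- function(hat_layers) {
  if (length(hat_layers) == 0L) stopf("contract error: no layers to aggregate")
  Reduce(`+`, hat_layers) / length(hat_layers)
}

#' Project a pooled vector and compute prototype distances
#'
#' z_p = W z_bar + b, then D[(c,n)] = ||z_p - p_{c,n}||^2 over the flat
#' class-major prototype order.
#'
#' @param z_bar Pooled modality vector.
#' @param space A `prototype_space`.
#' @param modality "g" or "t" (selects the projection).
#' @return Numeric vector of C*N squared distances, with the projected
#'   vector attached as attribute `projected`.
#' @export
project_and_distance <- function(z_bar, space, modality = c("g", "t")) {
  modality <- match.arg(modality)
  W <- if (modality == "g") space$Wgp else space$Wtp
  b <- if (modality == "g") space$bgp else space$btp
  if (length(z_bar) != ncol(W))
    stopf("contract error: vector has %d dims, projection expects %d",
          length(z_bar), ncol(W))
  zp <- as.numeric(W %*% z_bar + b)
  diff <- sweep(space$P, 2L, zp)
  D <- rowSums(diff * diff)
  attr(D, "projected") <- zp
  D
}

#' Log-ratio similarity transform
#'
#' s = log((D + 1) / (D + epsilon)); strictly decreasing in D for
#' epsilon < 1, with range (0, log(1/epsilon)].
#'
#' @param D Non-negative distance vector.
#' @param epsilon Small positive constant in (0, 1).
#' @return Similarity vector of the same length.
#' @export
log_ratio_similarity <- function(D, epsilon = 1e-6) {
  if (any(D < 0)) stopf("contract error: distances must be non-negative")
  if (epsilon <= 0 || epsilon >= 1) stopf("epsilon must lie in (0, 1)")
  as.numeric(log(D + 1) - log(D + epsilon))
}

# Indices of the K largest entries, ties broken by lowest index.
topk_indices <- function(s, K) {
  order(-s, seq_along(s))[seq_len(K)]
}

#' Top-K sparse prototype distribution
#'
#' Retains the K largest similarity scores (ties broken by lowest flat
#' index), zeroes the rest, and normalizes the retained raw scores with a
#' softmax into weights alpha over the selected prototypes.
#'
#' @param s Similarity score vector.
#' @param K Number of entries to retain.
#' @return A `prototype_distribution`: list with `scores` (= s), `sparse`
#'   (s with non-top-K zeroed), `support` (sorted retained indices) and
#'   `alpha` (softmax weights on the support, summing to 1).
#' @export
topk_distribution <- function(s, K) {
  if (K < 1L || K > length(s))
    stopf("contract error: K=%d out of range for %d scores", K, length(s))
  sup <- sort(topk_indices(s, K))
  sparse <- numeric(length(s))
  sparse[sup] <- s[sup]
  structure(list(scores = s, sparse = sparse, support = sup,
                 alpha = softmax_vec(s[sup])),
            class = "prototype_distribution")
}

#' @export
print.prototype_distribution <- function(x, ...) {
  cat(sprintf("<prototype_distribution> %d scores, support {%s}\n",
              length(x$scores), paste(x$support, collapse = ", ")))
  invisible(x)
}

# Full-length floored/renormalized probability vector for a top-K
# distribution; the off-support floor keeps KL finite when supports differ.
full_distribution <- function(dist, len, eps_kl) {
  v <- rep(eps_kl, len)
  v[dist$support] <- dist$alpha
  v / sum(v)
}

#' Prototype alignment loss (KL divergence)
#'
#' KL(alpha_g || alpha_t) computed on full-length vectors: on-support mass
#' is the softmax weight, off-support mass is floored at `eps_kl`, then
#' both vectors are renormalized. Zero when the distributions coincide;
#' always non-negative.
#'
#' @param dist_g,dist_t `prototype_distribution`s from the same space.
#' @param eps_kl Probability floor for off-support entries.
#' @param support One of "full" (default) or "intersection" (restrict to
#'   the shared support, renormalized).
#' @return Non-negative scalar.
#' @export
alignment_loss <- function(dist_g, dist_t, eps_kl = 1e-8,
                           support = c("full", "intersection")) {
  support <- match.arg(support)
  if (length(dist_g$scores) != length(dist_t$scores))
    stopf("contract error: distributions come from different spaces")
  if (support == "intersection") {
    shared <- intersect(dist_g$support, dist_t$support)
    if (length(shared) == 0L) return(0)
    p <- dist_g$alpha[match(shared, dist_g$support)]
    q <- dist_t$alpha[match(shared, dist_t$support)]
    p <- p / sum(p); q <- q / sum(q)
    return(sum(p * (log(p) - log(q))))
  }
  len <- length(dist_g$scores)
  p <- full_distribution(dist_g, len, eps_kl)
  q <- full_distribution(dist_t, len, eps_kl)
  sum(p * (log(p) - log(q)))
}
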