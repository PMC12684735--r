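# Layer-wise bidirectional cross-modal attention with residual fusion.
#
# Each layer projects the graph vector into text space (and vice versa) and
# attends with the projected vector as key and value. With pooled per-layer
# vectors the key set is a singleton, so the softmax weight is exactly 1 and
# the attention returns the projected cross-modal vector; the residual then
# gives z_hat = z + W z_other. A token-level mode with non-degenerate
# attention over sets is available via `cross_attend` on matrices.

#' Scaled dot-product cross-attention
#'
#' softmax(query kv^T / sqrt(scale_dim)) kv. `kv` may be a single vector
#' (the default singleton mode, where the softmax weight is exactly 1 and
#' the output equals `kv`) or a matrix of key/value rows (token-level
#' mode).
#'
#' @param query Numeric vector.
#' @param kv Numeric vector, or matrix with keys/values in rows.
#' @param scale_dim Scaling dimensionality under the square root.
#' @return Numeric vector of length `ncol(kv)`.
#' @export
cross_attend <- function(query, kv, scale_dim = length(query)) {
  if (!all(is.finite(query)) || !all(is.finite(kv)))
    stopf("non-finite attention inputs")
  if (is.null(dim(kv))) kv <- matrix(kv, nrow = 1L)
  if (length(query) != ncol(kv))
    stopf("query and key/value dimensionality differ (%d vs %d)",
          length(query), ncol(kv))
  logits <- as.numeric(kv %*% query) / sqrt(scale_dim)
  as.numeric(softmax_vec(logits) %*% kv)
}

#' Initialize fusion projection weights
#'
#' One pair of projection matrices per layer: W_gt (d_t x d_g) mapping graph
#' vectors into text space and W_tg (d_g x d_t) mapping text vectors into
#' graph space. Variance-scaled uniform init, no bias.
#'
#' @param L Number of layers.
#' @param d_g,d_t Branch dimensionalities.
#' @return List of L lists with `Wgt`, `Wtg`.
#' @export
init_fusion_weights <- function(L, d_g, d_t) {
  lapply(seq_len(L), function(l)
    list(Wgt = glorot(d_t, d_g), Wtg = glorot(d_g, d_t)))
}

#' Bidirectional layer-wise fusion
#'
#' For every layer l: project each modality into the other's space, attend
#' (singleton key set, so attention passes the projection through), and add
#' the residual: z_hat_t = z_t + W_gt z_g, z_hat_g = z_g + W_tg z_t.
#' Intermediates are retained for inspection.
#'
#' @param Z_g,Z_t Lists of L layer vectors for the graph and text branches.
#' @param weights Fusion weights from [init_fusion_weights()].
#' @return List with `hat_z_g`, `hat_z_t` (lists of L vectors) and the
#'   intermediates `z_g2t`, `z_t2g`, `tilde_z_g`, `tilde_z_t`.
#' @export
bidirectional_fuse <- function(Z_g, Z_t, weights) {
  L <- length(weights)
  if (length(Z_g) != L || length(Z_t) != L)
    stopf("contract error: need %d layers in both branches (got %d graph, %d text)",
          L, length(Z_g), length(Z_t))
  d_g <- length(Z_g[[1]])
  out <- list(hat_z_g = vector("list", L), hat_z_t = vector("list", L),
              z_g2t = vector("list", L), z_t2g = vector("list", L),
              tilde_z_g = vector("list", L), tilde_z_t = vector("list", L))
  for (l in seq_len(L)) {
    w <- weights[[l]]
    z_g2t <- as.numeric(w$Wgt %*% Z_g[[l]])
    z_t2g <- as.numeric(w$Wtg %*% Z_t[[l]])
    tilde_t <- cross_attend(Z_t[[l]], z_g2t, scale_dim = d_g)
    tilde_g <- cross_attend(Z_g[[l]], z_t2g, scale_dim = d_g)
    out$z_g2t[[l]] <- z_g2t; out$z_t2g[[l]] <- z_t2g
    out$tilde_z_t[[l]] <- tilde_t; out$tilde_z_g[[l]] <- tilde_g
    out$hat_z_t[[l]] <- Z_t[[l]] + tilde_t
    out$hat_z_g[[l]] <- Z_g[[l]] + tilde_g
  }
  out
}
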