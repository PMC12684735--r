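# Prediction heads and the three training losses with the weighted total
# objective.

#' Aggregate layer-specific head outputs into the final prediction
#'
#' o^(i) = Linear_i(z_hat_g^(i)); the final prediction is the mean of the L
#' layer outputs. Classification heads emit C logits, regression heads a
#' scalar.
#'
#' @param hat_Z_g List of L fused graph vectors.
#' @param heads List of L head parameter lists (`W`: n_out x d_g, `b`).
#' @return Numeric vector (length C) or scalar.
#' @export
predict_heads <- function(hat_Z_g, heads) {
  L <- length(heads)
  if (length(hat_Z_g) != L)
    stopf("contract error: %d fused layers but %d heads", length(hat_Z_g), L)
  o <- lapply(seq_len(L), function(i)
    as.numeric(heads[[i]]$W %*% hat_Z_g[[i]] + heads[[i]]$b))
  Reduce(`+`, o) / L
}

#' Task-specific predictive loss
#'
#' Classification: cross-entropy -log softmax(o)_y with y in 1..C.
#' Regression: squared error (y_hat - y)^2. Multi-task binary labels
#' (vector y with NA for missing): mean per-task binary cross-entropy over
#' the observed labels only.
#'
#' @param o Logit vector (C), scalar prediction, or n_tasks logits.
#' @param y Label: class index, numeric target, or 0/1 vector with NA mask.
#' @param task_kind "classification", "regression" or "multitask".
#' @return Non-negative scalar.
#' @export
predictive_loss <- function(o, y, task_kind = c("classification", "regression",
                                                "multitask")) {
  task_kind <- match.arg(task_kind)
  switch(task_kind,
    classification = {
      if (is.na(y)) stopf("contract error: unobserved single-task label")
      y <- as.integer(y)
      if (y < 1L || y > length(o)) stopf("label %d outside 1..%d", y, length(o))
      lse <- max(o) + log(sum(exp(o - max(o))))
      lse - o[y]
    },
    regression = {
      if (!is.finite(y)) stopf("contract error: non-finite regression label")
      (o - y)^2
    },
    multitask = {
      obs <- which(!is.na(y))
      if (length(obs) == 0L) stopf("contract error: no observed task labels")
      # numerically stable BCE with logits
      z <- o[obs]; t <- y[obs]
      mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    })
}

cosine_sim_matrix <- function(P) {
  nrm <- sqrt(rowSums(P * P))
  if (any(nrm == 0)) stopf("zero-norm prototype; cosine similarity undefined")
  Pn <- P / nrm
  Pn %*% t(Pn)
}

# Shared InfoNCE-style machinery: anchors indexed by rows of sim matrix M,
# `groups` assigning each prototype to a class/cluster. The denominator is
# the unrestricted double sum (it includes the anchor's self term).
proto_contrastive_from_groups <- function(P, groups, tau) {
  M <- cosine_sim_matrix(P)
  E <- exp(M / tau)
  total <- nrow(P)
  losses <- rep(NA_real_, total)
  for (a in seq_len(total)) {
    pos <- which(groups == groups[a])
    pos <- pos[pos != a]
    if (length(pos) == 0L) next  # skipped anchors handled by callers
    num <- mean(E[a, pos])
    den <- sum(E[a, ])
    losses[a] <- -log(num / den)
  }
  losses
}

#' Prototype contrastive loss (classification)
#'
#' Every prototype is an anchor in turn; same-class prototypes are
#' positives, all other classes negatives. Cosine similarity with
#' temperature tau; mean over all C*N anchors. The denominator includes the
#' anchor's self-similarity term.
#'
#' @param space A `prototype_space` (C >= 2, N >= 2), or a matrix of
#'   prototypes with `C`/`N` supplied.
#' @param tau Temperature (> 0).
#' @param C,N Overrides when `space` is a plain matrix.
#' @return Non-negative-ish scalar (mean InfoNCE value).
#' @export
proto_contrastive_cls <- function(space, tau = 0.5, C = space$C, N = space$N) {
  P <- if (is.matrix(space)) space else space$P
  if (tau <= 0) stopf("temperature must be positive")
  if (C < 2L) stopf("contract error: classification contrast needs C >= 2")
  if (N < 2L) stopf("contract error: need N >= 2 (no positives otherwise)")
  groups <- rep(seq_len(C), each = N)
  mean(proto_contrastive_from_groups(P, groups, tau))
}

#' Partition prototypes into two pseudo-classes by 2-means
#'
#' Lloyd's algorithm with 10 restarts under a fixed seed; both clusters are
#' guaranteed non-empty. Used by the regression contrastive loss, where the
#' clusters stand in for low/high ranges of the target property.
#'
#' @param space A `prototype_space` or a prototype matrix.
#' @param seed Integer seed for the restarts.
#' @return List of two integer index vectors.
#' @export
kmeans_partition <- function(space, seed = 1L) {
  P <- if (is.matrix(space)) space else space$P
  if (nrow(P) < 2L) stopf("need at least 2 prototypes to partition")
  if (max(stats::dist(P)) == 0)
    stopf("degenerate clustering: all prototypes identical")
  km <- with_seed(seed,
    stats::kmeans(P, centers = 2L, nstart = 10L, iter.max = 100L,
                  algorithm = "Lloyd"))
  # order clusters by first-occurrence for determinism across label swaps
  first <- c(min(which(km$cluster == 1L)), min(which(km$cluster == 2L)))
  ord <- order(first)
  list(which(km$cluster == ord[1]), which(km$cluster == ord[2]))
}

#' Prototype contrastive loss (regression)
#'
#' With C = 1 the class structure is replaced by the 2-means pseudo-classes
#' from [kmeans_partition()]: same-cluster prototypes are positives, the
#' other cluster negatives. Anchors in singleton clusters are skipped with
#' a warning; mean over the contributing prototypes.
#'
#' @param space A `prototype_space` or prototype matrix.
#' @param tau Temperature (> 0).
#' @param partition Optional precomputed partition (list of 2 index sets).
#' @param seed Seed for the default partition.
#' @return Scalar loss.
#' @export
proto_contrastive_reg <- function(space, tau = 0.5, partition = NULL,
                                  seed = 1L) {
  P <- if (is.matrix(space)) space else space$P
  if (tau <= 0) stopf("temperature must be positive")
  if (is.null(partition)) partition <- kmeans_partition(space, seed = seed)
  groups <- integer(nrow(P))
  groups[partition[[1]]] <- 1L
  groups[partition[[2]]] <- 2L
  sizes <- lengths(partition)
  if (all(sizes < 2L))
    stopf("contract error: both clusters are singletons; no positives exist")
  losses <- proto_contrastive_from_groups(P, groups, tau)
  if (anyNA(losses))
    warning(sprintf("%d anchor(s) in singleton clusters skipped", sum(is.na(losses))))
  mean(losses, na.rm = TRUE)
}

#' Weighted total objective
#'
#' L_total = lambda_align L_align + lambda_pred L_pred +
#' lambda_proto L_proto.
#'
#' @param components Named list or vector with `align`, `pred`, `proto`.
#' @param weights Named list/vector of non-negative lambdas (same names).
#' @return A `loss_breakdown`: list with the three components, the weights
#'   and `total`.
#' @export
total_loss <- function(components, weights = c(align = 0.9, pred = 0.9,
                                               proto = 0.9)) {
  comp <- unlist(components)[c("align", "pred", "proto")]
  w <- unlist(weights)[c("align", "pred", "proto")]
  if (any(is.na(comp))) stopf("loss components must be named align/pred/proto")
  if (any(w < 0)) stopf("config error: negative loss weight")
  if (!all(is.finite(comp))) stopf("non-finite loss component")
  structure(list(align = comp[["align"]], pred = comp[["pred"]],
                 proto = comp[["proto"]], weights = w,
                 total = sum(w * comp)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.6f (align %.6f, pred %.6f, proto %.6f)\n",
              x$total, x$align, x$pred, x$proto))
  invisible(x)
}
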