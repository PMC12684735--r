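# Evaluation metrics: ROC-AUC (midrank), RMSE, Davies-Bouldin index, and
# the model-level evaluation report.

#' ROC-AUC by the midrank (Mann-Whitney) statistic
#'
#' Probability that a randomly chosen positive is scored above a randomly
#' chosen negative, with ties receiving half credit.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) ground truth.
#' @return AUC in [0, 1]; `NA` with a message when only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    message("ROC-AUC undefined: evaluation set contains a single class")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root mean squared error
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse_metric <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  sqrt(mean((pred - truth)^2))
}

#' Davies-Bouldin index
#'
#' Cluster-separability score on embedding rows grouped by label: for each
#' cluster the within-cluster scatter is the mean Euclidean distance to the
#' centroid; the index averages, over clusters, the worst ratio
#' (s_i + s_j) / d(c_i, c_j). Lower is better.
#'
#' @param X Embedding matrix (rows = samples).
#' @param labels Cluster/class label per row (>= 2 distinct).
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  labs <- unique(labels)
  k <- length(labs)
  if (k < 2L) stopf("Davies-Bouldin needs >= 2 clusters")
  cent <- t(vapply(labs, function(l) colMeans(X[labels == l, , drop = FALSE]),
                   numeric(ncol(X))))
  scat <- vapply(seq_len(k), function(i) {
    rowsq <- sweep(X[labels == labs[i], , drop = FALSE], 2L, cent[i, ])
    mean(sqrt(rowSums(rowsq^2)))
  }, 0)
  db_i <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scat[i] + scat[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, 0))
  }, 0)
  mean(db_i)
}

#' Evaluate a fitted model on a dataset
#'
#' Computes the task metric (per-task ROC-AUC with a macro average, or
#' RMSE), plus the Davies-Bouldin index of the aggregated fused graph
#' embeddings grouped by label (classification only).
#'
#' @param model A fitted `molproto`.
#' @param dataset A `molecule_dataset`.
#' @param idx Optional index subset (e.g. a test split).
#' @return List of class `molproto_metrics`: `roc_auc` (per task),
#'   `macro_auc`, `rmse`, `davies_bouldin`, `n`.
#' @export
evaluate_model <- function(model, dataset, idx = NULL) {
  records <- dataset$records
  if (!is.null(idx)) records <- records[idx]
  sub <- molecule_dataset(records, dataset$task_kind)
  out <- list(n = length(records), task = model$task,
              roc_auc = NULL, macro_auc = NA_real_, rmse = NA_real_,
              davies_bouldin = NA_real_)
  if (model$task == "regression") {
    y <- vapply(records, function(r) r$labels[1], 0)
    out$rmse <- rmse_metric(predict(model, sub), y)
  } else if (model$task == "classification") {
    y <- vapply(records, function(r) r$labels[1], 0)
    score <- predict(model, sub, type = "score")
    out$roc_auc <- roc_auc(score, as.integer(y == max(model$classes)))
    out$macro_auc <- out$roc_auc
    emb <- predict(model, sub, type = "embedding")
    if (length(unique(y)) >= 2L)
      out$davies_bouldin <- davies_bouldin(emb, y)
  } else {
    Y <- do.call(rbind, lapply(records, `[[`, "labels"))
    S <- predict(model, sub, type = "score")
    out$roc_auc <- vapply(seq_len(ncol(Y)), function(tk) {
      obs <- !is.na(Y[, tk])
      if (length(unique(Y[obs, tk])) < 2L) return(NA_real_)
      suppressMessages(roc_auc(S[obs, tk], Y[obs, tk]))
    }, 0)
    out$macro_auc <- mean(out$roc_auc, na.rm = TRUE)
  }
  structure(out, class = "molproto_metrics")
}

#' @export
print.molproto_metrics <- function(x, ...) {
  cat(sprintf("<molproto_metrics> n=%d, task=%s\n", x$n, x$task))
  if (!is.na(x$macro_auc))
    cat(sprintf("  ROC-AUC (macro): %.4f\n", x$macro_auc))
  if (!is.na(x$rmse)) cat(sprintf("  RMSE: %.4f\n", x$rmse))
  if (!is.na(x$davies_bouldin))
    cat(sprintf("  Davies-Bouldin: %.4f\n", x$davies_bouldin))
  invisible(x)
}
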