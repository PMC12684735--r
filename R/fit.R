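# Model fitting and S3 methods.

#' Fit a prototype-guided multimodal molecular property model
#'
#' Trains the full model — GIN graph encoder with per-layer readout,
#' transformer-refined text branch, layer-wise bidirectional cross-modal
#' fusion, unified prototype space — by minimizing the weighted sum of the
#' KL prototype-alignment loss, the task-specific predictive loss and the
#' prototype contrastive loss, with Adam under a cosine-annealed learning
#' rate. Deterministic under a fixed seed.
#'
#' @param dataset A `molecule_dataset` (see [read_molecule_csv()],
#'   [generate_molecules()]).
#' @param config A [molproto_config()].
#' @param seed Integer seed driving initialization and batch shuffling.
#' @param provider Text-embedding provider; defaults to the deterministic
#'   hash embedder at the configured `d_t`.
#' @param split Optional [stratified_split()]; when given, training uses
#'   `split$train` and the epoch with the best validation metric (ROC-AUC
#'   for classification, RMSE for regression) supplies the returned
#'   parameters.
#' @param verbose Print per-epoch losses.
#' @return An object of class `molproto` with components `params`,
#'   `config`, `task`, `classes`, `history` (per-epoch loss components and
#'   validation metric), `best_epoch`, `provider`, `seed`.
#' @export
molproto <- function(dataset, config = molproto_config(), seed = 1L,
                     provider = NULL, split = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "molecule_dataset"))
  records <- dataset$records
  if (length(records) == 0L) stopf("empty dataset")

  task <- dataset$task_kind
  classes <- NULL
  if (task == "classification" && dataset$n_tasks > 1L) task <- "multitask"
  if (task == "classification") {
    raw <- vapply(records, function(r) r$labels[1], 0)
    classes <- sort(unique(raw))
    if (length(classes) < 2L) stopf("classification needs >= 2 classes")
    y_idx <- match(raw, classes)
    config$C <- length(classes)
    config$n_out <- length(classes)
  } else if (task == "multitask") {
    config$C <- 2L
    config$n_out <- dataset$n_tasks
  } else {
    config$C <- 1L   # continuous output space
    config$n_out <- 1L
  }
  config$task <- task
  if (config$K > config$C * config$N)
    stopf("config error: K=%d exceeds C*N=%d", config$K, config$C * config$N)

  if (is.null(provider))
    provider <- deterministic_text_embedder(config$d_t,
                                            seed = derive_seed(seed, "vocab"))
  if (provider$d_t != config$d_t)
    stopf("provider dimensionality %d != configured d_t %d",
          provider$d_t, config$d_t)

  # pooled initial text vector per record, computed once
  Z0_all <- t(vapply(records, function(r) embed_and_pool(r$tokens, provider),
                     numeric(config$d_t)))

  train_idx <- if (is.null(split)) seq_along(records) else split$train
  val_idx <- if (is.null(split)) integer(0) else split$validation
  if (length(train_idx) == 0L) stopf("empty train split")

  get_y <- function(idx) {
    if (task == "classification") y_idx[idx]
    else if (task == "regression") vapply(records[idx], function(r) r$labels[1], 0)
    else do.call(rbind, lapply(records[idx], `[[`, "labels"))
  }

  d_in <- ncol(records[[1]]$graph$features)
  params <- model_init_params(config, d_in, derive_seed(seed, "init"))
  flat <- flatten_params(params)
  opt <- adam_init(length(flat))

  history <- data.frame(epoch = integer(0), align = numeric(0),
                        pred = numeric(0), proto = numeric(0),
                        total = numeric(0), val_metric = numeric(0))
  best <- list(metric = NA_real_, params = params, epoch = NA_integer_)

  n_train <- length(train_idx)
  for (epoch in seq_len(config$epochs)) {
    lr_t <- if (config$schedule == "cosine")
      cosine_lr(config$lr, epoch, config$epochs) else config$lr

    # k-means pseudo-classes refreshed once per epoch (regression only)
    partition <- NULL
    if (task == "regression") {
      P_now <- if (config$proto_mode == "unified") params$proto$P
               else params$proto$Pg
      partition <- kmeans_partition(P_now, seed = derive_seed(seed, "kmeans"))
    }

    perm <- with_seed(derive_seed(seed, paste0("epoch", epoch)),
                      sample(train_idx))
    starts <- seq(1L, n_train, by = config$batch_size)
    ep_loss <- c(align = 0, pred = 0, proto = 0, total = 0)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n_train)]
      batch <- build_batch(records, idx, Z0_all, task, config$n_out)
      batch$y <- get_y(idx)
      fwd <- model_forward(params, batch, config, partition = partition)
      if (!is.finite(fwd$losses$total))
        stopf("training diverged (non-finite loss) at epoch %d, batch %d",
              epoch, which(starts == s))
      grads <- model_backward(params, fwd, batch, config)
      gflat <- flatten_params(conform_grads(grads, params))
      step <- adam_step(flat, gflat, opt, lr_t, config$weight_decay)
      flat <- step$theta
      opt <- step$state
      params <- unflatten_params(flat, params)
      w <- length(idx) / n_train
      ep_loss <- ep_loss + w * unlist(fwd$losses)[c("align", "pred",
                                                    "proto", "total")]
    }

    val_metric <- NA_real_
    if (length(val_idx) > 0L) {
      scores <- predict_internal(params, config, records, val_idx, Z0_all)
      y_val <- get_y(val_idx)
      val_metric <- if (task == "regression") {
        rmse_metric(scores$O[, 1], y_val)
      } else if (task == "classification") {
        roc_auc(scores$prob[, 2], as.integer(y_val == 2L))
      } else {
        mean(vapply(seq_len(ncol(y_val)), function(tk) {
          obs <- !is.na(y_val[, tk])
          if (length(unique(y_val[obs, tk])) < 2L) return(NA_real_)
          roc_auc(scores$prob[obs, tk], y_val[obs, tk])
        }, 0), na.rm = TRUE)
      }
      better <- if (task == "regression") {
        is.na(best$metric) || (!is.na(val_metric) && val_metric < best$metric)
      } else {
        is.na(best$metric) || (!is.na(val_metric) && val_metric > best$metric)
      }
      if (better) best <- list(metric = val_metric, params = params,
                               epoch = epoch)
    }

    history <- rbind(history, data.frame(
      epoch = epoch, align = ep_loss[["align"]], pred = ep_loss[["pred"]],
      proto = ep_loss[["proto"]], total = ep_loss[["total"]],
      val_metric = val_metric))
    if (verbose)
      cat(sprintf("epoch %3d  total %.5f  (align %.5f pred %.5f proto %.5f)%s\n",
                  epoch, ep_loss[["total"]], ep_loss[["align"]],
                  ep_loss[["pred"]], ep_loss[["proto"]],
                  if (is.na(val_metric)) "" else sprintf("  val %.4f", val_metric)))
  }

  use_best <- length(val_idx) > 0L && !is.na(best$metric)
  structure(list(
    params = if (use_best) best$params else params,
    final_params = params,
    config = config, task = task, classes = classes,
    n_tasks = dataset$n_tasks, d_in = d_in,
    history = history,
    best_epoch = if (use_best) best$epoch else config$epochs,
    provider = provider, seed = seed, split = split,
    call = match.call()), class = "molproto")
}

# Forward pass over records for prediction; no caches kept.
predict_internal <- function(params, config, records, idx, Z0_all,
                             chunk = 512L) {
  O <- NULL; Zbar <- NULL
  for (s in seq(1L, length(idx), by = chunk)) {
    sub <- idx[s:min(s + chunk - 1L, length(idx))]
    batch <- build_batch(records, sub, Z0_all, config$task, config$n_out)
    fwd <- model_forward(params, batch, config, need_cache = FALSE,
                         compute_loss = FALSE)
    O <- rbind(O, fwd$O)
    Zbar <- rbind(Zbar, fwd$Zbar_g)
  }
  prob <- switch(config$task,
    classification = row_softmax(O),
    multitask = 1 / (1 + exp(-O)),
    regression = NULL)
  list(O = O, prob = prob, Zbar_g = Zbar)
}

#' Predict from a fitted model
#'
#' @param object A fitted `molproto` model.
#' @param newdata A `molecule_dataset` (defaults were fit-time records are
#'   not stored; newdata is required).
#' @param type "response" (class labels / numeric predictions), "prob"
#'   (class or per-task probabilities), "score" (positive-class score used
#'   for ROC), or "embedding" (aggregated fused graph vectors z_bar_g).
#' @param ... Unused.
#' @return Vector, matrix or embedding matrix according to `type`.
#' @export
predict.molproto <- function(object, newdata,
                             type = c("response", "prob", "score",
                                      "embedding"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "molecule_dataset"))
  records <- newdata$records
  Z0_all <- t(vapply(records,
                     function(r) embed_and_pool(r$tokens, object$provider),
                     numeric(object$config$d_t)))
  res <- predict_internal(object$params, object$config, records,
                          seq_along(records), Z0_all)
  if (type == "embedding") return(res$Zbar_g)
  switch(object$task,
    regression = res$O[, 1],
    classification = switch(type,
      response = object$classes[max.col(res$prob)],
      prob = {
        colnames(res$prob) <- as.character(object$classes)
        res$prob
      },
      score = res$prob[, ncol(res$prob)]),
    multitask = switch(type,
      response = (res$prob > 0.5) * 1,
      prob = res$prob,
      score = res$prob))
}

#' @export
print.molproto <- function(x, ...) {
  cat(sprintf("Prototype-guided multimodal molecular property model (%s)\n",
              x$task))
  cat(sprintf("  layers L=%d, dims g/t/p = %d/%d/%d, prototypes C=%d x N=%d (K=%d)\n",
              x$config$L, x$config$d_g, x$config$d_t, x$config$d_p,
              x$config$C, x$config$N, x$config$K))
  cat(sprintf("  trained %d epochs (best epoch %d), final total loss %.5f\n",
              nrow(x$history), x$best_epoch,
              x$history$total[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.molproto <- function(object, ...) {
  h <- object$history
  cat("Loss trajectory (first/last epochs):\n")
  print(utils::head(h, 3L), row.names = FALSE)
  print(utils::tail(h, 3L), row.names = FALSE)
  np <- length(flatten_params(object$params))
  cat(sprintf("\nParameters: %d | task: %s | fusion: %s | prototype space: %s\n",
              np, object$task, object$config$fusion, object$config$proto_mode))
  if (!is.null(object$classes))
    cat("Classes:", paste(object$classes, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.molproto <- function(object, ...) object$params

#' @export
plot.molproto <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total, h$align, h$pred, h$proto),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "steelblue", "firebrick", "darkgreen"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "align", "pred", "proto"),
                   col = c("black", "steelblue", "firebrick", "darkgreen"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' @export
residuals.molproto <- function(object, newdata, ...) {
  if (object$task != "regression")
    stopf("residuals are defined for regression models")
  y <- vapply(newdata$records, function(r) r$labels[1], 0)
  y - predict(object, newdata)
}
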