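# Batched forward/backward engine for the full multimodal model.
#
# All gradients are analytic and hand-derived; finite-difference agreement
# on a micro configuration is part of the test suite. Parameters live in a
# nested named list so they can be flattened to a single numeric vector for
# the Adam update and for gradient checking.

model_init_params <- function(config, d_in, seed) {
  L <- config$L
  with_seed(seed, {
    p <- list(
      win = list(W = t(glorot(config$d_g, d_in)), b = rep(0, config$d_g)),
      gin = lapply(seq_len(L), function(l) init_gin_layer(config$d_g)),
      txt = lapply(seq_len(L), function(l) init_text_layer(config$d_t)),
      fus = init_fusion_weights(L, config$d_g, config$d_t),
      heads = lapply(seq_len(L), function(l)
        list(W = glorot(config$n_out, config$d_g), b = rep(0, config$n_out))))
    if (config$proto_mode == "unified") {
      p$proto <- list(
        P = matrix(stats::rnorm(config$C * config$N * config$d_p,
                                sd = 1 / sqrt(config$d_p)),
                   config$C * config$N, config$d_p),
        Wgp = 0.02 * glorot(config$d_p, config$d_g), bgp = rep(0, config$d_p),
        Wtp = 0.02 * glorot(config$d_p, config$d_t), btp = rep(0, config$d_p))
    } else {
      p$proto <- list(
        Pg = matrix(stats::rnorm(config$C * config$N * config$d_p,
                                 sd = 1 / sqrt(config$d_p)),
                    config$C * config$N, config$d_p),
        Pt = matrix(stats::rnorm(config$C * config$N * config$d_p,
                                 sd = 1 / sqrt(config$d_p)),
                    config$C * config$N, config$d_p),
        Wgp = 0.02 * glorot(config$d_p, config$d_g), bgp = rep(0, config$d_p),
        Wtp = 0.02 * glorot(config$d_p, config$d_t), btp = rep(0, config$d_p))
    }
    p
  })
}

# Assemble a mini-batch: block-diagonal adjacency over the selected
# records, stacked atom features, graph ids, precomputed pooled text
# vectors and labels.
build_batch <- function(records, idx, Z0_all, task, n_out) {
  graphs <- lapply(records[idx], `[[`, "graph")
  sizes <- vapply(graphs, function(g) nrow(g$atoms), 0L)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "features"))
  gid <- rep(seq_along(idx), sizes)
  bi <- unlist(lapply(seq_along(graphs), function(k) {
    b <- graphs[[k]]$bonds
    c(b$i, b$j) + offsets[k]
  }))
  bj <- unlist(lapply(seq_along(graphs), function(k) {
    b <- graphs[[k]]$bonds
    c(b$j, b$i) + offsets[k]
  }))
  n <- sum(sizes)
  A <- Matrix::sparseMatrix(i = bi, j = bj, x = rep(1, length(bi)),
                            dims = c(n, n))
  labs <- lapply(records[idx], `[[`, "labels")
  y <- if (any(vapply(labs, is.null, TRUE))) NULL else switch(task,
    classification = vapply(labs, function(x) as.numeric(x[1]), 0),
    regression = vapply(labs, function(x) as.numeric(x[1]), 0),
    multitask = do.call(rbind, labs))
  list(X = X, A = A, gid = gid, B = length(idx),
       Z0 = Z0_all[idx, , drop = FALSE], y = y, n_nodes = n)
}

# Per-row top-K machinery used by the forward pass.
batch_topk <- function(s, K) {
  B <- nrow(s)
  support <- matrix(0L, B, K)
  alpha <- matrix(0, B, K)
  for (b in seq_len(B)) {
    sup <- sort(topk_indices(s[b, ], K))
    support[b, ] <- sup
    alpha[b, ] <- softmax_vec(s[b, sup])
  }
  list(support = support, alpha = alpha)
}

model_forward <- function(params, batch, config, partition = NULL,
                          need_cache = TRUE, compute_loss = TRUE) {
  L <- config$L
  cache <- list()

  # ---- graph branch ----
  H <- init_node_embed(batch$X, params$win$W, params$win$b)
  cache$H0 <- H
  cache$gin <- vector("list", L)
  Zg <- vector("list", L)
  for (l in seq_len(L)) {
    fw <- gin_layer_forward(H, batch$A, params$gin[[l]])
    cache$gin[[l]] <- fw
    H <- fw$H
    Zg_l <- if (config$readout == "mean")
      rowsum(H, batch$gid) / as.numeric(table(batch$gid))
    else rowsum(H, batch$gid)
    rownames(Zg_l) <- NULL
    Zg[[l]] <- Zg_l
  }

  # ---- text branch ----
  Zt <- vector("list", L)
  cache$txt <- vector("list", L)
  Z <- batch$Z0
  for (l in seq_len(L)) {
    fw <- text_layer_forward(Z, params$txt[[l]])
    cache$txt[[l]] <- fw
    Z <- fw$Z
    Zt[[l]] <- Z
  }

  # ---- layer-wise bidirectional fusion (singleton attention) ----
  fused_at <- if (config$fusion == "final") L else seq_len(L)
  hatZg <- vector("list", L); hatZt <- vector("list", L)
  for (l in seq_len(L)) {
    if (l %in% fused_at) {
      hatZt[[l]] <- Zt[[l]] + Zg[[l]] %*% t(params$fus[[l]]$Wgt)
      hatZg[[l]] <- Zg[[l]] + Zt[[l]] %*% t(params$fus[[l]]$Wtg)
    } else {
      hatZt[[l]] <- Zt[[l]]
      hatZg[[l]] <- Zg[[l]]
    }
  }

  Zbar_g <- Reduce(`+`, hatZg) / L
  Zbar_t <- Reduce(`+`, hatZt) / L

  # ---- prediction heads ----
  O <- matrix(0, batch$B, config$n_out)
  for (l in seq_len(L))
    O <- O + (hatZg[[l]] %*% t(params$heads[[l]]$W) +
              rep(params$heads[[l]]$b, each = batch$B)) / L
  if (!compute_loss)
    return(list(losses = NULL, O = O, Zbar_g = Zbar_g, Zbar_t = Zbar_t))

  # ---- prototype space ----
  pr <- params$proto
  Pg_mat <- if (config$proto_mode == "unified") pr$P else pr$Pg
  Pt_mat <- if (config$proto_mode == "unified") pr$P else pr$Pt
  Zp_g <- Zbar_g %*% t(pr$Wgp) + rep(pr$bgp, each = batch$B)
  Zp_t <- Zbar_t %*% t(pr$Wtp) + rep(pr$btp, each = batch$B)
  sqdist <- function(Zp, P)
    pmax(outer(rowSums(Zp * Zp), rep(1, nrow(P))) +
         outer(rep(1, nrow(Zp)), rowSums(P * P)) - 2 * Zp %*% t(P), 0)
  D_g <- sqdist(Zp_g, Pg_mat)
  D_t <- sqdist(Zp_t, Pt_mat)
  eps <- config$epsilon
  s_g <- log(D_g + 1) - log(D_g + eps)
  s_t <- log(D_t + 1) - log(D_t + eps)
  tk_g <- batch_topk(s_g, config$K)
  tk_t <- batch_topk(s_t, config$K)

  # KL alignment on floored/renormalized full-length vectors
  CN <- ncol(s_g)
  Tnorm <- 1 + (CN - config$K) * config$eps_kl
  kl <- numeric(batch$B)
  for (b in seq_len(batch$B)) {
    p <- rep(config$eps_kl, CN); p[tk_g$support[b, ]] <- tk_g$alpha[b, ]
    q <- rep(config$eps_kl, CN); q[tk_t$support[b, ]] <- tk_t$alpha[b, ]
    p <- p / Tnorm; q <- q / Tnorm
    kl[b] <- sum(p * (log(p) - log(q)))
  }
  L_align <- mean(kl)

  # ---- task-specific predictive loss ----
  L_pred <- switch(config$task,
    classification = {
      mx <- apply(O, 1L, max)
      lse <- mx + log(rowSums(exp(O - mx)))
      mean(lse - O[cbind(seq_len(batch$B), as.integer(batch$y))])
    },
    regression = mean((O[, 1] - batch$y)^2),
    multitask = {
      obs <- !is.na(batch$y)
      z <- O; t <- batch$y
      bce <- pmax(z, 0) - z * ifelse(obs, t, 0) + log1p(exp(-abs(z)))
      mean(rowSums(bce * obs) / pmax(rowSums(obs), 1))
    })

  # ---- prototype contrastive loss (batch-independent) ----
  proto_groups <- function() {
    if (config$task == "regression") {
      part <- partition
      if (is.null(part)) part <- kmeans_partition(Pg_mat, seed = 1L)
      g <- integer(nrow(Pg_mat)); g[part[[1]]] <- 1L; g[part[[2]]] <- 2L
      g
    } else {
      rep(seq_len(config$C), each = config$N)
    }
  }
  groups_g <- proto_groups()
  if (config$proto_mode == "unified") {
    pc <- proto_contrastive_grad(Pg_mat, groups_g, config$tau)
    L_proto <- pc$loss
    cache$pc <- list(g = pc)
  } else {
    groups_t <- if (config$task == "regression") {
      part <- if (is.null(partition)) kmeans_partition(Pt_mat, seed = 1L)
              else partition
      g <- integer(nrow(Pt_mat)); g[part[[1]]] <- 1L; g[part[[2]]] <- 2L
      g
    } else groups_g
    pc_g <- proto_contrastive_grad(Pg_mat, groups_g, config$tau)
    pc_t <- proto_contrastive_grad(Pt_mat, groups_t, config$tau)
    L_proto <- (pc_g$loss + pc_t$loss) / 2
    cache$pc <- list(g = pc_g, t = pc_t)
  }

  losses <- list(align = L_align, pred = L_pred, proto = L_proto,
                 total = config$lambda_align * L_align +
                         config$lambda_pred * L_pred +
                         config$lambda_proto * L_proto)
  out <- list(losses = losses, O = O, Zbar_g = Zbar_g, Zbar_t = Zbar_t)
  if (need_cache) {
    out$cache <- c(cache, list(
      Zg = Zg, Zt = Zt, hatZg = hatZg, hatZt = hatZt, fused_at = fused_at,
      Zp_g = Zp_g, Zp_t = Zp_t, D_g = D_g, D_t = D_t, s_g = s_g, s_t = s_t,
      tk_g = tk_g, tk_t = tk_t, Tnorm = Tnorm, Pg_mat = Pg_mat,
      Pt_mat = Pt_mat))
  }
  out
}

# InfoNCE prototype contrastive loss with analytic gradient w.r.t. P.
proto_contrastive_grad <- function(P, groups, tau) {
  nrm <- sqrt(rowSums(P * P))
  Pn <- P / nrm
  M <- Pn %*% t(Pn)
  E <- exp(M / tau)
  nP <- nrow(P)
  gM <- matrix(0, nP, nP)
  losses <- rep(NA_real_, nP)
  for (a in seq_len(nP)) {
    pos <- which(groups == groups[a]); pos <- pos[pos != a]
    if (length(pos) == 0L) next
    soft_all <- E[a, ] / sum(E[a, ])
    soft_pos <- numeric(nP)
    soft_pos[pos] <- E[a, pos] / sum(E[a, pos])
    losses[a] <- -log(mean(E[a, pos]) / sum(E[a, ]))
    gM[a, ] <- (soft_all - soft_pos) / tau
  }
  n_eff <- sum(!is.na(losses))
  gM <- gM / n_eff
  gPn <- (gM + t(gM)) %*% Pn
  radial <- rowSums(gPn * Pn)
  gP <- (gPn - radial * Pn) / nrm
  list(loss = mean(losses, na.rm = TRUE), gP = gP)
}

model_backward <- function(params, fwd, batch, config) {
  cache <- fwd$cache
  L <- config$L
  B <- batch$B
  g <- list()

  # ---- prediction gradient (w.r.t. logits O), weighted by lambda_pred ----
  O <- fwd$O
  gO <- switch(config$task,
    classification = {
      Pr <- row_softmax(O)
      Pr[cbind(seq_len(B), as.integer(batch$y))] <-
        Pr[cbind(seq_len(B), as.integer(batch$y))] - 1
      Pr / B
    },
    regression = matrix(2 * (O[, 1] - batch$y) / B, ncol = 1L),
    multitask = {
      obs <- !is.na(batch$y)
      sig <- 1 / (1 + exp(-O))
      ((sig - ifelse(obs, batch$y, 0)) * obs) /
        (pmax(rowSums(obs), 1) * B)
    })
  gO <- gO * config$lambda_pred

  # ---- alignment gradient (w.r.t. similarity scores), x lambda_align ----
  CN <- ncol(cache$s_g)
  K <- config$K
  Tn <- cache$Tnorm
  gs_g <- matrix(0, B, CN)
  gs_t <- matrix(0, B, CN)
  if (config$lambda_align > 0) {
    for (b in seq_len(B)) {
      sup_g <- cache$tk_g$support[b, ]; a_g <- cache$tk_g$alpha[b, ]
      sup_t <- cache$tk_t$support[b, ]; a_t <- cache$tk_t$alpha[b, ]
      p <- rep(config$eps_kl, CN); p[sup_g] <- a_g; p <- p / Tn
      q <- rep(config$eps_kl, CN); q[sup_t] <- a_t; q <- q / Tn
      # d KL / d alpha_g on the graph support
      ga <- (log(p[sup_g]) - log(q[sup_g]) + 1) / Tn
      gs_sup <- a_g * (ga - sum(a_g * ga))
      gs_g[b, sup_g] <- gs_sup
      # d KL / d alpha_t on the text support
      gq <- -(p[sup_t] / q[sup_t]) / Tn
      gs_sup_t <- a_t * (gq - sum(a_t * gq))
      gs_t[b, sup_t] <- gs_sup_t
    }
    scale <- config$lambda_align / B
    gs_g <- gs_g * scale
    gs_t <- gs_t * scale
  }

  # similarity -> distance
  eps <- config$epsilon
  gD_g <- gs_g * (1 / (cache$D_g + 1) - 1 / (cache$D_g + eps))
  gD_t <- gs_t * (1 / (cache$D_t + 1) - 1 / (cache$D_t + eps))

  # distance -> projected vectors and prototypes
  pr <- params$proto
  gZp_g <- 2 * (rowSums(gD_g) * cache$Zp_g - gD_g %*% cache$Pg_mat)
  gZp_t <- 2 * (rowSums(gD_t) * cache$Zp_t - gD_t %*% cache$Pt_mat)
  gP_g <- -2 * (t(gD_g) %*% cache$Zp_g - colSums(gD_g) * cache$Pg_mat)
  gP_t <- -2 * (t(gD_t) %*% cache$Zp_t - colSums(gD_t) * cache$Pt_mat)

  # prototype contrastive gradient, x lambda_proto
  if (config$proto_mode == "unified") {
    gP <- gP_g + gP_t + config$lambda_proto * cache$pc$g$gP
    g$proto <- list(P = gP)
  } else {
    g$proto <- list(Pg = gP_g + (config$lambda_proto / 2) * cache$pc$g$gP,
                    Pt = gP_t + (config$lambda_proto / 2) * cache$pc$t$gP)
  }

  # projections
  g$proto$Wgp <- t(gZp_g) %*% fwd$Zbar_g
  g$proto$bgp <- colSums(gZp_g)
  g$proto$Wtp <- t(gZp_t) %*% fwd$Zbar_t
  g$proto$btp <- colSums(gZp_t)
  gZbar_g <- gZp_g %*% pr$Wgp
  gZbar_t <- gZp_t %*% pr$Wtp

  # ---- heads and aggregation back to fused layers ----
  gHatZg <- vector("list", L); gHatZt <- vector("list", L)
  g$heads <- vector("list", L)
  for (l in seq_len(L)) {
    go_l <- gO / L
    g$heads[[l]] <- list(W = t(go_l) %*% cache$hatZg[[l]],
                         b = colSums(go_l))
    gHatZg[[l]] <- go_l %*% params$heads[[l]]$W + gZbar_g / L
    gHatZt[[l]] <- gZbar_t / L
  }

  # ---- fusion backward ----
  gZg <- vector("list", L); gZt <- vector("list", L)
  g$fus <- vector("list", L)
  for (l in seq_len(L)) {
    w <- params$fus[[l]]
    if (l %in% cache$fused_at) {
      g$fus[[l]] <- list(Wgt = t(gHatZt[[l]]) %*% cache$Zg[[l]],
                         Wtg = t(gHatZg[[l]]) %*% cache$Zt[[l]])
      gZg[[l]] <- gHatZg[[l]] + gHatZt[[l]] %*% w$Wgt
      gZt[[l]] <- gHatZt[[l]] + gHatZg[[l]] %*% w$Wtg
    } else {
      g$fus[[l]] <- list(Wgt = matrix(0, nrow(w$Wgt), ncol(w$Wgt)),
                         Wtg = matrix(0, nrow(w$Wtg), ncol(w$Wtg)))
      gZg[[l]] <- gHatZg[[l]]
      gZt[[l]] <- gHatZt[[l]]
    }
  }

  # ---- text branch backward ----
  g$txt <- vector("list", L)
  gZ <- matrix(0, B, config$d_t)
  for (l in rev(seq_len(L))) {
    gZ_total <- gZ + gZt[[l]]
    tb <- text_layer_backward(gZ_total, cache$txt[[l]], params$txt[[l]])
    gZ <- tb$gZ
    tb$gZ <- NULL
    g$txt[[l]] <- tb
  }

  # ---- graph branch backward ----
  g$gin <- vector("list", L)
  counts <- as.numeric(table(batch$gid))
  gH <- matrix(0, nrow(batch$X), config$d_g)
  for (l in rev(seq_len(L))) {
    gZg_l <- gZg[[l]]
    if (config$readout == "mean") gZg_l <- gZg_l / counts
    gH <- gH + gZg_l[batch$gid, , drop = FALSE]
    gb <- gin_layer_backward(gH, cache$gin[[l]], batch$A, params$gin[[l]])
    gH <- gb$gH
    gb$gH <- NULL
    g$gin[[l]] <- gb
  }
  g$win <- list(W = t(batch$X) %*% gH, b = colSums(gH))

  # reorder to the params skeleton
  g[names(params)]
}

# ---- parameter flattening for Adam and gradient checks ----

# Reorder a nested gradient list to the exact structure of the parameter
# skeleton, so both flatten to aligned vectors.
conform_grads <- function(g, sk) {
  if (!is.list(sk)) return(g)
  nm <- names(sk)
  if (is.null(nm)) {
    out <- mapply(conform_grads, g, sk, SIMPLIFY = FALSE)
  } else {
    out <- lapply(nm, function(n) conform_grads(g[[n]], sk[[n]]))
    names(out) <- nm
  }
  out
}

flatten_params <- function(x) unlist(x, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(sk) {
    if (is.list(sk)) return(lapply(sk, walk))
    n <- length(sk)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(sk)
    out
  }
  out <- walk(skeleton)
  stopifnot(pos == length(flat))
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) grad <- grad + weight_decay * theta
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

cosine_lr <- function(lr0, epoch, n_epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(n_epochs, 1)))
}
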