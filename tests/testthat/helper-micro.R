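# Shared fixtures: micro model configurations and batches built in code.

ns <- asNamespace("molproto")

# A two-molecule micro batch with custom d-dimensional atom features.
micro_batch <- function(d = 8L, seed = 42L, task = "classification",
                        n_out = 2L) {
  set.seed(seed)
  g1 <- parse_smiles("CCO")
  g2 <- parse_smiles("C1CCCC1")
  g1$features <- matrix(rnorm(3 * d), 3, d)
  g2$features <- matrix(rnorm(5 * d), 5, d)
  recs <- list(list(graph = g1), list(graph = g2))
  Z0 <- matrix(rnorm(2 * d), 2, d)
  batch <- ns$build_batch(recs, 1:2, Z0, task, n_out)
  batch$y <- switch(task, classification = c(1, 2), regression = c(0.5, 2.1))
  batch
}

micro_config <- function(d = 8L, L = 2L, N = 2L, K = 2L, ...) {
  cfg <- molproto_config(L = L, d_g = d, d_t = d, d_p = d, N = N, K = K, ...)
  cfg$C <- 2L
  cfg$n_out <- 2L
  cfg$task <- "classification"
  cfg
}

# Straight-line re-implementation of the bidirectional fusion equations
# (projection, singleton softmax attention, residual), written as naive
# per-layer loops independent of the package internals.
oracle_fuse <- function(Z_g, Z_t, weights, d_g) {
  L <- length(weights)
  hat_g <- vector("list", L); hat_t <- vector("list", L)
  for (l in seq_len(L)) {
    z_g2t <- as.numeric(weights[[l]]$Wgt %*% Z_g[[l]])
    z_t2g <- as.numeric(weights[[l]]$Wtg %*% Z_t[[l]])
    # one key: softmax over a single logit is exactly 1
    logit_t <- sum(Z_t[[l]] * z_g2t) / sqrt(d_g)
    tilde_t <- (exp(logit_t) / exp(logit_t)) * z_g2t
    logit_g <- sum(Z_g[[l]] * z_t2g) / sqrt(d_g)
    tilde_g <- (exp(logit_g) / exp(logit_g)) * z_t2g
    hat_t[[l]] <- Z_t[[l]] + tilde_t
    hat_g[[l]] <- Z_g[[l]] + tilde_g
  }
  list(hat_z_g = hat_g, hat_z_t = hat_t)
}

# Straight-line prototype pipeline: mean-pool layers, affine projection,
# squared distances, log-ratio scores, top-K softmax, floored KL.
oracle_prototype_pipeline <- function(hat_g, hat_t, space, eps_kl = 1e-8) {
  pool <- function(zs) {
    acc <- rep(0, length(zs[[1]]))
    for (z in zs) acc <- acc + z
    acc / length(zs)
  }
  zg <- pool(hat_g); zt <- pool(hat_t)
  zpg <- as.numeric(space$Wgp %*% zg + space$bgp)
  zpt <- as.numeric(space$Wtp %*% zt + space$btp)
  CN <- nrow(space$P)
  Dg <- numeric(CN); Dt <- numeric(CN)
  for (j in seq_len(CN)) {
    Dg[j] <- sum((zpg - space$P[j, ])^2)
    Dt[j] <- sum((zpt - space$P[j, ])^2)
  }
  sg <- log((Dg + 1) / (Dg + space$epsilon))
  st <- log((Dt + 1) / (Dt + space$epsilon))
  topk <- function(s, K) {
    ord <- order(s, decreasing = TRUE)
    # resolve ties toward the lowest index
    ord <- ord[order(-s[ord], ord)]
    sup <- sort(ord[1:K])
    a <- exp(s[sup] - max(s[sup])); a <- a / sum(a)
    list(sup = sup, alpha = a)
  }
  tg <- topk(sg, space$K); tt <- topk(st, space$K)
  p <- rep(eps_kl, CN); p[tg$sup] <- tg$alpha
  q <- rep(eps_kl, CN); q[tt$sup] <- tt$alpha
  p <- p / sum(p); q <- q / sum(q)
  list(D_g = Dg, D_t = Dt, s_g = sg, s_t = st,
       sup_g = tg$sup, alpha_g = tg$alpha,
       sup_t = tt$sup, alpha_t = tt$alpha,
       kl = sum(p * (log(p) - log(q))))
}

# Brute-force InfoNCE prototype contrastive loss: double loop over
# anchors and the full similarity sums, nothing shared with the package.
oracle_proto_contrastive <- function(P, groups, tau) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  vals <- c()
  for (a in seq_len(nrow(P))) {
    pos <- setdiff(which(groups == groups[a]), a)
    if (length(pos) == 0) next
    num <- 0
    for (p in pos) num <- num + exp(cosine(P[a, ], P[p, ]) / tau)
    num <- num / length(pos)
    den <- 0
    for (j in seq_len(nrow(P))) den <- den + exp(cosine(P[a, ], P[j, ]) / tau)
    vals <- c(vals, -log(num / den))
  }
  mean(vals)
}

# Exhaustive minimum within-cluster-SSE 2-partition (for k-means checks).
oracle_best_2partition <- function(P) {
  n <- nrow(P)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(mask))[1:n]
    if (sum(grp) == 0 || sum(grp) == n) next
    sse <- 0
    for (g in 0:1) {
      rows <- P[grp == g, , drop = FALSE]
      ctr <- colMeans(rows)
      sse <- sse + sum(sweep(rows, 2, ctr)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- grp }
  }
  list(sets = list(which(best == 0), which(best == 1)), sse = best_sse)
}
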