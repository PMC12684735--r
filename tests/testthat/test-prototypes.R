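make_space <- function(C = 2L, N = 2L, d_p = 3L, d_g = 3L, d_t = 3L,
                       K = 2L, epsilon = 1e-6, seed = 1L) {
  ns$with_seed(seed, prototype_space(C, N, d_p, d_g, d_t,
                                     epsilon = epsilon, K = K))
}

test_that("layer aggregation is the arithmetic mean", {
  expect_equal(aggregate_layers(list(c(1, 1), c(3, 3))), c(2, 2))
  expect_equal(aggregate_layers(list(c(7, -1))), c(7, -1))
  expect_equal(aggregate_layers(list(c(0, 0), c(0, 0))), c(0, 0))
  expect_error(aggregate_layers(list()), "contract error")
})

test_that("projection and squared distances follow the flat class-major order", {
  sp <- make_space()
  sp$Wgp <- diag(3); sp$bgp <- rep(0, 3)
  sp$P <- rbind(c(3, 4, 0), c(0, 1, 0), c(0, 0, 0), c(1, 1, 1))
  D <- project_and_distance(c(0, 0, 0), sp, "g")
  expect_equal(as.numeric(D)[1:2], c(25, 1))   # hand Euclidean arithmetic
  expect_equal(as.numeric(D)[3], 0)            # self-distance
  expect_true(all(D >= 0))
  expect_equal(attr(D, "projected"), c(0, 0, 0))
  expect_error(project_and_distance(c(1, 2), sp, "g"), "contract error")
})

test_that("log-ratio similarity matches its closed form and limits", {
  expect_equal(log_ratio_similarity(0, 1e-6), log(1e6))
  expect_equal(log_ratio_similarity(1, 1e-6), log(2 / 1.000001))
  expect_lt(abs(log_ratio_similarity(1e9, 1e-6)), 1e-8)
  expect_error(log_ratio_similarity(-1, 1e-6), "contract error")
  # strictly decreasing in D, range (0, log(1/eps)]
  D_grid <- c(0, 10^seq(-4, 4, length.out = 40))
  s <- log_ratio_similarity(D_grid, 1e-3)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= log(1 / 1e-3) + 1e-12))
})

test_that("top-K retains the largest scores with deterministic tie-breaks", {
  d <- topk_distribution(c(3, 1, 2, 5, 4), K = 2)
  expect_equal(d$support, c(4L, 5L))
  expect_equal(d$alpha, c(exp(5), exp(4)) / (exp(5) + exp(4)),
               tolerance = 1e-9)
  expect_equal(round(d$alpha, 4), c(0.7311, 0.2689))
  expect_equal(sum(d$sparse != 0), 2L)

  # ties resolve toward the lowest flat index
  tie <- topk_distribution(c(2, 7, 7, 7), K = 2)
  expect_equal(tie$support, c(2L, 3L))

  uni <- topk_distribution(rep(1.5, 4), K = 4)
  expect_equal(uni$alpha, rep(0.25, 4))
  expect_equal(topk_distribution(c(1, 9), K = 1)$alpha, 1.0)
  expect_error(topk_distribution(1:3, K = 0), "contract error")
})

test_that("KL alignment matches hand computations and the Gibbs inequality", {
  mk <- function(scores, K) topk_distribution(scores, K)
  # identical distributions
  a <- mk(c(5, 4, 0, 0), 2)
  expect_equal(alignment_loss(a, a), 0, tolerance = 1e-9)

  # shared support, alpha_g = (0.75, 0.25), alpha_t = (0.5, 0.5):
  # 0.75 log 1.5 + 0.25 log 0.5 (the off-support floor perturbs at ~1e-8)
  g <- mk(c(log(3), 0, -10, -10), 2)       # softmax -> (0.75, 0.25)
  t <- mk(c(1, 1, -10, -10), 2)            # softmax -> (0.5, 0.5)
  expect_equal(alignment_loss(g, t),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-6)
  expect_equal(round(alignment_loss(g, t), 4), 0.1308)

  # non-negativity on random pairs, including mismatched supports
  set.seed(21)
  for (i in 1:100) {
    dg <- mk(rnorm(8), 3)
    dt <- mk(rnorm(8), 3)
    expect_gte(alignment_loss(dg, dt), 0)
  }
  expect_error(alignment_loss(mk(rnorm(4), 2), mk(rnorm(6), 2)),
               "contract error")
})

test_that("prototype distribution invariants: alpha sums to 1, exactly K nonzeros", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:12, 1); K <- sample(seq_len(n), 1)
    d <- topk_distribution(rnorm(n), K)
    expect_equal(sum(d$alpha), 1, tolerance = 1e-9)
    expect_equal(sum(d$sparse != 0), K)
    expect_true(all(d$alpha > 0))
  }
})

test_that("full prototype pipeline matches the straight-line oracle", {
  set.seed(41)
  for (rep in 1:50) {
    C <- sample(1:3, 1); N <- sample(2:4, 1)
    d_p <- sample(2:5, 1); d_g <- sample(2:5, 1); d_t <- sample(2:5, 1)
    K <- sample(seq_len(C * N), 1)
    L <- sample(1:3, 1)
    sp <- prototype_space(C, N, d_p, d_g, d_t, K = K)
    hat_g <- lapply(1:L, function(l) rnorm(d_g))
    hat_t <- lapply(1:L, function(l) rnorm(d_t))

    want <- oracle_prototype_pipeline(hat_g, hat_t, sp)

    zg <- aggregate_layers(hat_g); zt <- aggregate_layers(hat_t)
    Dg <- project_and_distance(zg, sp, "g")
    Dt <- project_and_distance(zt, sp, "t")
    sg <- log_ratio_similarity(Dg, sp$epsilon)
    st <- log_ratio_similarity(Dt, sp$epsilon)
    tg <- topk_distribution(sg, K)
    tt <- topk_distribution(st, K)

    expect_equal(as.numeric(Dg), want$D_g, tolerance = 1e-6)
    expect_equal(as.numeric(Dt), want$D_t, tolerance = 1e-6)
    expect_equal(sg, want$s_g, tolerance = 1e-6)
    expect_equal(tg$support, want$sup_g)
    expect_equal(tg$alpha, want$alpha_g, tolerance = 1e-6)
    expect_equal(tt$support, want$sup_t)
    expect_equal(alignment_loss(tg, tt), want$kl, tolerance = 1e-6)
  }
})

test_that("alignment-loss gradients pass a finite-difference check", {
  # gradient through projection, distances, scores, top-K softmax and KL
  set.seed(51)
  cfg <- micro_config(d = 3L, L = 1L, N = 2L, K = 2L)
  cfg$C <- 2L
  cfg$lambda_pred <- 0; cfg$lambda_proto <- 0; cfg$lambda_align <- 1
  batch <- micro_batch(d = 3L)
  params <- ns$model_init_params(cfg, 3L, seed = 3)
  fwd <- ns$model_forward(params, batch, cfg)
  grads <- ns$model_backward(params, fwd, batch, cfg)
  gP <- grads$proto$P
  gW <- grads$proto$Wgp
  f <- function(p2) ns$model_forward(p2, batch, cfg,
                                     need_cache = FALSE)$losses$align
  h <- 1e-6
  for (k in sample(length(params$proto$P), 5)) {
    pp <- params; pp$proto$P[k] <- pp$proto$P[k] + h
    pm <- params; pm$proto$P[k] <- pm$proto$P[k] - h
    num <- (f(pp) - f(pm)) / (2 * h)
    expect_lt(abs(num - gP[k]) / max(abs(num), abs(gP[k]), 1e-6), 1e-4)
  }
  for (k in sample(length(params$proto$Wgp), 5)) {
    pp <- params; pp$proto$Wgp[k] <- pp$proto$Wgp[k] + h
    pm <- params; pm$proto$Wgp[k] <- pm$proto$Wgp[k] - h
    num <- (f(pp) - f(pm)) / (2 * h)
    expect_lt(abs(num - gW[k]) / max(abs(num), abs(gW[k]), 1e-6), 1e-4)
  }
})
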