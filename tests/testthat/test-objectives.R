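test_that("prediction heads average layer-specific linear outputs", {
  heads <- list(list(W = diag(2), b = c(0, 0)),
                list(W = diag(2), b = c(0, 0)))
  expect_equal(predict_heads(list(c(1, 3), c(3, 5)), heads), c(2, 4))
  zero_heads <- list(list(W = matrix(0, 2, 2), b = c(0, 0)))
  expect_equal(predict_heads(list(c(5, 7)), zero_heads), c(0, 0))
  one <- list(list(W = matrix(c(1, 0, 0, 1), 2, 2), b = c(0.5, -0.5)))
  expect_equal(predict_heads(list(c(2, 2)), one), c(2.5, 1.5))
  expect_error(predict_heads(list(c(1, 2)), heads), "contract error")
})

test_that("predictive losses match their closed forms", {
  expect_equal(predictive_loss(c(0, 0), 1, "classification"), log(2))
  expect_equal(predictive_loss(c(0, 0), 2, "classification"), log(2))
  expect_equal(predictive_loss(1.5, 1.5, "regression"), 0)
  expect_equal(predictive_loss(2.5, 1.5, "regression"), 1.0)
  expect_error(predictive_loss(c(0, 0), NA, "classification"),
               "contract error")
  # multi-task: mean BCE over observed labels only
  o <- c(0, 100, -100)
  y <- c(1, NA, 0)
  expect_equal(predictive_loss(o, y, "multitask"),
               mean(c(log(2), 0)), tolerance = 1e-8)
  expect_error(predictive_loss(o, c(NA, NA, NA), "multitask"),
               "contract error")
})

test_that("classification contrastive loss matches the symmetric-config value", {
  # two classes, two prototypes each; within-class cosine 1, across 0
  P <- rbind(c(1, 0), c(2, 0), c(0, 1), c(0, 3))
  val <- proto_contrastive_cls(P, tau = 1, C = 2L, N = 2L)
  want <- -log(exp(1) / (2 * exp(1) + 2))   # denominator e + e + 1 + 1
  expect_equal(val, want, tolerance = 1e-9)
  expect_equal(round(val, 4), 1.0064)

  # invariant to permuting prototypes within a class
  expect_equal(proto_contrastive_cls(P[c(2, 1, 4, 3), ], tau = 1,
                                     C = 2L, N = 2L), val)
  expect_error(proto_contrastive_cls(P, tau = 1, C = 4L, N = 1L),
               "contract error")
})

test_that("contrastive losses match a brute-force double-loop oracle", {
  set.seed(61)
  P <- matrix(rnorm(12 * 4), 12, 4)          # C = 3, N = 4
  got <- proto_contrastive_cls(P, tau = 0.5, C = 3L, N = 4L)
  want <- oracle_proto_contrastive(P, rep(1:3, each = 4), tau = 0.5)
  expect_equal(got, want, tolerance = 1e-6)

  # regression with a fixed 2-cluster partition, N = 6
  P6 <- matrix(rnorm(6 * 3), 6, 3)
  part <- list(1:3, 4:6)
  got_r <- proto_contrastive_reg(P6, tau = 0.7, partition = part)
  want_r <- oracle_proto_contrastive(P6, rep(1:2, each = 3), tau = 0.7)
  expect_equal(got_r, want_r, tolerance = 1e-6)

  # lower-bound agreement over many random configurations
  for (i in 1:50) {
    Pr <- matrix(rnorm(8 * 3), 8, 3)
    got_i <- proto_contrastive_cls(Pr, tau = 0.5, C = 2L, N = 4L)
    want_i <- oracle_proto_contrastive(Pr, rep(1:2, each = 4), tau = 0.5)
    expect_gte(got_i, want_i - 1e-6)
    expect_gte(got_i, 0)
  }
})

test_that("regression contrastive mirrors the classification algebra", {
  # the symmetric two-cluster configuration reproduces the same value
  P <- rbind(c(1, 0), c(2, 0), c(0, 1), c(0, 3))
  val <- proto_contrastive_reg(P, tau = 1, partition = list(1:2, 3:4))
  expect_equal(round(val, 4), 1.0064)
  # cosine similarity makes the loss scale invariant
  expect_equal(proto_contrastive_reg(5 * P, tau = 1,
                                     partition = list(1:2, 3:4)), val)
  expect_error(proto_contrastive_reg(rbind(c(1, 0), c(0, 1)), tau = 1,
                                     partition = list(1L, 2L)),
               "contract error")
})

test_that("2-means partition agrees with exhaustive minimum-SSE search", {
  P <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  got <- kmeans_partition(P, seed = 1)
  expect_setequal(got[[1]], 1:2)
  expect_setequal(got[[2]], 3:4)
  want <- oracle_best_2partition(P)
  expect_true(setequal(got[[1]], want$sets[[1]]) ||
              setequal(got[[1]], want$sets[[2]]))

  # duplicated far-apart pairs: the split is seed-independent
  P2 <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  for (s in 1:5) {
    part <- kmeans_partition(P2, seed = s)
    expect_true(setequal(part[[1]], 1:2) || setequal(part[[1]], 3:4))
  }
  # two prototypes: one per cluster
  expect_equal(lengths(kmeans_partition(rbind(c(0, 0), c(1, 1)))), c(1L, 1L))
  expect_error(kmeans_partition(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("total loss is the stated weighted combination", {
  lb <- total_loss(list(align = 0.1308, pred = 0.6931, proto = 1.0064),
                   c(align = 0.9, pred = 0.9, proto = 0.9))
  expect_equal(lb$total, 0.9 * (0.1308 + 0.6931 + 1.0064), tolerance = 1e-9)
  expect_equal(round(lb$total, 4), 1.6473)
  expect_equal(total_loss(list(align = 3, pred = 2, proto = 7),
                          c(align = 0, pred = 1, proto = 0))$total, 2)
  expect_equal(total_loss(list(align = 0, pred = 0, proto = 0))$total, 0)
  expect_error(total_loss(list(align = 1, pred = 1, proto = 1),
                          c(align = -1, pred = 1, proto = 1)),
               "config error")
})
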