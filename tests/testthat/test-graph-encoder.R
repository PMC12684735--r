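test_that("node embedding initialization follows the input MLP contract", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(init_node_embed(X, diag(2)), X)             # identity map
  expect_equal(nrow(init_node_embed(X, matrix(0, 2, 3))), 2L)
  expect_equal(init_node_embed(X, matrix(0, 2, 2)),
               matrix(0, 2, 2))                            # zero weights
  expect_error(init_node_embed(X[0, , drop = FALSE], diag(2)), "empty graph")
})

test_that("GIN layer matches the (1+eps)h + neighbor-sum recurrence", {
  # path graph a-b with scalar states [1], [2]; identity MLP, eps = 0
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  lp <- init_gin_layer(1L, identity = TRUE)
  H <- matrix(c(1, 2), 2, 1)
  expect_equal(message_pass_layer(H, A, lp), matrix(c(3, 3), 2, 1))

  # isolated node receives a zero aggregate
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  expect_equal(message_pass_layer(matrix(5, 1, 1), A0, lp), matrix(5, 1, 1))

  expect_error(message_pass_layer(matrix(NaN, 1, 1), A0, lp), "non-finite")
})

test_that("readout operators are permutation invariant", {
  H <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(readout_layer(H, "sum"), c(4, 6))
  expect_equal(readout_layer(H, "mean"), c(2, 3))
  expect_equal(readout_layer(H[2:1, ], "sum"), readout_layer(H, "sum"))
  expect_equal(readout_layer(H[2:1, ], "max"), readout_layer(H, "max"))
})

test_that("encode_graph composes embedding, message passing and readout", {
  set.seed(1)
  g <- parse_smiles("C1CCCC1CC")
  d <- ncol(g$features)
  params <- list(win = list(W = ns$with_seed(1, ns$glorot(16, d)) |> t(),
                            b = rep(0, 16)),
                 gin = lapply(1:3, function(l)
                   ns$with_seed(l, init_gin_layer(16))))
  Z <- encode_graph(g, params)
  expect_length(Z, 3L)
  expect_true(all(vapply(Z, length, 0L) == 16L))

  # L=1, identity everything, sum readout on the worked path-graph example
  gp <- parse_smiles("CC")
  gp$features <- matrix(c(1, 2), 2, 1)
  params1 <- list(win = list(W = diag(1), b = 0),
                  gin = list(init_gin_layer(1L, identity = TRUE)))
  expect_equal(encode_graph(gp, params1)[[1]], 6)
})

test_that("layer-wise graph embeddings are invariant to atom relabeling", {
  set.seed(11)
  g <- parse_smiles("CC(C)C1CCC(N)C1")
  d <- ncol(g$features)
  params <- list(win = list(W = t(ns$glorot(8, d)), b = rnorm(8)),
                 gin = lapply(1:3, function(l) init_gin_layer(8)))
  Z_ref <- encode_graph(g, params)
  n <- nrow(g$atoms)
  for (rep in 1:20) {
    perm <- sample(n)
    gp <- g
    gp$features <- g$features[perm, , drop = FALSE]
    inv <- order(perm)   # new index of old atom i is inv[i]
    gp$bonds$i <- inv[g$bonds$i]
    gp$bonds$j <- inv[g$bonds$j]
    Z_perm <- encode_graph(gp, params)
    for (l in 1:3) expect_equal(Z_perm[[l]], Z_ref[[l]], tolerance = 1e-10)
  }
})

test_that("isomorphic graphs (relabeled ring) encode identically", {
  set.seed(2)
  benzene_a <- parse_smiles("c1ccccc1")
  benzene_b <- parse_smiles("c1ccccc1")  # same ring, rotate the labels
  benzene_b$bonds$i <- c(2L, 3L, 4L, 5L, 1L, 6L)[benzene_a$bonds$i]
  benzene_b$bonds$j <- c(2L, 3L, 4L, 5L, 1L, 6L)[benzene_a$bonds$j]
  d <- ncol(benzene_a$features)
  params <- list(win = list(W = t(ns$glorot(8, d)), b = rep(0, 8)),
                 gin = lapply(1:2, function(l) init_gin_layer(8)))
  Za <- encode_graph(benzene_a, params)
  Zb <- encode_graph(benzene_b, params)
  expect_equal(Za, Zb, tolerance = 1e-12)
})

test_that("readout gradients w.r.t. MLP weights pass a finite-difference check", {
  set.seed(5)
  g <- parse_smiles("CC(C)C")  # 4-atom graph
  g$features <- matrix(rnorm(4 * 3), 4, 3)
  A <- ns$graph_adjacency(g)
  W0 <- t(ns$glorot(4, 3))
  lp <- init_gin_layer(4L)
  # scalar objective: sum of the layer-1 readout vector
  fobj <- function(W) {
    H <- init_node_embed(g$features, W)
    sum(readout_layer(ns$gin_layer_forward(H, A, lp)$H, "sum"))
  }
  # analytic gradient via the engine backward
  H0 <- init_node_embed(g$features, W0)
  fw <- ns$gin_layer_forward(H0, A, lp)
  gHn <- matrix(1, 4, 4)  # d(sum readout)/dH is all-ones
  gb <- ns$gin_layer_backward(gHn, fw, A, lp)
  gW0 <- t(g$features) %*% gb$gH
  h <- 1e-6
  for (k in sample(length(W0), 6)) {
    Wp <- W0; Wp[k] <- Wp[k] + h
    Wm <- W0; Wm[k] <- Wm[k] - h
    num <- (fobj(Wp) - fobj(Wm)) / (2 * h)
    expect_lt(abs(num - gW0[k]) / max(abs(num), abs(gW0[k]), 1e-8), 1e-4)
  }
})
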