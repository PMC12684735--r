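test_that("parse_smiles builds correct heavy-atom graphs", {
  g <- parse_smiles("CCO")
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(g$atoms$element, c("C", "C", "O"))
  expect_equal(g$atoms$degree, c(1L, 2L, 1L))

  benzene <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benzene$atoms), 6L)
  expect_equal(nrow(benzene$bonds), 6L)
  expect_true(all(benzene$atoms$aromatic))
  expect_true(all(benzene$bonds$order == "aromatic"))

  # branches, double bonds, bracket charge
  g2 <- parse_smiles("CC(=O)[O-]")
  expect_equal(nrow(g2$atoms), 4L)
  expect_equal(g2$atoms$charge, c(0L, 0L, 0L, -1L))
  expect_equal(sum(g2$bonds$order == "double"), 1L)
})

test_that("malformed SMILES produce positional parse errors", {
  expect_error(parse_smiles("C("), "unclosed branch")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CC)"), "position 3")
  expect_error(parse_smiles("C[X!]O"), "position 2")
  expect_error(parse_smiles("CC.O"), "not supported")
  expect_error(parse_smiles(""), "empty")
})

test_that("graph invariants hold: symmetric adjacency, no duplicate bonds", {
  for (sm in c("C1CCCC1", "CC(C)(C)C", "c1ccc2ccccc2c1", "C1CC1C2CC2")) {
    g <- parse_smiles(sm)
    expect_true(all(g$bonds$i < g$bonds$j))
    expect_false(anyDuplicated(paste(g$bonds$i, g$bonds$j)) > 0)
    expect_true(all(c(g$bonds$i, g$bonds$j) <= nrow(g$atoms)))
    A <- as.matrix(ns$graph_adjacency(g))
    expect_identical(A, t(A))
    expect_equal(nrow(g$features), nrow(g$atoms))
  }
})

test_that("atom features one-hot blocks are well formed", {
  g <- parse_smiles("CC(=O)[O-]c1ccccc1Cl")
  X <- g$features
  expect_equal(ncol(X), 113L)
  expect_true(all(rowSums(X[, 1:100]) == 1))     # element block
  expect_true(all(rowSums(X[, 101:107]) == 1))   # degree block
  expect_true(all(rowSums(X[, 108:112]) == 1))   # charge block
  expect_equal(X[, 113], as.numeric(g$atoms$aromatic))
})

test_that("heavy-atom counts agree with an independent SMILES parser", {
  skip_if_not_installed("ChemmineR")
  suppressMessages(requireNamespace("ChemmineR"))
  fixtures <- c(
    "C", "CC", "CCO", "CC(C)C", "c1ccccc1", "c1ccccc1O", "CC(=O)O",
    "C1CCCCC1", "C1CCCC1", "CC(N)C(=O)O", "CCN(CC)CC", "c1ccncc1",
    "CC(C)(C)c1ccccc1", "OCC(O)C(O)C(O)C(O)CO", "CC(=O)Nc1ccccc1",
    "ClCCl", "BrCCBr", "CCS", "CSC", "NC(=O)N", "OC(=O)c1ccccc1",
    "C1CC2CCC1CC2", "CC1(C)CCCCC1", "N#CC", "C=CC=C", "CC#CC",
    "c1ccc2ccccc2c1", "Cc1ccccc1C", "OCCN", "C1COCCN1",
    "CC(C)CC(C)(C)C", "FC(F)(F)C", "c1ccsc1", "c1cc[nH]c1",
    "CCCCCCCCCC", "C(C(C(CO)O)O)O", "CN1CCCC1", "O=S(=O)(O)O",
    "CC(C)=CCCC(C)=CC=O", "CCOC(=O)C", "c1cnc2[nH]ccc2c1",
    "CC1CCC(C)CC1", "OC1CCCCC1O", "CNC", "CCC(CC)CO",
    "c1ccc(cc1)C(=O)N", "ICI", "C=O", "CC=O", "OO")
  expect_length(fixtures, 50L)
  ours <- vapply(fixtures, function(s) nrow(parse_smiles(s)$atoms), 0L)
  oracle <- vapply(fixtures, function(s) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(s))
    sum(ChemmineR::atomcount(sdf)[[1]])
  }, 0L)
  expect_equal(unname(ours), unname(oracle))
})
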