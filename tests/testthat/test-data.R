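test_that("CSV loading drops bad rows with a report and falls back to SMILES tokens", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,label", "CCO,1", "C(,2", "c1ccccc1,2"), tmp)
  ds <- read_molecule_csv(tmp, task_kind = "classification")
  expect_equal(length(ds$records), 2L)
  expect_equal(ds$report$dropped, 1L)
  expect_match(ds$report$reasons, "row 2")
  # no text column: SMILES tokens are the text surrogate
  expect_equal(ds$records[[1]]$tokens, c("C", "C", "O"))

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,y", "CCO,-0.77", paste0("CCC,", 1.5),
               rep("CC,0.1", 8)), tmp2)
  reg <- read_molecule_csv(tmp2, label_cols = "y", task_kind = "regression")
  expect_equal(reg$records[[1]]$labels, -0.77)

  expect_error(read_molecule_csv(tmp, label_cols = "missing"),
               "schema error")
})

test_that("records validate labels and text", {
  expect_error(molecule_record("CCO", labels = Inf,
                               task_kind = "regression"), "finite")
  expect_error(molecule_record("CCO", labels = NA,
                               task_kind = "classification"), "no observed")
  r <- molecule_record("CCO", labels = 1, text = "  an ether-like molecule ")
  expect_equal(r$tokens, c("an", "ether", "like", "molecule"))
})

test_that("stratified split preserves class proportions and is deterministic", {
  recs <- lapply(1:20, function(i)
    molecule_record("CCO", labels = ifelse(i <= 10, 1, 2)))
  ds <- molecule_dataset(recs, "classification")
  sp <- stratified_split(ds, seed = 7)
  expect_equal(lengths(sp[c("train", "test", "validation")]),
               c(train = 16L, test = 2L, validation = 2L))
  labs <- c(rep(1, 10), rep(2, 10))
  expect_equal(sum(labs[sp$train] == 1), 8)
  expect_equal(sum(labs[sp$test] == 1), 1)
  expect_equal(sum(labs[sp$validation] == 1), 1)
  # disjoint and exhaustive
  all_idx <- sort(c(sp$train, sp$test, sp$validation))
  expect_equal(all_idx, 1:20)
  # determinism
  sp2 <- stratified_split(ds, seed = 7)
  expect_identical(sp[c("train", "test", "validation")],
                   sp2[c("train", "test", "validation")])
  expect_error(stratified_split(ds, ratios = c(0.5, 0.2, 0.2)),
               "config error")
})

test_that("regression split stratifies on quantile bins of y", {
  set.seed(3)
  y <- rnorm(80)
  recs <- lapply(y, function(v) molecule_record("CCO", labels = v,
                                               task_kind = "regression"))
  ds <- molecule_dataset(recs, "regression")
  sp <- stratified_split(ds, seed = 1)
  # brute-force check: each quartile of y contributes ~80/10/10
  bins <- cut(y, quantile(y, 0:4 / 4), include.lowest = TRUE, labels = FALSE)
  for (b in 1:4) {
    members <- which(bins == b)
    expect_equal(sum(sp$train %in% members), 16)
    expect_equal(sum(sp$test %in% members), 2)
    expect_equal(sum(sp$validation %in% members), 2)
  }
})

test_that("tiny strata degrade to a random split with a warning", {
  recs <- lapply(1:12, function(i)
    molecule_record("CCO", labels = ifelse(i <= 11, 1, 2)))
  ds <- molecule_dataset(recs, "classification")
  expect_warning(sp <- stratified_split(ds, seed = 1), "random split")
  expect_equal(sort(c(sp$train, sp$test, sp$validation)), 1:12)
})
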