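# Dataset containers: molecule records, CSV loading, stratified splits.

#' Construct a molecule record
#'
#' A record pairs a parsed molecular graph with its tokenized textual
#' description and one or more property labels. When no description is
#' supplied the tokenized SMILES string is used as the text surrogate.
#'
#' @param smiles SMILES string (parsed immediately; errors propagate).
#' @param labels Numeric vector of labels. Classification: class indices
#'   (1..C) or 0/1 per task, `NA` marking missing labels in multi-task data.
#'   Regression: a finite scalar.
#' @param text Optional description string; tokenized on non-alphanumeric
#'   boundaries. `NULL` falls back to SMILES tokens.
#' @param task_kind One of "classification" or "regression".
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(smiles, labels, text = NULL,
                            task_kind = c("classification", "regression")) {
  task_kind <- match.arg(task_kind)
  graph <- parse_smiles(smiles)
  tokens <- tokenize_text(text, smiles)
  labels <- as.numeric(labels)
  if (task_kind == "regression") {
    if (length(labels) != 1L || !is.finite(labels))
      stopf("regression label must be a single finite number")
  } else if (all(is.na(labels))) {
    stopf("classification record has no observed label")
  }
  structure(list(smiles = smiles, graph = graph, tokens = tokens,
                 labels = labels, task_kind = task_kind),
            class = "molecule_record")
}

# Tokenize a free-text description; fall back to SMILES tokens.
tokenize_text <- function(text, smiles) {
  if (!is.null(text) && !is.na(text) && nzchar(trimws(text))) {
    toks <- strsplit(tolower(trimws(text)), "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) > 0L) return(toks)
  }
  as.character(smiles_tokenize(smiles))
}

#' Load a labeled molecule dataset from CSV
#'
#' Reads a CSV of (SMILES, optional text, label columns), parses every
#' SMILES, drops unparseable rows, and returns the records plus a drop
#' report.
#'
#' @param path CSV file path.
#' @param smiles_col Name of the SMILES column.
#' @param label_cols Character vector of label column names.
#' @param text_col Optional text column name.
#' @param task_kind "classification" or "regression".
#' @param sep Field delimiter.
#' @return A `molecule_dataset`: list with `records` (list of
#'   `molecule_record`), `task_kind`, `n_tasks`, and `report`
#'   (`dropped` count and per-row `reasons`).
#' @export
read_molecule_csv <- function(path, smiles_col = "smiles",
                              label_cols = "label", text_col = NULL,
                              task_kind = c("classification", "regression"),
                              sep = ",") {
  task_kind <- match.arg(task_kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, sep = sep,
                        check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(smiles_col, label_cols, text_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stopf("schema error: column(s) not in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  records <- list()
  reasons <- character(0)
  for (r in seq_len(nrow(df))) {
    rec <- tryCatch(
      molecule_record(
        smiles = df[[smiles_col]][r],
        labels = as.numeric(unlist(df[r, label_cols, drop = FALSE])),
        text = if (!is.null(text_col)) df[[text_col]][r] else NULL,
        task_kind = task_kind),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      reasons <- c(reasons, sprintf("row %d: %s", r, rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  molecule_dataset(records, task_kind,
                   report = list(dropped = length(reasons), reasons = reasons))
}

#' Bundle molecule records into a dataset
#'
#' @param records List of `molecule_record` objects with a common task kind.
#' @param task_kind "classification" or "regression".
#' @param report Optional load report.
#' @return A `molecule_dataset`.
#' @export
molecule_dataset <- function(records, task_kind, report = NULL) {
  if (length(records) > 0L) {
    kinds <- unique(vapply(records, `[[`, "", "task_kind"))
    if (!identical(kinds, task_kind))
      stopf("records disagree with task_kind '%s'", task_kind)
  }
  n_tasks <- if (length(records) > 0L) length(records[[1]]$labels) else 0L
  structure(list(records = records, task_kind = task_kind,
                 n_tasks = n_tasks,
                 report = report %||% list(dropped = 0L, reasons = character(0))),
            class = "molecule_dataset")
}

#' @export
print.molecule_dataset <- function(x, ...) {
  cat(sprintf("<molecule_dataset> %d records, task = %s, %d task(s), %d dropped\n",
              length(x$records), x$task_kind, x$n_tasks, x$report$dropped))
  invisible(x)
}

#' @export
length.molecule_dataset <- function(x) length(x$records)

dataset_labels <- function(dataset) {
  t(vapply(dataset$records, `[[`, numeric(dataset$n_tasks), "labels"))
}

#' Stratified train/test/validation split
#'
#' Splits record indices 80/10/10 (by default), preserving per-class
#' proportions for classification and stratifying regression targets by
#' 4 quantile bins of y. Deterministic under a fixed seed; strata with too
#' few members degrade to a random split with a warning.
#'
#' @param dataset A `molecule_dataset` (or a plain label vector).
#' @param ratios Length-3 numeric (train, test, validation) summing to 1.
#' @param seed Integer seed.
#' @param n_bins Quantile bins used for regression stratification.
#' @return List with `train`, `test`, `validation` index vectors plus the
#'   `seed` and `ratios` used; class `dataset_split`.
#' @export
stratified_split <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                             n_bins = 4L) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stopf("config error: split ratios must be 3 non-negative numbers summing to 1")
  if (inherits(dataset, "molecule_dataset")) {
    n <- length(dataset$records)
    if (dataset$task_kind == "regression") {
      y <- vapply(dataset$records, function(r) r$labels[1], 0)
      strata <- quantile_bins(y, n_bins)
    } else {
      lab <- vapply(dataset$records,
                    function(r) r$labels[which(!is.na(r$labels))[1]], 0)
      strata <- as.integer(factor(lab))
    }
  } else {
    strata <- as.integer(factor(dataset))
    n <- length(strata)
  }
  if (n < 10L) stopf("need at least 10 records to split")

  min_ratio <- min(ratios[ratios > 0])
  counts <- table(strata)
  if (any(counts < ceiling(1 / min_ratio))) {
    warning("some strata too small for stratification; using a random split")
    strata <- rep(1L, n)
  }

  idx <- list(train = integer(0), test = integer(0), validation = integer(0))
  with_seed(seed, {
    for (s in sort(unique(strata))) {
      members <- sample(which(strata == s))
      ns <- length(members)
      # largest-remainder allocation keeps per-stratum proportions exact
      raw <- ratios * ns
      base <- floor(raw)
      rem <- ns - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      cuts <- cumsum(base)
      idx$train <- c(idx$train, members[seq_len(base[1])])
      if (base[2] > 0)
        idx$test <- c(idx$test, members[(cuts[1] + 1):cuts[2]])
      if (base[3] > 0)
        idx$validation <- c(idx$validation, members[(cuts[2] + 1):cuts[3]])
    }
  })
  structure(list(train = sort(idx$train), test = sort(idx$test),
                 validation = sort(idx$validation),
                 seed = seed, ratios = ratios),
            class = "dataset_split")
}

quantile_bins <- function(y, n_bins) {
  qs <- stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L),
                        type = 7)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  as.integer(cut(y, qs, labels = FALSE, include.lowest = TRUE))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / test %d / validation %d (seed %d)\n",
              length(x$train), length(x$test), length(x$validation), x$seed))
  invisible(x)
}
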