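# Synthetic molecule/text fixture generator.
#
# Emulates small-molecule benchmark statistics (mean heavy-atom counts in
# the low teens, matching the solubility-benchmark average of 13.3) while
# planting class-correlated structural motifs: each class carries a
# distinct carbocycle size (acyclic decoration cannot fake a ring, so the
# motif is exactly recoverable by cycle search). Texts are class templates
# naming the motif plus distractor tokens. Everything is emitted as SMILES
# so the full parsing path is exercised.

VALENCE <- c(C = 4L, N = 3L, O = 2L)

DISTRACTOR_VOCAB <- c(
  "molecule", "aliphatic", "branched", "carbon", "skeleton", "alkyl",
  "compound", "saturated", "polar", "nonpolar", "substituted", "backbone",
  "organic", "small", "lipophilic", "soluble", "heteroatom", "amine",
  "ether", "framework")

MOTIF_TEMPLATES <- list(
  ring3 = c("three", "membered", "cyclopropane", "ring"),
  ring4 = c("four", "membered", "cyclobutane", "ring"),
  ring5 = c("five", "membered", "cyclopentane", "ring"),
  ring6 = c("six", "membered", "cyclohexane", "ring"),
  ring7 = c("seven", "membered", "cycloheptane", "ring"),
  ring8 = c("eight", "membered", "cyclooctane", "ring"))

motif_size <- function(motif) {
  m <- regmatches(motif, regexec("^ring([3-8])$", motif))[[1]]
  if (length(m) == 0L) stopf("unknown motif '%s' (supported: ring3..ring8)", motif)
  as.integer(m[2])
}

# Random acyclic decoration written directly as a SMILES branch; one
# valence is consumed by the bond to the parent.
random_tree_smiles <- function(n_atoms) {
  if (n_atoms <= 0L) return("")
  sym <- sample(c("C", "C", "C", "C", "C", "C", "C", "C", "N", "O"), 1L)
  cap <- VALENCE[[sym]] - 1L
  left <- n_atoms - 1L
  str <- sym
  kids <- character(0)
  while (left > 0L && cap > 0L) {
    size <- if (cap == 1L) left else sample.int(left, 1L)
    kids <- c(kids, random_tree_smiles(size))
    left <- left - size
    cap <- cap - 1L
  }
  if (length(kids) > 0L) {
    if (length(kids) > 1L)
      str <- paste0(str, paste0("(", kids[-length(kids)], ")", collapse = ""))
    str <- paste0(str, kids[length(kids)])
  }
  str
}

# One molecule: `ring_sizes` planted carbocycles joined by short linkers,
# decorated with random trees up to `target_size` heavy atoms.
build_molecule_smiles <- function(ring_sizes, target_size) {
  k <- length(ring_sizes)
  linker_len <- if (k > 1L) rep(2L, k - 1L) else integer(0)
  core <- sum(ring_sizes) + sum(linker_len)
  extra <- max(0L, target_size - core)

  # branch budget per ring atom: 2 free valences on a ring carbon, one of
  # which is taken by an outgoing linker on the joining atoms
  slots <- list()
  for (r in seq_len(k)) {
    capacity <- rep(2L, ring_sizes[r])
    if (r > 1L) capacity[1] <- capacity[1] - 1L        # incoming linker
    if (r < k) capacity[ring_sizes[r]] <- capacity[ring_sizes[r]] - 1L
    slots[[r]] <- capacity
  }
  branches <- lapply(seq_len(k), function(r)
    vector("list", ring_sizes[r]))
  while (extra > 0L) {
    open <- which(unlist(slots) > 0L)
    if (length(open) == 0L) break
    pick <- open[sample.int(length(open), 1L)]
    # map flat slot index back to (ring, atom)
    sizes <- vapply(slots, length, 0L)
    ring <- findInterval(pick - 1L, cumsum(c(0L, sizes)),
                         rightmost.closed = FALSE)
    atom <- pick - c(0L, cumsum(sizes))[ring]
    b_size <- sample.int(min(extra, 6L), 1L)
    branches[[ring]][[atom]] <- c(branches[[ring]][[atom]],
                                  random_tree_smiles(b_size))
    slots[[ring]][atom] <- slots[[ring]][atom] - 1L
    extra <- extra - b_size
  }

  parts <- character(0)
  for (r in seq_len(k)) {
    digit <- as.character(r)
    seg <- ""
    for (a in seq_len(ring_sizes[r])) {
      br <- unlist(branches[[r]][[a]])
      seg <- paste0(seg, "C",
                    if (a == 1L || a == ring_sizes[r]) digit else "",
                    if (length(br) > 0L)
                      paste0("(", br, ")", collapse = "") else "")
    }
    parts <- c(parts, seg)
    if (r < k) parts <- c(parts, strrep("C", linker_len[r]))
  }
  paste0(parts, collapse = "")
}

make_text_tokens <- function(template, n_distractors = 4L) {
  sample(c(template,
           sample(DISTRACTOR_VOCAB, n_distractors)))
}

#' Generate a synthetic molecule/text dataset
#'
#' Classification: each class plants one distinct carbocycle motif (ring
#' sizes from `motifs`), decorated with random acyclic branches up to a
#' Gaussian-sampled heavy-atom count; labels are flipped with probability
#' `label_noise`; the text is a class template naming the motif plus
#' distractor tokens. Regression: the target is
#' y = alpha * (number of planted rings) + N(0, sigma), with 1-3 copies of
#' the first motif joined by short linkers and the count named in the
#' text. Deterministic under `seed`.
#'
#' @param n Number of records.
#' @param task "classification" or "regression".
#' @param motifs Character vector of per-class motifs (distinct ring
#'   sizes), e.g. `c("ring5", "ring6")`.
#' @param mean_size Mean heavy-atom count (default 13.3, the solubility
#'   benchmark average); `size_sd` its spread.
#' @param label_noise Class-flip probability in [0, 0.5).
#' @param alpha,sigma Regression slope per motif copy and noise SD.
#' @param seed Integer seed.
#' @return A `molecule_dataset`; each record's SMILES round-trips through
#'   [parse_smiles()].
#' @export
generate_molecules <- function(n = 100L,
                               task = c("classification", "regression"),
                               motifs = c("ring5", "ring6"),
                               mean_size = 13.3, size_sd = 2.5,
                               label_noise = 0, alpha = 1.0, sigma = 0.1,
                               seed = 1L) {
  task <- match.arg(task)
  if (label_noise < 0 || label_noise >= 0.5)
    stopf("label_noise must lie in [0, 0.5)")
  sizes <- vapply(motifs, motif_size, 0L)
  if (anyDuplicated(sizes)) stopf("motifs must be distinct across classes")
  if (mean_size < max(sizes))
    stopf("config error: mean_size %.1f smaller than largest motif (%d atoms)",
          mean_size, max(sizes))
  n_classes <- length(motifs)

  records <- with_seed(derive_seed(seed, "synthetic"), {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (task == "classification") {
        cls <- ((i - 1L) %% n_classes) + 1L     # balanced by construction
        target <- max(sizes[cls],
                      as.integer(round(stats::rnorm(1, mean_size, size_sd))))
        smiles <- build_molecule_smiles(sizes[cls], target)
        label <- cls
        if (label_noise > 0 && stats::runif(1) < label_noise) {
          others <- setdiff(seq_len(n_classes), cls)
          label <- others[sample.int(length(others), 1L)]
        }
        tokens <- make_text_tokens(MOTIF_TEMPLATES[[motifs[cls]]])
        out[[i]] <- molecule_record(smiles, labels = label,
                                    text = paste(tokens, collapse = " "),
                                    task_kind = "classification")
      } else {
        k <- sample.int(3L, 1L)
        core <- k * sizes[1] + (k - 1L) * 2L
        target <- core + stats::rpois(1, 3)
        smiles <- build_molecule_smiles(rep(sizes[1], k), target)
        y <- alpha * k + stats::rnorm(1, 0, sigma)
        count_word <- c("one", "two", "three")[k]
        tokens <- make_text_tokens(c(count_word,
                                     MOTIF_TEMPLATES[[motifs[1]]], "copies"))
        out[[i]] <- molecule_record(smiles, labels = y,
                                    text = paste(tokens, collapse = " "),
                                    task_kind = "regression")
      }
    }
    out
  })
  molecule_dataset(records, task)
}

#' Count planted carbocycles of a given size
#'
#' Independent structural check used by the generator's tests: counts
#' cycles of length `size` in a molecular graph via its cycle space
#' (decorations are acyclic, so every cycle is a planted motif).
#'
#' @param graph A `molecular_graph`.
#' @param size Ring size to count.
#' @return Integer count.
#' @export
count_rings <- function(graph, size) {
  g <- igraph::graph_from_edgelist(as.matrix(graph$bonds[, c("i", "j")]),
                                   directed = FALSE)
  # each independent cycle in a cactus-like planted graph is chordless;
  # fundamental cycles from any spanning tree recover them
  n_cycles <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)
  if (n_cycles == 0L) return(0L)
  mst <- igraph::mst(g)
  extra <- igraph::difference(g, mst)
  cnt <- 0L
  ee <- igraph::as_edgelist(extra)
  for (e in seq_len(nrow(ee))) {
    sp <- igraph::shortest_paths(mst, from = ee[e, 1], to = ee[e, 2])
    if (length(sp$vpath[[1]]) == size) cnt <- cnt + 1L
  }
  cnt
}

#' Write a dataset to CSV
#'
#' Columns: smiles, text, label (or label_1..label_T for multi-task).
#'
#' @param dataset A `molecule_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  recs <- dataset$records
  labs <- t(vapply(recs, `[[`, numeric(dataset$n_tasks), "labels"))
  df <- data.frame(
    smiles = vapply(recs, `[[`, "", "smiles"),
    text = vapply(recs, function(r) paste(r$tokens, collapse = " "), ""))
  if (dataset$n_tasks == 1L) df$label <- labs[, 1]
  else for (tk in seq_len(dataset$n_tasks))
    df[[paste0("label_", tk)]] <- labs[, tk]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
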