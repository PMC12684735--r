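# SMILES parsing and atom featurization.
#
# The parser covers the organic subset (B C N O P S F Cl Br I), aromatic
# lowercase atoms, bracket atoms with charges, branches, explicit bond
# symbols and ring-closure digits (including %nn). Hydrogens stay implicit;
# atom order follows SMILES token order, so the graph is deterministic for a
# given string. Stereochemistry markers (/ \ @) are accepted and ignored.

# First 100 element symbols; the fixed one-hot vocabulary for atom features.
ELEMENT_VOCAB <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm")

# Raw atom feature dimensionality: element one-hot (100) + degree one-hot
# (0..6 -> 7) + formal charge one-hot (-2..+2 -> 5) + aromatic flag (1).
ATOM_FEATURE_DIM <- 113L

ORGANIC_ATOMS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atom, bond, branch and ring-closure tokens.
#' Used both by the parser and as the fallback text tokenizer for records
#' that carry no description.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens, with a `pos` attribute giving the
#'   1-based character position of each token.
#' @export
#' @examples
#' smiles_tokenize("c1ccccc1O")
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stopf("SMILES parse error: empty string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  pos <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stopf("SMILES parse error at position %d: unclosed '['", i)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      pos <- c(pos, i)
      i <- j + 1L
    } else if (ch == "%" ) {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = "")))
        stopf("SMILES parse error at position %d: '%%' needs two digits", i)
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      pos <- c(pos, i)
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      pos <- c(pos, i)
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      pos <- c(pos, i)
      i <- i + 1L
    }
  }
  attr(tokens, "pos") <- pos
  tokens
}

parse_bracket_atom <- function(token, pos) {
  body <- substr(token, 2L, nchar(token) - 1L)
  if (!nzchar(body))
    stopf("SMILES parse error at position %d: empty bracket atom", pos)
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
    body))[[1]]
  if (length(m) == 0L)
    stopf("SMILES parse error at position %d: bad bracket atom '%s'", pos, token)
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_ATOMS
  if (aromatic) {
    sym <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  }
  charge_tok <- m[6]
  charge <- 0L
  if (!is.na(charge_tok) && nzchar(charge_tok)) {
    sign <- if (substr(charge_tok, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", charge_tok)
    charge <- if (nzchar(digits)) sign * as.integer(digits)
              else sign * nchar(charge_tok)
  }
  list(element = sym, aromatic = aromatic, charge = charge)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph of a molecule: atoms (element, formal charge,
#' aromatic flag, degree), undirected bonds with an order tag, and the raw
#' atom-feature matrix used by the graph encoder. Atom order follows SMILES
#' token order; hydrogens are implicit.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecular_graph`: a list with `atoms`
#'   (data.frame: element, charge, aromatic, degree), `bonds` (data.frame:
#'   i, j, order — 1-based atom indices, i < j), `features` (numeric matrix,
#'   one row per atom, `ATOM_FEATURE_DIM` columns) and `smiles`.
#' @export
#' @examples
#' g <- parse_smiles("CCO")
#' nrow(g$atoms)  # 3 heavy atoms
parse_smiles <- function(smiles) {
  tokens <- smiles_tokenize(smiles)
  pos <- attr(tokens, "pos")

  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  bond_i <- integer(0); bond_j <- integer(0); bond_order <- character(0)

  prev <- NA_integer_              # atom awaiting the next bond
  pending_bond <- NULL             # explicit bond symbol before next atom
  branch_stack <- integer(0)
  ring_open <- list()              # closure label -> list(atom, bond)

  add_atom <- function(el, arom, chg) {
    element <<- c(element, el)
    aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg)
    length(element)
  }
  add_bond <- function(a, b, order, p) {
    if (a == b)
      stopf("SMILES parse error at position %d: self-bond on atom %d", p, a)
    lo <- min(a, b); hi <- max(a, b)
    if (any(bond_i == lo & bond_j == hi))
      stopf("SMILES parse error at position %d: duplicate bond %d-%d", p, lo, hi)
    bond_i <<- c(bond_i, lo); bond_j <<- c(bond_j, hi)
    bond_order <<- c(bond_order, order)
  }
  bond_for <- function(new_aromatic) {
    if (!is.null(pending_bond)) {
      b <- pending_bond; pending_bond <<- NULL
      return(b)
    }
    if (!is.na(prev) && aromatic[prev] && new_aromatic) "aromatic" else "single"
  }

  for (k in seq_along(tokens)) {
    tk <- tokens[k]; p <- pos[k]
    if (tk %in% ORGANIC_ATOMS || tk %in% AROMATIC_ATOMS ||
        startsWith(tk, "[")) {
      if (startsWith(tk, "[")) {
        info <- parse_bracket_atom(tk, p)
      } else if (tk %in% AROMATIC_ATOMS) {
        info <- list(element = toupper(tk), aromatic = TRUE, charge = 0L)
      } else {
        info <- list(element = tk, aromatic = FALSE, charge = 0L)
      }
      ord <- bond_for(info$aromatic)
      idx <- add_atom(info$element, info$aromatic, info$charge)
      if (!is.na(prev)) add_bond(prev, idx, ord, p)
      prev <- idx
    } else if (tk == "(") {
      if (is.na(prev))
        stopf("SMILES parse error at position %d: branch before any atom", p)
      branch_stack <- c(branch_stack, prev)
    } else if (tk == ")") {
      if (length(branch_stack) == 0L)
        stopf("SMILES parse error at position %d: unmatched ')'", p)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
    } else if (tk %in% c("-", "=", "#", "$", ":")) {
      pending_bond <- switch(tk, "-" = "single", "=" = "double",
                             "#" = "triple", "$" = "quadruple",
                             ":" = "aromatic")
    } else if (tk %in% c("/", "\\")) {
      pending_bond <- "single"   # stereo bonds treated as single
    } else if (grepl("^%?[0-9]+$", tk)) {
      if (is.na(prev))
        stopf("SMILES parse error at position %d: ring closure before any atom", p)
      label <- sub("^%", "", tk)
      if (!is.null(ring_open[[label]])) {
        open <- ring_open[[label]]
        ord <- if (!is.null(pending_bond)) pending_bond
               else if (!is.null(open$bond)) open$bond
               else if (aromatic[prev] && aromatic[open$atom]) "aromatic"
               else "single"
        pending_bond <- NULL
        add_bond(open$atom, prev, ord, p)
        ring_open[[label]] <- NULL
      } else {
        ring_open[[label]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NULL
      }
    } else if (tk == ".") {
      stopf("SMILES parse error at position %d: disconnected components ('.') are not supported", p)
    } else {
      stopf("SMILES parse error at position %d: unexpected token '%s'", p, tk)
    }
  }
  if (length(branch_stack) > 0L)
    stopf("SMILES parse error: unclosed branch '(' (depth %d) at end of input",
          length(branch_stack))
  if (length(ring_open) > 0L)
    stopf("SMILES parse error: unclosed ring closure(s): %s",
          paste(names(ring_open), collapse = ", "))
  if (length(element) == 0L)
    stopf("SMILES parse error: no atoms in '%s'", smiles)
  if (!is.null(pending_bond))
    stopf("SMILES parse error: dangling bond symbol at end of input")

  n <- length(element)
  degree <- integer(n)
  if (length(bond_i) > 0L) {
    tab <- table(factor(c(bond_i, bond_j), levels = seq_len(n)))
    degree <- as.integer(tab)
  }
  atoms <- data.frame(element = element, charge = charge,
                      aromatic = aromatic, degree = degree,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bond_i, j = bond_j, order = bond_order,
                      stringsAsFactors = FALSE)
  g <- structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
                 class = "molecular_graph")
  g$features <- featurize_atoms(g)
  g
}

#' Atom feature matrix for a molecular graph
#'
#' One-hot element over a fixed 100-symbol vocabulary, one-hot degree (0-6,
#' clamped), one-hot formal charge (-2..+2, clamped) and an aromatic flag;
#' 113 columns total.
#'
#' @param graph A `molecular_graph`.
#' @return Numeric matrix, `nrow(graph$atoms)` x 113.
#' @export
featurize_atoms <- function(graph) {
  atoms <- graph$atoms
  n <- nrow(atoms)
  X <- matrix(0, n, ATOM_FEATURE_DIM)
  el_idx <- match(atoms$element, ELEMENT_VOCAB)
  if (anyNA(el_idx))
    stopf("unknown element symbol(s): %s",
          paste(unique(atoms$element[is.na(el_idx)]), collapse = ", "))
  X[cbind(seq_len(n), el_idx)] <- 1
  deg <- pmin(pmax(atoms$degree, 0L), 6L)
  X[cbind(seq_len(n), 100L + deg + 1L)] <- 1
  chg <- pmin(pmax(atoms$charge, -2L), 2L)
  X[cbind(seq_len(n), 107L + chg + 3L)] <- 1
  X[, 113L] <- as.numeric(atoms$aromatic)
  X
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s\n  %d atoms, %d bonds (%d aromatic)\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds),
              sum(x$bonds$order == "aromatic")))
  invisible(x)
}

# Symmetric sparse adjacency matrix (no self loops) for one or more graphs.
graph_adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  b <- graph$bonds
  if (nrow(b) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(b$i, b$j), j = c(b$j, b$i),
                       x = rep(1, 2L * nrow(b)), dims = c(n, n))
}
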