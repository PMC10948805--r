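# Atom/bond sequence fragment descriptors, lengths 2-3 ("sequence" family,
# hydrogen-suppressed). A fragment is a simple path; its label joins atom
# symbols (lowercase when aromatic) with bond symbols (- = # :) and is
# canonicalized to the lexicographic minimum of the label and its reversal,
# so each undirected occurrence is counted once.

atom_label <- function(atoms, include_charge = FALSE) {
  lab <- ifelse(atoms$aromatic, tolower(atoms$symbol), atoms$symbol)
  if (include_charge) {
    q <- atoms$charge
    suff <- ifelse(q == 0, "",
            ifelse(q == 1, "+", ifelse(q == -1, "-",
            ifelse(q > 0, paste0("+", q), paste0("-", abs(q))))))
    lab <- paste0(lab, suff)
  }
  lab
}

path_label <- function(atom_seq, bond_seq, labels, bond_of) {
  fwd <- paste0(paste0(labels[atom_seq[-length(atom_seq)]], bond_seq, collapse = ""),
                labels[atom_seq[length(atom_seq)]])
  rev_atoms <- rev(atom_seq)
  rev_bonds <- rev(bond_seq)
  bwd <- paste0(paste0(labels[rev_atoms[-length(rev_atoms)]], rev_bonds, collapse = ""),
                labels[rev_atoms[length(rev_atoms)]])
  min(fwd, bwd)
}

# All undirected simple-path occurrences of 2..3 atoms with their canonical
# labels and member atoms. The substrate for both counting and the additive
# atom-contribution map.
fragment_occurrences <- function(graph, min_len = 2L, max_len = 3L,
                                 include_charge = FALSE) {
  atoms <- graph$atoms; bonds <- graph$bonds
  n <- nrow(atoms)
  labels <- atom_label(atoms, include_charge)
  occ_label <- character(0)
  occ_atoms <- list()
  if (n >= 2 && nrow(bonds) > 0 && min_len <= 2) {
    # length-2 paths: one per bond
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$from[k]; j <- bonds$to[k]
      occ_label <- c(occ_label, path_label(c(i, j), bonds$order[k], labels))
      occ_atoms <- c(occ_atoms, list(c(i, j)))
    }
  }
  if (n >= 3 && nrow(bonds) > 0 && max_len >= 3) {
    # length-3 paths: one per unordered neighbor pair around a center atom
    nb <- vector("list", n)
    bsym <- vector("list", n)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$from[k]; j <- bonds$to[k]; o <- bonds$order[k]
      nb[[i]] <- c(nb[[i]], j); bsym[[i]] <- c(bsym[[i]], o)
      nb[[j]] <- c(nb[[j]], i); bsym[[j]] <- c(bsym[[j]], o)
    }
    for (b in seq_len(n)) {
      nbs <- nb[[b]]
      if (length(nbs) < 2) next
      for (p in seq_len(length(nbs) - 1)) {
        for (q in seq((p + 1), length(nbs))) {
          a <- nbs[p]; c_ <- nbs[q]
          occ_label <- c(occ_label,
                         path_label(c(a, b, c_), c(bsym[[b]][p], bsym[[b]][q]), labels))
          occ_atoms <- c(occ_atoms, list(c(a, b, c_)))
        }
      }
    }
  }
  tibble::tibble(fragment = occ_label, atoms = occ_atoms)
}

#' Enumerate sequence fragments of a structure
#'
#' Counts every simple path of `min_len` to `max_len` atoms once per
#' undirected occurrence. Hydrogens are suppressed; aromatic atoms are
#' lowercased; bonds are `-` (single), `=` (double), `#` (triple), `:`
#' (aromatic). Formal charges are not encoded in labels unless
#' `include_charge = TRUE` (which appends `+`/`-` to the atom symbol).
#'
#' @param structure A SMILES string or a graph from [mol_graph()].
#' @param min_len,max_len Path lengths in atoms (defaults 2 and 3).
#' @param include_charge Append formal charges to atom symbols.
#' @return A tibble `fragment`, `count`, sorted by fragment label. A
#'   single-atom structure yields zero rows.
#' @examples
#' \dontrun{
#' enumerate_fragments("CCC") # C-C: 2, C-C-C: 1
#' }
#' @export
enumerate_fragments <- function(structure, min_len = 2L, max_len = 3L,
                                include_charge = FALSE) {
  stopifnot(min_len >= 2L, max_len <= 3L, min_len <= max_len)
  cache_key <- NULL
  if (is.character(structure)) {
    # memoized per SMILES: pools reuse the same bundled structures heavily
    cache_key <- paste("frag", structure, min_len, max_len, include_charge)
    if (exists(cache_key, envir = .aq_cache)) {
      return(get(cache_key, envir = .aq_cache))
    }
  }
  graph <- if (is.character(structure)) mol_graph(structure) else structure
  occ <- fragment_occurrences(graph, min_len, max_len, include_charge)
  out <- if (nrow(occ) == 0) {
    tibble::tibble(fragment = character(0), count = integer(0))
  } else {
    dplyr::arrange(dplyr::count(occ, .data$fragment, name = "count"),
                   .data$fragment)
  }
  if (!is.null(cache_key)) assign(cache_key, out, envir = .aq_cache)
  out
}

#' Fragment-count matrix for a set of structures
#'
#' @param smiles Character vector of SMILES strings.
#' @param min_len,max_len,include_charge Passed to [enumerate_fragments()].
#' @return A list with `matrix` (rows = structures in input order, columns
#'   = the sorted union vocabulary of fragment labels) and `vocabulary`.
#' @export
vectorize_dataset <- function(smiles, min_len = 2L, max_len = 3L,
                              include_charge = FALSE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  # standardize in one batch so mol_graph calls hit the cache
  invisible(bridge_standardize(unique(smiles)))
  frags <- lapply(smiles, function(s) {
    enumerate_fragments(s, min_len, max_len, include_charge)
  })
  vocab <- sort(unique(unlist(lapply(frags, function(f) f$fragment))))
  mat <- matrix(0L, nrow = length(smiles), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    if (nrow(f) > 0) mat[i, f$fragment] <- f$count
  }
  list(matrix = mat, vocabulary = vocab)
}

#' Additive per-atom contributions of a fragment model
#'
#' For a linear (additive) model on fragment counts, each fragment
#' occurrence's weight is split equally among its member atoms and
#' accumulated per atom, producing an interpretable atom coloring. The
#' split is exact for linear models: the per-atom contributions sum to the
#' model prediction minus the intercept.
#'
#' @param weights Named numeric vector of fragment-label weights; labels
#'   absent from it default to weight 0.
#' @param structure A SMILES string or a [mol_graph()] graph.
#' @param intercept Model intercept (reported in the `total` attribute
#'   computation only through `prediction = total + intercept`).
#' @inheritParams enumerate_fragments
#' @return A tibble `atom` (index), `symbol`, `contribution`, with
#'   attributes `total` (sum of contributions) and `prediction`
#'   (`total + intercept`).
#' @export
atom_contributions <- function(weights, structure, intercept = 0,
                               min_len = 2L, max_len = 3L, include_charge = FALSE) {
  stopifnot(is.numeric(weights))
  graph <- if (is.character(structure)) mol_graph(structure) else structure
  occ <- fragment_occurrences(graph, min_len, max_len, include_charge)
  contrib <- numeric(nrow(graph$atoms))
  for (i in seq_len(nrow(occ))) {
    w <- weights[occ$fragment[i]]
    if (is.na(w)) w <- 0
    members <- occ$atoms[[i]]
    contrib[members] <- contrib[members] + w / length(members)
  }
  out <- tibble::tibble(atom = seq_len(nrow(graph$atoms)),
                        symbol = graph$atoms$symbol,
                        contribution = contrib)
  attr(out, "total") <- sum(contrib)
  attr(out, "prediction") <- sum(contrib) + intercept
  out
}
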