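# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they check.

# sample standard deviation by explicit summation loop
oracle_sdi <- function(values) {
  n <- length(values)
  if (n == 1) return(-1)
  xbar <- 0
  for (v in values) xbar <- xbar + v
  xbar <- xbar / n
  ss <- 0
  for (v in values) ss <- ss + (v - xbar)^2
  sqrt(ss / (n - 1))
}

# all undirected simple paths of 2..3 atoms by exhaustive directed DFS,
# counting each direction then halving
oracle_fragments <- function(graph) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- nrow(atoms)
  lab <- ifelse(atoms$aromatic, tolower(atoms$symbol), atoms$symbol)
  adj <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]; o <- bonds$order[k]
    adj[[paste(i, j)]] <- o
    adj[[paste(j, i)]] <- o
  }
  neighbors <- function(i) {
    out <- integer(0)
    for (j in seq_len(n)) if (!is.null(adj[[paste(i, j)]])) out <- c(out, j)
    out
  }
  label_of <- function(path) {
    parts <- lab[path[1]]
    for (k in seq_along(path)[-1]) {
      parts <- c(parts, adj[[paste(path[k - 1], path[k])]], lab[path[k]])
    }
    fwd <- paste(parts, collapse = "")
    rpath <- rev(path)
    parts <- lab[rpath[1]]
    for (k in seq_along(rpath)[-1]) {
      parts <- c(parts, adj[[paste(rpath[k - 1], rpath[k])]], lab[rpath[k]])
    }
    bwd <- paste(parts, collapse = "")
    min(fwd, bwd)
  }
  counts <- list()
  bump <- function(l) counts[[l]] <<- (counts[[l]] %||% 0) + 1
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (a in seq_len(n)) {
    for (b in neighbors(a)) {
      bump(label_of(c(a, b)))
      for (c_ in neighbors(b)) {
        if (c_ != a) bump(label_of(c(a, b, c_)))
      }
    }
  }
  if (length(counts) == 0) {
    return(tibble::tibble(fragment = character(0), count = integer(0)))
  }
  out <- tibble::tibble(fragment = names(counts),
                        count = as.integer(unlist(counts) / 2))
  out[order(out$fragment), ]
}

# random connected molecular graph (tree plus optional extra edges)
random_graph <- function(n_atoms, aromatic = FALSE) {
  symbols <- sample(c("C", "N", "O", "S", "Cl"), n_atoms, replace = TRUE,
                    prob = c(0.6, 0.15, 0.15, 0.05, 0.05))
  # aromatic flags only on ring-capable elements (no aromatic halogens)
  arom <- if (aromatic) stats::runif(n_atoms) < 0.3 & symbols %in% c("C", "N", "O", "S")
          else rep(FALSE, n_atoms)
  atoms <- tibble::tibble(symbol = symbols, aromatic = arom, charge = 0L)
  if (n_atoms == 1) {
    return(list(atoms = atoms,
                bonds = tibble::tibble(from = integer(0), to = integer(0),
                                       order = character(0))))
  }
  from <- integer(0); to <- integer(0)
  for (i in 2:n_atoms) {
    from <- c(from, sample(i - 1, 1)); to <- c(to, i)
  }
  # a few extra edges to create cycles and branching
  extra <- sample(0:2, 1)
  tries <- 0
  while (extra > 0 && tries < 20) {
    tries <- tries + 1
    ij <- sample(n_atoms, 2)
    i <- min(ij); j <- max(ij)
    if (!any(from == i & to == j)) {
      from <- c(from, i); to <- c(to, j); extra <- extra - 1
    }
  }
  orders <- sample(c("-", "=", "#", ":"), length(from), replace = TRUE,
                   prob = c(0.7, 0.15, 0.05, 0.1))
  list(atoms = atoms, bonds = tibble::tibble(from = from, to = to, order = orders))
}
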