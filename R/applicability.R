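# Isolation-forest applicability domain. Trees isolate points by recursive
# (random dimension, uniform random split within the node's observed range)
# partitioning; points with short average path lengths are anomalous, i.e.
# far from the descriptor-space bulk of the training set.

#' Average path length of an unsuccessful BST search
#'
#' `c(n) = 2 H(n-1) - 2 (n-1)/n` with `H` the harmonic number; used to
#' normalize isolation depths and to extend paths truncated at the depth
#' ceiling by the expected remaining depth of the leaf. `c(0) = c(1) = 0`
#' by convention.
#'
#' @param n Number of points (vectorized).
#' @return Expected path length.
#' @export
avg_path_length <- function(n) {
  harmonic <- function(m) {
    # exact below 1e4, asymptotic (ln m + gamma) above
    ifelse(m < 1e4,
           vapply(m, function(k) if (k < 1) 0 else sum(1 / seq_len(k)), numeric(1)),
           log(m) + 0.5772156649015329)
  }
  out <- numeric(length(n))
  big <- n > 1
  m <- n[big]
  out[big] <- 2 * harmonic(m - 1) - 2 * (m - 1) / m
  out
}

grow_itree <- function(x, depth, ceiling_depth) {
  n <- nrow(x)
  if (n <= 1 || depth >= ceiling_depth) {
    return(list(leaf = TRUE, size = n, depth = depth))
  }
  rng <- apply(x, 2, range)
  splittable <- which(rng[2, ] > rng[1, ])
  if (length(splittable) == 0) {
    return(list(leaf = TRUE, size = n, depth = depth))
  }
  dim <- if (length(splittable) == 1) splittable else sample(splittable, 1)
  split <- stats::runif(1, rng[1, dim], rng[2, dim])
  left <- x[, dim] < split
  list(leaf = FALSE, dim = dim, split = split,
       left = grow_itree(x[left, , drop = FALSE], depth + 1, ceiling_depth),
       right = grow_itree(x[!left, , drop = FALSE], depth + 1, ceiling_depth))
}

tree_path_length <- function(tree, point) {
  depth <- 0
  node <- tree
  while (!node$leaf) {
    node <- if (point[node$dim] < node$split) node$left else node$right
    depth <- depth + 1
  }
  depth + avg_path_length(node$size)
}

#' Fit an isolation-forest applicability domain
#'
#' Each tree is grown on a random subsample of the training descriptor
#' matrix by recursive random splits until isolation or the depth ceiling
#' `ceil(log2(subsample))`. Deterministic for a fixed seed.
#'
#' @param x Numeric training matrix (rows = compounds, columns =
#'   descriptors, e.g. a fragment-count matrix from
#'   [vectorize_dataset()]).
#' @param n_trees Number of trees.
#' @param subsample Subsample size per tree (clamped to `nrow(x)`).
#' @param seed Integer seed.
#' @return An `ad_forest` object.
#' @export
fit_ad <- function(x, n_trees = 100, subsample = 256, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 training points", call. = FALSE)
  if (any(!is.finite(x))) stop("descriptors must be finite", call. = FALSE)
  if (all(apply(x, 2, function(col) max(col) == min(col)))) {
    stop("degenerate training matrix: all points identical, no split possible",
         call. = FALSE)
  }
  psi <- min(subsample, nrow(x))
  ceiling_depth <- ceiling(log2(psi))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    idx <- sample(nrow(x), psi)
    grow_itree(x[idx, , drop = FALSE], 0, ceiling_depth)
  })
  structure(list(trees = trees, n_trees = n_trees, subsample = psi,
                 n_train = nrow(x), n_dim = ncol(x), c_norm = avg_path_length(psi),
                 seed = seed),
            class = "ad_forest")
}

#' @export
print.ad_forest <- function(x, ...) {
  cat("<ad_forest>", x$n_trees, "trees, subsample", x$subsample,
      "over", x$n_train, "points x", x$n_dim, "descriptors\n")
  invisible(x)
}

#' One-row summary of an isolation forest
#'
#' @param x An `ad_forest`.
#' @param ... Unused.
#' @method glance ad_forest
#' @export
glance.ad_forest <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, subsample = x$subsample,
                 n_train = x$n_train, n_dim = x$n_dim, c_norm = x$c_norm)
}

#' Anomaly scores of points under an isolation forest
#'
#' `s(x) = 2^(-E[h(x)] / c(psi))`, with `E[h]` the average path length
#' over trees (truncated leaves extended by `c(leaf size)`) and `c(psi)`
#' the normalization at the subsample size. Scores near 1 are anomalous;
#' a point whose average path equals `c(psi)` scores exactly 0.5.
#'
#' @param forest An [fit_ad()] forest.
#' @param x Numeric matrix of points (columns must match training).
#' @return Numeric vector of scores in (0, 1).
#' @export
anomaly_score <- function(forest, x) {
  stopifnot(inherits(forest, "ad_forest"))
  x <- as.matrix(x)
  if (ncol(x) != forest$n_dim) {
    stop("descriptor dimension mismatch: forest has ", forest$n_dim,
         ", points have ", ncol(x), call. = FALSE)
  }
  eh <- vapply(seq_len(nrow(x)), function(i) {
    mean(vapply(forest$trees, tree_path_length, numeric(1), point = x[i, ]))
  }, numeric(1))
  2^(-eh / forest$c_norm)
}

#' @export
predict.ad_forest <- function(object, newdata, ...) {
  anomaly_score(object, newdata)
}

#' Contamination sweep of applicability-domain coverage and error
#'
#' For each contamination level `c` on the grid, the anomaly-score
#' threshold is the `(1 - c)` quantile of the training scores; test
#' compounds at or below the threshold are inside the applicability
#' domain. Coverage and RMSE are computed over that in-domain subset and
#' the RMSE is normalized by its value at contamination zero (where, by
#' definition, no molecule is rejected and coverage is 1). Grid points
#' whose in-domain subset holds fewer than 2 compounds are marked
#' unstable and carry `NA` errors rather than extrapolated values.
#'
#' @param forest An [fit_ad()] forest.
#' @param train_scores Anomaly scores of the training set under `forest`.
#' @param test_scores Anomaly scores of the test set.
#' @param observed,predicted Test-set observations and model predictions,
#'   aligned with `test_scores`.
#' @param step Contamination grid step over `[0, 0.99]`.
#' @return A tibble of class `ad_sweep`: `contamination`, `threshold`,
#'   `coverage`, `n_in_ad`, `rmse_in_ad`, `normalized_rmse`, `unstable`.
#' @export
sweep_contamination <- function(forest, train_scores, test_scores,
                                observed, predicted, step = 0.01) {
  stopifnot(length(test_scores) >= 1,
            length(observed) == length(test_scores),
            length(predicted) == length(test_scores))
  grid <- seq(0, 0.99, by = step)
  rows <- lapply(grid, function(cont) {
    if (cont == 0) {
      # contamination zero rejects nothing by definition
      threshold <- Inf
    } else {
      threshold <- stats::quantile(train_scores, probs = 1 - cont, names = FALSE)
    }
    in_ad <- test_scores <= threshold
    n_in <- sum(in_ad)
    unstable <- n_in < 2
    rmse_in <- if (unstable) NA_real_ else rmse(observed[in_ad], predicted[in_ad])
    tibble::tibble(contamination = cont, threshold = threshold,
                   coverage = mean(in_ad), n_in_ad = n_in,
                   rmse_in_ad = rmse_in, unstable = unstable)
  })
  out <- dplyr::bind_rows(rows)
  out$normalized_rmse <- out$rmse_in_ad / out$rmse_in_ad[1]
  class(out) <- c("ad_sweep", class(out))
  out
}

#' Plot a contamination sweep
#'
#' Coverage and normalized RMSE against the contamination parameter.
#'
#' @param object An `ad_sweep` tibble.
#' @param ... Unused.
#' @method autoplot ad_sweep
#' @export
autoplot.ad_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "contamination", "coverage",
                  "normalized_rmse"),
    cols = c("coverage", "normalized_rmse"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contamination, y = .data$value,
                                     color = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Contamination", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
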