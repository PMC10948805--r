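#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Run the full curation-and-deduplication pipeline
#'
#' Convenience wrapper: decision-tree curation, replicate grouping by
#' standardized structure, SDi-based median-or-discard resolution, and
#' assembly of the ten-column curated-entry table.
#'
#' @inheritParams curate_dataset
#' @return A list: `result` (the `curation_result`), `groups` (replicate
#'   groups), `resolved` (per-group outcomes), `entries` (curated-entry
#'   tibble ready for [write_curated()]).
#' @export
curate_solubility_data <- function(records, config = curation_config(),
                                   profiles = NULL) {
  result <- curate_dataset(records, config, profiles)
  groups <- group_replicates(result$accepted)
  resolved <- resolve_groups(groups, config$sdi_threshold)
  entries <- as_curated_entries(resolved)
  list(result = result, groups = groups, resolved = resolved, entries = entries)
}

#' Fit a ridge regression on fragment counts
#'
#' A deliberately simple fragment-count regressor (ridge via glmnet) used
#' to quantify how curation quality propagates into model error. It is a
#' stand-in for any external QSPR regressor, not a production solubility
#' model.
#'
#' @param x Fragment-count matrix (rows = compounds).
#' @param y Observed log10 mol/L solubilities.
#' @param lambda Ridge penalty.
#' @return A `fragment_model` object with `weights` (named vector),
#'   `intercept`, and `vocabulary`.
#' @export
fit_fragment_model <- function(x, y, lambda = 0.1) {
  stopifnot(nrow(x) == length(y), nrow(x) >= 2)
  fit <- glmnet::glmnet(x, y, alpha = 0, lambda = lambda,
                        standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  structure(list(weights = beta, intercept = as.numeric(fit$a0),
                 vocabulary = colnames(x), lambda = lambda),
            class = "fragment_model")
}

#' @export
predict.fragment_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  common <- intersect(colnames(newdata), object$vocabulary)
  pred <- rep(object$intercept, nrow(newdata))
  if (length(common) > 0) {
    pred <- pred + as.numeric(newdata[, common, drop = FALSE] %*%
                                object$weights[common])
  }
  pred
}

#' Tidy a fragment model
#'
#' @param x A `fragment_model`.
#' @param ... Unused.
#' @return A tibble `fragment`, `weight`, sorted by |weight|.
#' @method tidy fragment_model
#' @export
tidy.fragment_model <- function(x, ...) {
  tibble::tibble(fragment = names(x$weights), weight = unname(x$weights)) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' One-row summary of a fragment model
#'
#' @param x A `fragment_model`.
#' @param ... Unused.
#' @method glance fragment_model
#' @export
glance.fragment_model <- function(x, ...) {
  tibble::tibble(n_fragments = length(x$weights), intercept = x$intercept,
                 lambda = x$lambda)
}
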