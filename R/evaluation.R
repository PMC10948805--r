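# Error metrics and quality analytics. Note the "MAE" used throughout is a
# per-compound MEDIAN absolute error across models/folds, not a mean.

#' Regression error metrics
#'
#' Standard definitions over paired observed/predicted vectors:
#' `mse = mean((pred - obs)^2)`, `rmse = sqrt(mse)`,
#' `r2 = 1 - SS_res / SS_tot` (so a constant predictor at the observed
#' mean scores 0).
#'
#' @param observed,predicted Numeric vectors of equal length (log10 mol/L).
#' @return A single number.
#' @export
rmse <- function(observed, predicted) sqrt(mse(observed, predicted))

#' @rdname rmse
#' @export
mse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1,
            all(is.finite(observed)), all(is.finite(predicted)))
  mean((predicted - observed)^2)
}

#' @rdname rmse
#' @export
r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Per-compound median absolute error
#'
#' For each compound, the median of `|predicted - observed|` over all its
#' supplied predictions (across models and/or cross-validation folds).
#'
#' @param predictions A tibble with columns `compound_id`, `observed`,
#'   `predicted`, and optionally `model`.
#' @return A tibble `compound_id`, `mae`, `n_predictions`.
#' @export
compound_mae <- function(predictions) {
  stopifnot(all(c("compound_id", "observed", "predicted") %in% names(predictions)),
            nrow(predictions) >= 1)
  predictions |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(mae = stats::median(abs(.data$predicted - .data$observed)),
                     n_predictions = dplyr::n(), .groups = "drop")
}

#' Regression error characteristic (REC) curve
#'
#' Proportion of compounds predicted within an error tolerance, as a
#' function of that tolerance. The curve is non-decreasing and reaches 1
#' when the grid covers the maximum error.
#'
#' @param mae Numeric vector of per-compound errors (log units).
#' @param step Tolerance grid step, log units.
#' @param t_max Upper end of the grid; defaults to `max(mae)` rounded up
#'   to the grid.
#' @return A tibble of class `rec_curve` with columns `tolerance`,
#'   `proportion`.
#' @export
rec_curve <- function(mae, step = 0.01, t_max = NULL) {
  stopifnot(is.numeric(mae), length(mae) >= 1, all(mae >= 0), step > 0)
  if (is.null(t_max)) t_max <- ceiling(max(mae) / step) * step
  grid <- seq(0, t_max, by = step)
  prop <- vapply(grid, function(t) mean(mae <= t), numeric(1))
  out <- tibble::tibble(tolerance = grid, proportion = prop)
  class(out) <- c("rec_curve", class(out))
  out
}

#' Plot a REC curve
#'
#' @param object A [rec_curve()] tibble.
#' @param ... Unused.
#' @method autoplot rec_curve
#' @export
autoplot.rec_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tolerance, y = .data$proportion)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Error tolerance (log units)",
                  y = "Proportion predicted within tolerance") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Stratified error report
#'
#' Splits per-compound errors into strata — ionization charge class, data
#' source, or 1-log-wide solubility bins (left-closed, right-open) — and
#' reports per-stratum MAE distributions and REC curves. Empty strata are
#' reported as empty rather than dropped.
#'
#' @param entries A tibble carrying `mae` plus the stratum attribute:
#'   `charge_class`, `source`, or `solubility` (binned on the fly).
#' @param by One of `"charge_class"`, `"source"`, `"solubility_bin"`.
#' @param rec_step Grid step for the per-stratum REC curves.
#' @return A tibble with one row per stratum: `stratum`, `n`,
#'   `median_mae`, `mean_mae`, and a list-column `rec` of REC curves.
#' @export
stratified_report <- function(entries, by = c("charge_class", "source", "solubility_bin"),
                              rec_step = 0.01) {
  by <- match.arg(by)
  stopifnot("mae" %in% names(entries))
  if (by == "solubility_bin") {
    stopifnot("solubility" %in% names(entries))
    lo <- floor(min(entries$solubility))
    hi <- ceiling(max(entries$solubility))
    if (hi == max(entries$solubility)) hi <- hi + 1  # right-open bins
    breaks <- seq(lo, hi, by = 1)
    entries$stratum <- as.character(cut(entries$solubility, breaks = breaks,
                                        right = FALSE,
                                        labels = sprintf("[%d,%d)", breaks[-length(breaks)],
                                                         breaks[-1])))
    levels_all <- sprintf("[%d,%d)", breaks[-length(breaks)], breaks[-1])
  } else {
    stopifnot(by %in% names(entries))
    entries$stratum <- entries[[by]]
    levels_all <- sort(unique(entries$stratum))
  }
  out <- lapply(levels_all, function(s) {
    sub <- entries[entries$stratum == s, , drop = FALSE]
    tibble::tibble(
      stratum = s, n = nrow(sub),
      median_mae = if (nrow(sub)) stats::median(sub$mae) else NA_real_,
      mean_mae = if (nrow(sub)) mean(sub$mae) else NA_real_,
      rec = list(if (nrow(sub)) rec_curve(sub$mae, step = rec_step) else NULL)
    )
  })
  dplyr::bind_rows(out)
}

#' Hardest-to-predict compounds
#'
#' Top-`k` entries by descending per-compound MAE; ties are broken by
#' lexicographic ID order for deterministic output.
#'
#' @param entries A tibble with `ID` and `mae` columns; any metadata
#'   columns (CAS, LogS, method, remark) are carried through.
#' @param k Number of entries to report.
#' @return The top-`k` rows, ranked.
#' @export
hardest_k <- function(entries, k = 20) {
  stopifnot(all(c("ID", "mae") %in% names(entries)))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(entries)) stop("k exceeds the number of entries", call. = FALSE)
  entries |>
    dplyr::arrange(dplyr::desc(.data$mae), .data$ID) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
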