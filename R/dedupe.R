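# Replicate aggregation. Replicated measurements of one structure are
# grouped by InChIKey; the inter-laboratory standard deviation (SDi, the
# sample standard deviation of the replicate log-solubilities) decides
# between keeping the median and discarding the whole group.

#' Inter-laboratory standard deviation of replicate measurements
#'
#' Sample standard deviation (n-1 denominator) of replicated log10 mol/L
#' values for one compound. A single measurement has no scatter estimate
#' and returns the sentinel `-1`, matching the curated-schema convention.
#'
#' @param values Numeric vector of log10 mol/L measurements, length >= 1.
#' @return SDi in log units, or `-1` when `length(values) == 1`.
#' @examples
#' compute_sdi(c(-2, -3)) # 0.7071...
#' @export
compute_sdi <- function(values) {
  if (length(values) == 0) stop("compute_sdi requires at least one value", call. = FALSE)
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) == 1) return(-1)
  sqrt(sum((values - mean(values))^2) / (length(values) - 1))
}

#' Group accepted records into replicate groups by structure
#'
#' @param accepted A tibble carrying at least `inchikey` and `log_molar`
#'   (the `accepted` component of a `curation_result` qualifies).
#' @return A tibble with one row per InChIKey: list-column `values`, `n`,
#'   `mean`, `median`, `sdi` (sentinel `-1` for single measurements), and
#'   the first-seen `canonical_smiles`/`record_id` carried along when
#'   present.
#' @export
group_replicates <- function(accepted) {
  stopifnot(all(c("inchikey", "log_molar") %in% names(accepted)))
  carry <- intersect(c("record_id", "canonical_smiles", "charge_class",
                       "composition", "source", "group", "inchi"), names(accepted))
  accepted |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(
      values = list(.data$log_molar),
      n = dplyr::n(),
      mean = mean(.data$log_molar),
      median = stats::median(.data$log_molar),
      sdi = compute_sdi(.data$log_molar),
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$inchikey)
}

#' Resolve replicate groups: median or discard
#'
#' A single measurement is kept as-is with SD sentinel `-1`. A replicated
#' group is kept at its median value with `SD = SDi` when the scatter is
#' acceptable (`sdi <= sdi_threshold`, default 0.5 log); otherwise the
#' whole group is discarded — a median over strongly discordant values is
#' meaningless. The even-n median is the mean of the two central values.
#'
#' @param groups Output of [group_replicates()].
#' @param sdi_threshold Discard threshold in log units.
#' @return A tibble with one row per group: `inchikey`, `outcome`
#'   (`"keep"`/`"discard"`), `solubility` (the retained value, `NA` when
#'   discarded), `sd` (`-1`, SDi, or `NA`), `n`, plus carried metadata.
#' @export
resolve_groups <- function(groups, sdi_threshold = 0.5) {
  stopifnot(all(c("inchikey", "values", "n", "median", "sdi") %in% names(groups)))
  keep <- groups$n == 1 | groups$sdi <= sdi_threshold
  dplyr::mutate(groups,
    outcome = ifelse(keep, "keep", "discard"),
    solubility = ifelse(keep, .data$median, NA_real_),
    sd = ifelse(.data$n == 1, -1, ifelse(keep, .data$sdi, NA_real_))
  )
}

#' Assemble curated entries from resolved replicate groups
#'
#' Builds the ten-column curated-entry table (one row per surviving unique
#' structure) that [write_curated()] serializes.
#'
#' @param resolved Output of [resolve_groups()].
#' @return A tibble in the curated-entry schema, kept groups only.
#' @export
as_curated_entries <- function(resolved) {
  kept <- dplyr::filter(resolved, .data$outcome == "keep")
  grab <- function(nm, default) {
    if (nm %in% names(kept)) {
      x <- kept[[nm]]
      ifelse(is.na(x), default, x)
    } else rep(default, nrow(kept))
  }
  tibble::tibble(
    ID = grab("record_id", NA_character_),
    InChI = if ("inchi" %in% names(kept)) ifelse(is.na(kept$inchi), kept$inchikey, kept$inchi) else kept$inchikey,
    Solubility = kept$solubility,
    SMILEScurated = grab("canonical_smiles", NA_character_),
    SD = kept$sd,
    Group = grab("group", "unknown"),
    Dataset = grab("source", "unknown"),
    Composition = grab("composition", "mono"),
    Error = rep("None", nrow(kept)),
    Charge = grab("charge_class", "Uncharged")
  )
}
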