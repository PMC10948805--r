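# The curation decision tree. Filters are evaluated in a fixed order and a
# record's verdict collects every triggered reason; report counts are keyed
# by the FIRST triggered reason so the per-category counts are disjoint.
# Unknown tri-state metadata never fires a filter: records are rejected only
# on positive evidence of a violation.

REASON_CODES <- c("STRUCTURE_INVALID", "MICROSPECIES", "BUFFER_COSOLVENT",
                  "PH_OUT_OF_RANGE", "TEMPERATURE_OUT_OF_RANGE", "COMPOSITION",
                  "UNSTABLE", "BELOW_LOQ", "SUSPICIOUS_ORIGIN", "CALIBRATION")
QC_CODES <- c("METHOD_MISMATCH_OECD", "TEMPERATURE_UNKNOWN")

#' Curation configuration
#'
#' Thresholds of the curation decision tree. Defaults encode the
#' recommended experimental window for thermodynamic solubility used in
#' regression modeling: final pH 7 +/- 1, roughly room temperature
#' (293.15-303.15 K), a degradation half-life (DT50) cutoff of 24 h for
#' methods that equilibrate in hours to days and 7 days (168 h) for the
#' slow-stir method, the OECD 105 10 mg/L shake-flask appropriateness
#' cutoff, and the 0.5 log inter-laboratory standard deviation threshold
#' for replicate groups.
#'
#' @param ph_low,ph_high Inclusive final-pH window.
#' @param temp_low,temp_high Inclusive temperature window, K.
#' @param dt50_fast_cutoff DT50 cutoff (hours) for all methods except
#'   slow-stir.
#' @param dt50_slow_cutoff DT50 cutoff (hours) for slow-stir.
#' @param oecd_mass_cutoff Shake-flask solubility cutoff, mg/L (QC flag
#'   only, never a rejection).
#' @param sdi_threshold Replicate-group SDi discard threshold, log units.
#' @param max_microspecies Maximum tolerated number of microspecies.
#' @param major_fraction_min Minimum fraction for an unambiguous major
#'   microspecies.
#' @return A `curation_config` list.
#' @export
curation_config <- function(ph_low = 6.0, ph_high = 8.0,
                            temp_low = 293.15, temp_high = 303.15,
                            dt50_fast_cutoff = 24, dt50_slow_cutoff = 168,
                            oecd_mass_cutoff = 10, sdi_threshold = 0.5,
                            max_microspecies = 4L, major_fraction_min = 0.5) {
  stopifnot(ph_low < ph_high, temp_low < temp_high,
            dt50_fast_cutoff > 0, dt50_slow_cutoff > 0,
            oecd_mass_cutoff > 0, sdi_threshold > 0)
  structure(list(ph_low = ph_low, ph_high = ph_high, temp_low = temp_low,
                 temp_high = temp_high, dt50_fast_cutoff = dt50_fast_cutoff,
                 dt50_slow_cutoff = dt50_slow_cutoff,
                 oecd_mass_cutoff = oecd_mass_cutoff,
                 sdi_threshold = sdi_threshold,
                 max_microspecies = as.integer(max_microspecies),
                 major_fraction_min = major_fraction_min),
            class = "curation_config")
}

#' Read a curation configuration from a file
#'
#' Accepts a JSON object or a flat `key=value` file (one pair per line,
#' `#` comments allowed); keys mirror the [curation_config()] arguments.
#'
#' @param path Path to the configuration file.
#' @export
read_curation_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    txt <- txt[!grepl("^\\s*(#|$)", txt)]
    kv <- strsplit(txt, "=", fixed = TRUE)
    vals <- stats::setNames(lapply(kv, function(x) as.numeric(trimws(x[2]))),
                            vapply(kv, function(x) trimws(x[1]), character(1)))
  }
  unknown <- setdiff(names(vals), names(formals(curation_config)))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(curation_config, vals)
}

#' Apply the curation decision tree to raw records
#'
#' Evaluates, in fixed order: (1) structure validity, (2) microspecies
#' gate, (3) buffer/cosolvent/surfactant present, (4) final pH known and
#' outside the window (initial pH is consulted only when the final pH is
#' absent), (5) temperature known and outside the window, (6) composition
#' multi-constituent or UVCB, (7) instability (DT50 known and below the
#' method-dependent cutoff), (8) below LOQ, (9) origin averaged/predicted,
#' (10) recorded calibration bias. All triggered reasons are collected;
#' `first_reason` attributes the record to one disjoint category.
#' Unknown tri-state metadata never triggers. Two QC flags that never
#' cause rejection are set: `METHOD_MISMATCH_OECD` for shake-flask
#' measurements below the OECD 10 mg/L cutoff, and `TEMPERATURE_UNKNOWN`.
#'
#' @param records Raw-record tibble (see [read_raw_records()]).
#' @param config A [curation_config()].
#' @param profiles Optional named list of [microspecies_profile()] objects
#'   keyed by `record_id`.
#' @return A tibble of per-record decisions: `record_id`, `verdict`
#'   (`"accept"`/`"reject"`), `first_reason`, list-columns `reasons` and
#'   `qc_flags`, plus the standardized structure fields used downstream
#'   (`log_molar`, `canonical_smiles`, `inchikey`, `charge_class`,
#'   `charge_ratio`).
#' @export
curate_records <- function(records, config = curation_config(), profiles = NULL) {
  validate_raw_records(records)
  n <- nrow(records)
  std_in <- standardize_structure(records$smiles, strict = FALSE)

  # microspecies gate; the accepted structure may be replaced by the major
  # microspecies of the supplied profile
  gate_reason <- rep(NA_character_, n)
  final_smiles <- std_in$canonical_smiles
  major <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!std_in$valid[i]) next
    prof <- profiles[[records$record_id[i]]]
    g <- gate_microspecies(prof, config$max_microspecies, config$major_fraction_min)
    if (g$status == "reject") gate_reason[i] <- g$reason
    else if (!is.na(g$structure)) major[i] <- g$structure
  }
  has_major <- !is.na(major)
  if (any(has_major)) {
    std_major <- standardize_structure(major[has_major], strict = FALSE)
    final_smiles[has_major] <- std_major$canonical_smiles
  }
  # standardize the final (major-species) structures in one batch
  final_ok <- !is.na(final_smiles)
  std_final <- standardize_structure(ifelse(final_ok, final_smiles, "C"), strict = FALSE)
  mw <- ifelse(!is.na(records$mw), records$mw, std_final$mw)
  log_molar <- rep(NA_real_, n)
  convertible <- std_in$valid &
    !(records$value_units %in% c("mg_per_L", "g_per_L") & (is.na(mw) | mw <= 0)) &
    !(records$value_units != "log_molar" & records$value <= 0)
  if (any(convertible)) {
    log_molar[convertible] <- to_log_molar(records$value[convertible],
                                           records$value_units[convertible],
                                           mw[convertible])
  }

  ph_eff <- ifelse(!is.na(records$ph_final), records$ph_final, records$ph_initial)
  dt50_cut <- ifelse(records$method == "slow_stir",
                     config$dt50_slow_cutoff, config$dt50_fast_cutoff)

  trig <- list(
    STRUCTURE_INVALID = !std_in$valid,
    MICROSPECIES = !is.na(gate_reason),
    BUFFER_COSOLVENT = records$has_buffer == "true" |
      records$has_cosolvent == "true" | records$has_surfactant == "true",
    PH_OUT_OF_RANGE = !is.na(ph_eff) &
      (ph_eff < config$ph_low | ph_eff > config$ph_high),
    TEMPERATURE_OUT_OF_RANGE = !is.na(records$temperature) &
      (records$temperature < config$temp_low | records$temperature > config$temp_high),
    COMPOSITION = records$composition %in% c("multi", "UVCB"),
    UNSTABLE = !is.na(records$dt50_hours) & records$dt50_hours < dt50_cut,
    BELOW_LOQ = records$below_loq == "true",
    SUSPICIOUS_ORIGIN = records$origin %in% c("averaged", "predicted"),
    CALIBRATION = records$calibration_issue == "true"
  )
  trig_mat <- do.call(cbind, trig)
  reasons <- apply(trig_mat, 1, function(row) REASON_CODES[row], simplify = FALSE)
  first_reason <- vapply(reasons, function(r) if (length(r)) r[1] else NA_character_,
                         character(1))

  mg_per_l <- 10^log_molar * mw * 1000
  qc_oecd <- records$method == "shake_flask" & !is.na(mg_per_l) &
    mg_per_l < config$oecd_mass_cutoff
  qc_temp <- is.na(records$temperature)
  qc_flags <- purrr::map2(qc_oecd, qc_temp, function(a, b) {
    QC_CODES[c(a, b)]
  })

  charge <- classify_charge(std_final$formal_charges)
  tibble::tibble(
    record_id = records$record_id,
    verdict = ifelse(is.na(first_reason), "accept", "reject"),
    first_reason = first_reason,
    reasons = reasons,
    qc_flags = qc_flags,
    log_molar = log_molar,
    canonical_smiles = ifelse(final_ok, std_final$canonical_smiles, NA_character_),
    inchikey = ifelse(final_ok, std_final$inchikey, NA_character_),
    mw = ifelse(final_ok, mw, NA_real_),
    charge_class = ifelse(final_ok, charge$charge_class, NA_character_),
    charge_ratio = ifelse(final_ok, charge$charge_ratio, NA_real_)
  )
}

#' Curate a raw record dataset
#'
#' Partitions records into accepted and rejected by the decision tree (see
#' [curate_records()]) and tallies a report whose per-reason counts are
#' keyed by the first triggered reason, so that categories are disjoint and
#' sum to the number of rejected records.
#'
#' @inheritParams curate_records
#' @return A `curation_result` object: list with `accepted` (raw records
#'   joined with structure fields), `decisions` (the full per-record
#'   trace), `report` (totals, per-reason and per-QC-flag counts) and
#'   `config`.
#' @export
curate_dataset <- function(records, config = curation_config(), profiles = NULL) {
  if (nrow(records) == 0) {
    decisions <- tibble::tibble(record_id = character(0), verdict = character(0),
                                first_reason = character(0), reasons = list(),
                                qc_flags = list(), log_molar = numeric(0),
                                canonical_smiles = character(0),
                                inchikey = character(0), mw = numeric(0),
                                charge_class = character(0), charge_ratio = numeric(0))
  } else {
    decisions <- curate_records(records, config, profiles)
  }
  reason_counts <- stats::setNames(integer(length(REASON_CODES)), REASON_CODES)
  tab <- table(factor(decisions$first_reason, levels = REASON_CODES))
  reason_counts[names(tab)] <- as.integer(tab)
  qc_counts <- stats::setNames(integer(length(QC_CODES)), QC_CODES)
  qtab <- table(factor(unlist(decisions$qc_flags), levels = QC_CODES))
  qc_counts[names(qtab)] <- as.integer(qtab)
  report <- list(
    input = nrow(decisions),
    accepted = sum(decisions$verdict == "accept"),
    rejected = sum(decisions$verdict == "reject"),
    reasons = as.list(reason_counts),
    qc_flags = as.list(qc_counts)
  )
  accepted <- dplyr::inner_join(
    tibble::as_tibble(records),
    dplyr::select(dplyr::filter(decisions, .data$verdict == "accept"),
                  "record_id", "log_molar", "canonical_smiles", "inchikey",
                  "mw_std" = "mw", "charge_class", "charge_ratio"),
    by = "record_id")
  structure(list(accepted = accepted, decisions = decisions,
                 report = report, config = config),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("<curation_result>\n")
  cat("  records:", x$report$input, " accepted:", x$report$accepted,
      " rejected:", x$report$rejected, "\n")
  nz <- Filter(function(v) v > 0, x$report$reasons)
  if (length(nz)) {
    cat("  first-reason counts:\n")
    for (nm in names(nz)) cat("    ", nm, ": ", nz[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-record curation trace
#'
#' @param x A `curation_result`.
#' @param ... Unused.
#' @return The per-record decision tibble with reasons collapsed to a
#'   `;`-separated string.
#' @method tidy curation_result
#' @export
tidy.curation_result <- function(x, ...) {
  dplyr::mutate(x$decisions,
                reasons = vapply(.data$reasons, paste, character(1), collapse = ";"),
                qc_flags = vapply(.data$qc_flags, paste, character(1), collapse = ";"))
}

#' One-row summary of a curation run
#'
#' @param x A `curation_result`.
#' @param ... Unused.
#' @method glance curation_result
#' @export
glance.curation_result <- function(x, ...) {
  tibble::tibble(input = x$report$input, accepted = x$report$accepted,
                 rejected = x$report$rejected)
}

#' Write the curation report and per-record trace
#'
#' The report is a JSON object
#' `{input, accepted, rejected, reasons: {code: count}, qc_flags: {code: count}}`;
#' the optional trace is a JSON-lines log with one decision per line.
#'
#' @param result A `curation_result`.
#' @param path Output path for the JSON report.
#' @param trace_path Optional output path for the JSON-lines per-record
#'   trace.
#' @export
write_curation_report <- function(result, path, trace_path = NULL) {
  stopifnot(inherits(result, "curation_result"))
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(trace_path)) {
    lines <- vapply(seq_len(nrow(result$decisions)), function(i) {
      d <- result$decisions[i, ]
      jsonlite::toJSON(list(record_id = d$record_id, verdict = d$verdict,
                            reasons = d$reasons[[1]], qc_flags = d$qc_flags[[1]]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, trace_path)
  }
  invisible(path)
}

#' Split a dataset against a reference by structure identity
#'
#' Divides dataset `b` into the subset sharing a standardized structure
#' (InChIKey of the major microspecies) with reference dataset `a`, and the
#' subset specific to `b`. Shared and specific are disjoint and their union
#' is `b`.
#'
#' @param b,a Tibbles with either an `inchikey` column or a `smiles`
#'   column (standardized on the fly).
#' @return A list with tibbles `shared` and `specific`.
#' @export
split_against_reference <- function(b, a) {
  key <- function(df) {
    if ("inchikey" %in% names(df)) return(df$inchikey)
    standardize_structure(df$smiles)$inchikey
  }
  kb <- key(b); ka <- key(a)
  list(shared = b[kb %in% ka, , drop = FALSE],
       specific = b[!kb %in% ka, , drop = FALSE])
}
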