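# Raw-record table model. Solubility is held internally only as log10 mol/L;
# every other unit is converted at ingest so no downstream stage mixes units.

VALUE_UNITS <- c("log_molar", "mol_per_L", "mg_per_L", "g_per_L")
COMPOSITIONS <- c("mono", "multi", "UVCB", "unknown")
METHODS <- c("shake_flask", "column_elution", "slow_stir", "cheqsol",
             "qsar_predicted", "not_specified")
ORIGINS <- c("measured", "averaged", "predicted", "unknown")
TRISTATE <- c("true", "false", "unknown")

# Optional metadata columns with their defaults; anything absent from an
# input CSV is filled with these (tri-states default to "unknown": a filter
# only ever fires on positive evidence of a violation).
RAW_OPTIONAL <- list(
  inchi = NA_character_, cas = NA_character_, mw = NA_real_,
  temperature = NA_real_, ph_initial = NA_real_, ph_final = NA_real_,
  has_buffer = "unknown", has_cosolvent = "unknown", has_surfactant = "unknown",
  composition = "unknown", method = "not_specified", below_loq = "unknown",
  origin = "unknown", dt50_hours = NA_real_, source = NA_character_,
  calibration_issue = "unknown", pka_list = NA_character_,
  pkb_list = NA_character_, group = NA_character_
)

as_tristate <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x) | x == ""] <- "unknown"
  bad <- !x %in% TRISTATE
  if (any(bad)) stop("tri-state field must be true/false/unknown, got: ",
                     paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

#' Read a raw solubility record table
#'
#' Reads a CSV of reported solubility measurements into the raw-record
#' schema. Required columns: `record_id`, `smiles`, `value`, `value_units`.
#' All metadata columns are optional; missing tri-state metadata
#' (`has_buffer`, `has_cosolvent`, `has_surfactant`, `below_loq`,
#' `calibration_issue`) defaults to `"unknown"`, which never triggers a
#' rejection filter downstream. Row order is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble of raw records, one row per input row.
#' @export
read_raw_records <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("record_id", "smiles", "value", "value_units")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in names(RAW_OPTIONAL)) {
    if (!nm %in% names(df)) df[[nm]] <- RAW_OPTIONAL[[nm]]
  }
  num <- function(col) {
    x <- df[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(out)
    if (any(bad)) {
      stop("unparsable number in column '", col, "' for record_id: ",
           paste(df$record_id[bad], collapse = ", "), call. = FALSE)
    }
    out
  }
  out <- tibble::tibble(
    record_id = df$record_id,
    smiles = df$smiles,
    inchi = df$inchi,
    cas = df$cas,
    value = num("value"),
    value_units = df$value_units,
    mw = num("mw"),
    temperature = num("temperature"),
    ph_initial = num("ph_initial"),
    ph_final = num("ph_final"),
    has_buffer = as_tristate(df$has_buffer),
    has_cosolvent = as_tristate(df$has_cosolvent),
    has_surfactant = as_tristate(df$has_surfactant),
    composition = ifelse(is.na(df$composition) | df$composition == "",
                         "unknown", df$composition),
    method = ifelse(is.na(df$method) | df$method == "",
                    "not_specified", df$method),
    below_loq = as_tristate(df$below_loq),
    origin = ifelse(is.na(df$origin) | df$origin == "", "unknown", df$origin),
    dt50_hours = num("dt50_hours"),
    source = df$source,
    calibration_issue = as_tristate(df$calibration_issue),
    pka_list = df$pka_list,
    pkb_list = df$pkb_list,
    group = df$group
  )
  validate_raw_records(out)
  out
}

validate_raw_records <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("record_id", "smiles", "value", "value_units")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$value))) {
    stop("non-finite value for record_id: ",
         paste(records$record_id[!is.finite(records$value)], collapse = ", "),
         call. = FALSE)
  }
  bad_units <- !records$value_units %in% VALUE_UNITS
  if (any(bad_units)) {
    stop("unknown value_units: ",
         paste(unique(records$value_units[bad_units]), collapse = ", "), call. = FALSE)
  }
  bad_comp <- !records$composition %in% COMPOSITIONS
  if (any(bad_comp)) {
    stop("unknown composition: ",
         paste(unique(records$composition[bad_comp]), collapse = ", "), call. = FALSE)
  }
  bad_meth <- !records$method %in% METHODS
  if (any(bad_meth)) {
    stop("unknown method: ",
         paste(unique(records$method[bad_meth]), collapse = ", "), call. = FALSE)
  }
  bad_orig <- !records$origin %in% ORIGINS
  if (any(bad_orig)) {
    stop("unknown origin: ",
         paste(unique(records$origin[bad_orig]), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Convert a solubility value to log10 molar units
#'
#' @param value Numeric vector of reported values. Must be positive for the
#'   non-logarithmic units.
#' @param units One of `"log_molar"`, `"mol_per_L"`, `"mg_per_L"`,
#'   `"g_per_L"` (recycled if length 1).
#' @param mw Molecular weight in g/mol; required for the mass-based units.
#' @return log10 of the molar concentration. `log_molar` input is returned
#'   unchanged.
#' @examples
#' to_log_molar(1, "mol_per_L") # 0
#' to_log_molar(10, "mg_per_L", mw = 100) # -4
#' @export
to_log_molar <- function(value, units, mw = NA_real_) {
  n <- max(length(value), length(units), length(mw))
  value <- rep_len(value, n); units <- rep_len(units, n); mw <- rep_len(mw, n)
  bad <- !units %in% VALUE_UNITS
  if (any(bad)) stop("unknown value_units: ", paste(unique(units[bad]), collapse = ", "),
                     call. = FALSE)
  nonlog <- units != "log_molar"
  if (any(nonlog & (!is.finite(value) | value <= 0))) {
    stop("value must be positive for non-log units", call. = FALSE)
  }
  mass <- units %in% c("mg_per_L", "g_per_L")
  if (any(mass & (is.na(mw) | mw <= 0))) {
    stop("molecular weight (mw > 0) required to convert mass-based units", call. = FALSE)
  }
  molar <- ifelse(units == "mol_per_L", value,
           ifelse(units == "g_per_L", value / mw,
           ifelse(units == "mg_per_L", value / 1000 / mw, NA_real_)))
  ifelse(units == "log_molar", value, log10(molar))
}

#' Convert a log10 molar solubility back to a reporting unit
#'
#' Inverse of [to_log_molar()]; used by the synthetic generator to encode
#' ground-truth values in mixed units.
#'
#' @inheritParams to_log_molar
#' @param log_molar Numeric vector, log10 mol/L.
#' @export
from_log_molar <- function(log_molar, units, mw = NA_real_) {
  n <- max(length(log_molar), length(units), length(mw))
  log_molar <- rep_len(log_molar, n); units <- rep_len(units, n); mw <- rep_len(mw, n)
  molar <- 10^log_molar
  out <- ifelse(units == "log_molar", log_molar,
         ifelse(units == "mol_per_L", molar,
         ifelse(units == "g_per_L", molar * mw,
         ifelse(units == "mg_per_L", molar * mw * 1000, NA_real_))))
  if (any(is.na(out) & !is.na(log_molar))) stop("unknown value_units", call. = FALSE)
  out
}

CURATED_COLUMNS <- c("ID", "InChI", "Solubility", "SMILEScurated", "SD",
                     "Group", "Dataset", "Composition", "Error", "Charge")
CHARGE_CLASSES <- c("Positive", "Negative", "Zwitterion", "Uncharged")

validate_curated <- function(entries) {
  missing <- setdiff(CURATED_COLUMNS, names(entries))
  if (length(missing) > 0) {
    stop("curated entries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(entries$ID)) {
    dup <- unique(entries$ID[duplicated(entries$ID)])
    stop("duplicate ID in curated entries: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_sd <- !(entries$SD >= 0 | entries$SD == -1)
  if (nrow(entries) > 0 && any(bad_sd)) {
    stop("SD must be >= 0 or the sentinel -1", call. = FALSE)
  }
  if (nrow(entries) > 0 && any(!entries$Charge %in% CHARGE_CLASSES)) {
    stop("Charge must be one of ", paste(CHARGE_CLASSES, collapse = ", "), call. = FALSE)
  }
  invisible(entries)
}

#' Write curated entries in the ten-column curated-dataset schema
#'
#' Emits exactly the columns `ID, InChI, Solubility, SMILEScurated, SD,
#' Group, Dataset, Composition, Error, Charge` in that order. A single
#' measurement carries the SD sentinel `-1`. The file round-trips
#' losslessly through [read_curated()].
#'
#' @param entries A tibble of curated entries (one row per unique
#'   structure).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curated <- function(entries, path) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0 && length(names(entries)) == 0) {
    entries <- tibble::as_tibble(stats::setNames(
      as.list(c(rep(list(character(0)), 2), list(numeric(0)), list(character(0)),
                list(numeric(0)), rep(list(character(0)), 5))), CURATED_COLUMNS))
  }
  validate_curated(entries)
  readr::write_csv(entries[CURATED_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Read a curated-schema CSV
#'
#' @param path Path to a CSV written by [write_curated()] (or any file in
#'   the same ten-column schema).
#' @return A tibble of curated entries.
#' @export
read_curated <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    ID = readr::col_character(), InChI = readr::col_character(),
    Solubility = readr::col_double(), SMILEScurated = readr::col_character(),
    SD = readr::col_double(), Group = readr::col_character(),
    Dataset = readr::col_character(), Composition = readr::col_character(),
    Error = readr::col_character(), Charge = readr::col_character()
  ), progress = FALSE)
  validate_curated(df)
  df
}
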