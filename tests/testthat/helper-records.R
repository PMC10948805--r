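# A clean raw record that passes every filter; override fields per test.
clean_record <- function(record_id = "R1", smiles = "CCO", value = -1.0,
                         value_units = "log_molar", ...) {
  base <- tibble::tibble(
    record_id = record_id, smiles = smiles, inchi = NA_character_,
    cas = NA_character_, value = value, value_units = value_units,
    mw = 46.07, temperature = 298.15, ph_initial = 7.0, ph_final = 7.0,
    has_buffer = "false", has_cosolvent = "false", has_surfactant = "false",
    composition = "mono", method = "shake_flask", below_loq = "false",
    origin = "measured", dt50_hours = NA_real_, source = "LabA",
    calibration_issue = "false", pka_list = NA_character_,
    pkb_list = NA_character_, group = "test"
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

clean_records <- function(n, smiles) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    clean_record(record_id = sprintf("R%03d", i),
                 smiles = smiles[(i - 1) %% length(smiles) + 1])
  }))
}
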