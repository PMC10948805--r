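test_that("each decision-tree filter fires on its planted violation", {
  cases <- list(
    list(rec = clean_record(has_buffer = "true"), reason = "BUFFER_COSOLVENT"),
    list(rec = clean_record(has_surfactant = "true"), reason = "BUFFER_COSOLVENT"),
    list(rec = clean_record(ph_final = 9.1), reason = "PH_OUT_OF_RANGE"),
    list(rec = clean_record(ph_final = NA_real_, ph_initial = 4.0),
         reason = "PH_OUT_OF_RANGE"),
    list(rec = clean_record(temperature = 330), reason = "TEMPERATURE_OUT_OF_RANGE"),
    list(rec = clean_record(composition = "UVCB"), reason = "COMPOSITION"),
    list(rec = clean_record(composition = "multi"), reason = "COMPOSITION"),
    list(rec = clean_record(method = "shake_flask", dt50_hours = 10),
         reason = "UNSTABLE"),
    list(rec = clean_record(below_loq = "true"), reason = "BELOW_LOQ"),
    list(rec = clean_record(origin = "averaged"), reason = "SUSPICIOUS_ORIGIN"),
    list(rec = clean_record(origin = "predicted"), reason = "SUSPICIOUS_ORIGIN"),
    list(rec = clean_record(calibration_issue = "true"), reason = "CALIBRATION"),
    list(rec = clean_record(smiles = "C1CC("), reason = "STRUCTURE_INVALID")
  )
  for (case in cases) {
    d <- curate_records(case$rec)
    expect_equal(d$verdict, "reject", info = case$reason)
    expect_equal(d$reasons[[1]], case$reason, info = case$reason)
  }
})

test_that("boundary and method-dependent rules behave as specified", {
  # pH window is inclusive at both ends
  expect_equal(curate_records(clean_record(ph_final = 6.0))$verdict, "accept")
  expect_equal(curate_records(clean_record(ph_final = 8.0))$verdict, "accept")
  expect_equal(curate_records(clean_record(ph_final = 5.999))$verdict, "reject")
  # initial pH is consulted only when final pH is absent
  expect_equal(curate_records(clean_record(ph_final = 7.0, ph_initial = 3.0))$verdict,
               "accept")
  # slow-stir equilibrates over weeks: its DT50 cutoff is 7 days
  expect_equal(curate_records(clean_record(method = "slow_stir", dt50_hours = 100))$verdict,
               "reject")
  expect_equal(curate_records(clean_record(method = "shake_flask", dt50_hours = 100))$verdict,
               "accept")
})

test_that("a poorly soluble shake-flask record is retained with the OECD flag", {
  rec <- clean_record(value = -9, mw = 300, method = "shake_flask")
  d <- curate_records(rec)
  expect_equal(d$verdict, "accept")
  expect_true("METHOD_MISMATCH_OECD" %in% d$qc_flags[[1]])
  # temperature unknown is a flag, never a rejection
  d2 <- curate_records(clean_record(temperature = NA_real_))
  expect_equal(d2$verdict, "accept")
  expect_true("TEMPERATURE_UNKNOWN" %in% d2$qc_flags[[1]])
})

test_that("unknown metadata never changes a clean record's verdict", {
  rec <- clean_record()
  expect_equal(curate_records(rec)$verdict, "accept")
  for (fld in c("has_buffer", "has_cosolvent", "has_surfactant", "below_loq",
                "calibration_issue")) {
    mod <- rec; mod[[fld]] <- "unknown"
    expect_equal(curate_records(mod)$verdict, "accept", info = fld)
  }
  for (fld in c("temperature", "ph_final", "ph_initial", "dt50_hours")) {
    mod <- rec; mod[[fld]] <- NA_real_
    expect_equal(curate_records(mod)$verdict, "accept", info = fld)
  }
  mod <- rec; mod$composition <- "unknown"; mod$origin <- "unknown"
  expect_equal(curate_records(mod)$verdict, "accept")
})

test_that("multiple violations collect all reasons but count once, in order", {
  rec <- clean_record(has_buffer = "true", composition = "UVCB")
  res <- curate_dataset(rec)
  d <- res$decisions
  expect_equal(d$reasons[[1]], c("BUFFER_COSOLVENT", "COMPOSITION"))
  expect_equal(d$first_reason, "BUFFER_COSOLVENT")
  expect_equal(res$report$reasons$BUFFER_COSOLVENT, 1)
  expect_equal(res$report$reasons$COMPOSITION, 0)
})

test_that("report totals are consistent and empty input yields a zero report", {
  recs <- dplyr::bind_rows(
    clean_records(5, c("CCO", "CCC", "c1ccccc1", "CCN", "CCOC")),
    clean_record("B1", has_buffer = "true"),
    clean_record("B2", composition = "multi", smiles = "CCCC")
  )
  res <- curate_dataset(recs)
  expect_equal(res$report$input, res$report$accepted + res$report$rejected)
  expect_equal(sum(unlist(res$report$reasons)), res$report$rejected)
  expect_equal(glance(res)$accepted, 5)
  empty <- curate_dataset(clean_record()[0, ])
  expect_equal(empty$report$input, 0)
  expect_equal(sum(unlist(empty$report$reasons)), 0)
})

test_that("the accept/reject partition is independent of attribution order", {
  # every record rejected for >= 1 reason is rejected no matter which filter
  # is consulted first; verify by recomputing the verdict from the full
  # reason set rather than the first-reason shortcut
  recs <- dplyr::bind_rows(
    clean_record("M1", has_buffer = "true", below_loq = "true"),
    clean_record("M2", composition = "UVCB", origin = "predicted"),
    clean_record("M3")
  )
  d <- curate_records(recs)
  expect_equal(d$verdict, ifelse(lengths(d$reasons) > 0, "reject", "accept"))
})

test_that("curation report JSON round-trips with the documented schema", {
  res <- curate_dataset(dplyr::bind_rows(clean_record(),
                                         clean_record("R2", has_buffer = "true")))
  path <- withr::local_tempfile(fileext = ".json")
  trace <- withr::local_tempfile(fileext = ".jsonl")
  write_curation_report(res, path, trace)
  back <- jsonlite::read_json(path)
  expect_equal(back$input, 2)
  expect_equal(back$reasons$BUFFER_COSOLVENT, 1)
  expect_named(back, c("input", "accepted", "rejected", "reasons", "qc_flags"))
  expect_equal(length(readLines(trace)), 2)
})

test_that("configuration files override defaults and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# window override", "ph_low=5.5", "ph_high=8.5"), path)
  cfg <- read_curation_config(path)
  expect_equal(cfg$ph_low, 5.5)
  expect_equal(cfg$sdi_threshold, 0.5)
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sdi_threshold": 0.4}', jpath)
  expect_equal(read_curation_config(jpath)$sdi_threshold, 0.4)
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("phh_low=5", bad)
  expect_error(read_curation_config(bad), "phh_low")
})

test_that("splitting against a reference respects structure identity", {
  a <- tibble::tibble(smiles = c("CCO", "c1ccccc1"))
  b_sub <- tibble::tibble(smiles = c("OCC"))
  sp <- split_against_reference(b_sub, a)
  expect_equal(nrow(sp$specific), 0)
  b_dis <- tibble::tibble(smiles = c("CCN", "CCC"))
  sp <- split_against_reference(b_dis, a)
  expect_equal(nrow(sp$shared), 0)
  b_mix <- tibble::tibble(smiles = c("OCC", "Oc1ccccc1"))
  sp <- split_against_reference(b_mix, a)
  expect_equal(sp$shared$smiles, "OCC")
  expect_equal(sp$specific$smiles, "Oc1ccccc1")
  expect_equal(nrow(sp$shared) + nrow(sp$specific), nrow(b_mix))
})
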