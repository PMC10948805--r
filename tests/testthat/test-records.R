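test_that("read_raw_records parses required columns and defaults the rest", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,smiles,value,value_units,has_buffer",
    "A1,CCO,-1.5,log_molar,true",
    "A2,CCC,-2.0,log_molar,",
    "A3,c1ccccc1,0.5,mol_per_L,false"
  ), path)
  rec <- read_raw_records(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$record_id, c("A1", "A2", "A3"))  # row order preserved
  expect_equal(rec$has_buffer, c("true", "unknown", "false"))
  expect_equal(rec$has_cosolvent, rep("unknown", 3))
  expect_equal(rec$method, rep("not_specified", 3))
  expect_equal(rec$origin, rep("unknown", 3))
})

test_that("read_raw_records rejects malformed input with named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,smiles,value_units", "A1,CCO,log_molar"), path)
  expect_error(read_raw_records(path), "value")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,smiles,value,value_units",
               "A1,CCO,oops,log_molar"), path2)
  expect_error(read_raw_records(path2), "A1")
})

test_that("to_log_molar converts every unit and validates its domain", {
  expect_equal(to_log_molar(1.0, "mol_per_L"), 0.0)
  expect_equal(to_log_molar(10, "mg_per_L", mw = 100), -4.0)
  expect_equal(to_log_molar(-2.5, "log_molar"), -2.5)
  expect_equal(to_log_molar(1, "g_per_L", mw = 100), -2.0)
  expect_error(to_log_molar(10, "mg_per_L"), "mw")
  expect_error(to_log_molar(-1, "mol_per_L"), "positive")
  expect_error(to_log_molar(1, "furlongs"), "value_units")
})

test_that("unit conversion is strictly increasing and invertible", {
  set.seed(11)
  for (units in c("mol_per_L", "mg_per_L", "g_per_L", "log_molar")) {
    v <- sort(stats::runif(50, 0.001, 500))
    if (units == "log_molar") v <- sort(stats::rnorm(50, -4, 2))
    logm <- to_log_molar(v, units, mw = 180.2)
    expect_true(all(diff(logm) > 0))
    back <- from_log_molar(logm, units, mw = 180.2)
    expect_equal(back, v, tolerance = 1e-9)
  }
  # round trip in log space is tight
  logs <- stats::rnorm(100, -5, 2.5)
  for (units in c("mol_per_L", "mg_per_L", "g_per_L")) {
    again <- to_log_molar(from_log_molar(logs, units, mw = 250), units, mw = 250)
    expect_equal(again, logs, tolerance = 1e-9)
  }
})

test_that("write_curated emits the exact schema and round-trips", {
  entries <- tibble::tibble(
    ID = c("A-1", "A-2"), InChI = c("KEYONE-UHFFFAOYSA-N", "KEYTWO-UHFFFAOYSA-N"),
    Solubility = c(-2.25, -5.0), SMILEScurated = c("CCO", "c1ccccc1"),
    SD = c(0.21, -1), Group = c("G1", "G5"), Dataset = c("LabA", "LabB"),
    Composition = c("mono", "mono"), Error = c("None", "None"),
    Charge = c("Uncharged", "Uncharged"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curated(entries, path)
  expect_identical(readLines(path, n = 1),
                   "ID,InChI,Solubility,SMILEScurated,SD,Group,Dataset,Composition,Error,Charge")
  # single measurement carries the SD sentinel -1 in the file itself
  expect_match(grep("A-2", readLines(path), value = TRUE), ",-1,")
  back <- read_curated(path)
  expect_equal(as.data.frame(back), as.data.frame(entries))
})

test_that("write_curated handles the empty list and rejects duplicate IDs", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_curated(tibble::tibble(), path)
  expect_equal(length(readLines(path)), 1)  # header only
  dup <- tibble::tibble(ID = c("X", "X"), InChI = c("a", "b"),
                        Solubility = c(-1, -2), SMILEScurated = c("C", "CC"),
                        SD = c(-1, -1), Group = c("g", "g"),
                        Dataset = c("d", "d"), Composition = c("mono", "mono"),
                        Error = c("None", "None"),
                        Charge = c("Uncharged", "Uncharged"))
  expect_error(write_curated(dup, path), "X")
})
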