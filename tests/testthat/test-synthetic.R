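test_that("pool generation is deterministic and spans the charge classes", {
  cfg <- synthetic_config(n_compounds = 60, seed = 17)
  p1 <- generate_pool(cfg)
  p2 <- generate_pool(cfg)
  expect_equal(dplyr::select(p1, -"profile"), dplyr::select(p2, -"profile"))
  expect_equal(nrow(p1), 60)
  expect_false(anyDuplicated(p1$smiles) > 0)
  # classifying the pool structures at pH 7 reproduces the library labels
  std <- standardize_structure(p1$smiles)
  cls <- classify_charge(std$formal_charges)$charge_class
  expect_equal(cls, p1$charge_class)
  full <- generate_pool(synthetic_config(n_compounds = 225, seed = 1))
  expect_setequal(unique(full$charge_class),
                  c("Uncharged", "Zwitterion", "Positive", "Negative"))
  # glycine-like template: both groups ionized at pH 7
  gly <- standardize_structure("[NH3+]CC(=O)[O-]")
  expect_equal(classify_charge(gly$formal_charges)$charge_class, "Zwitterion")
  # quaternary ammonium template
  quat <- standardize_structure("C[N+](C)(C)C")
  expect_equal(classify_charge(quat$formal_charges)$charge_class, "Positive")
})

test_that("a clean noiseless population passes curation losslessly", {
  cfg <- synthetic_config(n_compounds = 40, replicates = 2, noise_sd = 0,
                          corruption_rates = c(buffer = 0),
                          high_scatter_fraction = 0, seed = 5)
  pool <- generate_pool(cfg)
  gen <- generate_records(pool, cfg)
  out <- curate_solubility_data(gen$records, profiles = gen$profiles)
  expect_equal(out$result$report$rejected, 0)
  expect_equal(nrow(out$entries), 40)
  # post-dedup values equal the true logS exactly (up to unit round trip)
  key <- standardize_structure(pool$smiles)$inchikey
  got <- out$entries$Solubility[match(key, out$entries$InChI)]
  expect_equal(got, pool$true_logs, tolerance = 1e-9)
})

test_that("exact-count corruption plants exactly the configured counts", {
  cfg <- synthetic_config(n_compounds = 100, replicates = 1,
                          corruption_rates = c(buffer = 0.1),
                          high_scatter_fraction = 0, seed = 23)
  gen <- generate_records(generate_pool(cfg), cfg)
  exp_rep <- expected_report(gen$labels)
  expect_equal(exp_rep$report$reasons$BUFFER_COSOLVENT, 10)
  expect_equal(exp_rep$report$rejected, 10)
  res <- curate_dataset(gen$records, profiles = gen$profiles)
  expect_equal(res$report$reasons$BUFFER_COSOLVENT, 10)
  expect_equal(res$report$accepted, 90)
})

test_that("the planted high-scatter fraction is discarded exactly", {
  cfg <- synthetic_config(n_compounds = 200, replicates = 3,
                          corruption_rates = c(buffer = 0),
                          high_scatter_fraction = 0.05, seed = 29)
  gen <- generate_records(generate_pool(cfg), cfg)
  out <- curate_solubility_data(gen$records, profiles = gen$profiles)
  expect_equal(sum(out$resolved$outcome == "discard"), 10)
  expect_equal(sum(gen$labels$groups$outcome == "discard"), 10)
})

test_that("replicate scatter reproduces the bias-corrected SDi expectation", {
  # E[SDi] = sigma * c4(n); for n = 5, c4 = sqrt(2/4) * gamma(2.5) / gamma(2)
  c4 <- sqrt(2 / 4) * gamma(5 / 2) / gamma(2)
  sdis <- unlist(lapply(1:3, function(seed) {
    cfg <- synthetic_config(n_compounds = 200, replicates = 5, noise_sd = 0.3,
                            corruption_rates = c(buffer = 0),
                            high_scatter_fraction = 0, mode = "bernoulli",
                            seed = seed)
    gen <- generate_records(generate_pool(cfg), cfg)
    gen$labels$groups$sdi
  }))
  expect_gte(length(sdis), 500)
  expect_equal(mean(sdis), 0.3 * c4, tolerance = 0.05)
})

test_that("the generating fragment model is recoverable after curation only", {
  cfg <- synthetic_config(n_compounds = 150, replicates = 1, noise_sd = 0.2,
                          corruption_rates = c(origin = 0.15),
                          high_scatter_fraction = 0, seed = 37)
  pool <- generate_pool(cfg)
  gen <- generate_records(pool, cfg)
  out <- curate_solubility_data(gen$records, profiles = gen$profiles)
  # curated entries: regression on fragment counts recovers the model
  std_key <- standardize_structure(pool$smiles)$inchikey
  fit_r2 <- function(entries_key, values) {
    idx <- match(entries_key, std_key)
    x <- vectorize_dataset(pool$smiles[idx])$matrix
    fit <- fit_fragment_model(x, values, lambda = 1e-3)
    r2(values, predict(fit, x))
  }
  r2_cur <- fit_r2(out$entries$InChI, out$entries$Solubility)
  expect_gte(r2_cur, 0.95)
  # same records without curation: corrupted values degrade the fit
  raw_groups <- gen$records |>
    dplyr::mutate(inchikey = standardize_structure(smiles, strict = FALSE)$inchikey,
                  log_molar = to_log_molar(value, value_units, mw)) |>
    dplyr::group_by(inchikey) |>
    dplyr::summarise(value = stats::median(log_molar), .groups = "drop")
  r2_raw <- fit_r2(raw_groups$inchikey, raw_groups$value)
  expect_lt(r2_raw, r2_cur)
})

test_that("expected reports tally the planted labels coherently", {
  cfg <- synthetic_config(n_compounds = 120, replicates = c(1, 4),
                          corruption_rates = c(buffer = 0.05, ph = 0.04,
                                               composition = 0.03,
                                               unstable = 0.02, origin = 0.02,
                                               below_loq = 0.01,
                                               microspecies = 0.01,
                                               calibration = 0.005),
                          seed = 41)
  gen <- generate_records(generate_pool(cfg), cfg)
  exp_rep <- expected_report(gen$labels)$report
  expect_equal(exp_rep$input, exp_rep$accepted + exp_rep$rejected)
  expect_equal(sum(unlist(exp_rep$reasons)), exp_rep$rejected)
  n_rec <- nrow(gen$records)
  expect_equal(exp_rep$reasons$BUFFER_COSOLVENT, round(0.05 * n_rec))
  expect_equal(exp_rep$reasons$MICROSPECIES, round(0.01 * n_rec))
})
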