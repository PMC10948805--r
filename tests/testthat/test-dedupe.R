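test_that("SDi matches its definition on worked examples", {
  expect_equal(compute_sdi(c(-2.0)), -1)
  expect_equal(compute_sdi(c(-2.0, -2.0, -2.0)), 0.0)
  expect_equal(compute_sdi(c(-2.0, -3.0)), 0.7071, tolerance = 1e-4)
  expect_equal(compute_sdi(c(-2.0, -3.0)), abs(-2 - -3) / sqrt(2))
  expect_error(compute_sdi(numeric(0)), "at least one")
})

test_that("SDi is permutation- and shift-invariant and 1-homogeneous", {
  set.seed(21)
  for (i in 1:50) {
    v <- stats::rnorm(sample(2:8, 1), -4, 1)
    s <- compute_sdi(v)
    expect_equal(compute_sdi(sample(v)), s)
    expect_equal(compute_sdi(v + 3.7), s)
    expect_equal(compute_sdi(mean(v) + 2 * (v - mean(v))), 2 * s)
    expect_equal(s, oracle_sdi(v), tolerance = 1e-12)
  }
})

test_that("replicates group by structure identity, not SMILES spelling", {
  recs <- dplyr::bind_rows(
    clean_record("D1", smiles = "CCO", value = -1.0),
    clean_record("D2", smiles = "OCC", value = -1.4),
    clean_record("D3", smiles = "CCC", value = -2.0)
  )
  res <- curate_dataset(recs)
  groups <- group_replicates(res$accepted)
  expect_equal(nrow(groups), 2)
  expect_equal(sum(groups$n), 3)
  eth <- groups[groups$n == 2, ]
  expect_equal(eth$values[[1]], c(-1.0, -1.4))
})

test_that("distinct structures give singleton groups", {
  recs <- clean_records(3, c("CCO", "CCC", "c1ccccc1"))
  res <- curate_dataset(recs)
  groups <- group_replicates(res$accepted)
  expect_equal(nrow(groups), 3)
  expect_true(all(groups$n == 1))
  expect_true(all(groups$sdi == -1))
})

test_that("resolution keeps the median or discards discordant groups", {
  g <- tibble::tibble(inchikey = c("K1", "K2", "K3"),
                      values = list(c(-2.0, -2.2, -2.4), c(-1.0, -3.0), c(-5.0)),
                      n = c(3L, 2L, 1L),
                      mean = vapply(list(c(-2.0, -2.2, -2.4), c(-1.0, -3.0), -5.0),
                                    mean, numeric(1)),
                      median = c(-2.2, -2.0, -5.0),
                      sdi = c(compute_sdi(c(-2.0, -2.2, -2.4)),
                              compute_sdi(c(-1.0, -3.0)), -1))
  r <- resolve_groups(g)
  expect_equal(r$outcome, c("keep", "discard", "keep"))
  expect_equal(r$solubility[1], -2.2)
  expect_equal(r$sd[1], 0.2, tolerance = 1e-12)
  expect_true(is.na(r$solubility[2]))  # sdi ~ 1.414 > 0.5
  expect_equal(r$solubility[3], -5.0)
  expect_equal(r$sd[3], -1)
})

test_that("resolution agrees with a brute-force oracle on random groups", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(1:6, 1)
    v <- round(stats::rnorm(n, -4, sample(c(0.1, 0.3, 1.0), 1)), 4)
    g <- tibble::tibble(inchikey = "K", values = list(v), n = n,
                        mean = mean(v), median = stats::median(v),
                        sdi = compute_sdi(v))
    r <- resolve_groups(g)
    sdi_o <- oracle_sdi(v)
    keep_o <- n == 1 || sdi_o <= 0.5
    expect_equal(g$sdi, sdi_o, tolerance = 1e-12)
    expect_equal(r$outcome, if (keep_o) "keep" else "discard")
    if (keep_o) {
      expect_equal(r$solubility, sort(v)[ceiling(n / 2)] / 2 +
                     sort(v)[floor(n / 2) + 1] / 2)  # median, both parities
      expect_equal(r$sd, if (n == 1) -1 else sdi_o, tolerance = 1e-12)
    }
  }
})

test_that("curated entries hold one row per surviving structure", {
  recs <- dplyr::bind_rows(
    clean_record("E1", smiles = "CCO", value = -1.0),
    clean_record("E2", smiles = "OCC", value = -1.2),
    clean_record("E3", smiles = "CCC", value = -2.0),
    clean_record("E4", smiles = "CCC", value = -5.0)  # discordant pair
  )
  out <- curate_solubility_data(recs)
  expect_equal(nrow(out$entries), 1)  # propane group discarded
  expect_false(anyDuplicated(out$entries$InChI) > 0)
  expect_equal(out$entries$Solubility, -1.1)
  expect_equal(out$entries$SD, compute_sdi(c(-1.0, -1.2)), tolerance = 1e-12)
})
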