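# Synthetic raw-record generator with exact ground truth. Every pipeline
# stage (curation verdicts, replicate SDi resolution, downstream model
# fits) has a known expected outcome computed by the generator's own
# bookkeeping, independent of the pipeline code it is used to test.

CORRUPTION_REASON <- c(
  buffer = "BUFFER_COSOLVENT", ph = "PH_OUT_OF_RANGE",
  composition = "COMPOSITION", unstable = "UNSTABLE",
  origin = "SUSPICIOUS_ORIGIN", below_loq = "BELOW_LOQ",
  microspecies = "MICROSPECIES", calibration = "CALIBRATION",
  structure_invalid = "STRUCTURE_INVALID")

#' Configuration of the synthetic record generator
#'
#' Defaults state the emulated record population once: replicate scatter
#' of 0.3 log (typical inter-laboratory reproducibility), a compound-level
#' residual of 0.25 log around the additive fragment ground-truth model,
#' and per-record corruption rates set to the relative frequencies of the
#' non-valid categories observed in a large aggregated solubility database
#' (pH/buffer violations dominating, then composition, instability,
#' suspicious origins, microspecies ambiguity and calibration bias).
#'
#' @param n_compounds Number of distinct compounds drawn from the bundled
#'   library (without replacement unless `allow_duplicates`).
#' @param replicates Integer range `c(min, max)` (or a single fixed count)
#'   of replicate measurements per compound.
#' @param noise_sd Within-compound replicate scatter, log units.
#' @param compound_sd Compound-level draw around the fragment model, log
#'   units (part of the ground truth, not noise).
#' @param corruption_rates Named per-record rates for the planted
#'   corruption categories (`buffer`, `ph`, `composition`, `unstable`,
#'   `origin`, `below_loq`, `microspecies`, `calibration`,
#'   `structure_invalid`).
#' @param high_scatter_fraction Fraction of compounds given a discordant
#'   replicate set with SDi forced above the 0.5 log discard threshold.
#' @param fraction_with_pka Fraction of ionizable compounds whose records
#'   carry a microspecies profile.
#' @param value_shift Log shift applied to the value of corrupted records
#'   (so that disabling curation measurably degrades model fits).
#' @param unit_mix Named probabilities over reporting units.
#' @param temperature_unknown_rate Fraction of records with unreported
#'   temperature (QC flag, never a rejection).
#' @param mode `"exact"` plants `round(rate * n)` corruptions per category
#'   deterministically disjoint (the default for testing); `"bernoulli"`
#'   draws each record's category at random.
#' @param seed Integer seed; the whole generation is reproducible per
#'   seed.
#' @param allow_duplicates Permit `n_compounds` above the library size by
#'   re-drawing structures (exact dedupe bookkeeping then no longer
#'   applies).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 150,
                             replicates = c(2L, 5L),
                             noise_sd = 0.3,
                             compound_sd = 0.25,
                             corruption_rates = c(buffer = 0.02, ph = 0.02,
                                                  composition = 0.01,
                                                  unstable = 0.005,
                                                  origin = 0.0017,
                                                  below_loq = 0.002,
                                                  microspecies = 0.0005,
                                                  calibration = 0.0002,
                                                  structure_invalid = 0),
                             high_scatter_fraction = 0.05,
                             fraction_with_pka = 1.0,
                             value_shift = 1.0,
                             unit_mix = c(log_molar = 0.7, mol_per_L = 0.15,
                                          mg_per_L = 0.1, g_per_L = 0.05),
                             temperature_unknown_rate = 0.1,
                             mode = c("exact", "bernoulli"),
                             seed = 1L,
                             allow_duplicates = FALSE) {
  mode <- match.arg(mode)
  if (length(replicates) == 1) replicates <- rep(replicates, 2)
  rates <- corruption_rates[names(corruption_rates) %in% names(CORRUPTION_REASON)]
  full <- stats::setNames(numeric(length(CORRUPTION_REASON)), names(CORRUPTION_REASON))
  full[names(rates)] <- rates
  stopifnot(all(full >= 0), sum(full) <= 1, noise_sd >= 0, compound_sd >= 0,
            high_scatter_fraction >= 0, high_scatter_fraction <= 1,
            n_compounds >= 1, replicates[1] >= 1, replicates[1] <= replicates[2])
  structure(list(n_compounds = as.integer(n_compounds),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 compound_sd = compound_sd, corruption_rates = full,
                 high_scatter_fraction = high_scatter_fraction,
                 fraction_with_pka = fraction_with_pka,
                 value_shift = value_shift,
                 unit_mix = unit_mix / sum(unit_mix),
                 temperature_unknown_rate = temperature_unknown_rate,
                 mode = mode, seed = as.integer(seed),
                 allow_duplicates = allow_duplicates),
            class = "synthetic_config")
}

#' The bundled compound library
#'
#' About 225 small-molecule SMILES spanning the four ionization classes,
#' written as the major microspecies at pH 7 (carboxylic acids with pKa
#' 4.2 and sulfonic acids ionized, aliphatic amines with conjugate-acid
#' pKa 10.5 protonated, phenols with pKa 10.0 neutral, amino acids
#' zwitterionic, quaternary ammonium permanent cations), with the neutral
#' form, annotations and molecular weight.
#'
#' @return A tibble `lib_id`, `smiles`, `neutral_smiles`, `charge_class`,
#'   `pka`, `pkb`, `mw`.
#' @export
compound_library <- function() {
  path <- system.file("extdata", "compound_library.csv", package = "aquacurate")
  if (!nzchar(path)) {
    path <- system.file("inst", "extdata", "compound_library.csv",
                        package = "aquacurate")
  }
  readr::read_csv(path, col_types = readr::cols(
    lib_id = readr::col_character(), smiles = readr::col_character(),
    neutral_smiles = readr::col_character(),
    charge_class = readr::col_character(),
    pka = readr::col_double(), pkb = readr::col_double(),
    mw = readr::col_double()), progress = FALSE)
}

# Fixed additive fragment ground-truth model: a deterministic weight per
# canonical fragment label, built from its atom and bond tokens. Carbons
# (aliphatic or aromatic) push solubility down, heteroatoms up, halogens
# down with size; this reproduces the qualitative polar-up / greasy-down
# structure a fragment-based solubility model learns.
FRAGMENT_TOKEN_WEIGHTS <- c(
  "C" = -0.09, "c" = -0.11, "O" = 0.16, "o" = 0.10, "N" = 0.14, "n" = 0.08,
  "S" = -0.03, "s" = -0.05, "F" = -0.05, "Cl" = -0.16, "Br" = -0.21,
  "I" = -0.26, "P" = 0.0, "=" = 0.03, "#" = 0.03, "-" = 0.0, ":" = 0.0)
TRUTH_INTERCEPT <- 0.2

#' Ground-truth weight of a fragment label
#'
#' @param labels Character vector of canonical fragment labels.
#' @return Numeric weights of the fixed generating model.
#' @export
synthetic_truth_weights <- function(labels) {
  vapply(labels, function(lab) {
    toks <- regmatches(lab, gregexpr("Cl|Br|[A-IK-PR-Zb-ik-pr-z]|[=#:-]", lab))[[1]]
    w <- FRAGMENT_TOKEN_WEIGHTS[toks]
    sum(w, na.rm = TRUE)
  }, numeric(1), USE.NAMES = TRUE)
}

# log-solubility of structures under the generating model (no compound draw)
truth_fragment_logs <- function(smiles) {
  vec <- vectorize_dataset(smiles)
  w <- synthetic_truth_weights(vec$vocabulary)
  as.numeric(TRUTH_INTERCEPT + vec$matrix %*% w)
}

neutralize_smiles <- function(s) {
  s <- gsub("[NH3+]", "N", s, fixed = TRUE)
  s <- gsub("[NH2+]", "N", s, fixed = TRUE)
  s <- gsub("[NH+]", "N", s, fixed = TRUE)
  s <- gsub("(=O)[O-]", "(=O)O", s, fixed = TRUE)
  s <- gsub("[O-]S(=O)(=O)", "OS(=O)(=O)", s, fixed = TRUE)
  s <- gsub("S(=O)(=O)[O-]", "S(=O)(=O)O", s, fixed = TRUE)
  s <- gsub("[O-]C(=O)", "OC(=O)", s, fixed = TRUE)
  s
}

# microspecies profile of one library compound at pH 7 from its pKa/pKb
# annotations (Henderson-Hasselbalch fractions)
library_profile <- function(smiles, neutral_smiles, charge_class, pka, pkb,
                            ph = 7.0) {
  fa <- if (!is.na(pka)) 1 / (1 + 10^(pka - ph)) else NA_real_
  fb <- if (!is.na(pkb)) 1 / (1 + 10^(ph - pkb)) else NA_real_
  if (charge_class == "Zwitterion" && !is.na(fa) && !is.na(fb)) {
    cation <- gsub("(=O)[O-]", "(=O)O",
                   gsub("S(=O)(=O)[O-]", "S(=O)(=O)O", smiles, fixed = TRUE),
                   fixed = TRUE)
    anion <- gsub("[NH3+]", "N", gsub("[NH2+]", "N", smiles, fixed = TRUE),
                  fixed = TRUE)
    return(microspecies_profile(
      species = c(smiles, neutral_smiles, anion, cation),
      fraction = c(fa * fb, (1 - fa) * (1 - fb), fa * (1 - fb), (1 - fa) * fb),
      ph = ph))
  }
  if (!is.na(fa)) {
    if (charge_class == "Negative") {
      return(microspecies_profile(c(smiles, neutral_smiles), c(fa, 1 - fa), ph))
    }
    # neutral acid (phenol): the neutral form dominates at pH 7 and the
    # ionized minor species is not enumerated
    return(microspecies_profile(smiles, 1 - fa, ph))
  }
  if (!is.na(fb)) {
    return(microspecies_profile(c(smiles, neutral_smiles), c(fb, 1 - fb), ph))
  }
  NULL
}

#' Generate a synthetic compound pool
#'
#' Draws compounds from the bundled library and assigns each a true
#' log-solubility from the fixed additive fragment model plus a
#' compound-level normal draw, a source label (nine emulated data
#' sources), and a microspecies profile where ionization annotations
#' exist. Deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble: `compound_id`, `smiles`, `neutral_smiles`,
#'   `charge_class`, `pka`, `pkb`, `mw`, `true_logs`, `source`, and a
#'   list-column `profile` of [microspecies_profile()] objects (or
#'   `NULL`).
#' @export
generate_pool <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  lib <- compound_library()
  set.seed(config$seed)
  n <- config$n_compounds
  if (n > nrow(lib) && !config$allow_duplicates) {
    stop("n_compounds exceeds the bundled library (", nrow(lib),
         "); set allow_duplicates = TRUE if structure collisions are acceptable",
         call. = FALSE)
  }
  idx <- sample(nrow(lib), n, replace = n > nrow(lib))
  pool <- lib[idx, ]
  pool$compound_id <- sprintf("S%04d", seq_len(n))
  pool$source <- sample(paste0("Lab", LETTERS[1:9]), n, replace = TRUE)
  base <- truth_fragment_logs(pool$smiles)
  pool$true_logs <- base + stats::rnorm(n, 0, config$compound_sd)
  with_pka <- (!is.na(pool$pka) | !is.na(pool$pkb)) &
    stats::runif(n) < config$fraction_with_pka
  pool$profile <- purrr::pmap(
    list(pool$smiles, pool$neutral_smiles, pool$charge_class,
         pool$pka, pool$pkb, with_pka),
    function(s, ns, cc, pka, pkb, use) {
      if (!use) return(NULL)
      library_profile(s, ns, cc, pka, pkb)
    })
  dplyr::select(pool, "compound_id", "smiles", "neutral_smiles", "charge_class",
                "pka", "pkb", "mw", "true_logs", "source", "profile")
}

# rescale the deviations of a replicate set to an exact sample SD
rescale_sd <- function(values, center, target_sd) {
  d <- values - mean(values)
  if (stats::sd(values) == 0) d <- seq_along(values) - mean(seq_along(values))
  center + d / stats::sd(center + d) * target_sd
}

#' Generate synthetic raw records with ground-truth labels
#'
#' Replicate measurements are the compound's true log-solubility plus
#' normal scatter. Planted corruptions set the corresponding metadata
#' (buffer/cosolvent/surfactant present, final pH outside 6-8,
#' multi-constituent or UVCB composition, DT50 below the cutoff,
#' averaged/predicted origin, below-LOQ, a 5-species microspecies
#' profile, a calibration note, or a mangled SMILES) and shift the
#' reported value by `value_shift` log units. A configured fraction of
#' compounds receives a discordant replicate set with SDi forced above
#' the discard threshold. In exact-count mode the planted counts are
#' `round(rate * n_records)` and, so that the planted discard count is
#' exact, corruptions avoid high-scatter compounds and a clean replicate
#' set whose random scatter would cross the threshold is rescaled back to
#' `noise_sd`.
#'
#' @param pool Output of [generate_pool()].
#' @param config The same [synthetic_config()].
#' @return A list with `records` (raw-record tibble), `profiles` (named
#'   list keyed by `record_id` for [curate_dataset()]), and `labels`
#'   (list: `records` per-record expected verdict/reason, `groups`
#'   per-structure expected dedupe outcome, `qc` expected flag counts).
#' @export
generate_records <- function(pool, config = synthetic_config()) {
  stopifnot(nrow(pool) >= 1)
  set.seed(config$seed + 1L)
  nc <- nrow(pool)
  reps <- seq(config$replicates[1], config$replicates[2])
  n_i <- reps[sample.int(length(reps), nc, replace = TRUE)]
  k_hs <- if (config$mode == "exact") {
    round(config$high_scatter_fraction * nc)
  } else {
    sum(stats::runif(nc) < config$high_scatter_fraction)
  }
  hs <- rep(FALSE, nc)
  if (k_hs > 0) {
    hs[sample(nc, k_hs)] <- TRUE
    n_i[hs] <- pmax(n_i[hs], 3L)  # a discordant set needs >= 3 replicates
  }

  rec <- tibble::tibble(
    compound_idx = rep(seq_len(nc), n_i),
    replicate = unlist(lapply(n_i, seq_len), use.names = FALSE)
  )
  n_rec <- nrow(rec)
  rec$record_id <- sprintf("R%05d", seq_len(n_rec))
  rec$true_logs <- pool$true_logs[rec$compound_idx]
  rec$logm <- rec$true_logs + stats::rnorm(n_rec, 0, config$noise_sd)
  for (ci in which(hs)) {
    rows <- which(rec$compound_idx == ci)
    rec$logm[rows] <- rescale_sd(rec$logm[rows], rec$true_logs[rows], 1.2)
  }

  # assign corruption categories, mutually exclusive per record
  rates <- config$corruption_rates
  rec$corruption <- NA_character_
  if (config$mode == "exact") {
    eligible <- which(!hs[rec$compound_idx])  # keep planted discards exact
    eligible <- eligible[sample.int(length(eligible))]
    counts <- round(rates * n_rec)
    pos <- 1L
    for (cat in names(counts)) {
      k <- counts[[cat]]
      if (k == 0) next
      if (pos + k - 1L > length(eligible)) {
        stop("corruption rates too high for the number of eligible records",
             call. = FALSE)
      }
      rec$corruption[eligible[pos:(pos + k - 1L)]] <- cat
      pos <- pos + k
    }
  } else {
    draw <- stats::runif(n_rec)
    cum <- cumsum(rates)
    cat_of <- function(u) {
      i <- which(u < cum)[1]
      if (is.na(i)) NA_character_ else names(rates)[i]
    }
    rec$corruption <- vapply(draw, cat_of, character(1))
  }
  corrupted <- !is.na(rec$corruption)
  rec$logm[corrupted] <- rec$logm[corrupted] + config$value_shift

  # exact mode: keep clean replicate sets below the discard threshold
  if (config$mode == "exact") {
    for (ci in which(!hs)) {
      rows <- which(rec$compound_idx == ci & !corrupted)
      if (length(rows) >= 2 && stats::sd(rec$logm[rows]) > 0.5) {
        rec$logm[rows] <- rescale_sd(rec$logm[rows], rec$true_logs[rows],
                                     config$noise_sd)
      }
    }
  }

  # clean metadata
  rec$smiles <- pool$smiles[rec$compound_idx]
  rec$mw <- pool$mw[rec$compound_idx]
  rec$source <- pool$source[rec$compound_idx]
  rec$has_buffer <- "false"; rec$has_cosolvent <- "false"
  rec$has_surfactant <- "false"
  rec$composition <- "mono"; rec$below_loq <- "false"
  rec$origin <- "measured"; rec$calibration_issue <- "false"
  rec$dt50_hours <- NA_real_
  rec$ph_final <- stats::runif(n_rec, 6.2, 7.8)
  rec$ph_initial <- rec$ph_final + stats::runif(n_rec, -0.2, 0.2)
  rec$temperature <- stats::runif(n_rec, 294, 302)
  temp_unknown <- stats::runif(n_rec) < config$temperature_unknown_rate
  rec$temperature[temp_unknown] <- NA_real_
  # measurement method: mostly appropriate for the solubility range, with
  # some shake-flask measurements of poorly soluble compounds (OECD flag)
  mg_true <- 10^rec$true_logs * rec$mw * 1000
  low <- mg_true < 10
  meth_low <- sample(c("column_elution", "slow_stir", "shake_flask"),
                     n_rec, replace = TRUE, prob = c(0.45, 0.25, 0.3))
  meth_high <- sample(c("shake_flask", "not_specified"),
                      n_rec, replace = TRUE, prob = c(0.7, 0.3))
  rec$method <- ifelse(low, meth_low, meth_high)

  # apply planted corruptions
  junk_profile <- microspecies_profile(
    c("C", "CC", "CCC", "CCCC", "CCCCC"), c(0.4, 0.2, 0.2, 0.1, 0.1))
  profiles <- list()
  alt <- 0L
  for (i in which(corrupted)) {
    cat <- rec$corruption[i]
    alt <- alt + 1L
    if (cat == "buffer") {
      fld <- c("has_buffer", "has_cosolvent", "has_surfactant")[(alt %% 3) + 1]
      rec[[fld]][i] <- "true"
    } else if (cat == "ph") {
      rec$ph_final[i] <- if (alt %% 2 == 0) stats::runif(1, 2, 5.5) else stats::runif(1, 8.5, 12)
    } else if (cat == "composition") {
      rec$composition[i] <- if (alt %% 2 == 0) "multi" else "UVCB"
    } else if (cat == "unstable") {
      rec$dt50_hours[i] <- stats::runif(1, 1, 20)
      if (rec$method[i] == "cheqsol") rec$method[i] <- "shake_flask"
    } else if (cat == "origin") {
      rec$origin[i] <- if (alt %% 2 == 0) "averaged" else "predicted"
    } else if (cat == "below_loq") {
      rec$below_loq[i] <- "true"
    } else if (cat == "microspecies") {
      profiles[[rec$record_id[i]]] <- junk_profile
    } else if (cat == "calibration") {
      rec$calibration_issue[i] <- "true"
    } else if (cat == "structure_invalid") {
      rec$smiles[i] <- paste0(rec$smiles[i], "(")
    }
  }
  # genuine ionization profiles for clean records of annotated compounds
  for (i in which(!corrupted)) {
    prof <- pool$profile[[rec$compound_idx[i]]]
    if (!is.null(prof)) profiles[[rec$record_id[i]]] <- prof
  }

  # encode values in mixed reporting units
  rec$value_units <- sample(names(config$unit_mix), n_rec, replace = TRUE,
                            prob = config$unit_mix)
  rec$value <- from_log_molar(rec$logm, rec$value_units, rec$mw)
  # the effective log-molar value after the encode/decode round trip is
  # what the pipeline will see; bookkeeping uses it
  rec$logm_effective <- to_log_molar(rec$value, rec$value_units, rec$mw)

  records <- tibble::tibble(
    record_id = rec$record_id, smiles = rec$smiles,
    inchi = NA_character_, cas = NA_character_,
    value = rec$value, value_units = rec$value_units, mw = rec$mw,
    temperature = rec$temperature, ph_initial = rec$ph_initial,
    ph_final = rec$ph_final, has_buffer = rec$has_buffer,
    has_cosolvent = rec$has_cosolvent, has_surfactant = rec$has_surfactant,
    composition = rec$composition, method = rec$method,
    below_loq = rec$below_loq, origin = rec$origin,
    dt50_hours = rec$dt50_hours, source = rec$source,
    calibration_issue = rec$calibration_issue,
    pka_list = as.character(pool$pka[rec$compound_idx]),
    pkb_list = as.character(pool$pkb[rec$compound_idx]),
    group = "synthetic"
  )
  validate_raw_records(records)

  record_labels <- tibble::tibble(
    record_id = rec$record_id,
    compound_id = pool$compound_id[rec$compound_idx],
    smiles = pool$smiles[rec$compound_idx],
    corruption = rec$corruption,
    expected_verdict = ifelse(corrupted, "reject", "accept"),
    expected_reason = ifelse(corrupted, CORRUPTION_REASON[rec$corruption],
                             NA_character_)
  )

  # dedupe oracle: naive explicit bookkeeping over surviving (clean) values
  group_labels <- lapply(seq_len(nc), function(ci) {
    rows <- which(rec$compound_idx == ci & !corrupted)
    if (length(rows) == 0) return(NULL)
    v <- rec$logm_effective[rows]
    n <- length(v)
    if (n == 1) {
      sdi <- -1
    } else {
      xb <- sum(v) / n
      sdi <- sqrt(sum((v - xb)^2) / (n - 1))
    }
    keep <- n == 1 || sdi <= 0.5
    tibble::tibble(compound_id = pool$compound_id[ci], smiles = pool$smiles[ci],
                   n = n, sdi = sdi,
                   outcome = if (keep) "keep" else "discard",
                   expected_value = if (keep) stats::median(v) else NA_real_,
                   expected_sd = if (n == 1) -1 else if (keep) sdi else NA_real_,
                   true_logs = pool$true_logs[ci])
  })
  group_labels <- dplyr::bind_rows(group_labels)

  # QC-flag oracle (flags are computed for every record, rejected or not)
  valid_struct <- is.na(rec$corruption) | rec$corruption != "structure_invalid"
  mg_eff <- 10^rec$logm_effective * rec$mw * 1000
  qc <- list(
    METHOD_MISMATCH_OECD = sum(valid_struct & rec$method == "shake_flask" &
                                 mg_eff < 10),
    TEMPERATURE_UNKNOWN = sum(is.na(rec$temperature))
  )

  list(records = records, profiles = profiles,
       labels = list(records = record_labels, groups = group_labels, qc = qc))
}

#' Expected curation report and dedupe summary
#'
#' Builds, from the generator's labels alone, the report that
#' [curate_dataset()] followed by [group_replicates()] and
#' [resolve_groups()] must reproduce field-for-field.
#'
#' @param labels The `labels` component of [generate_records()].
#' @return A list with `report` (same shape as a `curation_result`
#'   report) and `dedupe` (the per-structure expected outcomes).
#' @export
expected_report <- function(labels) {
  rl <- labels$records
  reason_counts <- stats::setNames(as.list(integer(length(REASON_CODES))),
                                   REASON_CODES)
  tab <- table(factor(rl$expected_reason, levels = REASON_CODES))
  for (nm in names(tab)) reason_counts[[nm]] <- as.integer(tab[[nm]])
  list(
    report = list(
      input = nrow(rl),
      accepted = sum(rl$expected_verdict == "accept"),
      rejected = sum(rl$expected_verdict == "reject"),
      reasons = reason_counts,
      qc_flags = list(METHOD_MISMATCH_OECD = as.integer(labels$qc$METHOD_MISMATCH_OECD),
                      TEMPERATURE_UNKNOWN = as.integer(labels$qc$TEMPERATURE_UNKNOWN))
    ),
    dedupe = labels$groups
  )
}
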