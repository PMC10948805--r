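# Closed-form solubility estimators. All three return log10 mol/L.

#' General solubility equation (GSE)
#'
#' `logS = 0.5 - 0.01 (MP - 25) - logP`, with MP the melting point in
#' degrees Celsius and logP the octanol/water partition coefficient. The
#' equation is strictly valid for solid non-electrolytes; for liquids
#' (MP < 25) the melting-point term can optionally be clamped to zero
#' (`liquid_clamp = TRUE`), but the default applies the equation as
#' written.
#'
#' @param mp Melting point, degrees C.
#' @param logp Octanol/water log partition coefficient.
#' @param liquid_clamp If `TRUE`, treat `mp < 25` as `mp = 25`.
#' @return Estimated aqueous solubility, log10 mol/L.
#' @examples
#' gse(mp = 125, logp = 2) # -2.5
#' @export
gse <- function(mp, logp, liquid_clamp = FALSE) {
  stopifnot(is.numeric(mp), is.numeric(logp), all(is.finite(mp)), all(is.finite(logp)))
  if (liquid_clamp) mp <- pmax(mp, 25)
  0.5 - 0.01 * (mp - 25) - logp
}

#' Henderson-Hasselbalch pH-dependent solubility
#'
#' Total aqueous solubility of an ionizable compound from its intrinsic
#' (neutral-species) solubility `S0`:
#' `logS(pH) = logS0 + log10(1 + 10^(pH - pKa) + 10^(pKb - pH))`, with the
#' acid and/or base term omitted when the compound has no such group.
#' Here `pKb` denotes the protonation constant of the basic group on the
#' pH scale (the conjugate-acid pKa), so the basic term grows as the pH
#' drops below it. The ionization term is non-negative, so the apparent
#' solubility is never below the intrinsic solubility.
#'
#' @param logs0 Intrinsic solubility, log10 mol/L.
#' @param ph Solution pH (vectorized).
#' @param pka Acid dissociation constant, or `NULL` for no acidic group.
#' @param pkb Basic-group constant as described above, or `NULL`.
#' @return log10 mol/L at the given pH.
#' @examples
#' hh_solubility(-5, ph = 7, pka = 4) # about -2.0
#' @export
hh_solubility <- function(logs0, ph, pka = NULL, pkb = NULL) {
  stopifnot(is.numeric(logs0), is.numeric(ph), all(ph >= 0 & ph <= 14))
  term <- 1
  if (!is.null(pka)) {
    stopifnot(length(pka) <= 1 || length(pka) == length(ph))
    term <- term + 10^(ph - pka)
  }
  if (!is.null(pkb)) {
    stopifnot(length(pkb) <= 1 || length(pkb) == length(ph))
    term <- term + 10^(pkb - ph)
  }
  logs0 + log10(term)
}

#' Johnson ansatz for pH-dependent solubility with crystal packing
#'
#' `logS(pH) = logS0 + min[ sum_i (pH - pKa_i) + sum_j (pKb_j - pH) + 1,
#' 4.25 ] - chi_pack * exp(-F_I)`, where `chi_pack` is a crystal-packing
#' penalty (supplied externally, e.g. from molecular dynamics) and `F_I`
#' the degree of ionization. The inner `log10(10^(...))` collapses
#' analytically to its exponent; the 4.25 cap is applied after summation.
#' Note the `+1` inside the capped term applies even with no ionizable
#' groups (a +1 log offset for non-electrolytes); the ansatz is
#' implemented as stated.
#'
#' @param logs0 Intrinsic solubility, log10 mol/L.
#' @param ph Solution pH.
#' @param pka Numeric vector of acid pKa values (may be empty).
#' @param pkb Numeric vector of basic-group constants (may be empty).
#' @param chi_pack Crystal packing penalty, log units.
#' @param f_i Degree of ionization (dimensionless).
#' @return log10 mol/L.
#' @export
johnson_solubility <- function(logs0, ph, pka = numeric(0), pkb = numeric(0),
                               chi_pack = 0, f_i = 0) {
  stopifnot(is.numeric(logs0), is.numeric(ph), length(ph) == 1,
            all(ph >= 0 & ph <= 14), is.finite(chi_pack), is.finite(f_i))
  ionization <- sum(ph - pka) + sum(pkb - ph) + 1
  logs0 + min(ionization, 4.25) - chi_pack * exp(-f_i)
}
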