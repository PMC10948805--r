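#' Standardize chemical structures
#'
#' Canonicalizes SMILES strings (aromatic perception, implicit hydrogens,
#' stereochemistry preserved) and derives the standard InChIKey used as the
#' structure grouping key throughout the pipeline. Counterions are *not*
#' stripped: salt and multi-fragment structures are handled by the
#' composition filter of the curation decision tree, not by desalting.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), an unparsable SMILES raises an error
#'   naming the offending string. If `FALSE`, such rows are returned with
#'   `valid = FALSE` and `NA` fields, which is how the curation pipeline
#'   turns parse failures into `STRUCTURE_INVALID` verdicts.
#' @return A tibble with one row per input: `smiles`, `valid`,
#'   `canonical_smiles`, `inchikey`, `mw` (g/mol), `n_atoms`, and a
#'   list-column `formal_charges` of per-atom formal charges.
#' @examples
#' \dontrun{
#' standardize_structure(c("OCC", "CCO")) # identical canonical forms
#' }
#' @export
standardize_structure <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  res <- bridge_standardize(smiles)
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (strict && any(!ok)) {
    bad <- vapply(res[!ok], function(r) r$smiles, character(1))
    stop("unparsable SMILES: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    smiles = smiles,
    valid = ok,
    canonical_smiles = vapply(res, function(r) if (isTRUE(r$ok)) r$canonical else NA_character_, character(1)),
    inchikey = vapply(res, function(r) if (isTRUE(r$ok)) r$inchikey else NA_character_, character(1)),
    mw = vapply(res, function(r) if (isTRUE(r$ok)) r$mw else NA_real_, numeric(1)),
    n_atoms = vapply(res, function(r) if (isTRUE(r$ok)) as.integer(r$n_atoms) else NA_integer_, integer(1)),
    formal_charges = lapply(res, function(r) {
      if (isTRUE(r$ok)) as.integer(unlist(r$charges, use.names = FALSE)) else NULL
    })
  )
}

#' Extract the molecular graph of a structure
#'
#' Heavy-atom graph with typed bonds, the substrate for fragment
#' enumeration. Hydrogens are suppressed; aromatic atoms are flagged.
#'
#' @param smiles A single SMILES string.
#' @return A list with `atoms` (tibble: `symbol`, `aromatic`, `charge`) and
#'   `bonds` (tibble: `from`, `to`, `order` with `order` one of
#'   `-`, `=`, `#`, `:`).
#' @export
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  r <- bridge_standardize(smiles)[[1]]
  if (!isTRUE(r$ok)) stop("unparsable SMILES: ", smiles, call. = FALSE)
  list(
    atoms = tibble::tibble(
      symbol = unlist(r$atom_symbol, use.names = FALSE) %||% character(0),
      aromatic = as.logical(unlist(r$atom_aromatic, use.names = FALSE) %||% logical(0)),
      charge = as.integer(unlist(r$charges, use.names = FALSE) %||% integer(0))
    ),
    bonds = tibble::tibble(
      from = as.integer(unlist(r$bond_from, use.names = FALSE) %||% integer(0)),
      to = as.integer(unlist(r$bond_to, use.names = FALSE) %||% integer(0)),
      order = unlist(r$bond_order, use.names = FALSE) %||% character(0)
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classify the ionization state of a structure by its charge ratio
#'
#' The charge ratio (CR) is the sum of formal charges divided by the number
#' of charged atoms. Structures with no charged atom are `Uncharged`
#' (CR = 0); CR > 0 is `Positive`, CR < 0 is `Negative`, and CR = 0 with at
#' least one charged atom is `Zwitterion`. Fractional CR (e.g. charges
#' \{+1, +1, -1\} give CR = +1/3) classifies by sign, a consistent
#' extension of the integer cases. The four classes partition all
#' structures.
#'
#' @param charges Either an integer vector of per-atom formal charges for a
#'   single structure, or a list of such vectors.
#' @return A tibble with columns `charge_class` (one of `"Uncharged"`,
#'   `"Zwitterion"`, `"Positive"`, `"Negative"`) and `charge_ratio`.
#' @examples
#' classify_charge(c(1L, -1L)) # Zwitterion
#' @export
classify_charge <- function(charges) {
  if (!is.list(charges)) charges <- list(charges)
  one <- function(ch) {
    ch <- ch[!is.na(ch)]
    charged <- ch[ch != 0]
    if (length(charged) == 0) {
      return(list(class = "Uncharged", cr = 0))
    }
    cr <- sum(charged) / length(charged)
    cls <- if (cr > 0) "Positive" else if (cr < 0) "Negative" else "Zwitterion"
    list(class = cls, cr = cr)
  }
  out <- lapply(charges, one)
  tibble::tibble(
    charge_class = vapply(out, function(x) x$class, character(1)),
    charge_ratio = vapply(out, function(x) x$cr, numeric(1))
  )
}

#' Build a microspecies profile
#'
#' Ionization microspecies of one compound and their fractional abundance
#' at a given pH (default 7.0). The pipeline treats pKa values and
#' microspecies distributions as *inputs*: the profiles are supplied, not
#' predicted.
#'
#' @param species Character vector of SMILES, one per microspecies.
#' @param fraction Numeric vector of fractions in `[0, 1]`, same length;
#'   the sum may be below 1 (unenumerated minor species) but not above.
#' @param ph The pH the fractions refer to.
#' @return An object of class `microspecies_profile`.
#' @export
microspecies_profile <- function(species, fraction, ph = 7.0) {
  stopifnot(is.character(species), length(species) >= 1L,
            length(species) == length(fraction))
  if (any(fraction < 0 | fraction > 1)) {
    stop("microspecies fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(fraction) > 1 + 1e-6) stop("microspecies fractions sum above 1", call. = FALSE)
  structure(list(species = species, fraction = as.numeric(fraction), ph = ph),
            class = "microspecies_profile")
}

#' Gate a record on its microspecies distribution
#'
#' Records whose compound presents too many microspecies (more than
#' `max_species`, default 4) are rejected: no single structure can stand
#' for the measurement. Records whose *major* microspecies is uncertain
#' (largest fraction below `major_fraction_min`, default 0.5; a tie at the
#' threshold is treated conservatively as uncertain) are rejected for the
#' same reason. Otherwise the major microspecies structure is returned and
#' used for modeling and grouping.
#'
#' @param profile A [microspecies_profile()], or `NULL` meaning no
#'   ionization information — the record's own structure is taken as the
#'   single species and passes the gate.
#' @param max_species Maximum number of microspecies tolerated.
#' @param major_fraction_min Minimum fraction for an unambiguous major
#'   species.
#' @return A list with `status` (`"ok"` or `"reject"`), `reason`
#'   (`NA` or `"MICROSPECIES"`), and `structure` (the major-species SMILES
#'   when `status == "ok"`).
#' @export
gate_microspecies <- function(profile, max_species = 4L, major_fraction_min = 0.5) {
  if (is.null(profile)) {
    return(list(status = "ok", reason = NA_character_, structure = NA_character_))
  }
  stopifnot(inherits(profile, "microspecies_profile"))
  if (length(profile$species) == 0) stop("empty microspecies profile", call. = FALSE)
  if (length(profile$species) > max_species) {
    return(list(status = "reject", reason = "MICROSPECIES", structure = NA_character_))
  }
  i <- which.max(profile$fraction)
  top <- profile$fraction[i]
  tied <- sum(abs(profile$fraction - top) < 1e-12) > 1
  if (top < major_fraction_min || tied) {
    return(list(status = "reject", reason = "MICROSPECIES", structure = NA_character_))
  }
  list(status = "ok", reason = NA_character_, structure = profile$species[i])
}
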