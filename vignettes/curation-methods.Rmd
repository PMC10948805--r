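---
title: "Curating thermodynamic solubility data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating thermodynamic solubility data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Thermodynamic aqueous solubility — the equilibrium concentration of a
compound against its most stable crystalline form — is one of the
hardest-to-predict ADME properties, and the quality ceiling of any QSPR
model is set by its training data. Aggregated public datasets mix water,
apparent and kinetic solubilities; measurements in buffers or with
cosolvents; substances of unknown composition; chemically unstable
solutes whose measured "solubility" reflects degradation products; and
entries that are themselves predictions. The inter-laboratory standard
deviation of genuinely replicated measurements (around 0.5–1.0 log
units in public data) is the floor any regression model inherits.

`aquacurate` operationalizes a curation guideline for such data as a
deterministic, testable pipeline, and pairs it with the analytics used
to judge whether curation helped: error stratification, REC curves, and
an applicability-domain sweep.

## The decision tree

Records pass through ten checks in a fixed order; every triggered reason
is recorded, and the *first* reason attributes the record to one
disjoint report category (so category counts sum to the rejected total):

1. structure validity (unparsable SMILES);
2. microspecies gate: more than 4 microspecies at pH 7, or no major
   species reaching the 0.5 fraction threshold;
3. buffer, cosolvent or surfactant present;
4. final pH outside [6, 8] — the initial pH is consulted only when the
   final pH is unreported, since self-buffering shifts the endpoint;
5. temperature outside [293.15, 303.15] K;
6. multi-constituent or UVCB composition (solubility is a property of a
   pure compound);
7. instability: DT50 below 24 h, or below 7 days for slow-stir
   measurements, which equilibrate over weeks;
8. below the limit of quantification — unusable for regression;
9. origin "averaged" or "predicted";
10. recorded calibration/experimental bias.

**Tri-state semantics.** Metadata are `true/false/unknown`, and
`unknown` never rejects: in real aggregated data, condition metadata are
retrievable for only a small minority of entries, and discarding the
majority for missing metadata would defeat the purpose. A green run of
the pipeline therefore establishes the *absence of positive evidence* of
violations, not their impossibility.

**QC flags.** Two conditions flag without rejecting: unknown
temperature, and OECD-105 method mismatch (shake-flask measurements of
compounds below 10 mg/L, where column elution or slow-stir is advised).
Curated reference sets demonstrably retain such entries, so a flag — not
a rejection — is the faithful behavior; the flags feed the
hardest-compound reports instead.

**Boundary choices.** The pH window "7 ± 1" is taken inclusive at both
ends. The DT50 cutoff is keyed on the *method* (slow-stir → 7 days,
everything else → 24 h): the motivating argument is equilibration time,
and method is the operable field, whereas the alternative
hydrophilicity-keyed reading would require a logP estimate the pipeline
deliberately does not compute. A tie at exactly the microspecies major
fraction threshold rejects (conservative: no structure is privileged).

## Replicate aggregation

Replicates are grouped by the standard InChIKey of the standardized
major microspecies. The inter-laboratory standard deviation

$$ SDi = \sqrt{\frac{\sum_{i=1}^{n} (x_i - \bar x)^2}{n-1}} $$

is the sample standard deviation of a group's log-molar values. Groups
with $SDi \le 0.5$ log keep their **median** (robust to a single stray
replicate; the even-$n$ median is the mean of the two central values);
groups above the threshold are discarded entirely — a median over
multi-modal or discordant values is meaningless, and the threshold
subsumes the "two or three clusters of values" failure mode without a
clustering step. Single measurements are kept with the SD sentinel −1,
matching the curated-schema convention.

## Structure handling

Canonicalization, InChIKey generation, formal charges, molecular weight
and molecular graphs come from RDKit through a batched subprocess
(memoized per session). Counterions are *not* stripped: salt
correctness is a verification problem, not a normalization problem, and
multi-fragment records are handled by the composition filter. pKa values
and microspecies distributions are **inputs** — the reference workflow
used a commercial predictor, and decoupling keeps the pipeline free of
that dependency.

The ionization state of the major microspecies at pH 7 is summarized by
the charge ratio $CR = \sum q_i / \#\{q_i \ne 0\}$: no charged atoms →
Uncharged; $CR > 0$ → Positive; $CR < 0$ → Negative; $CR = 0$ with
charged atoms → Zwitterion. Fractional $CR$ (e.g. two cationic and one
anionic site, $CR = +1/3$) classifies by sign, the consistent extension
of the integer cases. The four classes partition all structures and
drive the stratified error reports.

## Closed-form baselines

- General solubility equation: $\log S = 0.5 - 0.01(MP - 25) - \log P$.
  Valid for solid non-electrolytes; an optional clamp treats liquids
  ($MP < 25$ °C) as $MP = 25$, but the default applies the equation as
  written.
- Henderson–Hasselbalch: $\log S(pH) = \log S_0 + \log_{10}(1 +
  10^{pH - pK_a} + 10^{pK_b - pH})$, with absent groups' terms dropped.
  The source prints this relation without the logarithm on the
  parenthesized term, which would add a spurious $\ge \log_{10} 3$
  offset even for neutral species; the standard form with the logarithm
  is implemented as the evident intent.
- Johnson ansatz: $\log S(pH) = \log S_0 + \min[\sum_i (pH - pK_{a,i})
  + \sum_j (pK_{b,j} - pH) + 1,\; 4.25] - \chi_{pack} e^{-F_I}$. The
  inner $\log_{10} 10^{(\cdot)}$ collapses analytically; the cap applies
  after summation. The $+1$ inside the capped term applies even for
  non-electrolytes — the ansatz is implemented as stated and this
  behavior is documented rather than "fixed". $\chi_{pack}$ and $F_I$
  are inputs (their estimation, e.g. by molecular dynamics, is out of
  scope).

## Fragment descriptors and atom contributions

Descriptors are counts of atom/bond sequence fragments of 2–3 atoms:
simple paths in the hydrogen-suppressed graph, labeled by atom symbols
(lowercase for aromatic) joined with bond symbols (`- = # :`), each
undirected occurrence counted once under the lexicographic-minimum
canonical label. Formal charges are not encoded in labels by default
(keeping the vocabulary compact at desk scale); a flag appends them.

For an additive model on fragment counts, each occurrence's weight is
split equally among its member atoms and accumulated, giving per-atom
contributions that sum *exactly* to the prediction minus the intercept.
This equal-split rule is an approximation to dedicated atom-coloring
schemes defined through a model's internals, but it is exact for linear
models, which is the class used here.

## Applicability domain

An isolation forest: each tree is grown on a random subsample
(default 256, clamped to $n$) by choosing a random descriptor and a
uniform split within the node's range, until isolation or the depth
ceiling $\lceil \log_2 \psi \rceil$; truncated leaves are extended by
$c(\text{leaf size})$, where $c(n) = 2H(n-1) - 2(n-1)/n$ (exact harmonic
numbers below $10^4$). The anomaly score is $s = 2^{-E[h]/c(\psi)}$.

The contamination sweep sets, for each $c$ on a 0.01-step grid over
[0, 0.99], the threshold at the $(1-c)$ training-score quantile —
standard contamination semantics, which the source does not restate —
and reports test coverage and RMSE over the in-domain subset, normalized
by the RMSE at contamination zero. Contamination zero rejects nothing by
definition (threshold $+\infty$), so coverage(0) = 1 exactly. Grid
points with fewer than two in-domain compounds are flagged unstable
with `NA` error rather than extrapolated.

## Error analytics

The per-compound "MAE" is the **median** of absolute errors over all
supplied predictions (models and/or CV folds) for that compound —
following the source convention, not the mean. REC curves report the
fraction of compounds within a tolerance on an ascending grid (step
0.01 log). Stratified reports split by charge class, source, or
solubility bins of width 1 log (left-closed, right-open; the bin width
is this package's choice, as the reference binning is unspecified), and
empty strata are reported, not dropped. Hardest-$k$ tables rank by
descending MAE with lexicographic ID tie-breaks for deterministic
output.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
with a known ground truth, and its defaults are stated once:

- **Library**: 225 bundled small-molecule SMILES (written as the major
  microspecies at pH 7) spanning the four charge classes via a built-in
  substructure table — carboxylic acids pKa 4.2, sulfonic acids 1.8,
  phenols 10.0, aliphatic amines 10.5 (conjugate acid), amino acids
  zwitterionic, quaternary ammonium permanent.
- **Truth model**: log-solubility is a fixed additive function of
  fragment counts (carbons down, heteroatoms up, halogens down with
  size; intercept 0.2) plus a compound-level draw of SD 0.25 log — the
  residual a fragment model cannot explain.
- **Replicates**: 2–5 per compound, scatter 0.3 log (typical
  inter-laboratory reproducibility).
- **Corruption rates** mirror the relative frequencies of non-valid
  categories reported for a ~10⁴-entry public database: pH/buffer
  violations ~4% (split evenly), composition 1%, instability 0.5%,
  suspicious origin 0.17%, microspecies 0.05%, calibration 0.02%,
  below-LOQ 0.2%. Corrupted records also shift their value by +1 log so
  that skipping curation measurably degrades downstream fits.
- **High-scatter compounds** (5%) receive replicate sets rescaled to
  SDi = 1.2, exercising the discard rule.

In the default exact-count mode, planted counts are `round(rate × n)`
and two bookkeeping guards keep expected outcomes exact: corruptions
avoid high-scatter compounds, and a clean replicate set whose random
scatter happens to cross the 0.5 discard threshold (probability ≈ 2.5%
at n = 5, σ = 0.3) is rescaled back to σ. This truncation biases the
mean SDi by well under the 5% tolerance used in the scatter-calibration
test; the Bernoulli mode applies no such guards and is used for the
unbiased scatter checks. The generator's expected report is computed by
its own naive bookkeeping, never by calling the pipeline.

What a green test does **not** establish: the synthetic world has no
unit typos, no wrong-compound measurements, no correlated lab biases,
no tautomer/polymorph ambiguity, and its corruption is metadata-visible
by construction — real curation additionally needs the manual
verification steps (CAS/structure cross-checks) that are out of scope
here.

## Numerical and interface choices

- Solubility is held internally only as log₁₀ mol/L; conversion happens
  at ingest (mass units require a molecular weight — the record's, or
  RDKit's if absent). Conversions invert to within 10⁻⁹ log units.
- The curated CSV schema is exactly `ID, InChI, Solubility,
  SMILEScurated, SD, Group, Dataset, Composition, Error, Charge`; the
  `Group` quality label is carried through verbatim (its semantics are
  inherited from the upstream database), `SD` uses the −1 sentinel, and
  files round-trip losslessly.
- Config files are flat `key=value` or JSON (no YAML parser is
  available in the target environment); CLI flags mirror config keys
  and override them.
- All stochastic components (generator, forest) are seeded and
  reproducible bit-for-bit per seed.

## Known limitations

- The standardization contract is delegated to RDKit; differences from
  other standardizers (tautomer canonicalization in particular) will
  move records between groups.
- The microspecies gate depends entirely on supplied profiles; without
  them every record is treated as a single species.
- The equal-split atom contribution is exact only for linear models.
- The isolation forest is the canonical variant; extended/rotated
  variants and other AD formalisms (leverage, kNN distance) are out of
  scope.
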