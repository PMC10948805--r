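# aquacurate

Curation and quality analytics for thermodynamic aqueous solubility data.

Aggregated solubility databases mix measurements taken under incompatible
conditions: buffered or cosolvent-laden solutions, out-of-range pH,
unstable or multi-constituent substances, values below the quantification
limit, and entries that are themselves model predictions. Training QSPR
regressors on such data caps their accuracy well above the
inter-laboratory reproducibility limit. `aquacurate` implements a
rule-based curation pipeline for raw solubility records, for
cheminformaticians assembling modeling-grade solubility sets:

- **Decision-tree curation.** Each record is checked, in fixed order, for
  structure validity, microspecies ambiguity, buffer/cosolvent/surfactant
  presence, final pH outside 7 ± 1, temperature outside ~300 K,
  multi-constituent/UVCB composition, instability (DT50 below 24 h, or
  7 days for slow-stir), below-LOQ status, and suspicious origin
  (averaged or ML-predicted values). Tri-state metadata
  (`true/false/unknown`) rejects only on positive evidence. Method
  appropriateness (OECD 105: shake-flask only above 10 mg/L) is a QC
  flag, never a rejection.
- **Replicate aggregation.** Replicates of one structure (grouped by
  standardized InChIKey) are summarized by the inter-laboratory standard
  deviation `SDi = sqrt(sum_i (x_i - x̄)² / (n - 1))`; groups with
  `SDi ≤ 0.5` log keep their median, discordant groups are discarded,
  single measurements carry the SD sentinel −1.
- **Closed-form baselines.** The general solubility equation
  `logS = 0.5 − 0.01(MP − 25) − logP`, the Henderson–Hasselbalch
  pH-dependence `logS(pH) = logS₀ + log₁₀(1 + 10^(pH−pKa) + 10^(pKb−pH))`,
  and the capped Johnson ansatz with crystal-packing penalty.
- **Fragment descriptors and interpretation.** Atom/bond sequence
  fragments of 2–3 atoms with canonical labels, count matrices for
  modeling, and exact additive per-atom contribution maps for linear
  fragment models.
- **Quality analytics.** RMSE/MSE/R², per-compound *median* absolute
  error, regression error characteristic (REC) curves, stratified reports
  (charge class, source, 1-log solubility bins), hardest-*k* tables.
- **Applicability domain.** An isolation forest over descriptor space
  with a contamination sweep reporting coverage and normalized RMSE.
- **Synthetic ground truth.** A bundled 225-compound library and a record
  generator with planted corruption and known structure→logS truth, so
  every stage is testable offline.

Structure standardization (canonical SMILES, InChIKey, formal charges,
molecular graphs) is delegated to RDKit through a batched `python`
subprocess; everything else is plain R.

## Worked example

```r
library(aquacurate)

cfg  <- synthetic_config(n_compounds = 100, replicates = 3, seed = 7)
pool <- generate_pool(cfg)
gen  <- generate_records(pool, cfg)
out  <- curate_solubility_data(gen$records, profiles = gen$profiles)
out$result
#> <curation_result>
#>   records: 300  accepted: 281  rejected: 19
#>   first-reason counts:
#>     BUFFER_COSOLVENT: 6
#>     PH_OUT_OF_RANGE: 6
#>     COMPOSITION: 3
#>     UNSTABLE: 2
#>     BELOW_LOQ: 1
#>     SUSPICIOUS_ORIGIN: 1
head(out$entries, 3)
#> # A tibble: 3 × 10
#>   ID     InChI                       Solubility SMILEScurated    SD Group     Dataset Composition Error Charge
#>   <chr>  <chr>                            <dbl> <chr>         <dbl> <chr>     <chr>   <chr>       <chr> <chr>
#> 1 R00187 AFBPFSWMIHJQDM-UHFFFAOYSA-N      -3.29 CNc1ccccc1    0.191 synthetic LabH    mono        None  Uncharged
#> 2 R00064 AILKHAQXUAOOFU-UHFFFAOYSA-N      -2.01 CCCCCC#N      0.392 synthetic LabB    mono        None  Uncharged
#> 3 R00151 ALBYIUDWACNRRB-UHFFFAOYSA-N      -1.92 CCCCCC(N)=O   0.246 synthetic LabG    mono        None  Uncharged
write_curated(out$entries, "curated.csv")
```

The 300 raw records collapse to one row per surviving structure; the 19
rejected records are exactly the generator's planted violations, and
`SD` holds each replicate group's inter-laboratory standard deviation in
log units (−1 for single measurements).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/aquacurate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/aquacurate.R", package="aquacurate"))')" \
    curate raw.csv --out curated.csv --report report.json
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a seeded synthetic population, runs curation, deduplication,
fragment vectorization, a ridge fragment model, the error analytics and
the applicability-domain contamination sweep end to end, verifying the
curation report against the generator's expected report, and writes the
JSON summary to `--out`.
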