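# peakRating

Feature rating and curation for untargeted LC-MS metabolomics peak tables.

An aligned peak table from an untargeted LC-MS experiment carries far more
rows than metabolites: every molecule can appear as several adduct forms
(`[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M+K]+`, ...), as in-source fragments,
and next to background signals. peakRating screens the *real* features.
Within each feature cluster (co-eluting, intensity-correlated features
presumed to derive from one compound) it applies a feature-rating rule:

* **Adduct flagging.** For cluster members *i*, *j* with
  *m/z*<sub>j</sub> > *m/z*<sub>i</sub>, a correlation rule
  (A<sub>low</sub> → A<sub>high</sub>, Δ = offset(A<sub>high</sub>) −
  offset(A<sub>low</sub>)) matches when
  |(*m/z*<sub>j</sub> − *m/z*<sub>i</sub>) − Δ| ≤ 0.01 Da. Matched
  candidates are resolved to one adduct label per feature by maximising
  the number of accepted edges (ties: minimal total mass error);
  connected components of accepted edges form TRF (top-rated feature)
  correlation groups. Because the evidence is the pairwise *difference*,
  molecules with no visible quasi-molecular ion are still recovered.
* **In-source fragment removal.** A non-TRF feature *f* is a fragment
  when some heavier cluster member's MS2 spectrum contains a peak *p*
  with |*m/z*<sub>f</sub> − *p*| ≤ 0.05 Da; it is removed from the final
  table (TRFs are never screened as candidates).
* **SRF classification.** Remaining cluster members are second-rated
  features (SRFs): isolated quasi-molecular ions.
* **Representative selection.** Each TRF group is collapsed to its most
  intense member (mean biological height; ties by lower m/z); the final
  curated table is representatives + SRFs.

The package also ships a minimal upstream prefilter (internal-standard
normalisation, blank filter, within-class RSD filter, Pearson/RT feature
clustering at r ≥ 0.8 within 0.03 min), readers/writers for the MS-DIAL /
MS-CleanR CSV/TSV export dialect (including the `mz:intensity` MS2 string
encoding and MSP export), and a synthetic peak-table generator with
planted ground truth (`simulatePeakTable()`) so the whole pipeline is
benchmarkable without instrument data. See the vignette
(`vignettes/feature-rating.Rmd`) for the model, parameter and design
discussion.

## Worked example

```r
library(peakRating)

sim <- simulatePeakTable(simConfig(nCompounds = 20, nNoiseFeatures = 8,
                                   seed = 42))
sim$table
#> PeakTable (positive mode): 60 features x 15 samples
#>   samples: 12 biological, 1 blank, 2 QC
#>   clusters: 28 assigned
#>   attributions: unrated=60 TRF=0 SRF=0 fragment=0 interference=0

res <- runPipeline(sim$table, "demo-run")
res$result
#> RatingResult: 60 features
#>   TRF=42 SRF=9 fragment=7 interference=2
#>   17 TRF correlation group(s), final table 26 feature(s)
```

The 20 compounds emitted 60 features; rating recognised 42 adduct forms
(TRFs) in 17 correlation groups, removed 7 in-source fragments, kept 9
isolated quasi-molecular ions (SRFs), and the blank filter had marked 2
blank-dominated noise features as interference. The final table (17 group
representatives + 9 SRFs = 26 features) approaches one feature per
compound. Against the planted truth:

```r
sc <- scoreAgainstTruth(res$result, sim$truth, res$table)
#> TRF precision 1.000 recall 1.000; fragment precision 1.000 recall 1.000
```

`demo-run/` then contains the full annotated table, the final curated
table, the attribution report, the fragment-call audit CSV and a JSON run
manifest whose count ledger satisfies
`input = TRF + SRF + fragment + interference` at every stage. A
command-line wrapper with `clean` / `simulate` / `score` subcommands is
installed at `inst/scripts/peakrating.R`.

Real tables are read with
`readAlignmentTable("MS_peaks-clusters_final.csv")`; upstream cluster ids
are honoured when present, and `clusterFeatures()` builds them otherwise.

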