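---
title: "Feature rating for untargeted LC-MS peak tables"
author: "peakRating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature rating for untargeted LC-MS peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakRating)
```

## The problem

An aligned untargeted LC-MS peak table contains thousands of features, of
which only a fraction represent intact metabolites. The rest are adduct
forms of the same molecules, in-source fragments, isotopes and background
signals. Statistics computed on such a table (PCA, marker selection) are
distorted when one metabolite contributes many rows, so a curation step
that reduces the table towards "one feature per metabolite" is standard
practice.

peakRating implements a feature-rating rule for this curation. It operates
on *feature clusters* — groups of co-eluting, intensity-correlated
features presumed to derive from one compound, as produced by upstream
cleaning tools or by the package's own clustering — and partitions every
feature into one of four attributions:

* **TRF** (top-rated feature): a parental feature evidenced by at least
  one *adduct correlation* within its cluster. In positive mode, the
  singly charged species `[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M+K]+` of one
  molecule differ by fixed m/z offsets (e.g. 21.9819 Da between `[M+H]+`
  and `[M+Na]+`, 15.9739 Da between `[M+Na]+` and `[M+K]+`). Two cluster
  members whose m/z difference matches such a delta within the adduct
  tolerance are linked; linked features are TRFs. Because the evidence is
  the *pairwise difference*, molecules whose quasi-molecular ion is absent
  are still recovered through their other adducts.
* **fragment**: a feature whose MS1 m/z reappears as a peak in the MS2
  spectrum of a *heavier* member of the same cluster, within the fragment
  tolerance. Such a feature is an in-source fragment of that member and is
  removed from the final table. TRFs are exempt from being screened: an
  established adduct form is never a fragment candidate (its spectrum can
  still own other features' calls).
* **SRF** (second-rated feature): everything left in the cluster — a
  parental feature present only as an isolated quasi-molecular ion.
* **interference**: features removed by the generic prefilters (blank
  filter, within-class RSD filter) before rating.

Finally, each TRF correlation group is collapsed to its most intense
member (the representative), and the final curated table is the set of
representatives plus all SRFs.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| adduct tolerance | 0.01 | Da | max deviation of a pair's m/z difference from a rule delta |
| fragment tolerance | 0.05 | Da | max deviation of an MS1 m/z from an owner's MS2 peak |
| min Pearson | 0.8 | — | clustering edge threshold on biological height vectors |
| cluster RT tolerance | 0.03 | min | co-elution window for clustering edges |
| min blank ratio | 0.8 | — | keep a feature when max biological ≥ ratio × mean blank |
| max class RSD | 0.30 | — | keep a feature stable (sd/mean) in ≥ 1 biological class |

The two mass tolerances are the standard settings for high-resolution
QTOF data and are deliberately absolute (Da, not ppm): the fragment match
is an existence test against centroided MS2 peaks whose calibration is
poorer than MS1. The blank-ratio and RSD defaults follow common practice
of the MS-CleanR family of cleaning tools; all four filter thresholds are
plain config values (`filterConfig()`), not estimates.

The built-in positive-mode rule set is the six pairwise correlations among
`[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M+K]+`. Offsets carry the electron-mass
correction (Na+ = 22.989218, not the atomic 22.989770): at a 0.01 Da
tolerance the 0.55 mDa electron makes a difference. Arbitrary rule sets —
e.g. 21 correlations over seven negative-mode adduct types — are built
with `adductSpec()` + `buildRules()`; only singly charged species are
supported (dimers and multiply charged ions are out of scope).

## Design choices

**Label resolution is exact, not greedy.** A feature can match several
rules with incompatible labels (is m/z 420.09 an `[M+Na]+` or a fragment
that happens to sit 15.976 Da below a cluster mate?). The resolver chooses
the joint labelling that maximises the number of accepted correlation
edges, breaking ties by minimal total absolute mass error and then by a
fixed lexicographic order, so results are deterministic and invariant
under row permutation. The search space is restricted to labels that occur
in candidate edges (provably sufficient), which keeps exact enumeration
cheap on real cluster sizes; a greedy pass ordered by ascending mass error
exists as a fallback for degenerate clusters with astronomically many
candidate labellings. We chose exact maximisation over pure greedy because
greedy can accept one small-error edge that blocks two mutually compatible
edges, silently losing a TRF.

**Cluster membership is trusted.** Flagging never re-checks correlation or
retention time inside a cluster: if upstream clustering grouped two
unrelated features whose m/z difference matches a rule delta, they *will*
be flagged — a documented failure mode of the approach that originates in
the clustering, not the flagger. An opt-in strict mode
(`flagCluster(..., strict = TRUE)`) re-imposes the manual-annotation
criterion (Pearson ≥ 0.8 and co-elution within 0.03 min) per edge.

**Fragment screening is single-pass.** Calls are computed against the
original cluster state; removing a fragment never changes other calls in
the same run (no cascade). The owner must have a larger precursor m/z than
the candidate — a fragment cannot outweigh its parent — which also rules
out mutual-removal cycles. A candidate's own MS2 is irrelevant; only the
owner's spectrum matters. No intensity floor is applied to owner MS2
peaks by default (the rule is a pure m/z existence test);
`ms2MinRelIntensity` is available for noisy spectra.

**Representative selection is automatic.** "Most intense" is measured as
the mean height over biological samples by default (maximum single sample
and QC mean are selectable); ties break by lower m/z, then feature id. An
intensity criterion stated for a manual step is thereby encoded as a
deterministic rule; the per-group tables written with the full output
support a manual review where one is wanted.

**Filters mark, downstream drops.** The blank and RSD filters set
`attribution = "interference"` but keep the rows, so every count ledger
satisfies `input = TRF + SRF + fragment + interference` at each stage and
the full output remains auditable. Only the `final` writer drops
non-representative TRFs, fragments and interference.

Degenerate inputs are handled conservatively: unparseable MS2 strings
become empty spectra with a warning (never an error), constant-height
features have undefined Pearson correlation and are left as singletons,
clustering on fewer than three biological samples is refused, and an empty
input file is a format error rather than an empty table.

## The synthetic study

`simulatePeakTable()` generates peak tables with known ground truth so
that every stage is testable without instrument data. The default
configuration — the package's reference study — is 200 compounds with
neutral masses uniform in 150–1000 Da and retention times in 1–18 min;
each compound emits its quasi-molecular ion (dropped for 10 % of
compounds, which then receive at least two other adducts, exercising the
no-quasi-molecular-ion recovery path) and each further adduct with
probability 0.4; 30 % of compounds shed 1–2 in-source fragments whose m/z
(precursor minus water/formic acid/hexose or a uniform 20–120 Da loss) is
planted in the precursor's MS2; m/z jitter is Gaussian with sd 0.002 Da
(typical QTOF mass accuracy), RT jitter 0.005 min. The biological design
is 4 classes × 3 replicates plus one blank and two pooled QCs; compound
abundances share class, sample and compound effects so that
within-compound features are Pearson-correlated while within-class RSD
stays near 0.25; 50 uncorrelated noise singletons are added, 30 % of them
blank-dominated.

The generator actively avoids confounds so that planted truth is exact:
fragment m/z values are redrawn when they would sit within 0.05 Da of an
adduct-correlation delta against any cluster member, and background MS2
peaks are kept at least 0.2 Da away from every member's MS1 m/z. Real data
offer no such courtesy — the simulation validates the *rule*, not the
rate of coincidental matches in a given instrument's data. It also does
not simulate isotope envelopes, chromatographic peak shapes, multiply
charged species or cross-cluster fragment sharing, so perfect recovery on
synthetic tables is a correctness statement about the implementation, not
a performance claim about any real study.

`scoreAgainstTruth()` compares a rating with the planted construction:
the expected attribution is TRF for members of compounds with at least
two correlated adduct forms, fragment for planted fragments, interference
for blank-dominated noise (once the blank filter has run), SRF otherwise.
The RSD filter is a statistical screen on replicate noise: with three
replicates its sample RSD occasionally exceeds the threshold for a
genuine feature, which is expected behaviour of the filter rather than a
rating error, so truth-recovery comparisons run the pipeline with the RSD
filter disabled while the filter's own behaviour is tested on fixed
fixtures.

The test suite's problem sizes are chosen to keep the whole suite fast
while still exercising every code path: oracle-equivalence checks run
1000 random clusters of up to 6 (adduct resolution, against a full
exhaustive enumeration) and 8 members (fragment calls, against a
triple-loop reference); recovery checks use the 200-compound study at
zero jitter (exact recovery) and at 0.002 Da jitter (recall ≥ 0.99 at the
0.01/0.05 Da tolerances).

## Known limitations

* Charge states other than 1, dimers (`[2M+H]+`) and isotopologues are
  not modelled; upstream tools should deconvolute them first.
* Fragment screening cannot see fragments whose parent lost its MS2
  acquisition, nor fragments clustered apart from their parent
  (cross-cluster search is out of scope).
* The adduct flagger inherits upstream clustering mistakes by design
  (see strict mode above).
* Blank/RSD prefilters are minimal re-implementations for
  self-containedness, not a replacement for a full cleaning tool
  (no mass-defect filters, no drift correction, no ghost-peak logic).

## A complete run

```{r example}
sim <- simulatePeakTable(simConfig(nCompounds = 20, nNoiseFeatures = 8,
                                   seed = 42))
out <- file.path(tempdir(), "demo-run")
res <- runPipeline(sim$table, out)
res$summary[c("counts", "real_fraction", "final_table_size")]
scoreAgainstTruth(res$result, sim$truth, res$table)[c("trf", "fragment")]
```
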