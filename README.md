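# PromCliff

Compound promiscuity profiling and promiscuity-cliff analysis for
qualitative screening data.

## What problem this solves, and for whom

Public high-throughput screening repositories report, for very large
compound collections, binary per-assay outcomes (*active* / *inactive*)
against hundreds of protein targets. For chemical biologists and
polypharmacology-oriented medicinal chemists, such matrices are the raw
material for questions like: which compounds are genuinely active against
many targets, which of those hit targets from *different* target classes
(and are therefore candidates for polypharmacology or binding-mode
studies), and which single-atom structural changes switch a compound
between consistently inactive and highly promiscuous?

Answering those questions naively is dangerous, because apparent
promiscuity is often an assay artifact (pan-assay interference
substructures, colloidal aggregation, reactive chemistry). PromCliff
implements the full, artifact-aware analysis pipeline in R.

## The analysis in standard notation

For each compound *c*, qualitative calls are aggregated per target; a
compound–target pair with contradictory calls is discarded entirely. The
**promiscuity degree** is

> PD(c) = |{targets with a consistent "active" call for c}|

computed only for compounds tested against ≥ 100 distinct targets, and
after removal of compounds flagged by any of three PAINS SMARTS catalogs,
an aggregation-likeness screen (Tanimoto ≥ 0.85 to a known aggregator
**and** Crippen-type atomic-contribution logP ≥ 3), or a
medicinal-chemistry alert rule set.

A **matched molecular pair** (MMP) is a pair of compounds differing by a
single-site substituent exchange over an identical core, found by
single-cut fragmentation with canonical core indexing under transformation
size restrictions (substituent ≤ 13 heavy atoms, core ≥ 2× substituent,
exchange difference ≤ 8). A **promiscuity cliff** (PC) is an MMP with
PD ≥ 10 on one side and PD ≤ 1 on the other. Cliffs form a bipartite
**PC network** in which multiclass ligands with ≥ 10 cliff edges are
**promiscuity hubs** and maximal simple paths are alternating
**PC pathways**. A **multiclass ligand** is a compound with PD ≥ 10 whose
active targets span ≥ 2 of eight drug-target classes (Enzymes, GPCRs,
Transcription factors, Ion channels, Receptors, Transporters, Others,
Unclassified), assigned by ordered keyword rules.

Because real screening snapshots are neither redistributable nor stable,
the package ships a deterministic synthetic-data generator with planted
ground truth (analog series, planted PD values, spiked liability
compounds, injected call conflicts) against which every stage is
validated.

## Worked example

Three biphenyls differing at one position — unsubstituted, chloro, and
methyl — with activity profiles in which the chloro compound is active
against 34 of 178 tested targets while the parent is inactive in all 195
assays, 170 targets being shared:

```r
library(PromCliff)

cs <- standardizeMolecules(
  c("c1ccc(-c2ccccc2)cc1", "Clc1ccc(-c2ccccc2)cc1", "Cc1ccc(-c2ccccc2)cc1"),
  ids = c("biphenyl", "chloro", "methyl"))

mmps <- findMMPs(cs)
mmpTable(mmps)[, c("compound_a", "compound_b", "core", "transformation")]
#>   compound_a compound_b                core transformation
#> 1   biphenyl     chloro *c1ccc(cc1)c1ccccc1  [*][H] >> *Cl
#> 2   biphenyl     methyl *c1ccc(cc1)c1ccccc1   [*][H] >> *C
#> 3     chloro     methyl *c1ccc(cc1)c1ccccc1      *Cl >> *C
```

All three pairs share the canonical biphenyl core; hydrogen counts as a
substituent, so the H ≫ Cl and H ≫ CH3 replacements are found. Given the
activity profiles (`promiscuityDegree(prof)` returns 0, 34 and 2), cliff
detection keeps exactly the pair crossing the promiscuity thresholds:

```r
cliffTable(detectPromiscuityCliffs(mmps, prof))
#>   promiscuous_id partner_id pd_promiscuous pd_partner                core
#> 1         chloro   biphenyl             34          0 *c1ccc(cc1)c1ccccc1
#>   transformation shared_tested
#> 1  *Cl >> [*][H]           170
```

One chlorine atom separates a compound active against 34 targets from one
consistently inactive in 195 assays — with 170 shared tested targets
giving both compounds comparable opportunity to show activity. The
methyl analog (PD = 2) is on neither side of the cliff definition and is
correctly absent.

The full pipeline (aggregation, filters, census, classes, MMPs, cliffs,
network, deposition-style exports) runs from TSV inputs in one call:

```r
dat <- generateScreeningData(syntheticSpec(seed = 1), "demo_data")
res <- runPipeline(pipelineConfig("demo_data", "demo_out"))
res$summary$n_promiscuity_cliffs
#> [1] 1200
```

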