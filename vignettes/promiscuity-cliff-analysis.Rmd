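---
title: "Promiscuity profiling and promiscuity-cliff analysis of qualitative screening data"
author: "PromCliff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promiscuity profiling and promiscuity-cliff analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis

Large public screening repositories report, for hundreds of thousands of
compounds, qualitative per-assay calls — *active* or *inactive* — against
hundreds of protein targets. PromCliff implements a promiscuity analysis of
such data: how many distinct targets is each compound active against
(its **promiscuity degree, PD**), which highly promiscuous compounds hit
targets from several distinct drug-target classes (**multiclass ligands**),
and which minimal structural changes separate a highly promiscuous compound
from an inactive analog (**promiscuity cliffs, PCs**).

The analysis is deliberately potency-free. Screening potency values are
assay-dependent and sparse, so only the binary call is used, and promiscuity
is a count over targets, not an affinity profile. The compensating safeguards
are (i) a test-frequency requirement, (ii) a consistency rule for repeated
measurements, and (iii) aggressive removal of compounds prone to assay
artifacts, accepting false negatives to avoid false-positive promiscuity.

## Activity aggregation and the consistency rule

Raw calls are aggregated per compound–target pair:

* consistent duplicate calls collapse to one;
* a pair with at least one *active* and one *inactive* call is
  **discarded** — it counts neither as tested nor towards PD;
* PD = number of targets with a consistent *active* call.

Only compounds tested against at least 100 distinct targets (after conflict
discarding) enter the analysis; this `minTested` threshold is the
test-frequency safeguard that makes a PD of 0 meaningful ("consistently
inactive despite extensive testing"). Whether discarded pairs should count
towards the threshold is genuinely open; PromCliff excludes them, on the
reading that a discarded interaction provides no usable evidence either way.

## Liability filters

Apparent promiscuity is frequently an artifact. Three filter families are
applied, and a compound must pass **all** of them:

* **PAINS substructures** — three named SMARTS catalogs; a match in any
  catalog flags the compound. Published PAINS catalogs differ between
  sources, so the engine is data-driven: any three catalog files can be
  configured. The shipped catalogs are a representative self-curated subset
  of the published PAINS chemotype classes (rhodanines, catechols, quinones,
  azo compounds, alkylidene barbiturates, ...), sufficient for the shipped
  analyses and tests; site-specific full catalogs drop in without code
  changes.
* **Aggregation likeness** — colloidal aggregators cause non-specific
  inhibition. Following the published advisor logic, a compound is flagged
  when its nearest Tanimoto similarity (FP2 path fingerprints) to a curated
  list of known aggregators is ≥ 0.85 **and** its calculated logP is ≥ 3.
  Both conditions are required: an exact structural match with logP < 3
  (e.g. resveratrol in the shipped reference list) is not flagged.
* **Medicinal-chemistry structural alerts** — a data-driven rule engine
  (SMARTS with category labels: acylating agents, aldehydes, chelators,
  reactive electrophiles, ...). The original industrial rule system uses
  demerit scores; since the analysis only needs exclusion, matching is
  reduced to binary reject.

The final passing set is a pure intersection, so the cascade order affects
only the staged attrition counts reported alongside the results, never the
outcome — a property the test suite verifies by permuting the order.

logP is computed as a sum of atomic contributions (Wildman–Crippen scheme,
via OpenBabel). It is deterministic and representation-invariant; the test
suite pins the single-atom case to the hand-summed contribution table value
(methane: one aliphatic carbon + four hydrogens = 0.6361).

## PD census and distribution summaries

The census counts compounds in the bins *all*, PD = 0, PD = 1, PD ≥ 2, 5,
10, 15. Two invariants are asserted on every call, not assumed:
conservation (PD=0 + PD=1 + PD≥2 = all) and nesting (counts over the ≥ bins
are non-increasing). Distribution summaries (tested targets per PD bin;
logP per promiscuity stratum) use five-number summaries with quartiles by
linear interpolation between order statistics (R's default type-7 — stated
because quartile conventions differ between tools) and boxplot outliers
beyond 1.5×IQR whiskers. Kernel densities for logP strata use a Gaussian
kernel with Scott's-rule bandwidth and are cosmetic output only.

## Target classes and multiclass ligands

Targets are assigned to eight classes (Enzymes, G protein-coupled
receptors, Transcription factors, Ion channels, Receptors, Transporters,
Others, Unclassified) by ordered, case-insensitive keyword rules over
protein and family names. Precedence is specific-before-generic: enzyme
keywords come first, so a "receptor tyrosine kinase" classifies as an
enzyme and the bare "receptor" rule is the last keyword resort. "Others"
is an aggregate of small classes with no defining keyword, so it is only
ever assigned through an explicit label in the target table. Every target
receives exactly one class; unmatched targets are Unclassified.

A **multiclass ligand** is a compound with PD ≥ 10 whose active targets
span at least two classes. The PD ≥ 10 threshold follows established
promiscuity analyses in which this level marks the confined top of the
promiscuity distribution. The complementary set — compounds with PD ≥ 2
active in a single class — is reported as single-class promiscuous.

## Matched molecular pairs and promiscuity cliffs

An MMP is a pair of compounds that differ by a substituent exchange at a
single site over an identical core. PromCliff enumerates single cuts of
acyclic single bonds between heavy atoms (ring bonds are never cut),
canonicalizes both fragments with the attachment point encoded as a
wildcard atom, and indexes cores by exact canonical-string equality, so
the pair search is a hash join rather than a quadratic scan. A hydrogen at
any position is treated as a valid substituent during matching, making
hydrogen-replacement transformations (H ≫ Cl, H ≫ CH3) discoverable —
exactly the transformations observed in exemplary cliffs.

Transformation size restrictions keep pairs chemically meaningful:
substituents of at most 13 heavy atoms, a core at least twice the size of
each substituent, and at most 8 heavy atoms difference between exchanged
substituents. The exact values are not fixed by the analysis itself; the
defaults follow the established MMP-with-size-restrictions methodology and
all three are configurable. Single cuts only: the transformations of
interest are single-site substituent exchanges, not core rearrangements.

A **promiscuity cliff** is an MMP whose members sit at opposite ends of
the promiscuity scale: one member with PD ≥ 10, the other with PD ≤ 1
(single-target or consistently inactive). Each cliff records the number of
shared tested targets of its two members — the confidence measure that
both compounds had comparable opportunity to show activity.

Correctness of the pair engine is established two ways: a reconstruction
invariant (every fragmentation welds back to its parent's canonical
SMILES) and equivalence with an independent brute-force pairwise oracle on
random small sets.

## The PC network

Cliffs form a bipartite network (promiscuous vs non-promiscuous side);
bipartiteness is checked at construction and a violation is a hard error
since it can only arise from an upstream bug. **Promiscuity hubs** are
multiclass-ligand nodes with at least 10 cliff relationships; the fixed
threshold is primary because it is exactly testable, with an
above-average-degree mode available as an alternative. **PC pathways**
are maximal simple paths, enumerated by depth-first search with
lexicographic tie-breaking (deterministic) and a hard cap; bipartiteness
makes them alternate between promiscuous and inactive compounds, and the
alternation is re-verified on every reported path. Whether such pathways
should be maximal paths or curated selections is open in general; maximal
paths were chosen because they are well-defined and reproducible.

## The synthetic-data generator

Real screening snapshots are neither redistributable nor stable over time,
so every pipeline stage is validated against generated data with planted
ground truth. The generator emulates:

* **analog series**: 25 scaffolds (a 5 × 5 grid of skeleton-distinct
  two-ring systems) × 21 substituents (including hydrogen) = 525
  compounds. Within a series every pair differs at exactly one site, so
  all C(21,2) intra-series pairs are true MMPs; substituents are capped at
  3 heavy atoms so that cutting the scaffold's ring-link bond can never
  satisfy the 2:1 core ratio, which guarantees zero cross-series pairs.
* **test frequency**: each compound is tested on 120–160 of 160 targets —
  the regime of extensively tested screening compounds (tested-set sizes
  well above the selection threshold, median far above it) at a scale that
  keeps the full test suite fast.
* **planted PD**: per series {0×7, 1×5, 2, 3, 4, 5, 7, 12, 13, 16, 20},
  giving 175/125/225/150/100/50 compounds in the census bins and four
  highly promiscuous members per series, each with 12 low-PD analogs
  (1200 planted cliffs; every promiscuous compound is a hub candidate).
* **class structure**: 160 targets over the eight classes with
  enzyme-dominant sizes; actives of promiscuous compounds spread over 2–6
  classes, with one series planted single-class (including one PD = 12
  single-class compound, mirroring the rare single-class highly
  promiscuous case).
* **noise**: consistent duplicate calls at 3%, and (optionally)
  contradictory duplicate calls at a configurable rate. Conflicts are
  injected on tested-inactive pairs: they reduce the tested count and must
  surface in the discarded set, while the planted PD remains the exact
  recovery truth.
* **liabilities**: nine spiked compounds, three per filter family, each
  labeled with the family that must flag it.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: realistic assay noise beyond binary
conflicts, potency information, correlated activity between structurally
similar compounds, target panel structure, or the heavy-tailed compound
series sizes of real screening collections. The recovery results (100% PD
recovery, perfect cliff precision/recall) certify the implementation on
noiseless planted truth, not the biology of any particular snapshot; the
corresponding headline counts of any real data set depend on the snapshot
and on the exact filter catalogs used, and are deliberately not
reproduction targets.

## Numerical and degenerate-input choices

* Standardization keeps the largest contiguous fragment, neutralizes
  simple charges and canonicalizes tautomers as given (no enumeration);
  the recipe is idempotent and unparseable inputs go to an explicit
  rejection log.
* Molecules with no eligible bond (single atoms, pure ring systems)
  simply yield no fragmentations; they can still form MMPs as the
  hydrogen-bearing member of a pair.
* When one unordered pair is reachable through several cores (nested
  substituent cuts), the recorded transformation is the smallest one,
  with a lexicographic tie-break, so output is deterministic and
  input-order independent.
* Empty inputs propagate as empty results everywhere except where the
  contract demands an error (empty aggregator reference list, malformed
  SMARTS, unknown outcome tokens, unknown target ids).
* All randomness in the generator flows from a single integer seed
  through R's RNG; identical spec and seed give byte-identical data.

## Problem sizes

The shipped validation uses the full 525-compound reference conditions for
end-to-end checks (including the ~5,250-pair MMP search) and reduced 2 × 2
scaffold grids for unit tests. The brute-force MMP oracle is compared on
random subsets of ≤ 50 molecules, where the quadratic scan is exact and
cheap; pathway enumeration is cross-checked against exhaustive path
enumeration on random networks of ≤ 9 nodes.

## Known limitations

* OpenBabel canonical SMILES defines fragment identity; a different
  toolkit's canonicalization would partition cores identically in almost
  all cases but is not guaranteed byte-compatible.
* The shipped PAINS/alert catalogs are representative subsets; absolute
  filter attrition on real data depends entirely on the catalog files
  supplied.
* Stereochemistry is carried through canonical SMILES but cuts are
  constitutional: a pair differing only in stereochemistry is not an MMP
  (identical canonical cores and substituents collapse).
* The keyword classifier is a flat first-match scheme, not an ontology;
  targets with adversarially ambiguous names follow rule order.
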