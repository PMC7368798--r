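---
title: "Family-structure-aware candidate-variant filtering: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-structure-aware candidate-variant filtering: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical exome/genome analysis of a rare-disease patient leaves thousands of
candidate variants after basic quality and frequency filters. Genotyping
additional family members shrinks that set by *segregation*: a true recessive
causal variant must be homozygous in every affected member, heterozygous in
unaffected carrier parents, and must not be homozygous in any unaffected
member. `pedseg` implements this filtering for the three designs used in
clinical practice — trio (index + parents), sibship (index + siblings, no
parents), and incremental extended-family testing (index, then parents, then
further siblings, up to eight members) — together with a synthetic cohort
generator for consanguineous families, so the whole pipeline can be exercised
and validated end-to-end without patient data.

## Filtering model

Site-level filters come first: the caller FILTER must be PASS, and the
population allele frequency must satisfy AF < 1.5% (strict, matching the
usual clinical phrasing). A genotype call is only trusted at depth ≥ 20x
(inclusive); an under-covered call is downgraded to MISSING rather than
discarding the site. Mitochondrial records are excluded (heteroplasmy breaks
the diploid zygosity model). The depth rule is per-call by default; a
`depth_scope = "site"` switch drops a site unless every tested member meets
the bound, since some laboratories apply the rule per site.

Zygosity is classified per call as HOM_ALT / HET / HOM_REF / MISSING. On chrX
males are hemizygous and **any alt-carrying call is counted homozygous**,
including diploid-coded `0/1` calls, which real callers emit on X.
Pseudoautosomal regions are not special-cased; this is a documented
limitation. Females on X follow the autosomal rule, as do samples of unknown
sex.

Two inheritance models are evaluated, separately or united (`model =
"both"`):

* **recessive homozygous** — index and affected relatives HOM_ALT, unaffected
  parents of the index HET (the parental-carrier rule), unaffected relatives
  anything but HOM_ALT (carriers are allowed — forced by recessive genetics);
* **de novo** — index and affected relatives carry the alt, parents and
  unaffected relatives HOM_REF. With unaffected parents under full
  penetrance, de novo is the only coherent reading of a heterozygous
  candidate in a trio; an `inherited_het` relaxation (parents may be
  carriers) is available for sensitivity analysis.

Under `"both"`, candidates are stratified by the index's zygosity
(homozygous/heterozygous) and by region (coding/noncoding), mirroring the
four-way tables used in extended-family reports.

### Missing genotypes

A MISSING genotype in a relative is non-informative: the constraint is
skipped (permissive default), because clinical practice does not discard a
candidate over a relative's coverage gap. A `missing_policy = "strict"`
switch treats MISSING as incompatible instead. The index is the exception
under either policy: a candidate is by definition a variant *observed* in the
patient, and the stratification needs the index's zygosity, so an index
MISSING call is never compatible. This also keeps `segregation_filter` with
`tested = index` equal to "all pass-filter sites where the index carries a
determinate candidate genotype".

### Trio versus sibship comparison

`compare_trio_vs_sibship()` reports *recessive-model* coding counts for both
strategies, not the homozygous stratum of the united model. The distinction
matters: the united model also retains index-homozygous sites whose parents
are homozygous-reference — under unaffected parents those are almost always
genotyping artifacts, and excluding them is exactly what the parental-carrier
rule is for. Using the recessive model on both sides makes the comparison a
clean contrast of the parental constraint against the sibling constraints.
The function also reports the counts of sites homozygous-alt in all affected
and in all unaffected members of the sibship, the two "shared homozygous"
summaries quoted in family studies.

## Region classification

A variant is coding or noncoding by the most severe of its consequence terms
under a fixed, documented severity ranking modelled on the standard
sequence-ontology hierarchy — reproducibility is preferred over fidelity to
any particular annotator. Synonymous and stop-retained terms map coding (they
mark exonic positions); splice-region, UTR, intronic, up/downstream and
intergenic terms map noncoding, following the working dichotomy of exonic
versus intronic. Unknown terms rank least severe and map noncoding. Both the
order and the class map are overridable. Unannotated sites can fall back to a
BED-like gene model (1-based inclusive by default to match VCF coordinates,
with a zero-based switch); with neither annotation nor model the class is
noncoding, keeping the function total.

## The synthetic cohort generator

The generator emulates the situation the filters are designed for: a
consanguineous family segregating a recessive disorder, sequenced at clinical
depth.

* **Pedigree.** One great-grandparental couple, two of their children married
  to unrelated founders, producing a father and mother who are first cousins
  (offspring inbreeding coefficient F = 1/16 — the canonical consanguinity
  depth; the generator tracks founder alleles so autozygosity is emergent and
  measurable rather than asserted). The octet template tests index, parents
  and five siblings (affected, unaffected, unaffected, affected, unaffected —
  the member-addition order of the extended-family analysis); the quintet
  template tests index, parents and two siblings. For the quintet the default
  siblings are unaffected: a single affected child with parents and healthy
  siblings is the most common presentation of a recessive family, and the
  affection mix in published sibship cohorts is not stated.
* **Sites.** 100,000 independent rare population sites with AF log-uniform on
  [1e-4, 0.015) — all below the 1.5% filter, as real pipelines apply the
  frequency cut upstream — plus 1,000 family-enriched sites drawn in the
  founders at pool frequency 0.3 while their *database* AF is still drawn
  from the rare spectrum. These model locally common alleles invisible to
  population databases; they are what the parental and sibling constraints
  mostly remove, and they drive the large index-to-trio drop. 2% of sites are
  coding (missense vs intronic consequence terms), 5% lie on chrX with true
  hemizygous male emission. No linkage and no recombination map: the analysis
  counts per-site candidates, and linkage would only correlate counts between
  sites, which replicate medians absorb.
* **Noise.** Genotype error flips each emitted call to a uniformly chosen
  different code with probability 0.005; de novo alt alleles arrive at mean 1
  per offspring; depth is Poisson at mean 90 (WES profile; 30 for WGS), with
  1% of calls drawn at mean 10 so the 20x rule is exercised.
* **Causal variant.** One autosomal coding population site is overwritten
  error-free with the full recessive pattern (alt introduced in a
  great-grandparent, both parents heterozygous, index and affected siblings
  homozygous, unaffected siblings carriers or reference), depth forced to
  ≥ 20 in every member. With genotype error disabled, it is retained by every
  strategy at every step by construction — the recovery tests verify this
  end-to-end through the pipeline.

What the generator does **not** emulate: linkage disequilibrium, indel
realignment artifacts, batch effects, population stratification of the AF
spectrum, pseudoautosomal X behaviour, compound heterozygosity. Passing tests
therefore demonstrate the correctness of the segregation logic and the
direction and rough magnitude of the reduction curves, not the absolute
candidate counts of any real cohort — those depend on capture design,
annotation pipeline and population, and the patient-level inputs behind the
published counts are not available.

## Worked example

```{r, eval = FALSE}
library(pedseg)

sim <- simulate_cohort(sim_config(seed = 1))
curve <- incremental_reduction(sim$vt, sim$ped)
curve
reduction_percentages(curve)

cmp <- compare_trio_vs_sibship(
  simulate_cohort(sim_config(template = "quintet", seed = 1))$vt,
  simulate_cohort(sim_config(template = "quintet", seed = 1))$ped)
cmp
```

## Numerical and design choices

* Boundary semantics are fixed by the clinical phrasing: AF strictly `<`
  0.015, depth inclusive `≥` 20.
* Percent drops are `100 * (1 - total_k / total_(k-1))`; a zero previous
  total defines the drop as 0.
* Step labels follow the count of tested individuals (Index, Trio, Quartet,
  ..., Octet); when steps two and three are exactly the two parents, step
  two is already labelled Trio, because the trio constraint binds only once
  both parents are present; a two-member plan is labelled by its count.
* Index selection in PED files without a proband column: the first affected
  member in file order — deterministic and matching clinical convention.
  Unknown-affection members are carried through I/O but impose no
  segregation constraint. Half-siblings count as siblings.
* Multi-allelic splitting recodes an allele matching a *different* alt as
  unobserved, leaving a half-call: the sample still counts as a carrier of
  the retained alt (no carrier is invented or lost), but a half-call on an
  autosome classifies only by its observed allele (alt half-calls as HET,
  ref half-calls as HOM_REF). No left-alignment or coordinate lifting is
  performed; inputs are assumed normalized, as the simulator's are.
* Aggregated replicate tables keep exact fractional means in JSON and round
  half-up only for display.
* Test and validation problem sizes: exhaustive enumerations (27 trio / 243
  sibship genotype configurations) are checked in full; replicate-based
  checks use 20 full-size cohorts (101,000 sites); structural properties
  (monotonicity) use 50 reduced cohorts of 2,200 sites, since they hold
  site-by-site and do not depend on scale.

## Limitations

Compound heterozygotes are not modelled (a non-goal inherited from the
analysis design). X handling treats the whole chromosome as hemizygous in
males. The severity ranking is a fixed approximation of annotator behaviour.
Site-frequency and enrichment parameters are scenario choices, not fits to
any dataset.
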