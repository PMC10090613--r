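---
title: "Integrative species delimitation from multi-marker barcode data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation from multi-marker barcode data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otudelim)
```

## The problem

Morphologically conservative parasite groups — the motivating case is
*Bivesicula* (Trematoda: Bivesiculidae) from Indo-Pacific holocentrid,
muraenid and serranid fishes — often cannot be delimited from morphology
alone. Mitochondrial barcodes (cox1) resolve fine-scale structure that the
ribosomal markers (ITS2, 28S rDNA) miss entirely, but cox1 alone
over-splits: reciprocally monophyletic regional populations of one species
can differ at levels comparable to differences between good species.
`otudelim` implements the criterion-based integrative workflow for this
situation:

1. **Distances.** Raw pairwise base-position differences ("number of
   differences"), with *pairwise deletion* of columns carrying gaps, `N`
   or IUPAC ambiguity codes. The metric is deliberately model-free: at
   barcode-scale divergences the count of differing positions is the
   quantity practitioners reason with, and a rates-across-sites model
   would be a no-op on it.
2. **OTUs.** Single-linkage clustering at a raw-difference threshold
   (default 10): sequence pairs differing at fewer than 10 positions are
   treated as intraspecific variation, and OTUs are the connected
   components of the resulting graph. Chaining is an accepted property of
   this criterion and is documented by a worked test case.
3. **Trees.** Unrooted neighbour joining on the same distances, with
   column-bootstrap supports attached to edge-induced bipartitions.
4. **Decision engine.** Species are recognized when they are reciprocally
   monophyletic on the most informative marker **and** separated from
   their neighbours by morphological distinction or by biological
   distinction (disjoint host-family distributions). Two OTUs merge into
   one species only when they are morphologically indistinguishable,
   host-overlapping, and jointly form a clade of the guide tree.

## The decision rule in detail

`delimit_species()` operates on an `evidence_table()`: OTU labels, a guide
tree over OTUs, a symmetric matrix of pairwise flags (morphology:
`distinct` / `indistinguishable` / `unknown`; biology: `distinct` /
`overlapping` / `unknown`), host records, and optional morphology-only
taxa. A pair of OTUs is *merge-compatible* iff morphology is
`indistinguishable` and biology is `overlapping`; `unknown` blocks
merging, which is what keeps a sequence-only OTU (no morphological
specimen) separate and `provisional_sequence_only`. Species are the
maximal bipartition-clades of the guide tree whose members are pairwise
merge-compatible. Maximality plus pairwise compatibility makes these
clades non-overlapping (the engine asserts this rather than assuming it).

Two consequences are worth spelling out because they are the scientific
point of the rule:

* **Cryptic non-sister pairs stay split.** If OTUs X and Y are
  indistinguishable and host-overlapping, but every guide-tree clade
  containing both also contains a clearly distinct species Z, no
  compatible clade covers X and Y, and they remain separate species. The
  justification trace records this as topological separation ("separated
  by another clearly distinct species"). This is exactly the situation of
  *B. sheni* vs *B. claviformis*, with *B. obovata* as the wedge.
* **Deep conspecific populations merge.** Distance is deliberately *not* a
  criterion: regional populations differing at up to 23 cox1 positions
  merge into one species when they are indistinguishable, host-overlapping
  and form a clade. An optional `merge_distance_ceiling` exists for
  sensitivity analyses only; it is off by default.

Reciprocal monophyly is assessed on the single configured most-informative
marker (default priority cox1 > ITS2 > 28S). Additional marker trees are
reported, never vetoing: ribosomal markers that fail to resolve a species
complex should not be able to overturn a resolution the informative marker
supports.

Morphological distinction is an expert input flag, not something computed
from measurements: published distinctions in this group ("massive body
form", "relatively small cirrus-sacs") are judgements a rank test cannot
replace. `shape_comparison()` supports such judgements — per-group
summaries, cross-group exceedance counts and a Wilcoxon test on the
elongation ratio — and the test is labelled in reports as an analytic
addition, since the workflow it emulates plotted shapes without testing.

## The worked evidence fixture

`bivesicula_evidence()` encodes, from embedded constants, the full
evidence set of the bivesiculid study: 15 cox1 OTUs in three clades
(9 + 4 + 2), the guide-tree topology over OTUs, distinction flags, host
and locality records with prevalences, *B. nana* as a morphology-only
taxon, and published raw-difference anchors (e.g. 35 cox1 differences
between *B. neglecta* and *B. unexpecta*) used for cross-checks. Two OTUs
derive from archival comparative material from apogonid/pomacentrid hosts;
they carry a `comparative` flag and the engine reports them separately
from the focal hypothesis set, so the focal count matches the collection
under study. The OTU numbering inside the pairs 8/9 and 14/15 is not
determined by the source and is fixed here by convention.

```{r fixture}
fx <- bivesicula_evidence()
res <- delimit_species(fx$evidence)
res
explain_decision(res, "Bivesicula sheni", "Bivesicula claviformis")
```

## Diagnostics

`composition_chi2()` is the classic R×C chi-square of per-taxon base
counts against the pooled expectation, with degrees of freedom
`3 * (n_taxa - 1)` by the convention of phylogenetic software (empty base
classes contribute nothing to the statistic but are not subtracted from
the df). `saturation_index()` scores mean per-column Shannon entropy
against a *seeded randomization null* in which every column is redrawn
i.i.d. uniformly over the four bases: the alignment is called saturated
when its index is not significantly below that full-saturation null
(one-sided, default α = 0.05). Published saturation tests rely on critical
values from an external simulation study; the randomization null
reproduces the same decision semantics while being fully reproducible
offline from a seed. Diagnostics annotate the run report and never block
the pipeline — they are go/no-go context, not filters.

## Numerical choices

* **NJ determinism.** When several pairs minimize the Q criterion, the
  pair with the lexicographically smallest (min label, max label) key is
  joined, clusters being keyed by their smallest leaf label. Negative
  intermediate branch lengths are clamped to zero with the deficit
  transferred to the sister edge, preserving the joined pair's path
  length. These conventions are not claimed to coincide with any
  particular desktop program's internal tie policy; topology-level
  properties (exact recovery of additive matrices) are the tested
  contract.
* **Undefined distances.** A pair with zero jointly comparable columns is
  `NA`, never 0. `neighbor_joining()` refuses such matrices listing the
  offending pairs; `cluster_otus()` treats them as non-edges and isolates
  fully non-overlapping fragments as warned singletons.
* **Bootstrap.** Supports are computed for the point-estimate tree's
  bipartitions only (no consensus tree), matching how supports are drawn
  on a single NJ phylogram. Replicates whose resampled columns leave a
  pair undefined are discarded and counted; more than 10% discarded is an
  error. The default is 1000 replicates: the properties of interest are
  threshold exceedances (e.g. supports above a display cut-off), which
  stabilize well below publication-grade replicate counts; 10000 remains a
  configuration choice.
* **Ambiguity codes** are accepted on input and treated as missing in all
  distance work, matching a joint "gaps/missing data" treatment; `U` is
  normalized to `T` on read.

## What the generators emulate — and what they do not

`simulate_tree_sequences()` evolves sequences along a tree under
Jukes–Cantor (via `phangorn::simSeq`), with branch lengths calibrated by
the inverse JC map from target expected raw differences on a 474-column
cox1-like fragment. The default design (`default_sim_spec()`) plants the
study-shaped structure: three deep clades (~80 expected differences
apart), species ≥ 40 apart, regional populations of one species ~16 apart,
and ~2 expected differences within species. JC is intentionally the
simplest adequate process: the pipeline's metric is model-free raw
differences, so richer substitution models would add parameters without
exercising anything new. The generator does **not** simulate indels, rate
heterogeneity or base-composition drift, so passing tests say nothing
about robustness to alignment error or compositional non-stationarity —
which is precisely why the diagnostics module exists on real data.

`simulate_morphometrics()` draws lognormal body lengths and elongation
ratios with a multiplicative host-family effect on the ratio (default 1.5,
serranid-hosted specimens more elongate than holocentrid-hosted ones,
`sdlog` 0.12 chosen so simulated ratios span the published 1.6–3.6 range).
Width is derived as length/ratio so the scatter is jointly consistent.

## Problem sizes used in the test suite

The suite verifies NJ topology recovery on 200 random additive matrices
of 4–12 taxa, compares the monophyly test with exhaustive split
enumeration on all tip subsets of trees with up to 7 leaves, recovers
planted OTU partitions on 100 seeded simulations (474 columns, 6–12
sequences), checks the pairwise-deletion distance against a brute-force
column-by-column oracle on 1000 random alignments (≤ 8 sequences × ≤ 40
columns), and measures ≥ 95% rejection at α = 0.01 for the morphometric
host effect over 100 seeded draws of 40 specimens per family. These sizes
were chosen as the smallest at which the properties are sharp; all are
fixed-seed and deterministic.

## Known limitations

* Alignment construction and trimming are out of scope: inputs are
  pre-aligned, and published alignment-length values depend on unpublished
  trimming coordinates.
* Maximum-likelihood and Bayesian tree inference are not provided; the NJ
  guide tree is the decision substrate, as in the workflow emulated.
* Whether the deposited subset of sequences reproduces the full study's
  OTU count cannot be guaranteed (not every analysed sequence was
  deposited); `verify_published_anchors()` therefore reports the OTU count
  on deposited data without a hard reference value.
* The decision engine is only as good as its flags: it formalizes expert
  judgements, it does not produce them.
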