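---
title: "Finding broad-host-range plasmids with cognate similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding broad-host-range plasmids with cognate similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidrange)
```

## The problem and the model

A broad-host-range (BHR) plasmid is one that replicates in bacteria from
more than one taxonomic group. Direct experimental host-range assays do not
scale to public sequence databases, but the databases contain an indirect
signal: when near-identical copies of the same plasmid are deposited from
isolates of *different* taxa, the plasmid has, at minimum, been maintained in
all of them. `plasmidrange` operationalizes this idea as a pipeline:

1. **Screen** a plasmid sequence collection down to complete, non-phage
   records, using title keywords and (optionally) an assembly-completeness
   flag in the metadata.
2. **Align** every record against every other and keep, per ordered pair,
   the single best-scoring local alignment (one HSP).
3. **Filter** hits to *cognate* links: query coverage strictly above 80%,
   and the two sequence lengths within 80% of each other
   (`min(qlen, slen) / max(qlen, slen) >= 0.80`). The coverage rule discards
   shared-gene matches between otherwise different plasmids; the length rule
   discards containment of a small plasmid (or fragment) in a larger one.
4. **Group** records into connected components of the undirected graph whose
   edges are cognate links. Each multi-member component is one cognate
   group; singletons are plasmids with no detected cognates.
5. **Classify** each group's host range as `inter_R`, where R is the
   *broadest* rank (species < genus < family < order < class < phylum) at
   which at least two members carry different assigned taxon names. Groups
   whose members agree at every assigned rank are `intra_species`; groups
   with no rank at which two members are even comparable are
   `unclassifiable`.
6. **Type** plasmids against replicon (Inc group) and relaxase (MOB family)
   marker references, and optionally **tally** single-letter functional
   (COG) categories from a precomputed annotation table.

Summaries are cumulative by design: a group spanning different phyla also
counts among groups spanning different families, genera and species, so the
counts are nested (species ≥ genera ≥ families ≥ …), matching how such
surveys report them.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `qcov_min` | 80 (strict `>`) | per-HSP query coverage, percent of query bases aligned |
| `length_ratio_min` | 0.80 (inclusive) | min/max length ratio of the pair |
| `pident_min` | unset | optional identity floor; high identity is normally a *consequence* of the other two rules, not a rule itself |
| match/mismatch | +2 / −3 | local alignment scoring |
| gap open/extend | 5 / 2 | a gap of length L costs 5 + 2L |
| typing `pident_min` | 80 (inclusive) | percent identity of the best marker hit |
| typing `cov_min` | 60 (inclusive) | coverage of the **marker** (the short reference gene), not of the plasmid |

Two coverage profiles exist because the two screening steps they serve are
phrased differently: the cognate filter is strict (`> 80`), while the
secondary profile for screening hits against an external nucleotide
collection (`cognate_criteria(qcov_strict = FALSE)`) is inclusive
(`>= 80`). Typing coverage is measured on the marker because a replication
determinant of a few hundred bases can never cover a 50 kb plasmid; the
established replicon-typing convention covers the reference gene.

## Alignment engines and determinism

`align_pair()` computes the optimal affine-gap local alignment by full
dynamic programming in compiled code, so its statistics are exact, and ties
are resolved deterministically: the alignment ends at the first
score-maximal cell in query-major order, and traceback prefers a
substitution over a query-consuming gap over a subject-consuming gap,
extending rather than restarting when the local zero floor ties (which
favours the longest co-optimal alignment into that cell). `N` characters
never count as identities. Exact dynamic programming is quadratic in time
and memory, so `align_pair()` refuses pairs beyond ~6×10⁸ cells; for
collection-scale input, `all_vs_all(engine = "blast")` shells out to the
standard `blastn` search tool with the same scoring parameters and one HSP
per pair — the tool a practitioner would (and the original survey did) use.
The `"auto"` engine picks blast only when the total alignment work is large.
The test suite verifies that the compiled aligner agrees *exactly* (nident,
alignment length, pident) with an independent plain-R dynamic-programming
oracle on dozens of seeded pairs, that its optimal scores match
`Biostrings::pairwiseAlignment`, and that both engines produce the same
cognate graph on a planted population.

The hit `evalue` column is a raw-score-based surrogate kept only for layout
compatibility; no filter in the package reads it.

## Edge rule and classification choices

A cognate edge is drawn when **either** direction's hit passes the filter.
Coverage is asymmetric for unequal lengths, and a pooled hit list implies
one qualifying direction suffices; the stricter reciprocal-AND rule is
available as `build_cognate_graph(reciprocal = TRUE)`. Taxa are compared by
rank-name string equality after whitespace normalization — not by taxid
ancestry — so a missing rank never counts as a difference. This matters for
groups with patchy metadata: two members with different families but
unassigned classes classify as `inter_family`, a lower bound on their true
range.

Degenerate inputs are defined, not errors: an empty collection yields an
empty grouping; a plasmid with no qualifying marker hit is `untyped`; a
plasmid with no coding sequences yields an empty tally; recovery scoring of
a single record has adjusted Rand index 1 by convention (the ARI is also
defined as 1 whenever its chance-correction denominator vanishes, which
only happens when the two partitions are identical up to relabeling).

## The synthetic population generator

Real inputs at survey scale (a dated public snapshot of >10⁴ plasmid
records) are neither redistributable nor necessary for validating the
machinery. `generate_dataset()` plants the structure the filters act on:

* **Cognate groups** — a random uniform-composition ancestor per group,
  members derived by per-site substitutions (uniform among the three
  alternative bases), optional geometric-length indels, and optional suffix
  truncation mimicking incomplete assemblies.
* **Decoys** — independent random sequences, length-matched to the
  ancestors. At kilobase lengths two independent random sequences share no
  high-coverage alignment, so decoys stay singletons.
* **Taxonomy** — each group is assigned a target host-range class and its
  lineages are constructed to realize exactly that class (shared names
  above the target rank, two clades at and below it); round-tripping
  through `classify_host_range()` is tested to return the target.
* **Markers** — replicon/relaxase marker sequences embedded verbatim in a
  configured fraction of records, with the carrier list recorded.

Everything is a deterministic function of the config (including the seed);
outputs are byte-identical across runs. The defaults are the benchmark the
package validates against: 20 groups × 4 members, 20–40 kb ancestors, 3%
substitution divergence with no indels and no truncation, and 150 decoys.
At 3% divergence members align at ≈97% identity with ≈100% coverage — far
inside the filter — while decoys sit far outside, so the pipeline is
expected to recover the planted partition with ARI = 1.0, and does; the
acceptance script recomputes this end to end. What passing this benchmark
does *not* show: robustness to real-data features the generator omits —
shared mobile elements between unrelated plasmids (which can bridge groups
at high coverage only when lengths also match), GC and repeat structure,
chimeric assemblies, or metadata errors. The curated ten-group fixture of
published inter-family plasmids exercises the classifier on real taxonomy,
but the alignment stage at real-database scale is exercised only by the
synthetic benchmark.

## Problem sizes used in validation

Unit tests run the exact aligner on sequences up to a few hundred bases
(where the independent oracle is cheap) and full pipelines on populations of
10–30 records at 0.3–2.5 kb; the end-to-end benchmark runs the blast engine
on the full 230-record, 6–7 Mb default population. The oracle-equivalence
suite checks ≥50 seeded pairs up to 300 bases. These sizes were chosen so
the whole suite validates every contract in a few minutes on one CPU while
still covering the regime (tens of kb, hundreds of records) the method
targets.

## Known limitations

* Connected components are a coarse clustering: one promiscuous record can
  chain otherwise distinct groups. The reciprocal edge rule tightens this
  slightly; community detection is out of scope.
* Host-range classes are lower bounds under missing metadata, and
  string-based taxon comparison inherits any synonymy or misspelling in the
  metadata.
* MOB typing here is nucleotide marker matching under the same contract as
  replicon typing; it does not reproduce protein-space relaxase searches.
* The blast engine reports integer-rounded query coverage (`qcovhsp`);
  records sitting exactly on the 80% boundary could be decided differently
  by the two engines. The planted benchmark keeps true coverage near 100%,
  where the engines provably agree.
* Circular topology support (doubling the subject and capping the alignment
  length) is an option, not the default; the survey this package models
  aligned linear representations.
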