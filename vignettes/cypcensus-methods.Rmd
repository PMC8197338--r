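---
title: "Methods: census and classification of bacterial P450 complements"
author: "cypcensus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census and classification of bacterial P450 complements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypcensus)
```

## The problem

Bacterial cytochrome P450s (CYPs) are named by an identity-threshold
convention rather than by phylogeny: a candidate sharing more than 40%
identity with a named P450 belongs to the same family, more than 55% to
the same subfamily, and a candidate below 40% to everything founds a
new family. A clade-wide "P450 census" applies this rule to every
proteome in a cohort and then summarises the result: how many families,
how diverse the repertoire is relative to cohort size, how many P450s
sit inside secondary-metabolite biosynthetic gene clusters (BGCs), and
which families are shared across taxa. `cypcensus` implements each of
those stages as a testable function with explicit parameters.

This vignette records the modelling and numerical decisions, the
defaults and why they were chosen, and what the synthetic-data tests do
and do not demonstrate.

## Pairwise alignment engine

Every identity in the pipeline comes from an optimal affine-gap
pairwise alignment (`alignPair()`), delegated to
`Biostrings::pairwiseAlignment()`. Defaults:

* **Matrix** BLOSUM62, **gap open** 11, **gap extend** 1 (a gap of
  length $k$ costs $11 + k$). These mirror protein-BLAST defaults — the
  most plausible reading of how published identity figures in this
  field are produced. All three are configurable via
  `alignmentParams()`.
* **Mode**: global for classification (family membership is a
  whole-protein notion), local for homolog search (distant homologs
  align over domains).
* **Identity denominator**: alignment columns excluding terminal-gap
  columns in global mode, the aligned span in local mode. This matches
  the common BLAST "% identity" reading and keeps a fragment's identity
  to its source near 100% — fragments are instead handled by the
  explicit short-P450 length rule, not by diluted identity.
* **`X` policy**: the unknown residue scores a uniform floor (−4)
  against everything including itself, and never counts as identical or
  similar. Similarity ("homology") counts columns whose residue pair
  scores positively.
* **Degenerate case**: a local alignment with an empty aligned span has
  identity, similarity and coverage 0 by definition.
* **Tie-breaking**: among co-optimal alignments the engine's traceback
  is deterministic (repeated runs are byte-identical, which is the
  property the tests assert); the reported *score* is unique regardless
  of traceback, and the test suite verifies it against exhaustive
  enumeration of all alignments on small sequences.

## The classifier

`classifyProtein()`/`classifyProteome()` implement the naming rule with
thresholds in `classifierThresholds()`:

* `familyMin = 40`, `subfamilyMin = 55` (percent identity, best hit
  only). Boundary semantics are **strict** by default: exactly 40.0 or
  55.0 falls to the lower band, the literal reading of "more than 40%".
  `strict = FALSE` gives inclusive comparisons for sensitivity checks.
* **Best-hit-only**: assignment follows the single highest-identity
  named P450 (ties broken by database order), mirroring manual curation
  practice; when a query clears the family threshold for two different
  families, the runner-up is reported in a warning and the best hit
  wins.
* `shortMinLength = 300` residues. Census practice excludes
  "short-P450s" (truncated gene models) from totals but the length
  cutoff is not standardised; 300 aa was chosen as a round figure
  comfortably below the ~400–450 aa of intact bacterial P450s yet above
  most fragments, and it is configurable precisely because it is a
  convention, not a measurement.
* **Incremental naming**: within a run, every named query is added to
  the database (flagged `provisional`) and can be the best hit for
  later queries — greedy single-pass clustering, as in manual curation.
  Consequences: (i) reclassifying an assigned sequence returns its own
  name at 100% identity; (ii) input order can matter only for queries
  within a few points of a threshold, so the tests assert
  order-invariance away from the 38–42% band rather than universally.
* **Allocators**: new family numbers are `max(observed) + 1` upward —
  a local convention, since real numbers are assigned centrally by the
  nomenclature committee, which is why allocated names carry the
  `provisional` flag. New subfamily letters follow A…Z, AA, AB, …
  skipping letters already used in that family (multi-letter blocks
  such as JE or AC occur in real names). The unassigned-subfamily
  marker `_` never blocks a letter.
* The optional heme-motif screen (`screenCandidate()`, pattern
  FxxGxxxCxG with one anchored mismatch allowed) is a crude heuristic
  stand-in for domain-level candidate detection and is **off** by
  default: the pipeline trusts its input candidate set.

## Census statistics and rounding

`buildCensus()` excludes `short` and `rejected` queries from all
totals. The subfamily total does not count `_` (a family member with
no assigned subfamily is not a subfamily). Three summary statistics are
exposed directly:

* `averageP450s(n, s) = n / s` — by convention this package uses the
  number of species *with* P450s as denominator. Published tables are
  not fully consistent on this point (one cohort's printed average is
  only recovered with all analyzed species as denominator), so the
  function takes the denominator explicitly rather than hiding the
  choice.
* `diversityPercentage(f, n, s) = 100·f/(n·s)` — exactly homogeneous:
  doubling the P450 count halves it.
* `bgcPercentage(b, n) = 100·b/n`.

`roundAsPrinted()` rounds **half away from zero** (2.5 → 3,
8.009 → 8.01), which is how such tables are conventionally printed;
base R's banker's rounding cannot reproduce them. A `"truncate"` mode
exists because one published diversity value is evidently printed with
its final digit cut rather than rounded; the acceptance tests use it
for that single value and half-away rounding everywhere else.

`compareFamilySets()` computes exact Venn regions (families in exactly
a given taxon combination) and pairwise intersection sizes over
normalised family tokens.

## Presence/absence profiles

`buildPresenceMatrix()` codes presence 3 and absence −3 — the MeV
heat-map convention for P450 family profiles — with one row per
P450-bearing species and one column per observed family (an all-absent
column therefore cannot exist). `clusterMatrix()` runs agglomerative
clustering on both axes with Euclidean distance and **average linkage**
(the MeV hierarchical-clustering default; complete and single linkage
are available). The clustering is `stats::hclust()`, whose merge-order
tie handling is deterministic; the tests pin down hand-computable
cases (e.g. the first merge of a three-row fixture) and permutation
invariance of cophenetic distances rather than a specific tie-break
convention. Dendrograms export to Newick via `ape`.

## BGC membership

`parseBgcTable()` reads a simplified TSV dialect of antiSMASH region
exports (`species`, `region_id`, `cluster_type`, `contig`, `start`,
`end`, optional `most_similar_known_cluster`, `similarity`; a trailing
`%` on similarity is accepted). Coordinates are 1-based inclusive
(GenBank convention). Membership (`p450sInBgcs()`) requires **full
containment** of the gene interval in the region on the same contig —
a cluster *contains* its genes in antiSMASH region semantics — so a
boundary-straddling gene is not a member; strand is ignored. This is
an assumption (published counts do not state how partial overlaps were
treated) and the containment rule is monotone: enlarging a region
never removes members. Hybrid cluster types (`"NRPS, T1PKS"`) count
once per label in `tallyClusterTypes()`. `bgcSummary()` reports member
and species counts and reuses `bgcPercentage()` so the two can never
disagree.

## Pathway homolog calls

`bestHomolog()`/`runPathwayPanel()` search each reference enzyme of a
pathway panel against a target proteome with local alignment; the best
target wins on score, then identity, then input order (stable under
proteome reordering). A call is `present` when percent identity,
percent similarity and query coverage all clear
`homologThresholds()` — defaults 25/35/50, consistent with accepting
homologs between distantly related genomes where the weakest published
accepted calls sit near 25% identity / 38% similarity. Published calls
also weighed database annotation text, which is outside this package's
evidence; the thresholds are therefore configurable, and calls within
2 points of any non-zero threshold are reported `ambiguous` rather
than silently accepted or rejected. With all thresholds zero every
enzyme in a non-empty proteome is `present` (degenerate bound used in
tests). The pathway verdict requires every panel enzyme to have at
least one present call; all above-threshold hits are retained per
enzyme, so duplicated homologs (two targets for one reference enzyme)
are visible.

## Synthetic data: what it emulates and what it does not

The generators exist so that every downstream stage has known ground
truth:

* `randomProtein()` draws i.i.d. residues from a fixed
  Robinson–Robinson-style background table (`AA_BACKGROUND`) —
  reproducibility over realism.
* `mutateToIdentity()` substitutes exactly `round((1−t)·L)` uniformly
  chosen positions, each to a different residue, with **no indels**, so
  realized identity equals the target within 1/L and threshold-band
  tests are analytically controlled. Indel robustness is exercised
  separately with explicit deletion fixtures in the alignment tests.
* `generateSpecies()` emits mutated copies of named references at
  requested identities plus short fragments (120–250 aa) and random
  decoys (350–450 aa), with a truth table of expected verdicts.
  Distinct reference families are independent random sequences, i.e.
  near background identity (~10%) from one another.
* `generateGenomeWithBgcs()` plants P450 genes inside typed BGC
  windows (and others outside) with non-overlapping gene intervals;
  the membership truth set is recoverable by construction.

All generators are pure functions of (spec, seed): randomness is
routed through an internal seed-scoped RNG wrapper that restores the
caller's RNG state.

What passing these tests shows: the classifier applies the threshold
rule exactly when identities sit away from the 38–42% and 53–57%
bands; the interval, census and clustering machinery is correct on
data of known structure. What it does **not** show: behaviour on real
proteomes, where homologous families form identity continua across the
thresholds, domain architecture varies, and gene models are imperfect.
In that regime best-hit classification inherits the order sensitivity
and boundary ambiguity of the underlying convention itself; the
package surfaces those cases (warnings, `provisional` flags, the
strictness switch) rather than resolving them.

## Problem sizes and runtime choices

The test suite works at deliberately small scale, chosen to exercise
every code path while keeping a full run in a few minutes: reference
databases of 3–8 families (sequences of 100–450 aa), a 200-query
classifier-recovery cohort at identities {0.30, 0.50, 0.70}, 500
random tiny pairs (length ≤ 8) for the exhaustive alignment-oracle
comparison, 10–12-gene genomes with 2 BGCs, and 8-enzyme pathway
panels against 20-protein proteomes. A full published-scale census
(hundreds of genomes) is the same code on more input; runtime is
dominated by the one-query-versus-database alignment step, which is a
single vectorised `pairwiseAlignment()` call per query.

## Known limitations

* Provisional family numbers and subfamily letters are a local
  allocation convention; authoritative naming requires the
  nomenclature committee.
* Identity is computed over full-length global alignments; surveys
  that computed identity over the P450 domain only will differ near
  the thresholds.
* The heme-motif screen is far weaker than profile-based domain
  detection and is off by default.
* BGC region quality is taken as given; the package parses and
  intersects, it does not predict clusters or score similarity to
  known clusters.
* Eukaryotic-style CYP names with letter-bearing family tokens are out
  of scope; the grammar covers numeric families as used for bacteria.
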