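# cypcensus

Genome-census tools for cytochrome P450 monooxygenases (CYPs/P450s) in
bacteria.

Cytochrome P450s are heme-thiolate enzymes central to secondary
metabolism, and comparative "P450 profiling" across bacterial genomes
has become a standard genome-mining exercise: collect the P450
complement of every species in a clade, name each sequence under the
International P450 Nomenclature Committee rule, and compare family
repertoires, biosynthetic-gene-cluster (BGC) involvement and pathway
capabilities across taxa. `cypcensus` implements that whole analysis as
a reproducible pipeline for R users — microbial genomics groups running
clade-wide P450 surveys, and anyone who needs the nomenclature rule as
a programmable classifier rather than a manual curation step.

## The method

A candidate P450 is compared against a database of named P450s by
global pairwise alignment. With best-hit identity *p* to a named
sequence CYP*F**S**n*:

- *p* > 55% — the candidate joins subfamily *F S* (next free allele
  number);
- 55% ≥ *p* > 40% — the candidate joins family *F* under a newly
  allocated subfamily letter;
- *p* ≤ 40% — the candidate founds a new (provisional) family.

Candidates shorter than 300 residues are set aside as "short-P450s"
and excluded from census totals. Classification is incremental: each
named query immediately becomes a potential best hit for later
queries.

On top of the classifier the package computes the standard census
statistics —

- average P450s per species = `nP450s / nSpecies`,
- P450 diversity percentage = `100 · nFamilies / (nP450s · nSpeciesWithP450s)`,
- percentage of P450s in BGCs = `100 · nP450sInBgcs / nP450s`,

— plus family/subfamily census tables, species-by-family
presence/absence profiles (coded 3/−3) with Euclidean hierarchical
clustering, P450 membership calls in BGC regions (full interval
containment), cross-taxon family-set comparisons, and best-homolog
pathway reconstruction from percent identity, percent similarity
("homology") and coverage.

A first-class synthetic-data module generates proteomes with P450s at
controlled identity to named references (plus short fragments and
decoys) and genomes with planted BGC membership, so every stage is
testable with known ground truth and no downloads.

## Worked example

```r
library(cypcensus)

db <- generateReferenceDB(c("CYP202A1", "CYP202B1", "CYP153A1"), seed = 7)
sp <- generateSpecies(speciesSpec("Phenylobacterium zucineum",
        data.frame(ref = c("CYP202A1", "CYP202A1", "CYP153A1"),
                   identity = c(0.95, 0.50, 0.30)),
        nShort = 1, seed = 11), db)
run <- classifyProteome(sp$proteome, "Phenylobacterium zucineum", db)
as.data.frame(run$results)[, c("query", "best_hit", "best_identity",
                               "assigned_name", "status")]
```

```
                               query best_hit best_identity assigned_name             status
1  Phenylobacterium_zucineum_p450_01 CYP202A1      94.88889      CYP202A2 existing_subfamily
2  Phenylobacterium_zucineum_p450_02 CYP202A1      50.00000      CYP202C1      new_subfamily
3  Phenylobacterium_zucineum_p450_03 CYP153A1      29.86726      CYP203A1         new_family
4 Phenylobacterium_zucineum_short_01     <NA>            NA          <NA>              short
```

The 95%-identity candidate becomes a new allele of CYP202A; the
50%-identity candidate stays in family 202 but founds subfamily C
(B is already taken by a named reference); the 30%-identity candidate
founds provisional family 203; the fragment is flagged short and never
counted.

```r
ct <- buildCensus(run$results, data.frame(species = "Phenylobacterium zucineum"))
ct
#> P450 census: 3 P450s in 2 families / 3 subfamilies
#>  species with P450s: 1 of 1 | genera: 1 of 1 | short-P450s excluded: 1

roundAsPrinted(diversityPercentage(143, 874, 241), 2)
#> [1] 0.07
```

The last line is the diversity statistic for a real published cohort
(143 families, 874 P450s, 241 P450-bearing species).

`runCohort()` chains all stages over a manifest of species (proteome
FASTA plus optional gene/BGC coordinate TSVs) and writes every table as
TSV; see the methods vignette (`vignettes/cypcensus-methods.Rmd`) for
the modelling choices and file dialects.

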