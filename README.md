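# rinpep

Pattern detection in nonribosomal peptide biosynthesis from monomer-pair
fingerprints of gene-cluster predictions.

## The problem

Nonribosomal peptide synthetases (NRPS) are modular enzymatic assembly
lines: each module incorporates one monomer (a proteinogenic or
nonproteinogenic amino acid, or — in hybrid NRPS–PKS pathways — a
polyketide unit) into a natural product. Genome-mining platforms such as
antiSMASH predict, for every biosynthetic gene cluster (BGC), an ordered
*core structure* of monomers plus the most similar known gene cluster in
MIBiG with a gene-homology percentage. Whole-structure predictions are
rarely exact, but *portions* of a backbone recur across related genomes
and are informative about what a clade reliably biosynthesizes.

`rinpep` works at the level of those portions. It reorganizes predictions
and known compounds into canonical two-monomer fragments and asks which
fragments are shared, by whom, and how reliably they are predicted:

- **Pairs.** A backbone `m1 + m2 + ... + mL` is fragmented into its `L-1`
  adjacent pairs, each normalized alphabetically (`canonical_pair("val",
  "ala")` is `"ala.val"`), so a fragment is identified regardless of its
  orientation in the chain. Pairs from predicted core structures are POPs
  (pairs of predictions); pairs from known compound backbones are PECs
  (pairs of existent compounds).
- **Consensus.** A module's monomer is accepted only when the three
  predictors (NRPSpredictor2, Stachelhaus code, Minowa) agree; any
  incongruence yields the unresolved token `nrp` (a 2-of-3 majority
  policy is available as an option).
- **Match points.** Each POP is scored against a compound's PEC set:
  1 point for an exact match, 0.5 when exactly one token is `nrp` and the
  other occurs in the compound, 0 otherwise (including `nrp.nrp`).
  Polyketide-class tokens (`pk`, `mal`, `mmal`, `ohmal`, ...) are
  collapsed to a single comparison class on both sides first. Per-cluster
  totals are related to the cluster's gene-homology percentage.
- **Similarity.** Clusters (or organisms) × pairs form a 0/1 matrix;
  pairwise Jaccard indices `|A∩B| / |A∪B|` quantify POP sharing, and
  Euclidean-distance, average-linkage hierarchical clustering groups
  instances with convergent fragments. Distribution tables report each
  pair's percentage of occurrence globally, per cohort, or per
  dendrogram branch; organism→compound homology networks export to
  SIF/GraphML for Cytoscape-class tools.

A seeded synthetic-cohort generator (`simulate_records()`) corrupts a
template backbone at the predictor level so the whole pipeline — and the
expected decay of prediction correctness with genomic identity — is
testable without any genome downloads.

## Worked example

The bundled compound library contains Delftibactin (MIBiG BGC0000984),
whose backbone `pk + asp + thr + gly + thr + orn + ser + arg + orn`
fragments into 8 PECs (7 unique; `gly.thr` occurs twice):

```r
library(rinpep)
delft <- default_compound_library()[["Delftibactin"]]
pecs_for(delft)
#> <pair multiset> origin=Delftibactin, 7 unique / 8 total
#>   arg.orn:1  arg.ser:1  asp.pk:1  asp.thr:1  gly.thr:2  orn.ser:1  orn.thr:1
```

Scoring a divergent gene cluster (bundled illustrative record; its six
POPs are `nrp.pk`, `nrp.ohmal`, `ohmal.ser`, `orn.ser`, `orn.thr`,
`asp.thr`) against those PECs:

```r
rs <- read_cluster_records(system.file("extdata", "example_clusters.json",
                                       package = "rinpep"))
score_cluster(rs$records[[1]], delft)
#> <cluster score> Variovorax paradoxus-C3 vs Delftibactin: 4.0 / 6 points (fraction 0.667)
```

The two `nrp`-containing POPs earn 0.5 each (one unresolved token, the
other present in the compound), `ohmal.ser` earns 0 (it maps to `pk.ser`,
which is not adjacent in the backbone), and the remaining three match
exactly — the cluster reproduces the most characteristic portions of the
molecule even though the full prediction diverges. Identical POP sets
give `jaccard_index()` 1.0; disjoint sets give 0.0.

A full run over a record file writes every artifact (score reports,
binary and Jaccard matrices, Newick dendrogram, distribution tables,
SIF/GraphML networks, checksummed manifest):

```r
run_pipeline("clusters.json", "results/")
```

or from a shell via the thin wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("exec", "rinpep", package = "rinpep"))') \
  run --records clusters.json --out results/
```

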