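---
title: "Monomer-pair fingerprints for NRPS gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monomer-pair fingerprints for NRPS gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinpep)
```

## The model

Nonribosomal peptides are assembled module-by-module, so a predicted core
structure and a known compound backbone are both ordered monomer chains.
`rinpep` compares them not as whole structures — whole-structure
predictions are brittle — but as multisets of *adjacent monomer pairs*.
A chain `m1 + m2 + ... + mL` yields the `L-1` fragments
`{m1.m2, m2.m3, ...}`, each canonicalized by alphabetical ordering of its
two tokens. The chemical argument for erasing orientation is that a
two-monomer fragment is identified identically in a mass or NMR spectrum
whichever way it sits in the chain. Pairs derived from predictions are
POPs; pairs derived from known compounds are PECs.

Three modeling conventions fix the fragment vocabulary:

- **Consensus and `nrp`.** A module's monomer call is accepted only when
  NRPSpredictor2, the Stachelhaus code and Minowa agree after
  normalization (`consensus_call()`); disagreement — or an absent call —
  produces the unresolved placeholder `nrp`, which then participates in
  pairs like any token. Strict unanimity is the default because the
  method's premise is to keep only predictions that are certain at the
  module level; a 2-of-3 majority policy is exposed as configuration for
  sensitivity analysis, since two-predictor agreement is common in
  practice and the cost of unanimity is a higher `nrp` rate.
- **Modification stripping.** Annotation tags in parentheses
  (`Thr(mod)`, `Orn(cyclic)`, `pk(NH2+ohmal)`) are stripped into a
  `modifications` field and never affect pair identity: a modified and an
  unmodified threonine are the same building block from the
  pattern-matching point of view.
- **Linear fragmentation.** No fragment joins the terminal monomer back
  to the start, even for compounds drawn with a cyclized terminus. The
  bundled Delftibactin backbone ends in a cyclized ornithine, and its
  documented pair set contains no terminal-to-start pair; treating
  cyclization as a modification rather than an adjacency keeps predicted
  (always linear) and known backbones comparable.

N-gram sizes 1 and 3 are supported alongside the default 2 for
sensitivity comparison: unigrams discard all adjacency information,
trigrams demand longer correct runs and are correspondingly sparser.
Trigram keys sort all three tokens, extending the pair rule.

## The match-point system

`match_pop()` scores one POP against a compound's PEC set:

1. **1 point (exact):** the POP equals some PEC after polyketide-class
   mapping on both sides;
2. **0.5 points (partially correct):** exactly one POP token is `nrp`
   and the other token occurs anywhere in the mapped PEC set — one
   subunit is out of consensus but the resolved half is genuinely part of
   the compound;
3. **0 points (incorrect):** everything else, including `nrp.nrp` and
   pairs whose tokens occur in the compound but never adjacently.

Polyketide-class mapping collapses the tokens of hybrid NRPS–PKS
portions (`pk`, `mal`, `mmal`, `ohmal`, `emal`, `mxmal`, editable as
bundled configuration) to a single comparison token, because a predictor
may emit a specific acyl unit where a backbone is drawn with a generic
polyketide unit, or vice versa. The mapping is applied *symmetrically*
before comparison. Of the candidate rules (no mapping, map one side
only, symmetric), only the symmetric rule and the POP-side rule
reproduce the documented worked-example points, and they coincide
whenever the library backbone uses the generic class token; symmetric is
kept as the fixed rule because it also covers libraries transcribed with
specific acyl tokens. The scoring tests demonstrate this discrimination
by brute force.

PECs are matched *without consumption*: pairs are types, not slots, so a
PEC duplicated in a backbone (or matched by two different POPs) imposes
no assignment problem. Each **distinct** POP is scored once by default —
the denominator of a cluster's `fraction_correct` is its number of
distinct POPs; an occurrence-weighted option exists for sensitivity
analysis, and is the natural scale for the closed-form expectation used
in testing (below). The partial-match rule requires only that the
resolved token occur somewhere in the compound, not that it have an
unmatched neighbor; the stricter variant would deny partial credit to a
predicted polyketide-adjacent fragment whenever the polyketide pairs are
already matched elsewhere, contradicting the worked example.

## Similarity and distributions

`build_binary_matrix()` encodes instances × pairs as 0/1 (presence of a
pair in the instance's POP support). The default instance is the single
gene cluster, keyed `organism-C<index>`; organism granularity unions the
organism's clusters and is a flag. `jaccard_matrix()` computes
`|A∩B| / |A∪B|` over row supports — 1 means identical POP sets, 0 means
disjoint; the degenerate both-empty case is defined as 0 and flagged.
`hierarchical_cluster()` is Euclidean distance + average linkage
(`stats::hclust(method = "average")`, i.e. unweighted group average /
UPGMA) — chosen as the standard reading of "average" linkage; the
weighted variant is not exposed. Exports are data, not pixels: TSV
matrices for heatmap tools, Newick for the dendrogram.

Distribution tables (`pop_distribution()`) use multiplicities by default
— a pair occurring twice in one backbone counts twice — with a
unique-pair option, since published per-cohort percentages count
occurrences. `nrp.nrp` is retained in matrices and distributions (its
prevalence per dendrogram branch is itself informative: it marks NRPS
domains whose monomers could not be resolved) but scores 0 points — a
deliberate asymmetry between description and validation.
`branch_distribution()` consumes an externally produced cluster→branch
table (tree building from sequences is out of scope) and always emits a
global `Branch_0` reference distribution.

Networks (`build_network()`) are directed bipartite graphs, organisms
(diamonds) → compounds or POPs (circles), weighted by homology percent
or occurrence count; clusters without a known match share a single
`unknown` node. Degree filtering is inclusive (`degree >= min_edges`)
with optional first-neighbor expansion, mirroring how a dense subset and
its compounds are selected interactively. Degrees are recomputed on the
filtered subset; note that refiltering is a fixed operation only when
the surviving subgraph retains threshold degrees (a star hub retained at
the threshold becomes isolated once its spokes' endpoints are dropped).

## The synthetic cohort generator

`simulate_records()` emulates a validation cohort: every cluster copies
a template compound backbone (Delftibactin by default) and corrupts each
module *at the predictor level, before consensus* — either three
discordant calls (so the consensus mechanism itself produces `nrp`,
exactly as in real data) or a unanimous decoy monomer. The configured
`nrp_rate` and `wrong_monomer_rate` are the per-module probabilities at
0% genomic identity; each cluster's effective rates are
`rate * (100 - identity)/100`, a linear identity–corruption link (the
functional form is configurable in code because nothing pins it down;
linear is the simplest monotone choice). Identity levels are assigned in
rotation and recorded as the cluster's known-match identity, so
`identity_vs_correctness()` can recover the designed relationship.
Default conditions are 4 identity levels (100/75/50/25), `nrp_rate`
0.2 and `wrong_monomer_rate` 0.1 at the zero-identity anchor, and a
10-token decoy vocabulary disjoint from the template — a cohort in which
high-identity clusters are near-perfect and low-identity clusters
degrade visibly, matching the qualitative behavior of real
validation cohorts.

With pure `nrp` corruption at per-module rate `p`, a fragment scores 1
with probability `(1-p)^2`, 0.5 with probability `2p(1-p)` and 0
otherwise, so the expected per-fragment score is exactly `1 - p`; the
test suite checks the simulated mean against this closed form
(occurrence-weighted scoring, 200 clusters). `simulate_outlier()`
relabels a fraction of clusters to the top identity level while
corrupting them at full base rates, producing the
high-identity/low-correctness outliers that identity-vs-correctness
plots are meant to expose.

What the generator does *not* emulate: real predictor error is
correlated across modules and predictors (shared substrate ambiguity),
cluster type and module count vary, and known-match annotations can be
wrong. Passing tests therefore demonstrate the pipeline's correctness
and its statistical behavior under the designed corruption model, not
antiSMASH's accuracy on real genomes.

## Numerical and degenerate-input conventions

- Pair ordering is plain lexicographic byte order over lowercase ASCII
  tokens; ties (equal tokens) are trivially stable (`nrp.nrp`).
- A backbone shorter than the n-gram size yields an empty multiset with
  a warning flag, not an error; records with no modules are retained but
  inert and are reported as all-zero, flagged matrix rows.
- Jaccard of two empty sets is 0, flagged `both_empty`; the JI matrix
  diagonal is 1 only for nonempty supports.
- `hclust` merge order under exact distance ties is
  implementation-defined; the test suite's independent average-linkage
  reference is compared on tie-free inputs.
- Rank correlations are reported as `NA` with a `correlation_defined`
  flag when fewer than two usable rows remain or either column has zero
  variance.
- Scored problem sizes in the test suite (200–500 simulated clusters,
  5-row clustering oracles, ≤5-token brute-force vocabularies) were
  chosen as the smallest sizes at which the statistical assertions are
  stable across seeds.

## Known limitations

- The bundled compound library contains only Delftibactin, the one
  backbone fully documented for validation; other compounds must be
  transcribed by the user (the TSV format accepts literature backbones
  verbatim).
- The bundled monomer synonym table covers the tokens named in the main
  analyses; Norine/KEGG spelling variants beyond it are added by editing
  the TSV, not code.
- Dendrogram construction from gene-cluster *sequences* (alignment,
  neighbor-joining) is out of scope; branch assignments are consumed as
  input.
- MIBiG id suffixes such as `_c1` are carried as opaque text.
- Scoring targets one compound per cluster (the most similar known
  cluster); scoring against several candidate compounds is a caller-side
  loop.
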