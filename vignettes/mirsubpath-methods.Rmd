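---
title: "Locating and scoring miRNA-mediated metabolic subpathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and scoring miRNA-mediated metabolic subpathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsubpath)
```

## The model

Metabolic dysregulation in disease is frequently local: a short enzyme
cascade, together with the microRNAs repressing those enzymes, carries
most of the differential signal while the surrounding pathway is
quiet. mirsubpath formalizes this in three stages.

**Graph reconstruction.** A metabolic pathway is represented as an
undirected graph whose nodes are genes (enzymes) and whose edges carry
the compounds that connect two enzymatic steps. Edges come from two
complementary encodings in KGML pathway descriptions, and the union of
both is used: explicit enzyme-enzyme (`ECrel`) relations, and pairs of
reactions where a product of one is a substrate of the other. Compound
entries never become nodes — a deliberate modeling choice that keeps
every node a molecule whose differential status can be observed in an
expression experiment. Verified miRNA-target interactions are cleaned
(one record per miRNA/target/species key, low-throughput evidence
winning over high-throughput when sources disagree, restricted to
low-throughput support in the study species) and each miRNA with an
in-graph target is added as a node with one undirected edge per
target. miRNA-target edges are stored undirected so that they
participate in shortest-path computations exactly like gene-gene
edges; the regulatory direction is implied by the node kinds and is
recoverable in all exports.

**Lenient-distance location.** Differential genes and miRNAs present
in a graph are its *signature nodes*. For every pair of signatures the
shortest connecting path is inspected, and the pair is grouped when at
most `n` *non-signature* molecules lie strictly between them on some
minimum-length path. Three conventions here were genuinely open and
are fixed as follows:

* *Signature interiors do not count against `n`.* The rule bounds the
  number of non-differential molecules tolerated between two
  differential ones, so a differential molecule sitting on the path is
  evidence for the cascade, not against it. With `n = 1` this reads:
  no more than one non-differential molecule between any two
  differential molecules.
* *All minimum-length paths contribute.* When several shortest paths
  tie, the interiors of all of them enter the candidate set. Choosing
  one path would make the output depend on traversal order; the union
  is deterministic and reflects that any of the tied routes could
  carry the signal.
* *Singleton seeding.* Every signature also seeds its own
  one-element candidate set before merging. A dense region whose
  pairwise paths individually fail the `n` test can still assemble
  through transitive merging, and isolated signatures are not silently
  lost before the size filter.

Candidate sets sharing a node are merged transitively, the merged set
is located in the graph, its induced subgraph extracted, and every
connected component with at least `s` nodes reported as a subpathway.
Component splitting is required because a merged node set can induce a
disconnected subgraph, and a subpathway is by definition one connected
subregion. Ordinal identifiers within a pathway are assigned by
descending component size, ties broken by the lexicographically
smallest member id — an arbitrary but deterministic convention.

**Scoring.** A subpathway with `t_g` genes and `t_mir` miRNAs, of
which `r_g` and `r_mir` are differential, is scored against background
universes of `m_g` genes and `m_mir` miRNAs containing `n_g` and
`n_mir` differential molecules:

$$P = 1 - \sum_{k=0}^{r_g+r_{mir}-1}
  \frac{\binom{t_g+t_{mir}}{k}\binom{m_g+m_{mir}-t_g-t_{mir}}{n_g+n_{mir}-k}}
       {\binom{m_g+m_{mir}}{n_g+n_{mir}}}$$

Genes and miRNAs are pooled into one urn and treated as exchangeable
draws. A two-urn product (independent gene and miRNA tests combined)
would also be defensible, but the pooled form is implemented because
it is the statistic this method family defines; it lets a subpathway
reach significance through genes, through miRNAs, or jointly.
P-values are adjusted by Benjamini–Hochberg over **all** subpathways
of a run — one FDR family per result list, not per pathway — matching
how a single ranked list per data set is reported and thresholded
(FDR < 0.01 by default).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` | 1 | non-signature molecules tolerated on the connecting shortest path; raising it admits longer quiet gaps and grows subpathways |
| `s` | 10 | minimum subpathway size in nodes; raising it prunes small fragments and never adds subpathways |
| `background_mode` | `"genome"` | `"genome"` uses the caller-supplied whole-genome/whole-miRNAome counts; `"annotated"` uses the union of molecules across the supplied graphs (the common ORA convention) and restricts differential counts to it |
| `fdr_threshold` | 0.01 | significance cut applied to reported lists |

Both background modes are provided because published analyses are
ambiguous about which universe they used; every report records the
mode and the universe sizes so results are self-describing. The
overlap statistics between pathway lists are independent of this
choice.

## Baselines and downstream analyses

The two complete-pathway comparators are implemented exactly as
restrictions of the same tail formula: gene-only over-representation
(`ora_pvalue`) and the miRNA-only test (`mirna_pvalue`), the latter
counting each miRNA linked to a pathway once regardless of its number
of targets there. `ora_pvalue(m, n, t, r)` is identical to the joint
statistic with all miRNA counts zero; this reduction is asserted in
the test suite.

Significant subpathways can be merged into one regulatory network:
edge weight is the number of distinct subpathways containing the edge
(provenance retained), a miRNA's node weight its number of distinct
linked genes and a gene's its number of distinct linked miRNAs. Only
edges present in member subpathways are merged; nothing new is
inferred, and compound labels are dropped in this view.

Robustness follows a perturb-and-recall protocol: delete a fraction of
differential molecules (or of graph edges, pooled across edge classes
or per class), re-run the full pipeline, and measure the fraction of a
reference significant-pathway list recovered, a pathway counting as
recovered when any of its subpathways passes the threshold. One
protocol simplification is deliberate: the published experiment
perturbs expression *profiles* and re-derives differential lists,
but differential-expression calling is out of scope here, so the
differential lists are perturbed directly. The stress being tested —
loss of signature molecules — is the same; absolute recall values are
not comparable to profile-level experiments. Deleted counts use the
floor rule (`floor(fraction * n)`), so small inputs at small fractions
can be perturbation-free by construction.

## The synthetic-data generator

`generate_fixture()` produces a complete, self-contained study: a
collection of connected random pathway graphs (random spanning tree
plus Bernoulli extra edges), a raw interaction table, differential
lists and a ground-truth manifest. Defaults are sized after the
composition of real reconstructed metabolic collections — about 50
genes and 140 gene-gene edges per pathway, a handful of embeddable
miRNAs each — so that distances, merge behavior and multiplicity are
exercised at realistic scale: 12 pathways, a planted connected region
of 12 genes at 90% signature density plus 3 differential miRNAs wired
to it, a 5% differential background everywhere else, and off-pathway
background molecules (1400 genes, 60 miRNAs) so the genome and
miRNAome universes exceed the annotated molecules, as they do in real
analyses. The interaction table deliberately contains duplicated
records from a second source and high-throughput-only records, so the
cleaning steps have real work to do in every end-to-end test.

What the generator does **not** emulate: expression matrices (lists
are generated directly), scale-free degree structure, hub enzymes
shared between pathways (gene namespaces are pathway-disjoint),
compound-mediated cross-pathway links, and correlated miRNA families.
Passing tests therefore demonstrate correctness of the algorithms and
calibration under a uniform null, not performance on real KEGG/TCGA
inputs.

## Numerical choices and degenerate inputs

* Tail probabilities are computed through the hypergeometric survival
  function (log-space internally) rather than `1 - CDF` subtraction,
  and clamped to `[0, 1]`; with `r_g + r_mir = 0` the empty sum forces
  `P = 1` exactly.
* Count invariants (`r ≤ min(n, t)`, `t ≤ m`, `n ≤ m`, per margin) are
  validated on construction, with the failing inequality named.
* Readers follow a log-and-continue policy: rows with missing ids or
  unrecognized evidence are dropped and counted, never fatal, so large
  dirty tables remain usable. Structural errors (missing columns,
  malformed XML) are fatal and name the offender.
* A pathway with no gene entries parses to an empty graph with a
  warning; an empty result table is a valid pipeline outcome.
* All randomness (generator, perturbations) flows from explicit seeds;
  a master seed spawns per-replicate seeds so any replicate is
  reproducible in isolation. End-to-end runs are byte-deterministic
  under a fixed seed.

## Verification strategy and problem sizes

The test suite checks every statistic against an independent
exhaustive-enumeration oracle (all $\binom{m}{n}$ draws counted
directly) on pooled universes up to 20, and the locator against a
brute-force implementation (hand-rolled BFS path enumeration, set
merging and component extraction, igraph-free) on hundreds of random
graphs of up to 15 nodes across `n ∈ {0,1,2}`, `s ∈ {1,3,5}`.
Planted-signal recovery is measured over 20 generator seeds at the
default study shape. These sizes were chosen to make exhaustive
oracles exact and the whole suite fast; the algorithms themselves have
no size-dependent branches.

## Known limitations

* Identifiers are opaque strings; callers must supply one consistent
  gene namespace and one mature-miRNA namespace across pathways,
  interactions and differential lists. No id conversion is bundled,
  and no KEGG download client is included — inputs arrive as KGML
  files or the package's plain-text exchange format.
* Only metabolic-style pathway encodings are parsed (gene entries,
  `ECrel` relations, reactions); signaling-pathway relation types are
  ignored.
* Multi-gene KGML entries are split into one node per gene id, each
  inheriting the entry's relations and reactions. This follows the
  KEGG convention that such entries are enzyme alternatives, but it is
  a convention, not something the format mandates.
* No redundancy pruning is applied between overlapping subpathways of
  the same pathway, and significance is purely hypergeometric — no
  permutation or topology-weighted nulls.
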