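---
title: "Mining polyphenotype genes with a trait-gene knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining polyphenotype genes with a trait-gene knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgtrait)
library(dplyr)
```

## The problem

Crop breeding wants *polyphenotype* genes — single genes that influence two
or more agronomic traits at once (say, plant height together with grain
weight and disease resistance), because they can side-step the classical
trade-offs between yield, quality and resistance. Mapping methods (GWAS,
QTL, bulked segregant analysis) tie genes to one trait at a time; what is
missing is a way to pool the heterogeneous evidence that accumulates across
databases — protein homology, GO annotation, pathway membership,
subcellular localization, protein families and domains — and use it to
transfer trait labels from well-studied genes to unannotated ones, across
species.

`kgtrait` does this with a typed knowledge graph over 13 entity categories
(trait, gene, protein, gene symbol, signal pathway, subcellular
localization, protein domain, protein family, cellular component, molecular
function, biological process, metabolic pathway, enzyme) connected by 14
relation types, each constrained to one pair of endpoint categories (a
protein *associates with* a trait, a gene *performs* a molecular function,
and so on). Edges are stored with their input direction, but the schema
check treats the endpoint-category pair as unordered and every neighborhood
query is undirected — adjacency, not direction, is what the method uses.

## The similarity model

For a known trait-regulating gene $g_1$ and a candidate gene $g_2$, with
encoded proteins $p_1, p_2$, the score is

$$S(g_1, g_2) = C(k) \cdot D(k) \cdot S(p_1, p_2), \qquad
  k = N(g_1) \cap N(g_2),$$

where $N(x)$ is the scoring neighborhood of gene $x$, $C(k)$ the number of
entities shared by the two neighborhoods, $D(k)$ the number of distinct
entity categories among them, and $S(p_1, p_2)$ a protein similarity on a
0–100 scale. $C$ measures how much annotation the genes share, $D$ whether
that sharing spans molecular levels rather than piling up in one, and
$S(p_1,p_2)$ conservation of the gene products themselves. The product form
means any factor at zero annihilates the score; a pair whose proteins
cannot be scored at all is reported as *unscorable*, never silently as
zero.

Three modelling choices deserve comment, because the score's definition
leaves them open:

* **Neighborhood scope.** A gene's scoring neighborhood is its 1-hop
  neighbors plus, by default, the 1-hop neighbors of each protein linked to
  it by *corresponding to* (`include_protein_hop = TRUE`). Most annotation
  in the schema hangs off the protein (pathways, localizations, families,
  domains), so a strictly 1-hop neighborhood would blind $C$ and $D$ to it.
  A flag restores strict 1-hop.
* **Trait exclusion.** Trait nodes are excluded from scoring neighborhoods
  by default (`excluded_categories = "trait"`). Including the very trait
  being predicted would leak the label into the score. This also explains
  why a pair can share one more node than its $C$ counts when the shared
  node is a trait.
* **Multi-protein genes.** When a gene maps to several proteins the pair
  with the maximal provider score is used (`protein_pair_policy = "max"`);
  a single sufficiently conserved product is taken as evidence enough.

All counts are over entities: parallel edges to the same neighbor count
once, and duplicate triples collapse at load.

### Protein similarity

The similarity term is pluggable. The default `alignment_provider()`
computes global (Needleman–Wunsch) percent identity under BLOSUM62 with
affine gaps (open 10, extend 0.5), identity denominator the full alignment
length including gap columns — parameters all surfaced because no single
convention is canonical. A `table_provider()` instead looks up externally
computed scores (e.g. from a homology pipeline), which both lets published
scores be injected verbatim and keeps the similarity definition open.
Both providers are exactly symmetric.

## Threshold calibration and evaluation

Scores are turned into predicted gene–trait links by a single decision
threshold, calibrated on literature gene–gene association pairs split by
publication year: pairs whose later gene was published at or before the
cutoff year train the threshold, later pairs validate it. This time slicing
imitates prospective prediction — the validation associations did not exist
when the threshold was (notionally) set.

`sweep_threshold()` evaluates F1 at every distinct observed score. F1 is
piecewise constant between observed scores, so this grid is exact and no
denser sweep can find a better threshold; ties break toward the smallest
maximizing threshold, which favors recall. Classification uses
`score >= threshold` — a pair exactly at the threshold is positive.
Accuracy, precision, recall and F1 are computed from unrounded counts, with
zero-denominator cases reported as 0 and flagged. Negative pairs are not
defined by the literature; the package accepts explicit negative labels and
the fixture generator (and `labeled_pairs_from_associations()`) builds them
as gene pairs documented to share no trait, sampled with a fixed seed.

## Prediction, mining and ranking

For a candidate gene, each trait's score is the maximum similarity to any
of that trait's known genes (one strong supporter suffices; the supporting
gene is reported). A known gene carrying several traits supports each of
them. Genes passing the threshold for two or more traits are polyphenotype
candidates; `combination_counts()` tabulates them by their full trait set.

To prioritize candidates for a chosen trait set, per-trait score ranks
(rank 1 = best) are averaged:

$$S_{sum} = \frac{1}{n} \sum_{i=1}^{n} R(g_i),$$

and genes are ordered by ascending $S_{sum}$. Two tie policies are
supported because published usage is itself mixed: the default *dense*
policy gives equal $S_{sum}$ a shared comprehensive rank (so a top-10 list
can contain more than ten genes), while *ordinal* breaks ties by gene id
and returns exactly k. $S_{sum}$ is kept at full precision internally —
17/3 is 5.666…, printed as 5.7 only at display.

The ranked population is the genes predicted for *all* n target traits;
ranking genes missing a trait would need an imputation rule the method does
not define.

## DEG-set validation

As an independent check, mined genes are intersected with
differentially-expressed-gene sets from stress-treatment transcriptome
experiments, filtered at $|\log_2 \text{fold change}| \ge 1$ (base and
inclusiveness configurable). Each gene falls in exactly one Venn region —
the exact subset of DEG sets containing it — and the verification fraction
is the share found in at least one set. No identifier mapping is attempted
across species or nomenclatures: fuzzy matching would fabricate overlaps.
Fractions are exact internally and rounded to whole percent for display.

## What the synthetic fixtures emulate — and what they do not

Because the full literature-derived graph cannot be redistributed, the
package ships a generator (`generate_fixture()`) that plants the structure
the score exploits: genes of a common trait share an annotation core of 12
entities spread over 4 categories (matching the magnitude of the worked
example, $C = 12$, $D = 4$) and proteins with mean similarity 80, while
decoys share at most one noise annotation and proteins near similarity 10.
Association years are placed so an 8:2 train/validation time slice exists
by construction, with planted unknown genes "discovered" after the cutoff.
Default sizes (2 traits × 3 known genes, 4 planted polyphenotype unknowns,
10 decoys) keep the whole pipeline runnable in seconds; the generator
subsamples the labeled-pair table above 500 pairs.

Under these defaults positives and negatives are linearly separable, so the
swept threshold reaches F1 = 1 and prediction recovers the planted manifest
exactly — that is the point: the tests verify the machinery, not the
difficulty of real data. Real graphs have hub annotations, degree
heterogeneity, correlated traits, missing proteins and noisy years; passing
on fixtures says nothing about predictive performance there, and headline
metrics from the original literature-scale datasets are not reproducible
from this package alone.

## Worked example

```{r example}
bundle <- generate_fixture(fixture_config(seed = 7), dir = tempdir())
provider <- table_provider(bundle$sim_table)

split <- time_slice_split(bundle$labeled_pairs, bundle$manifest$cutoff_year)
sweep <- sweep_threshold(split$train)
glance(sweep)

pred <- predict_all(bundle$kg,
                    unique(bundle$manifest$planted_links$gene),
                    bundle$associations, provider,
                    threshold = sweep$threshold)
mine_polyphenotype(pred, bundle$associations)
```

```{r plot, fig.width = 5, fig.height = 3}
autoplot(sweep)
```

## Numerical notes and limitations

* Scores, thresholds and fractions are compared with plain floating-point
  equality only where they are exact by construction (integer counts times
  a stored similarity); the sweep never interpolates between observed
  scores, so no tolerance is needed there.
* Percent identity of an optimal alignment can depend on traceback
  tie-breaking when several alignments share the optimal score; the
  alignment score itself is unique. The reported identity is always
  consistent with the alignment actually returned.
* Degenerate inputs are defined, not guessed: empty validation slices skip
  evaluation, metrics with zero denominators report 0 with a flag, an
  empty candidate set is an error in ranking, and a polyphenotype set of
  size zero makes the verification fraction undefined (error) rather
  than 0.
* Entity ids are case-sensitive and taken verbatim; the package never
  normalizes between LOC_/AT/Zm/TraesCS conventions. Species is carried as
  annotation and never used by the scorer — the method is deliberately
  cross-species, with protein homology doing the bridging.
* The graph store is two tibbles plus row scans; it is comfortable at the
  scale the package targets (10^4–10^5 triples) but is not a graph
  database. Bulk CSV export (`kg_export_bulk_csv()`) hands larger work to
  one.
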