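# kgtrait

Knowledge-graph link prediction of trait-regulating and polyphenotype genes
in crops.

Breeding programs want **polyphenotype genes** — genes that influence two or
more agronomic traits at once (plant height and grain weight and disease
resistance) — because they can escape the classical trade-offs between
yield, quality and resistance. `kgtrait` finds candidates by pooling
heterogeneous evidence in a typed knowledge graph over 13 entity categories
(traits, genes, proteins, GO terms, pathways, localizations, domains,
families, enzymes, gene symbols) and 14 relation types spanning
Arabidopsis, rice, maize and wheat, then transferring trait labels from
literature-annotated genes to unannotated ones.

## The model

For a known trait-regulating gene g₁ and a candidate g₂ encoding proteins
p₁, p₂:

```
S(g1, g2) = C(k) · D(k) · S(p1, p2),   k = N(g1) ∩ N(g2)
```

- `N(x)` — the gene's scoring neighborhood: its 1-hop graph neighbors plus
  the neighbors of its encoded protein(s); trait nodes are excluded so the
  label being predicted cannot leak into the score.
- `C(k)` — number of entities shared by both neighborhoods.
- `D(k)` — number of distinct entity categories among them (evidence
  spanning molecular levels beats evidence piled in one).
- `S(p1, p2)` — protein similarity on a 0–100 scale: global-alignment
  percent identity (BLOSUM62, affine gaps) or an externally supplied score
  table.

A decision threshold on S is calibrated by maximizing F1 on gene–gene
association pairs time-sliced by publication year (train = pairs known by
the cutoff year, validation = later pairs; `score >= threshold` is
positive). Genes passing the threshold for ≥ 2 traits are polyphenotype
candidates; for a chosen trait set they are prioritized by the mean of
their per-trait score ranks, `Ssum = Σ R(gᵢ) / n`, and validated against
differentially-expressed-gene sets (|log₂FC| ≥ 1) via Venn-region
accounting.

## Worked example

Every input can be synthesized with planted ground truth, so the full
pipeline runs without any download:

```r
library(kgtrait)

bundle   <- generate_fixture(fixture_config(seed = 7))
provider <- table_provider(bundle$sim_table)

split <- time_slice_split(bundle$labeled_pairs, bundle$manifest$cutoff_year)
sweep <- sweep_threshold(split$train)
glance(sweep)
#> # A tibble: 1 × 3
#>   threshold best_f1 n_candidates
#>       <dbl>   <dbl>        <int>
#> 1     3800.       1            7

pred <- predict_all(bundle$kg, unique(bundle$manifest$planted_links$gene),
                    bundle$associations, provider, threshold = sweep$threshold)
head(pred, 4)
#>   gene    trait    best_score supporting_gene threshold passed
#> 1 G_UNK01 trait_01      4003. G_TRAIT_01_K03      3800. TRUE
#> 2 G_UNK01 trait_02      3832. G_TRAIT_02_K03      3800. TRUE
#> 3 G_UNK02 trait_01      3945. G_TRAIT_01_K02      3800. TRUE
#> 4 G_UNK02 trait_02      3825. G_TRAIT_02_K02      3800. TRUE

rank_candidates(pred, c("trait_01", "trait_02"),
                associations = bundle$associations)
#>   gene    rank_trait_01 rank_trait_02  ssum r_comp status
#> 1 G_UNK03             1             2   1.5      1 unknown
#> 2 G_UNK01             2             3   2.5      2 unknown
#> 3 G_UNK04             4             1   2.5      2 unknown
#> 4 G_UNK02             3             4   3.5      3 unknown
```

The swept threshold separates the planted trait-sharing pairs from decoys
perfectly (F1 = 1 on the training slice), every planted two-trait gene is
recovered (`passed = TRUE` for exactly its planted traits), and the rank
table orders candidates by mean per-trait rank — `G_UNK03`, ranked 1 and 2
on the two traits, leads with Ssum 1.5. With the dense tie policy, genes
with equal Ssum (here 2.5) share a comprehensive rank.

`run_pipeline()` chains all stages (load → score → sweep → predict → mine →
rank → DEG overlap) from one config; `inst/cli/kgtool.R` exposes each stage
as a shell subcommand. See the vignette
(`vignettes/mining-polyphenotype-genes.Rmd`) for the model's assumptions,
parameter choices and limitations.

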