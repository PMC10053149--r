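# omicsig

Consensus molecular-signature discovery and drug prioritization for
multi-cohort case/control transcriptomics.

Studies that profile the same disease across several independent cohorts
face a common chain of questions: which genes are differentially expressed
in *every* cohort, which of those sit at topological hubs of the
protein–protein interaction (PPI) network, which biological functions and
upstream regulators they implicate, and which drugs bind the resulting
protein panel strongly enough to be repurposing candidates. `omicsig`
implements that chain as a tested, reusable pipeline, together with
synthetic-data generators that plant known structure at every stage so the
whole pipeline is verifiable by recovery tests — no external downloads
required.

## The statistics at the core

**Moderated t.** Per cohort, gene-wise two-group models give the contrast
γ̂_g (tumor − normal, log2), pooled variance s²_g on d_g = n₁+n₂−2 df, and
δ_g = 1/n₁ + 1/n₂. Variances are shrunk toward an inverse-chi-square prior
(d₀, s₀²), estimated from the data by moment matching with trigamma
inversion, giving

    s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g),
    t̃_g  = γ̂_g / (s̃_g·√δ_g)   ~   t(d_g + d₀) under H₀.

A gene is *up* if BH-adjusted p < 0.01 and aLog2FC > 1 (*down* with the
signs flipped). **Consensus DEGs** (cDEGs) are the direction-wise
intersection across cohorts.

**Key genes.** On the cDEG PPI network, four centralities — degree,
betweenness, stress, bottleneck — are computed exactly (validated against
brute-force path-enumeration oracles); the key-gene set is the union of
the per-measure top-k lists. Over-representation of the signature uses the
one-sided hypergeometric (Fisher exact) tail; regulators (TFs/miRNAs) are
ranked by degree onto the key genes; drugs are ranked from a
receptor-by-drug binding-affinity matrix (kcal/mol) by column sums, with
candidates required to hit ≥ m−1 of m receptors at ≤ −7.0 and average
≤ −7.5.

## Worked example

Uniting published per-centrality top lists into a key-gene signature and a
docking receptor panel:

```r
library(omicsig)
ex <- crc_example_lists()
kg <- key_gene_union(ex$centrality_lists)
kg
#>  [1] "ADH1C"  "CA4"    "CEMIP"  "CLCA4"  "CLDN1"  "CXCL8"  "GUCA2A" "GUCA2B"
#>  [9] "MMP7"   "MS4A12" "ZG16"
length(receptor_panel(kg, ex$key_tfs))
#> [1] 15
```

The 11-gene union is the key-gene signature; adding its 4 key
transcription factors yields the 15-protein receptor panel used for drug
docking.

A fully synthetic end-to-end run (three cohorts, planted DE core):

```r
cfg <- pipeline_config()
sim <- simulate_expression(G = 2000, n_datasets = 3, seed = 42)
res <- run_pipeline(sim$datasets, config = cfg)
res$consensus
#> consensus_sets: 59 common up, 48 common down (3 datasets)
core <- sim$truth$planted_de$gene
length(intersect(res$cdegs, core)) / length(core)
#> [1] 0.535
```

107 cDEGs survive the three-way intersection; about half of the planted
200-gene core is recovered (intersection trades recall for precision —
here every one of the 107 cDEGs is a planted gene; see the methods
vignette), with
directions matching the planted signs.

Hub recovery and drug prioritization on planted structure:

```r
ppi <- simulate_ppi(seed = 42)
select_key_genes(centrality_table(ppi$graph), k = 6)$union
#> [1] "G001" "G010" "G014" "G025" "G036" "G037" "G049"   # contains all 6 planted hubs

aff <- simulate_affinity(seed = 42)
cand <- select_candidates(rank_drugs(aff$am, tau_hit = cfg$tau_hit), cfg)
head(cand, 3)
#>   drug column_sum mean_affinity hits
#> 1 D024  -137.1091     -9.140608   15
#> 2 D071  -136.8968     -9.126454   15
#> 3 D065  -136.8704     -9.124695   15
```

The selected candidates are exactly the nine planted pan-binder drugs:
each hits all 15 receptors below −7.0 kcal/mol with mean affinity near
−9.1.

See `vignettes/signature-discovery.Rmd` for the models, parameter
defaults, numerical choices and limitations.

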