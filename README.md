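# bioidflow

Analysis of BioID proximity-labeling screens: from per-run protein evidence
tables to a filtered candidate-interactor list, cross-condition comparisons,
GO over-representation statistics, and a ratio-weighted interaction network.

## The problem

BioID fuses a promiscuous biotin ligase (BirA\*) to a bait protein; proteins
within ~10 nm are biotinylated in vivo, captured on streptavidin, and
identified by label-free LC–MS. The raw candidate lists are contaminated by
sticky background proteins, keratins, and endogenously biotinylated
carboxylases. `bioidflow` is for analysts of such screens who need the
selection logic to be explicit, auditable, and testable.

The core statistic is the **biotinylation ratio** of a protein *p* within
one experiment (cell line × biotin time × treatment, quantified as one
batch):

```
r_p = mean(normalized bait-fusion abundance over replicates) /
      mean(normalized control abundance over replicates)
```

Candidates must pass, in order: a unique-peptide floor (> 3 bait peptides
and ≥ 1 control peptide), a peptide-direction check (control > bait
disqualifies an experiment), keratin and endogenous-biotin exclusion lists,
and a ratio strictly above 1.5 in at least one experiment. Each removed
protein records the first stage that removed it. Candidate sets feed
per-term hypergeometric over-representation tests (upper tail, log-space)
with Benjamini–Hochberg adjustment per GO namespace (reported when k ≥ 3
and adjusted p < 0.01), and a bait-centred network whose `bioid` edges are
weighted by each candidate's maximum ratio, merged with known interactions
above a 0.5 confidence floor.

A synthetic-data generator produces complete, ground-truth-labeled
experiments (log-normal abundances, planted interactor effects, bait
self-biotinylation, contaminant classes, abundance-tied dropout, ER-stress
shrinkage of labeling effects) so every stage is validated by parameter
recovery. See the methods vignette (`vignettes/bioid-analysis.Rmd`) for the
model and its assumptions.

## Worked example

```r
library(bioidflow)

sim <- generate_experiment(simulation_config(seed = 1))  # 48 runs, 120 proteins
rt  <- compute_ratio_table(sim)                          # normalize + ratios per batch
cs  <- run_cascade(rt, cascade_config())                 # the selection cascade
print(cs)
#> Candidate set: 120 proteins assessed, 14 retained
#> removed by stage:
#>   endogenous_biotin  7
#>   keratin            8
#>   ratio_threshold    91
#> candidates per experiment:
#>   HCT116_24h_stress        1
#>   HCT116_24h_vehicle       11
#>   HCT116_6h_stress         2
#>   HCT116_6h_vehicle        11
#>   HEK293T_24h_stress       1
#>   HEK293T_24h_vehicle      9
#>   HEK293T_6h_stress        1
#>   HEK293T_6h_vehicle       10
```

The 14 retained proteins are the bait (ranked first, by self-biotinylation),
the 10 planted interactors, and 3 background proteins that crossed the ratio
threshold by noise; all 15 planted contaminants were removed by the
exclusion stages, and the stress arms collapse to the bait plus one or two
survivors — the structure the filters are designed to produce.

```r
ann <- plant_annotations(sim$truth, n_terms = 51, enriched_terms = 1, seed = 1)
head(run_enrichment(retained(cs)$gene, ann), 1)
#>      term_id          namespace k  K        p_adj reported
#> 1 TERM_ENR01 biological_process 8 12 2.178224e-05     TRUE

build_network(cs, plant_known_edges(sim$truth, seed = 1))
#> Interaction network: 14 nodes (bait EIF3A), 13 bioid + 31 known edges
```

The planted-enriched term ranks first with 8 of its 12 members among the
candidates. A whole run (simulate → quantify → filter → compare → enrich →
network, with all stage outputs and a JSON summary) is:

```r
run_bioid_pipeline(pipeline_config(seed = 1), outdir = "run1")
```

or from a shell, `Rscript inst/scripts/run-pipeline.R --outdir run1 --seed 1`.

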