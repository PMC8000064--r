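# hubscreen

Hub-gene discovery from expression, interaction and survival data — an R
implementation of the analysis style used to mine treatment-resistance
transcriptomes, modeled on serial xenograft generations of anti-VEGF
(bevacizumab) resistant glioblastoma (the GSE81465 design: 3 shared IgG
controls plus 3 treated replicates in each of generations 1, 4 and 9).

The pipeline: per-generation differential expression (strict
|logFC| > 1 and p < 0.05 cuts) → partition of cross-generation common
DEGs into up / down / discordant → confidence-filtered protein–protein
interaction network (combined score > 0.4) → hub genes by a **hybrid
centrality measure** → MCODE-style dense-module detection (degree
cutoff 2, node score cutoff 0.2, k-core 2, max depth 100, module
score > 5) → hypergeometric over-representation analysis (p < 0.05,
count ≥ 2) → median-split Kaplan–Meier / log-rank / proportional-hazards
survival screen of the hubs.

The hub score of a node v is the plain sum of four centrality terms:

    HCM(v) = deg(v) + closeness(v) + betweenness(v)
             + mean degree of v's neighbors

with an explicit, output-stamped normalization mode (default: raw
degree, per-component closeness in (0,1], pair-normalized betweenness in
[0,1], raw mean neighbor degree); nodes with HCM strictly above 12 are
hubs. Because the raw microarray, interaction-database and clinical
inputs of the motivating study live behind external services, the
package ships seeded synthetic-data generators with planted ground truth
(planted DEGs, cliques, hubs, enriched sets and prognostic genes) so
every stage is testable offline, plus the study's printed gene lists as
plain-text fixtures.

## Worked example

```r
library(hubscreen)

b <- simulate_bundle(seed = 42)     # expression + network + sets + survival
res <- run_pipeline(pipeline_config(), expr = b$expr, edges = b$edges,
                    gmt = b$sets, surv_table = b$survival)
```

The bundle simulates 2000 genes over 12 samples (3 controls, 3 treated
per generation), a 158-node interaction network with a planted 7-clique
and a planted 40-spoke hub named after planted DEGs, two planted
enriched gene sets, and a 200-subject survival table in which the hub
gene carries a true hazard ratio of 2.5. The run reports:

```
DEGs per generation:
gen1 gen4 gen9
 198  200  200
common: 198  up: 96  down: 92  both: 10
network: 152 277
    gene degree closeness betweenness mean_neighbor_degree      hcm direction
1 G01677     40 0.4402332    0.592839                3.575 44.60807        up
planted hub: G01677
modules:
  G01593 7 nodes score 7
  set_id overlap_count      p_value n_up n_down
1 SET001            12 2.554069e-10   12      0
2 SET002            12 7.567786e-05   12      0
    gene    logrank_p hazard_ratio         hr_p significant
1 G01677 1.311865e-08    2.5478899 3.688460e-08        TRUE
2 G00014 8.469327e-01    0.9692268 8.469388e-01       FALSE
```

Reading this: 200 of the 2000 genes were planted differential per
generation and essentially all are recalled; the planted hub `G01677`
tops the hub table (degree 40 dominates its HCM of 44.6); the planted
7-clique is recovered as a module with the maximal score 7 (density 1 ×
7 nodes), passing the score > 5 filter; both planted enriched sets lead
the enrichment table with their exact planted overlap of 12; and the
planted prognostic gene is flagged significant with an estimated hazard
ratio of 2.55 against a planted 2.5, while a null gene is not. Every
stage also works from files (`read_expression_table()`,
`read_edge_list()`, `read_gmt()`, `read_survival_table()`; see
`?pipeline_config` for the path-based configuration and
`vignettes/hubscreen-methods.Rmd` for the full model description).

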