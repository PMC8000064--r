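---
title: "Hub-gene discovery with hubscreen: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-gene discovery with hubscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubscreen)
```

## The analysis in one paragraph

`hubscreen` implements a hub-gene discovery workflow of the kind used to
mine treatment-resistance transcriptomes — here modeled on serial
xenograft generations of anti-VEGF (bevacizumab) resistant glioblastoma
profiled on log2-scale expression arrays. Per generation, treated
replicates are compared against shared IgG controls; genes passing strict
fold-change and p-value cuts are DEGs; DEGs common to all generations are
partitioned into consistently up, consistently down, and discordant
("both") sets. The DEGs seed a protein–protein interaction network
(edges kept above a confidence filter), on which two structures are
mined: hub genes, ranked by a hybrid centrality score, and dense modules,
extracted MCODE-style. Gene lists at every stage are tested for
over-representation against a gene-set collection with the
hypergeometric tail, and candidate hubs are screened for prognostic
value by median-split Kaplan–Meier, log-rank, and proportional-hazards
analysis.

## Differential expression

For generation $g$, each gene's log fold change is
$\mathrm{logFC} = \bar{x}_{\text{treated},g} - \bar{x}_{\text{control}}$
on the log2 scale; controls are shared across generations, matching the
3-control + 3-treated-per-generation design the simulator also emulates.
The default test is a two-sided Welch $t$-test computed row-wise
(Welch–Satterthwaite degrees of freedom). A `"moderated"` mode shrinks
the pooled per-gene variance halfway toward the median pooled variance
before an equal-variance $t$-test. This is a deliberately transparent
approximation of moderated-variance pipelines; it is *not* claimed to be
numerically compatible with any of them, because the upstream analyses
this package re-implements report only thresholds, never fitted model
internals.

A gene is a DEG when $|\mathrm{logFC}| > 1$ **and** $p < 0.05$, both
inequalities strict — a gene at exactly logFC 1 or p 0.05 is excluded.
No multiple-testing correction is applied by default (raw-p reporting is
the convention this workflow mirrors); Benjamini–Hochberg is available
via `call_degs(..., adjust = "BH")`.

Degenerate inputs are handled explicitly: with zero variance in both
groups, equal means give $p = 1$ and unequal means $p = 0$ (this is what
makes the zero-noise simulation limit an exact-recovery test); genes with
missing values in a compared group are dropped from that comparison with
a message; fewer than two replicates per group is a hard error.

The "both" category of the cross-generation partition is defined at the
cross-generation level: a gene that is a DEG in every generation but
changes direction between generations. That is the only reading under
which the three partition categories are disjoint and exhaust the common
set, which `partition_common()` asserts on every call.

## The hybrid centrality hub score

The hub score of a node is the plain sum

$$\mathrm{HCM}(v) = \deg(v) + C(v) + B(v) +
\frac{\sum_{u \sim v} \deg(u)}{|\{u : u \sim v\}|},$$

degree plus closeness plus betweenness plus the mean degree of the
node's neighbors. The four terms live on different scales, and the
source convention for normalizing them is not recoverable, so the
normalization is an explicit mode stamped into every output:

* `default` — raw degree + per-component closeness in $(0, 1]$
  ($({n_c - 1})/{\sum_u d(v, u)}$) + pair-normalized betweenness in
  $[0, 1]$ (Brandes value divided by $\binom{n-1}{2}$) + raw mean
  neighbor degree. Degree-scale terms dominate, which is what makes a
  double-digit hub threshold (default: strictly greater than 12)
  meaningful.
* `all_raw` — raw degree + $1/\sum d$ closeness + raw betweenness + raw
  mean neighbor degree.
* `all_normalized` — every term scaled to $[0, 1]$.

Shortest paths ignore edge confidences (standard practice for these
centralities in the Cytoscape ecosystem); the confidence filter acts
only at network construction, keeping edges with combined score strictly
above 0.4. Isolated nodes get closeness 0 and a flagged
mean-neighbor-degree of 0, so they can never pass a positive hub
threshold. Worked values used throughout the tests: the center of the
4-leaf star scores $4 + 1 + 1 + 1 = 7$, a leaf scores
$1 + 4/7 + 0 + 4 \approx 5.571$, and every node of a triangle scores
$2 + 1 + 0 + 2 = 5$ under the default mode.

## Module detection

The MCODE-style pass is pinned to one variant so results are
reproducible:

1. **Vertex weighting** (`mcode_vertex_weights`): for each node of degree
   at least 2, take the closed neighborhood, find its highest $k$-core by
   peeling, and set the weight to $k_{\max}$ times the density of that
   core. Lower-degree nodes get weight 0.
2. **Growth** (`mcode_grow`): seeds are unvisited nodes in descending
   weight (lexicographic symbol tie-break); breadth-first expansion
   admits a neighbor when its weight is at least
   $(1 - 0.2) \times$ the *seed* weight, up to depth 100. Nodes join at
   most one module (MCODE's single-membership behavior). Seeds are
   restricted to positive-weight nodes: a zero-weight seed would admit
   every neighbor (the threshold degenerates to $0 \ge 0$) and sweep
   arbitrary background into meaningless candidates.
3. **Post-processing** (`mcode_postprocess`): candidates without a 2-core
   are discarded; a single haircut pass removes within-module degree-1
   nodes; density and score (density × node count) are recomputed on the
   final node set. "Fluff" expansion is not implemented.
4. **Filter**: module score strictly greater than 5.

All iteration orders are lexicographic, so any permutation of the input
edge list yields the identical module set (tested).

## Enrichment

Over-representation of a query of size $n$ against a set with $K$
members in a universe of size $N$ uses the upper hypergeometric tail
$P(X \ge k)$, equivalent to the one-sided Fisher exact test; the EASE
variant (overlap reduced by one) is available behind a flag. The
universe defaults to the union of all set members extended by the query,
and can be overridden. Reported sets need $p < 0.05$ (strict) and
overlap at least `min_count = 2` — the count filter is *inclusive* at 2
because printed enrichment tables in this literature routinely include
count-2 rows even when the accompanying methods text says "count > 2";
the printed results are treated as authoritative and the filter is a
plain argument.

One statistical subtlety the test suite accounts for: the
hypergeometric test is discrete, so its attained size at nominal 0.05
is below 0.05 and depends on the margins. The null-calibration check
therefore uses margins (universe 5000, query 500, set size 300) where
the attained size is ≈0.0495, close enough to nominal that a
Monte-Carlo estimate over 1000 null sets lands in [0.03, 0.07] with
high probability. At small set sizes the same check would "fail" purely
through conservatism, not through any implementation defect.

## Survival screen

Each screened gene is dichotomized at its median (50% cut by default;
subjects tied with the cutoff go to the *low* group — a deterministic,
documented rule). The two groups are compared by:

* the Kaplan–Meier product-limit estimator (censoring decrements the
  risk set without a probability step),
* the Mantel–Haenszel log-rank test referred to $\chi^2_1$, and
* a single-covariate proportional-hazards fit with Efron tie handling,
  giving the hazard ratio of the high group with a 95% Wald interval.
  This fit is pinned as *the* definition of the reported HR, since the
  upstream web tool's machinery is unpublished.

A gene is called significant when the log-rank p *or* the HR p is at
most 0.05 (non-strict, per the dual-criterion convention). Complete
separation leaves the partial likelihood monotone; such fits are flagged
and the unbounded interval side is reported as infinite. Months are the
canonical time unit. Per-group median survival is reported for
transparency, since "survival rate in months" summaries in the
literature are ambiguous about which group they describe.

## The synthetic-data generators

Every pipeline input can be generated with planted ground truth, so all
downstream stages are testable without downloads:

* **Expression** — gene baselines uniform on (6, 10) log2 units,
  i.i.d. Gaussian noise (default sd 0.3), planted shifts of ±2 logFC
  (default) in treated samples, 3 replicates per group, generations
  1/4/9 with shared controls; a 5% fraction of planted genes flips sign
  in the last generation to exercise the discordant category.
* **Network** — an Erdős–Rényi (or preferential-attachment) background
  at roughly the published scale (≈800 nodes, ≈5000 edges under the
  defaults), plus planted cliques each bridged to the background by one
  edge, plus a planted hub wired to a configurable number of random
  spokes. All retained edges carry confidences above the 0.4 filter;
  sub-threshold noise edges are optional.
* **Survival** — standard-normal expression per subject and gene; event
  times exponential with the hazard multiplied by the planted ratio for
  the high-expression group of each prognostic gene; independent
  exponential censoring. The default baseline rate of 0.02 events/month
  puts median survival near 35 months, a plausible scale for
  glioma cohorts.
* **Annotation** — null sets drawn uniformly from the universe; enriched
  sets containing an exact planted overlap with a target query.

Every generator is a pure function of its parameters and seed, restores
the caller's RNG state, and the bundle generator fans one master seed
out through fixed offsets so adding a generator never perturbs the
others.

What the generators deliberately do **not** emulate: bead-level array
noise, probe-level effects, correlated gene co-expression, STRING
evidence-channel structure, non-proportional hazards, and informative
censoring. Passing the planted-truth suites therefore demonstrates the
correctness of the algorithms under clean, known-truth conditions — not
robustness to every pathology of real microarray, interaction-database,
or clinical data.

## Problem sizes and runtime choices

The planted-truth suites run at deliberately modest scale so the whole
test suite completes in well under a minute: DEG recovery uses 20 seeds
of 1000 genes; clique recovery 20 seeds of ER(100, 0.03) backgrounds
with planted cliques of size 6–7; log-rank calibration 500 replicates
of 200 subjects; HR recovery 40 replicates of 500 subjects per planted
ratio; and the end-to-end bundle 10 seeded runs of a 2000-gene, ~160-node
configuration. These sizes were chosen to keep Monte-Carlo error well
inside the acceptance bands while remaining quick; all are plain
function arguments and scale up freely.

## Known limitations

* The per-generation DEG counts, exact module compositions, enrichment
  p-values and survival p-values published for the motivating study
  depend on external services and database versions (GEO2R internals,
  STRING v10.0, DAVID's background, TCGA/GTEx cohorts) and are not
  reproducible from a desk; this package reproduces the *method* and the
  printed worked examples, and verifies the statistics against
  independent oracles instead.
* The moderated-variance mode is an approximation, not a limma
  replacement.
* Gene symbols are opaque, case-sensitive tokens; an optional uppercase
  normalization is the only folding offered, and it is off by default so
  that symbol-space mismatches surface as errors rather than silent
  drops.
* MCODE's "fluff" option and directed/weighted centrality variants are
  out of scope.
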