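---
title: "Methods: the network-pharmacology funnel and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the network-pharmacology funnel and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The analysis this package implements

Multi-compound herbal preparations act on a disease through many proteins at
once, so their mechanism is studied as a network rather than a single
dose–response curve. The conventional analysis is a funnel of set and graph
operations:

1. **ADME screen.** Candidate compounds are filtered on predicted oral
   bioavailability (OB, percent) and drug-likeness (DL, unitless), both
   supplied as inputs — the package never computes them from structures.
2. **Target mapping.** Per-compound target predictions from several sources
   are normalised to upper-case gene symbols, deduplicated, pooled, and
   intersected with a disease gene list. The intersection is the set of
   *potential targets* of the preparation against the disease.
3. **Hub screening.** The PPI network of the potential targets is screened
   for hubs: nodes at or above the median of all three of degree,
   betweenness and closeness survive, the subgraph they induce is taken,
   the centralities and medians are recomputed, and the screen is applied
   again. The survivors of the final round are the *key targets*.
4. **Enrichment.** The key targets are tested for overrepresentation in an
   annotation collection (GO-style BP/CC/MF plus pathway sets) with the
   one-sided hypergeometric test and Benjamini–Hochberg FDR control.
5. **Networks.** Compound–target and compound–target–pathway layered
   networks are built and exported for visualization.
6. **Validation arithmetic.** Bench-side quantities that accompany such
   studies are computed exactly: Livak 2^−ΔΔCt relative expression and the
   strong/weak classification of docking affinities.

In published practice these steps are performed interactively across web
databases (compound catalogues, target predictors, disease gene portals,
PPI servers) whose contents change over time. This package replaces those
external inputs with a synthetic generator so the *procedure* is fully
reproducible and testable; it makes no attempt to reproduce any particular
database snapshot.

## Numerical conventions

Several quantities have more than one convention in the wild; the package
fixes the ones whose normalised ranges match how published screening
thresholds are printed (values inside [0, 1]):

* **Betweenness** is Brandes shortest-path betweenness with endpoints
  excluded and path multiplicities weighted fractionally, normalised by
  `2/((n−1)(n−2))` for an undirected graph — the NetworkAnalyzer
  convention. `n` is always the node count of the **current** (sub)graph,
  so thresholds shift between screening rounds. Graphs with fewer than 3
  nodes get all zeros.
* **Closeness** is the reciprocal of the mean shortest-path distance to the
  nodes actually reachable (i.e. within the connected component); isolated
  nodes get 0 by convention. This keeps values in (0, 1] on disconnected
  graphs, where the textbook all-nodes definition would degenerate.
* **Medians** over an even number of nodes are the arithmetic mean of the
  two central order statistics.
* **Threshold comparisons are inclusive (≥) by default** for both the ADME
  screen and the hub screen, with a strict mode available. Inclusive
  semantics describe what median screening actually selects (on a fully
  symmetric graph such as a clique, every node equals the median and the
  screen keeps all of them rather than none); the strict flag covers the
  alternative reading of "greater than the median". The enrichment cutoff
  is the opposite: `FDR < 0.05` is strict, matching how significance
  thresholds are conventionally reported.
* **Hypergeometric p-values** are computed via the log-space tail of
  `phyper`, with `P(X ≥ 0) = 1` returned exactly. **FDR is adjusted within
  each category** (BP, CC, MF, pathway) by default, mirroring how GO tools
  treat the three ontologies as separate families; a flag switches to
  global adjustment. The default universe is the set of genes appearing in
  the annotation collection, overridable because published analyses rarely
  state their background.
* **ΔΔCt** uses the conventional Livak calibration: ΔCt per sample, ΔΔCt
  against the *arithmetic mean of the control-group ΔCt* (not a single
  calibrator sample). A direct consequence — used as a test invariant — is
  that the geometric mean of the control-group folds is exactly 1, and
  that adding a constant to both genes of a sample cancels. SEM uses the
  n−1 variance.
* **Degenerate inputs** are contracts, not crashes: an all-eliminating
  screening round returns an empty, flagged result; an empty disease
  overlap propagates through the pipeline as empty-but-valid artifacts;
  ties in enrichment ranking break by FDR, then p, then term id, so output
  files are byte-stable.

## The synthetic study conditions

The generator plants recoverable structure in every input. Its defaults are
the package's reference study conditions; they were chosen once, by the
separation arguments below, and define what the tests demonstrate.

| parameter | default | rationale |
|---|---|---|
| `n_compounds`, `ob_pass_fraction` | 20, 0.25 | a candidate table of tens of molecules with a planted active subset of 5, the typical size of a screened flavonoid panel |
| `n_target_universe` | 400 | keeps exact brute-force set oracles fast while leaving room for non-overlapping terms and disease genes |
| `targets_per_compound` | 20–60 | per-compound target predictions in the tens, as multi-database target fishing typically yields |
| `n_disease_genes`, `disease_overlap_fraction` | 200, 0.6 | a disease list larger than any compound's target set, with a majority-but-not-total overlap so both Venn regions are non-trivial |
| `ppi_n_nodes`, `ppi_n_planted_hubs` | 80, 16 | PPI on the overlap genes; a 20% hub fraction so that two halving rounds of median screening leave a survivor set dominated by hubs |
| `ppi_hub_attach_prob` vs `ppi_background_edge_prob` | 0.6 vs 0.05 | expected hub degree ≈ 0.6·79 ≈ 47 versus background ≈ 0.05·63 + 0.6·16 ≈ 13 — a wide margin, so recovery failures indicate implementation errors, not noise |
| `n_terms`, `term_size_range`, `planted_term_enrichment` | 50, 10–40, ×5 | one planted term whose query overlap is five times the hypergeometric expectation (capped at the term size); with a query of ~90 overlap genes the planted term is essentially contained in the query, while 49 random terms provide a realistic competing background. `planted_term_enrichment = 1` disables planting and yields the signal-free collections used for null calibration |
| `ct_true_fold`, `ct_noise_sd`, `n_ct_replicates` | 2, 0.2 cycles, 4 | a two-fold induction with instrument-scale Ct noise and a typical biological replicate count |

Each generator draws from its own stream derived from `(seed, stage name)`,
so any stage can be regenerated independently and the full input set is
byte-identical across reruns. Associations are generated for the
ADME-passing compounds only — target fishing is performed on active
compounds, as in the study design this emulates — which makes the planted
disease overlap exactly the set the pipeline recomputes. The PPI graph uses
one attachment rule for every hub-incident pair, including hub–hub pairs,
which keeps hubs central without a second parameter. When a configuration
makes the realised overlap smaller than `ppi_n_nodes` (e.g. a zero-overlap
setting), the pipeline shrinks the graph to the available genes instead of
failing, so degenerate conditions propagate cleanly.

**What the generator does not emulate.** OB/DL values are uniform draws on
either side of the cutoffs, not chemistry; the PPI model is a planted-hub
random graph, not a fit to any real interactome's degree distribution
(which is unknown for the screened networks this emulates); annotation
terms are disjoint random draws with no DAG structure or ancestor
propagation; the disease list has no per-source structure. Passing tests
therefore demonstrate that the *procedures* are correct and that planted
signal of realistic strength is recovered — not that the pipeline
reproduces any particular database-backed study, whose headline counts
depend on versioned external resources.

## Problem sizes in the test suite

The suite verifies the centrality implementations against an independent
BFS path-counting oracle on 200 random graphs of up to 50 nodes, the
hypergeometric tail against direct PMF summation for universes up to 60,
the BH step-up against a literal reference on 1,000 random vectors,
planted-structure recovery over 20 replicate simulations at the default
conditions, and FDR null calibration over 200 signal-free collections —
sizes at which the exact oracles are affordable and the whole suite runs in
well under a minute.

## Known limitations

* Graphs are unweighted and undirected; there is no interaction-confidence
  filtering, because the screening procedure this implements does not state
  one.
* Identifier normalisation is symbol-level (case, whitespace, synonym
  table); it is not an ortholog or accession mapping service.
* Enrichment is plain overrepresentation on the provided sets; GO DAG
  propagation is out of scope.
* The docking side is classification arithmetic only — no structures,
  poses or scoring functions.
* Fold changes are reported as mean ± SEM without inferential testing;
  the package's scope is the network analysis, not wet-lab statistics.
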