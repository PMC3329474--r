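---
title: "Notification networks: decayed edges, role indices and structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Notification networks: decayed edges, role indices and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasffnet)
```

## The model

Cross-border food-safety surveillance systems such as the EU's Rapid Alert
System for Food and Feed log one record per incident: a *detector* country
reports a faulty product originating from a *transgressor* country, on a
date, with a notification type (alert, information, or border rejection) and
a free-text hazard description. `rasffnet` treats this stream as a directed
weighted network between countries and asks two questions at any chosen
date: who carries transgressor impact, and who carries detector impact?

### Temporal decay

A notification's relevance does not end on the day it is logged, nor does it
last forever. Each record contributes to the edge from its detector to its
transgressor a weight

$$w(a) = 2^{-a/h},$$

where $a$ is the record's age in whole days at the query date and $h$ is the
half-life (default 180 days): full weight on the day of logging, half after
one half-life, a quarter after two. The half-life is the single
model-defining timescale; the exponential form is our modelling choice — it
is the unique memoryless decay consistent with a stated half-life, and it
makes edge weights additive over records and monotonically "forgetful" as
the query date moves forward. Records dated after the query date are
excluded outright (closed inclusion boundary at the query date), not decayed
with negative age. Parallel records between the same ordered country pair
are summed into one weighted edge, since every downstream algorithm consumes
aggregate weights. Decayed weights never reach exactly zero, so
`build_snapshot()` exposes `min_weight` for optional pruning; the default is
0 (no pruning).

### Transgressor and Detector Indices

On a snapshot we compute two per-country indices with two algorithms:

* **PageRank.** The Transgressor Index (TI) is the weighted PageRank of the
  detector→transgressor orientation: a country accumulates TI by being
  reported, the more so when reported by countries that are themselves
  heavily involved. The Detector Index (DI) is the weighted PageRank of the
  reversed orientation. The two runs are independent of each other.
* **HITS.** The hub/authority iteration on the detector→transgressor
  orientation, where DI = hub score and TI = authority score. Here the
  indices are mutually reinforcing: a detector scores high by reporting
  high-TI countries and vice versa.

Both families are L1-normalized, so TIs sum to exactly 1 over countries at
every query date (likewise DIs); reports multiply the values by 1000 for
readability (`scale_for_report()`). Zero-score countries stay in the vector
rather than being dropped, keeping export schemas stable. Ties in rankings
are broken lexicographically by country code, so reports are deterministic.

Numerical choices: the PageRank damping factor defaults to the standard
0.85 and is exposed as a parameter; countries with no out-edge in the
orientation being ranked (e.g. pure transgressors in the TI run) are
dangling nodes and teleport uniformly, which keeps the index a proper
probability distribution. The power iteration stops when the L1 change
drops below `tol` (default 1e-10, well inside the 1e-9 normalization
contract) and errors rather than returning an unconverged vector. The HITS
iteration is L2-normalized internally for stability and L1-normalized on
return; its iteration cap is generous (10,000) because graphs whose two
leading singular values nearly tie converge slowly.

## A worked snapshot

```{r}
log <- generate_log(default_scenario(n_notifications = 2000, seed = 7))
snap <- build_snapshot(filter_log(log, "mycotoxin"), "2008-01-01",
                       filters = list(category = "mycotoxin", ntype = "all"))
idx <- pagerank_indices(snap)
idx$TI
```

The colour coding mirrors the surveillance-map convention: red intensity
proportional to TI, green to DI, so dominant transgressors render red,
dominant detectors green, and dual-role countries a brownish blend; opacity
is the larger of the two intensities, so marginal actors fade out. The
transfer function (linear in the index, clamped at 1, with the default
`strength_scale` set to the reciprocal of the 95th percentile of the pooled
index values so colour saturates exactly for the top actors) is our
documented choice; no canonical mapping exists.

```{r}
head(node_colors(idx$TI, idx$DI))
```

## Filters

Records can be filtered before snapshotting by contamination category —
assigned from the hazard text by case-insensitive substring match against a
keyword table (heavy metals, mycotoxins, bacteria, chemicals, other) — and
by notification type, separating border rejections from the full stream.
`"microorganism"` aggregates mycotoxin and bacteria; `"all"` keeps
everything including uncategorized records. Matching is literal (no
stemming), because the keyword table lists literal contaminant names; a text
matching several categories is assigned to the first matching category in
table order with a warning, and all matches are kept in a diagnostics
attribute — the convention is ours, as no tie rule is canonical. We match
against the hazard text only, the one free-text field the data model
carries.

## Structure

Two structural views of the undirected projection (pair weights summed over
both directions) are provided: community detection by greedy multilevel
modularity maximization (`find_communities()`, with a fixed seed for
reproducible refinement order) and k-core decomposition (`k_core()`, on the
unweighted simple projection — coreness is a count-based notion, so weights
are deliberately ignored there). Modularity uses Newman's weighted form;
the returned Q is always recomputable from the returned assignment via
`modularity_q()`. Direction handling is our choice: both analyses are
defined for undirected graphs, and the notification relation is treated as
a symmetric association for this purpose.

## Trajectories

`index_trajectory()` recomputes filter → snapshot → index at every date of
a grid (monthly by default via `monthly_grid()`; the spacing is a display
choice, as snapshots are well-defined at any date). Countries absent from a
date's snapshot score 0 at that date, so the per-date normalization to 1
holds across the whole country set at every grid point. A country whose
reports stop decays smoothly: with no new contributions its edge weights
halve every half-life while others keep accruing, so its normalized index
falls — this is the signature by which an effective intervention (e.g. a
remediation programme ending a country's contamination reports) becomes
visible in the trend line.

## The synthetic generator

Real notification extracts are not redistributable, so the package ships a
generator (`generate_log()`) whose defaults emulate the published structure
of the EU stream over May 2003–August 2008: detectors restricted to EU
member states (non-EU countries appear only as transgressors, EU states in
both roles); 15,000 records; category mixture over categorized records of
mycotoxin 50.45%, bacteria 20.26%, metal 10.95%, chemical 15.54%, other
2.80%; and 39.6% of records uncategorized (labelling issues, foreign
bodies, and other non-contamination infringements), included only in the
`"all"` filter. Where the emulated system publishes no value we chose once:
border rejections are drawn with probability 0.25 — a major but not
dominant class — with the remainder split evenly between alerts and
information notices; dates are uniform over the range (no seasonality);
detector and transgressor are drawn independently in proportion to
per-country rates, with self-pairs resampled by default. Stylized default
rates make DEU the dominant detector (with ITA and ESP strong) and IRN the
dominant transgressor (with CHN next), echoing the era's mycotoxin problem.
`rate_change_events` switch a country's transgress rate at a date, for
intervention scenarios.

What the generator does *not* emulate: seasonality, hazard-specific
country–country affinities (a pair's categories are independent of the
pair), serial correlation in reporting, and free-text noise such as
misspelled contaminant names. Tests passing on generated logs therefore
validate the pipeline's algebra and statistics, not the linguistic
robustness of the categorizer on real free text.

## Problem sizes used in validation

The shipped checks run the engines against independent oracles — a dense
linear solve for PageRank, repeated squaring of the explicit Gram operator
for HITS — on 100 random weighted digraphs of up to 8 nodes; exhaustive
partition search certifies the modularity heuristic on graphs up to 10
nodes (the two-triangle optimum Q = 0.5 is hand-derivable); brute-force
peeling certifies coreness up to 12 nodes; planted-role recovery uses 200
replicates of a 10-country scenario with 500 records each, and the
generator-fidelity check uses one 15,000-record log. These sizes make the
oracles (some of which enumerate all set partitions) exact and fast while
exercising every code path; the engines themselves scale comfortably to the
few hundred countries a real extract contains.

## Limitations

* Categorization is keyword-based on a single free-text field; synonyms,
  misspellings and contaminants outside the table fall into
  `"uncategorized"`.
* The decay form is exponential by design choice; only the half-life is
  externally given.
* Community detection is heuristic; optimality is certified only at oracle
  scale, and near-degenerate modularity landscapes may admit several
  optimal partitions.
* Index values depend on the filter through the record subset only; there
  is no category-specific teleportation or personalization.
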