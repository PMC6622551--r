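---
title: "Monthly horse-movement contact networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monthly horse-movement contact networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equinet)
```

This vignette explains the models and conventions behind `equinet`: how a
pile of monthly movement-diary rows becomes a set of directed contact
networks, which statistics are computed on them and under exactly which
definitions, what the synthetic diary generator does and does not
emulate, and where design choices were genuinely open.

## 1. From diaries to records

A movement record is one horse trip between two locations: participant
and horse identifiers, a discipline (competition / leisure / racing), an
origin (by default the owner's current home facility), a destination
name and city/town, departure and return dates, a travel reason, and an
optional sanctioned-competition flag. Ingestion (`read_movements()`) is
deliberately conservative: a row whose mandatory fields cannot be parsed
is returned in a rejects table with a reason code, never silently
dropped, and exact duplicates (questionnaire re-submissions) are
collapsed with a warning. Free-text reasons are mapped through a
user-extensible keyword table; anything unmatched becomes `other`.

The inclusion filter mirrors longitudinal diary studies: a record is
analysable when its dates are complete (a return date is required unless
the movement is a permanent boarding change) and at least the
destination's city/town is known. Racing-discipline records are set
aside entirely — racehorse logistics differ enough from sport and
leisure travel that mixing them would blur both.

**Location identity.** Locations are keyed by the (alias-resolved name,
city/town) pair. This keeps the double-counting behaviour of open-ended
questionnaires: two participants reporting "my friend's farm" in the
same town remain two locations, because nothing in the data licenses
merging them. The consequence — slightly inflated node counts and extra
fragmentation relative to the unobservable true network — is a property
of the data source, and we prefer exposing it to hiding it. Coordinates
and census regions come only from the supplied gazetteer (no geocoding
services); unresolved cities fall back to a configurable region
(`out_of_province` by default) with no coordinates, and such movements
are skipped-and-counted in distance summaries.

**Monthly location types.** Each location active in a month is typed by
the single purpose observed there that month — `home` for trip origins
and boarding-change destinations, otherwise the travel reason — or
`mixed` when more than one purpose occurs. A trip spanning a month
boundary marks both endpoints in both months, so every node of every
monthly network carries a type.

**Completeness scenarios.** Participants are filtered by how many of the
seven monthly questionnaires they completed: `any` (≥ 1), `most` (≥ 5),
`all` (7). When an explicit response table is available it should be
used, because a "no movements this month" submission counts as a
completed questionnaire yet leaves no records; otherwise completion is
inferred from record presence per participant-month. The thresholds are
nested, so the retained participant sets are provably nested — a
property test exercises this on arbitrary response patterns.

## 2. Network construction

Monthly aggregation windows match the incubation-plus-detection
timescale of the equine pathogens that motivate this kind of analysis.
Within a month, each movement contributes a directed edge from origin to
destination; if the trip returns, the return contributes the reverse
edge in the month of the return date. A trip spanning a month boundary
therefore feeds two networks — the convention that conserves both
directed movements (the alternative, assigning both edges to the
departure month, would fabricate a same-month reciprocation that never
happened). Permanent moves contribute a single edge. Edges are
deduplicated (how many horses moved is not considered) and nodes are
active locations only.

Node attributes: the monthly type, the census region, and a discipline
label — the disciplines of horses touching the node that month, reduced
to `competition` / `leisure` / `both`. Treating `both` as its own
nominal category is this package's choice; diary data do not define a
node-level discipline, and the alternative (majority label) discards the
signal that a facility mixes disciplines.

## 3. Measures and their conventions

* **Reciprocity** is edge-wise: the fraction of edges whose reverse
  exists. The dyadic variant (mutual dyads over connected dyads) is
  selectable; for near-fully-reciprocated networks the two are close,
  but the edge-wise reading matches "proportion of reciprocal edges".
* **Nominal assortativity** is Newman's coefficient on the directed
  mixing matrix. Undefined cases (a single category present) are
  reported as `NA`, never as 0 — a month in which every active location
  is a home tells you nothing about mixing.
* **Degree assortativity** is the Pearson correlation across edges of a
  source-degree with a target-degree. Published tables rarely state
  which convention they used, so the default (raw degrees, out-degree at
  the source against in-degree at the target — the default of the widely
  used graph libraries) is paired with `total` and excess-degree
  toggles. Zero-variance configurations are `NA`.
* **GSC** is the largest strongly connected component from standard SCC
  decomposition; with ties only the size is meaningful.
* **Loyalty** of a node is the Jaccard overlap of its neighbour sets in
  consecutive months. Neighbourhoods are the undirected union of in- and
  out-neighbours by default (an out-only variant is exposed); in
  near-fully-reciprocal networks the two conventions almost coincide. A
  node absent from one month scores 0 under the default eligibility
  rule — a location that stops being visited has preserved nothing — and
  a drop-absent variant restricts to nodes present in both months. Both
  poolings of the overall summary (all node values pooled, or per-pair
  medians) are implemented, because published summaries are often
  ambiguous between them.
* **Pair-level preserved contacts** (`edge_loyalty`): the Jaccard index
  of two months' contact sets, by default over unordered dyads. Reported
  per consecutive pair alongside the node-level summaries; a published
  "loyalty" time series with one value per month pair and a tight,
  strictly positive IQR is this quantity, not a median of per-node
  Jaccards (those are lumpy fractions with mass at 0 and 1).
* **Similarity of highly connected nodes**: nodes are ranked by average
  degree, the top `ceiling(0.1 n)` are taken, and every node tied with
  the cut-off value is included — deterministic and label-independent,
  at the price of occasionally larger sets. The index is the Jaccard
  overlap of the two months' sets; an all-pairs mode supports
  "farther apart in time" comparisons.

Distances use the haversine formula on a sphere of radius 6371.0088 km
between city/town centroids; at city resolution, ellipsoidal corrections
are far below the coordinate error. Distance summaries are
movement-level (each movement contributes one distance, so a venue
visited weekly counts weekly); quantiles use R's default linear
interpolation (type 7). Within-region fractions are the trace of the
region-by-region flow matrix over its total.

## 4. The synthetic movement-diary generator

`generate_movement_data()` simulates the data-generating process of a
seven-month (May–November) Ontario equestrian season, so that every
pipeline stage has a realistic, fully known input. Its defaults encode
the cohort structure this kind of longitudinal diary study reports:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 197 | enrolled owners |
| `horses_per_owner` | P(1) = 0.52 … P(10) = 0.01 | median 1, IQR 1–3, mean ≈ 2.4 (≈ 470 horses) |
| `p_competition_horse` | 0.636 | competition vs leisure |
| `monthly_totals` | 313, 290, 280, 312, 250, 200, 109 | expected movements of a 330-horse reference herd; May/August peaks, November trough (totalling 1754) |
| `activity_dispersion` | 1 | gamma shape of the per-horse-month activity multiplier (negative-binomial travel) |
| `weekend_multiplier` | 2.5 | Saturday/Sunday departure upweighting |
| `reason_mix` | competition 0.21, riding 0.40, training 0.15, healthcare 0.12, other 0.12 | travel reasons |
| `distance_meanlog`, `distance_sdlog` | log 47, 0.93 | log-normal trip-distance kernel: median 47 km, Q3 ≈ 88 km, heavy right tail |
| `p_within_region` | 0.73 | movements staying in the home census region |
| `p_out_of_province`, `p_international` | 0.015, 0.005 | long-tail trips (up to ~3200 km) |
| `p_round_trip` | 0.95 | same-month return → reciprocity ≈ 0.95 |
| `p_boarding_late` | 0.5 | October one-way movements that are permanent boarding changes (November one-ways always are) |
| `response_model` | 30 % semi-dropouts at 0.35/month, others 0.935/month | chosen analytically so the expected any/most/all participant counts are ≈ 194/140/86 |
| `p_sanctioned` | 0.343 | sanctioned share of competition movements |
| `exploration_weight`, `repertoire_decay` | 1, 0.02 | destination urn (below) |
| `p_private` | riding 0.6, other 0.5, training 0.3, healthcare 0.1, competition 0.05 | participant-private destinations |

Unprinted monthly totals (June, July, September, October) were
interpolated between the stated May/August peaks and November trough so
the season totals 1754 movements for the reference herd.

**Destination choice.** Each movement either revisits a destination from
the owner's repertoire or explores a new one, via a Pólya urn: a
repertoire entry is drawn with probability proportional to its
accumulated visit weight, exploration with probability proportional to
`exploration_weight`. Visit weights are multiplied by
`repertoire_decay` at each month boundary, so a freshly decayed
repertoire loses out against exploration at the start of a month and
the set of venues an owner frequents churns between months — this is
what produces the low month-to-month loyalty characteristic of observed
equestrian travel, while within-month visits stay concentrated (edge
counts well below movement counts). Pooling the repertoire across travel
reasons lets one facility be visited for different purposes, which is
how mixed-use locations arise. Explored destinations draw a target
distance from the log-normal kernel — stratified so within-region trips
take the kernel's lower `p_within_region` quantile band — and choose a
gazetteer city within ±max(25 %, 10 km) of the target, weighted by 1/d
to offset the growth of city count with radius. Short targets can land
in the origin's own city (0 km, a different venue in the same town).
With some per-reason probability a new destination is
participant-private (a friend's farm, a local trail), fragmenting the
network the way unresolvable questionnaire answers do.

**Trip fates.** 95 % of movements return within the month (durations
0–3 days, weekend-peaked departures). The remainder return early the
next month or, in October/November, permanently relocate the home
facility within the region; subsequent movements originate from the new
home. Every generated cohort comes in two views: the ground truth and
the questionnaire view, in which non-responded participant-months are
deleted and a fraction of venue names appear under abbreviated alias
spellings (with the alias table to resolve them) — so missing-data and
standardisation machinery can be tested against a known answer.

**What the generator does *not* emulate.** Emergent network topology is
deliberately not calibrated: the synthetic cohort produces more unique
locations (~800 over the season vs ~550 in comparable observed data),
smaller giant strong components (medians around 7 vs ~15), a more stable
top-degree set (similarity ~0.2 vs ~0.07: owners with many horses keep
their home facilities highly connected every month), and *positive*
discipline assortativity — synthetic homes belong to a single owner and
are therefore discipline-pure, whereas real home facilities are
multidisciplinary boarding barns whose mixture comes mostly from horses
outside any study sample. Passing recovery tests on this cohort
therefore validates the pipeline's arithmetic and the generator's
configured marginals (reciprocity, distances, regional mixing,
discipline and sanctioned shares, response structure), not the
fine-grained topology of any real horse network.

## 5. Numerical and degeneracy conventions

Undefined statistics are `NA`, never imputed: reciprocity of an edgeless
month, nominal assortativity with one category, degree assortativity
with zero variance, loyalty of a node with empty neighbourhoods in both
months. Quantiles everywhere are type 7. Month labels are ISO
`YYYY-MM`; all CSV output is UTF-8 with ISO-8601 dates, making reruns
byte-identical (a test asserts this). The only randomness in the whole
package lives in the generator and flows from a single integer seed;
the analysis path is fully deterministic. Gazetteer conflicts (one city,
two coordinate entries) abort rather than guess. Location identifiers
are assigned by sorted (name, city) key, which makes standardisation
idempotent.

## 6. Validation strategy and problem sizes

The test suite checks every network statistic against brute-force
oracles computed directly from edge lists: exhaustively over all 64
digraphs on three labelled nodes, and on batches of random 4–8-node
digraphs (including degenerate cases). Degree-preserving rewiring is
used as a null model for nominal assortativity (200 rewirings of a
50-node graph, mean coefficient within ±0.05 of zero). Generator
recovery runs 20 seeds of the full default cohort (~2500 movements
each) and compares Monte-Carlo means with configured targets:
reciprocity within ±0.03, within-region fraction within ±0.05, median
distance within ±10 %. End-to-end pipeline tests use 40-participant
cohorts for speed; the acceptance script runs the full 197-participant
configuration. The complete suite runs in well under a minute on one
core.

## 7. Known limitations

* Node counts inherit the double-counting of unresolvable location
  names; measures should be read as properties of the *observed* diary
  network, not of the true contact network (which unobserved horses at
  the same facilities would connect further).
* The questionnaire schema is single-leg (origin → destination); tours
  (A→B→C) must arrive as separate records.
* XLSX diaries must be converted to CSV before ingestion.
* The exact degree-assortativity convention behind any published table
  may differ; the toggles cover the common choices, and reported
  coefficients should name their convention.
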