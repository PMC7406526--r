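---
title: "Scoring fluency lists and estimating semantic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fluency lists and estimating semantic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencynet)
library(dplyr)
```

This vignette is the package's account of the methods it implements: the
scoring rules, the generative model behind the likelihood-based estimator,
the parameters that matter, and the choices we made where the methods
literature leaves the design open.

## Data model and cleaning pipeline

A fluency dataset is a tibble with one row per response, in chronological
order within each list, keyed by `id` (subject) and `listnum`. Lists are
ordered by subject (lexicographically) and list number (numerically).
Cleaning at load time happens in a fixed order:

1. lowercase and trim whitespace (all matching in the package is
   case-insensitive; scheme members and spell keys are folded the same
   way);
2. strip non-alphabetic characters if `remove_nonalpha = TRUE`;
3. apply the spelling dictionary;
4. drop verbatim perseverations if requested;
5. drop intrusions if requested.

Correcting spelling *before* deduplicating matters: a dictionary that
canonicalizes variants (two elephant subspecies to `elephant`, `eating` to
`eat`) turns semantically equivalent responses into verbatim repeats, which
is the only kind of repeat the scorer counts. Running the steps the other
way would let variants slip past deduplication. Intrusion removal runs
last, after the vocabulary has been normalized, so that a correctly spelled
form is never flagged as out-of-category because of a typo. The dictionary
is deliberately dumb: chained entries (a corrected form that is itself a
key) are rejected at load rather than resolved transitively, because silent
rewriting chains tend to hide coding errors in hand-maintained files.

The `hierarchical` flag is a view, not a transformation: hierarchical
datasets return one value per subject (the unweighted mean over that
subject's lists), flat datasets one value per list. Toggling twice is the
identity.

## Cluster scoring

Both boundary rules operate on the *label sets* a scheme assigns to each
response; continuity requires a non-empty intersection of label sets, not
label equality, because schemes may give one response several labels.

* **Fluid**: a cluster breaks between consecutive responses whose label
  sets are disjoint.
* **Static**: a running intersection is carried across the cluster; the
  cluster breaks when the next response shares nothing with that
  intersection, and the breaking response starts the next cluster. The
  running intersection equals the intersection over the whole run, so the
  static criterion is at least as strict as the fluid one — static switch
  counts can never be lower, a property the test suite checks on a
  thousand random list/scheme pairs.

Two decisions here are ours. Responses absent from a semantic scheme get a
unique singleton label: they form their own cluster and switch on both
sides, and a warning names them. The alternative — silently fusing unknown
words into neighboring clusters — makes dictionary gaps invisible, which is
exactly how scoring drift starts. Second, the switch *rate* divides by the
number of scored responses in the list; "switches per item" admits other
denominators (items minus one, valid items only), and the choice is
documented here rather than hidden.

For letter fluency, a prefix length *k* makes the first *k* characters the
(single) label, so any word is in-scheme by construction and intrusions are
instead defined by the target letter.

## Word norms

`word_stat()` averages a word→value table over each list. The missing-word
policy is explicit and belongs to the norm table: either a substitute value
(0.5 is the conventional default for per-million word frequency) or
exclusion from the mean. A list with *no* words in the table yields `NA`
with a warning under the exclusion policy — never a silent zero, which
would masquerade as a legitimate mean.

## The censored random walk and its exact likelihood

The generative model behind both the simulator and the U-INVITE estimator:
memory retrieval is a random walk on an undirected semantic network that
steps uniformly at random over neighbors, and a concept is *spoken* only on
its first visit — revisits are censored. This produces lists with the
qualitative signature of real fluency data (local runs of related items,
diminishing returns over time) from a single structural object.

For an observed list $x_1, \dots, x_m$ the likelihood factorizes over
transitions. We condition on the first response rather than modeling a
start distribution: the methods literature does not commit to a start
prior, and conditioning keeps log-likelihoods comparable across candidate
networks (every network pays the same zero cost for the first item). Each
subsequent factor is a first-passage probability: the walk sits at
$x_{k-1}$, may wander freely among the already-spoken set
$\{x_1,\dots,x_{k-1}\}$, and the factor is the probability that its first
exit from that set lands on $x_k$. With transient states the spoken nodes
and absorbing states their unspoken neighbors, the vector $h$ of
absorption-at-$x_k$ probabilities solves $(I - Q)\,h = r$, where $Q$ holds
walk transition probabilities among spoken nodes and $r$ the one-step
probabilities into $x_k$. This is exact — no sampling, no truncation.

Numerical choices: the solve uses a relative tolerance of 1e-10; spoken
nodes that cannot reach any absorbing state (possible when the spoken set
is disconnected inside the network) are removed before solving, which keeps
the reduced system nonsingular and assigns those states their correct
absorption probability of zero. A transition onto a node that is not an
unspoken neighbor of the spoken set has probability zero and makes the
whole list log-likelihood $-\infty$. Perseverations are rejected up front —
under censoring a node cannot be emitted twice, so the model assigns
repeat-bearing lists no probability at all.

The test suite validates the solver against two independent oracles: an
iterative bounded-walk mass-propagation computation of the same
probabilities (agreement within 1e-6 on all full emission orders over
connected graphs of up to four nodes, and within 1e-9 on random 4–5-node
graphs), and empirical frequencies from $10^5$ simulated walks (within
three binomial standard errors). Conservation — next-emission probabilities
summing to one whenever the spoken set has unspoken neighbors — is checked
directly from the absorbing-chain solution.

## U-INVITE search

The estimator maximizes the dataset log-likelihood plus an independent
Bernoulli($\theta$) log-prior over edges. Defaults: $\theta = 0.5$ (flat,
so the default fit is pure maximum likelihood; smaller values act as a
sparsity knob), `max_passes = 20`.

The optimizer is greedy coordinate ascent over single-edge toggles,
first-improvement acceptance, sweep order drawn freshly each pass from a
seeded RNG; it stops after a pass with no accepted toggle. The starting
point is the naive-random-walk network, which is always representable:
every observed transition then runs along an edge, so the starting
likelihood is finite. A toggle that would zero the likelihood scores
$-\infty$ and is never accepted, so the objective is non-decreasing by
construction (asserted on the recorded `score_trace`). Only lists
containing a toggled endpoint can change likelihood — an edge between two
nodes affects first-passage probabilities only through the degrees and
adjacency of spoken nodes — so per-list scores are cached and selectively
recomputed. The result is a local optimum and a deterministic function of
(dataset, seed); with 50 simulated lists from a planted 10-node, 15-edge
network, the fit recovers the planted edge set with F1 at or above 0.9
(exactly 1.0 in the runs the acceptance script performs).

## The other estimators

**First edge** and **naive random walk** are definitional and
parameter-free. **Pathfinder** here is the sparsest classical variant: keep
an edge iff it belongs to at least one minimum spanning tree of the
distance graph. By the cycle property that holds exactly when the endpoints
are disconnected among strictly lighter edges, which a Kruskal-style sweep
with equal-weight batching decides without enumerating trees; the suite
checks equality with brute-force enumeration of all spanning trees on 100
random graphs. The distance itself is not canonical in the fluency
literature, so it is isolated in `pathfinder_distances()`: we use the mean
absolute positional lag over lists containing both items, infinite for
never-co-listed pairs.

**Correlation networks** threshold the product-moment correlation of
presence/absence vectors across lists (default threshold 0.5, always
explicit). Items present in every list or none have undefined correlation
and are excluded — as isolated nodes, with a warning — rather than dropped.
Graph-planarity refinements that exist in that literature are out of scope.

**Conceptual networks** test windowed co-occurrence against a within-list
random-order null. For a list of length $m$ containing both items, the
probability that two uniformly placed items fall within $w$ positions is
$p = w(2m - w - 1)/(m(m-1))$; the co-occurrence count over qualifying lists
is Poisson-binomial, its upper tail computed by exact convolution, and an
edge requires tail probability below `alpha`. Defaults `window = 2`,
`alpha = 0.05`, no multiple-comparison correction — the classical usage;
all three are arguments. Edge sets are nested in `alpha` by construction.
A window spanning a whole list makes its null probability one — such lists
add no evidence, and the loader warns.

## The synthetic-data generator

`generate_synthetic_dataset()` simulates censored walks from a known
network (by default emitting every node, under a uniform start and a step
budget of 100 steps per requested emission) and optionally plants
perseverations and intrusions: after each emitted response beyond the
first, a verbatim copy of a uniformly chosen earlier response is inserted
with the perseveration rate, and a fresh out-of-lexicon token (sampled
without replacement within the list) with the intrusion rate. Every
insertion is recorded in a ledger with its position, making recovery checks
exact: the measures module must return precisely the planted counts, and
does. Lists truncated by the step budget are flagged in the ledger.

What the generator emulates: order structure driven by graph topology,
repeats, out-of-vocabulary noise, subject/list structure, and the CSV
format, so the entire pipeline can be exercised end to end from files. What
it does not emulate: response times, frequency-weighted or priming-driven
transitions, inter-subject network variation, or fatigue. Passing
recovery tests therefore demonstrates correctness of the scoring and
estimation machinery under the model's own assumptions, not validity of the
model for any particular clinical population.

## Problem sizes and determinism

The automated checks run at sizes chosen to make the mathematics exhaustive
where possible and cheap everywhere: all connected graphs on up to four
nodes for the likelihood oracle, graphs of up to six nodes for spanning-tree
enumeration (100 instances), a 10-node planted network with 50 lists for
recovery, $10^5$ walks for the simulation frequency check, and 1,000 random
list/scheme pairs for the switch-ordering invariant. Every stochastic
component takes an explicit seed, and seeded runs are bit-reproducible,
including across the config/CLI layer.

## Known limitations

* The greedy U-INVITE search finds a local optimum; restarts with different
  seeds can differ on sparse data. Hierarchical (per-participant) variants
  with a shared group prior are not implemented.
* The pathfinder distance and the correlation thresholding rule are
  reasonable reconstructions of common practice, flagged as configurable
  decision points rather than canonical definitions.
* The exact likelihood solves a linear system per transition, so cost
  grows with list length cubed per list; comfortable through tens of
  nodes, not intended for hundred-node-list datasets.
* Spell files are applied as exact string maps; there is no fuzzy
  matching, by design.
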