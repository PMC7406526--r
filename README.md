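# fluencynet

Verbal fluency scoring and semantic network estimation in R.

The verbal fluency task — "name as many animals as you can in one minute"
(semantic fluency), or "words starting with F" (letter fluency) — is a
staple of neuropsychological assessment and of research on semantic memory.
The resulting response lists are richly structured: responses arrive in
semantically related runs (*clusters*) separated by *switches*, and contain
occasional repeats (*perseverations*) and out-of-category responses
(*intrusions*). Scoring these by hand is slow and subjective, and the same
lists can also be used to *estimate* the latent semantic network — the
graph of concept-to-concept relations — that produced them. fluencynet
automates both: standardized scoring of fluency lists, and network
estimation by several methods, including an exact maximum-likelihood fit
under a censored-random-walk model of retrieval.

Everything is tidyverse-shaped: datasets are tibbles with one row per
response, every measure takes the dataset first and returns a tibble, and
fitted networks support `tidy()`, `glance()` and `autoplot()`.

## What it computes

**Fluency measures.** Cluster segmentation under two boundary rules —
*fluid* (a switch when a response shares no category label with the
previous response) and *static* (a switch when it shares no label common to
the whole current run); switch counts and switch rate (switches per item);
mean cluster size; verbatim perseverations (with dictionary
canonicalization, so `african elephant` and `asian elephant` can both be
mapped to `elephant` and caught as a repeat); scheme- or letter-based
intrusions; and per-list means of any word norm (frequency, age of
acquisition, ...), with an explicit missing-word policy.

**Network estimation.** Let the lists be ordered response sequences. The
estimators are:

| method | edge rule |
| --- | --- |
| first edge | the first two responses of each list |
| naive random walk | every adjacent response pair |
| pathfinder | union of all minimum spanning trees of a positional-proximity distance matrix |
| correlation | presence/absence vectors with r at or above a threshold |
| conceptual network | pairs co-occurring within a positional window more often than a within-list random-order null allows (exact Poisson-binomial tail test) |
| U-INVITE | the network maximizing the censored-random-walk likelihood |

**The censored-random-walk model.** Retrieval is modelled as a random walk
on an undirected graph G that moves uniformly over neighbors; a node is
spoken only on its first visit (revisits are censored). For an observed
list x₁…xₘ, the first response is conditioned on, and each later transition
contributes the probability that a walk started at xₖ₋₁, free to wander
among the already-spoken nodes, first leaves that set at exactly xₖ. These
first-passage probabilities are computed exactly by solving the linear
system of the absorbing Markov chain whose transient states are the spoken
nodes and whose absorbing states are their unspoken neighbors. The
U-INVITE estimator maximizes the summed log-likelihood over networks by
greedy, seed-deterministic edge toggles from the naive-random-walk start,
optionally with an independent Bernoulli(θ) edge prior. The same model runs
forward as a simulator, which doubles as a synthetic-data generator with a
planted ground-truth ledger.

## Worked example

The bundled toy dataset has two subjects, a misspelling, two elephant
subspecies, a repeat, and one non-animal:

```r
library(fluencynet)
library(dplyr)

path   <- system.file("extdata", "example_fluency.csv", package = "fluencynet")
spell  <- system.file("extdata", "example_spell.csv",  package = "fluencynet")
scheme <- system.file("extdata", "example_scheme.csv", package = "fluencynet")

fl  <- load_fluency_data(path, spell = spell)
sch <- read_scheme(scheme)

segment_clusters(c("hamster", "cat", "dog", "wolf", "coyote", "zebra"),
                 sch, mode = "static")
#> <cluster_segmentation: static> 3 clusters, 2 switches
#>   [hamster, cat, dog]
#>   [wolf, coyote]
#>   [zebra]
```

Under the static rule the run breaks at *wolf* (no label shared with all of
*hamster, cat, dog*) and again at *zebra*; under the fluid rule *dog* and
*wolf* are both canines, so only the *coyote*→*zebra* transition switches
(1 switch, clusters of sizes 5 and 1).

```r
bind_rows(cluster_switches(fl, sch, mode = "static"),
          perseverations(fl))
#> # A tibble: 8 × 4
#>   id    listnum measure          value
#>   <chr>   <int> <chr>            <dbl>
#> 1 A101        1 cluster_switches     2
#> 2 A101        2 cluster_switches     0
#> 3 A102        1 cluster_switches     1
#> 4 A102        2 cluster_switches     1
#> 5 A101        1 perseverations       0
#> 6 A101        2 perseverations       1
#> 7 A102        1 perseverations       1
#> 8 A102        2 perseverations       0
```

Subject A101's list 2 shows a perseveration because the spell file
canonicalizes both elephant subspecies to `elephant`; A102's repeat of
`eagle` is verbatim. Network estimation and its summary:

```r
net <- estimate_naive_random_walk(fl)
glance(net)
#> # A tibble: 1 × 7
#>   n_nodes n_edges mean_degree clustering_coefficient mean_shortest_path
#>     <int>   <int>       <dbl>                  <dbl>              <dbl>
#> 1      16      14        1.75                  0.146               2.57
#> # i 2 more variables: n_components <int>, largest_component_size <int>
```

Sixteen distinct responses, fourteen adjacency edges, two components. For a
clean dataset (perseverations removed at load), `estimate_uinvite()` fits
the censored-walk maximum-likelihood network the same way.

A command-line wrapper is included for batch use:

```sh
Rscript inst/cli/fluencynet.R stats --input data.csv --scheme scheme.csv \
  --measures n_responses,cluster_switches,perseverations \
  --output-csv measures.csv --output-json summary.json
```

The summary JSON records every parameter plus itemized spelling
corrections, perseverations and intrusions, so an analysis is reproducible
from the file alone.

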