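# prynt

Network-based prioritization of disease candidate proteins from
urinary proteomics.

A urinary proteome comparison between cases and controls yields a list
of deregulated proteins (DPs), but the urinary changes only partially
reflect what is deregulated in kidney tissue. `prynt` mines a directed
protein–protein interaction network (a STRING-style `protein.actions`
table) to rank every *other* protein by its closeness to the
deregulated set, surfacing disease actors that never appear in the
urine.

## The method

The pipeline has two halves:

**Contextualized network construction.** The raw network keeps
directional interactions at highest confidence (score ≥ 0.9), oriented
from the acting to the acted-on protein. Two contextualizations adapt
it to a study: **+DP** re-injects every interaction incident to a
deregulated protein regardless of confidence, and **+C** collapses
maximal cliques (protein complexes, detected on the undirected
projection) into disjoint super-nodes so a complex occupies one
ranking slot instead of many. The default **+DP+C** network combines
both; seed proteins are never absorbed into super-nodes.

**Rank-product prioritization.** Each non-seed candidate *x* gets

- a shortest-path score `SP(x) = 1 / Σ_y d(x, y)` over directed hop
  distances to the seeds *y*, and
- a random-walk-with-restart score, the steady state of
  `P(t+1) = (1 − r) A P(t) + r P0` with restart `r = 0.7`, the
  column-normalized out-edge adjacency `A`, and `P0` uniform on the
  seeds.

Candidates are ranked under each score and combined by the rank
product `CS = rank_sp × rank_rw`, ascending. Super-nodes are expanded
back to their best-ranked member protein. Rankings are evaluated
against reference disease-candidate lists (CTD-style exports) with
precision-at-k curves, trapezoidal AUC, and cross/overall specificity
against decoy diseases.

## Worked example

The package carries a synthetic-study generator (planted complexes,
planted candidate signal), so the whole pipeline runs without any
download:

```r
library(prynt)

study <- generate_study(synthetic_spec(rng_seed = 42))
net <- build_variant(study$interactions, "dp_c", dps = study$dps)
net
#> <collapsed_ppi_network/ppi_network> 114 node(s), 495 directed edge(s) (39 injected)

ranking <- prioritize(net, study$dps)
head(tidy(ranking), 5)
#> # A tibble: 5 × 10
#>    rank node  reachable_dps     sp rank_sp      rw rank_rw    cs in_clique
#>   <int> <chr>         <int>  <dbl>   <int>   <dbl>   <int> <dbl> <chr>
#> 1     1 P0007            10 0.0526       3 0.0209        1     3 <NA>
#> 2     2 P0037            10 0.0556       1 0.0111        5     5 clique_005
#> 3     3 P0024            10 0.05         5 0.0179        2    10 clique_003
#> 4     4 P0131            10 0.0556       1 0.00712      17    17 clique_002
#> 5     5 P0070            10 0.05         5 0.0109        6    30 <NA>

precision_curve(ranking, study$reference, k_max = 30)
#> <precision_curve vs 'synthetic'> K = 30, AUC = 18.147 (normalized 0.626)
```

Reading the ranking: every top candidate reaches all 10 seeds
(`reachable_dps`), `sp` and `rw` are the two closeness scores, and the
combined score `cs` is the exact product of the two ranks — P0007 is
3rd by shortest path but 1st by random walk, giving `cs = 3`. Rows
with an `in_clique` label are the best-ranked representative of a
collapsed complex. The precision curve says 18.147 (trapezoidal area
over k = 1..30, i.e. 0.626 of the maximum): far above the chance level
of 20 planted reference candidates among 140 possible candidates
(0.143), because 80% of the reference was wired close to the seeds.

`autoplot()` draws any precision curve or specificity report;
`tidy()`/`glance()` give broom-style tables. A thin command line lives
at `inst/cli/prynt.R` (`build`, `rank`, `evaluate`, `synth`, `run`),
and `run_pipeline()` chains everything with provenance metadata
(parameters, input checksums) beside each output.

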