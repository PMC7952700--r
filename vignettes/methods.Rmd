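---
title: "Network-based prioritization of disease candidates from urinary proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based prioritization of disease candidates from urinary proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prynt)
```

## The problem

Urinary proteomics yields, for a kidney disease cohort, a list of
proteins whose abundance differs between cases and controls — the
*deregulated proteins* (DPs). These urinary changes only partially
reflect what is deregulated in kidney tissue: not all renal proteins
reach the urine and not all urinary proteins originate from the kidney.
The question this package addresses is therefore indirect inference:
given the DP list and a directed protein–protein interaction (PPI)
network, which *other* proteins — candidates that were never seen in
the urine — sit so close to the deregulated set in the network that
they are likely disease actors?

`prynt` implements a complete pipeline for this: contextualized network
construction from a STRING-style `protein.actions` table, two
closeness-based scores combined by rank product, clique consolidation,
and an evaluation layer (precision-at-k, trapezoidal AUC, cross- and
overall specificity against reference disease-candidate lists such as
CTD exports).

## Network construction

The interaction table gives, per record, the two proteins, whether the
action is directional, which partner is acting, and a confidence score
(normalized internally to the 0–999 integer scale). The **raw**
network keeps directional records with confidence at or above
`min_score` (default 900, the conventional "highest confidence"
cutoff), oriented from the acting to the acted-on protein, with
self-loops and duplicate ordered pairs removed. The threshold
comparison is `>=`; users who prefer the strictly-greater reading pass
`min_score = 901`. Both readings are exposed because the two are
genuinely ambiguous in common usage and differ by exactly the records
scored 900.

Two contextualizations modify the raw network for a given study:

* **+DP** — every directional interaction incident to a DP is
  re-added regardless of confidence. The rationale: the DPs are
  experimentally observed, so their interactions are worth keeping
  even below the global confidence cutoff. Injected edges are flagged,
  and DPs with no interaction record at all are reported rather than
  silently dropped.
* **+C** — PPI networks at high confidence are massively structured
  into cliques (sets of proteins that all interact, typically protein
  complexes). Maximal cliques of the *undirected projection* (direction
  is ignored inside complexes) with at least `min_clique_size = 3`
  members are detected, reduced to disjoint groups, and each group is
  collapsed into one super-node. Collapse de-crowds the ranking: a
  complex occupies one slot instead of a dozen.

Maximal cliques overlap, but grouping needs each protein in at most
one clique. No assignment rule is canonical, so the package uses a
deterministic greedy rule: take cliques in decreasing size (ties broken
by lexicographically smallest membership), strip members already
claimed, and keep the remainder only if it still has
`min_clique_size` members. DP nodes are *never* absorbed into a
super-node — the seeds must remain addressable for the scoring
equations below, a corner the one-line description of clique grouping
in the source method leaves open. Likewise open is whether cliques are
detected before or after DP injection in the combined **+DP+C**
variant; the default here is after (injected edges may create
cliques), with `cliques_after_dp = FALSE` to flip.

## The prioritization model

Candidates are all network nodes except the DPs; DPs do participate as
intermediate hops and transit states but are excluded from the output
ranking. Two scores are computed per candidate $x$:

**Shortest path.** With $d(x, y)$ the directed hop count from $x$ to
seed $y$,

$$SP(x) = \frac{1}{\sum_y d(x, y)},$$

larger is better; a candidate adjacent to the single seed scores 1.
Seeds unreachable from $x$ make the sum ill-defined and the source
method is silent about them. The default policy (`"count-first"`) sums
over reachable seeds only and ranks primarily by the number of
reachable seeds, then by $SP$: "closer to more seeds is better"
without inventing a penalty constant. Alternatives are exposed
(`"penalty"`: unreachable seeds contribute distance $|V|$;
`"exclude"`: reachable-only sum, score-only ranking).

**Random walk with restart.** With $A$ the adjacency matrix
column-normalized over out-edges and $P_0$ uniform over the seeds,

$$P_{t+1} = (1 - r)\,A P_t + r P_0,$$

iterated from $P_0$ until the L1 change falls below `tol` (default
1e-10, capped at 10,000 iterations; non-convergence is an error
carrying the residual). The restart probability defaults to
$r = 0.7$. The steady-state visiting probability scores each node.
Note the deliberate asymmetry, kept exactly as specified by the source
method: $SP$ measures candidate → seed distances while the walker
travels seed → outward along edge direction.

Dangling nodes (out-degree 0) have an all-zero column in $A$: the mass
sitting on them leaks each step and $\sum_i P_i < 1$; the restart term
keeps re-injecting mass, so the iteration still converges (the fixed
point is the same linear solve $P = r(I - (1-r)A)^{-1}P_0$). A
`dangling = "teleport"` flag redistributes the leaked mass over $P_0$
instead. Probability conservation ($\sum P = 1$ within 1e-9) is
asserted in the tests only for dangling-free graphs.

**Combination.** Candidates are ranked from higher to lower $SP$
(rank$_{sp}$) and from higher to lower $RW$ (rank$_{rw}$); the
combined score is the rank product

$$CS = \mathrm{rank}_{sp} \times \mathrm{rank}_{rw},$$

and the final ranking orders candidates by ascending $CS$. Score ties
get competition ("1224") ranks; ties on $CS$ are broken by node
identifier so that identical inputs always produce byte-identical
output files.

**Clique expansion.** A ranking computed on a collapsed network places
super-nodes among the candidates. Each super-node is replaced by its
single best member — "best" judged by a second prioritization pass on
the uncollapsed network with the same seeds (the source method says
only "best ranking following prioritization"; the reference ranking it
means is unspecified, and the second pass is this package's reading,
recorded in the result metadata). Remaining members are dropped and
ranks renumbered.

A direct-neighbour baseline (`direct_scores()`: candidates ranked by
the number of seeds among their out-neighbours) and the conventional
experimental baseline (`pvalue_ranking()`: the DPs themselves sorted
by p-value) are included for comparison.

## Evaluation

Precision at $k$ is the fraction of the top-$k$ candidates present in
a reference disease-candidate list (CTD-style export, truncated to its
top 500 by inference score by convention). The curve runs over
$k = 1..K$ (default $K = 100$) and its area is computed by the
trapezoidal rule over $k$; since the source method never normalizes
the area and only relative comparisons are made, the raw area is
reported along with area$/(K-1)$ for readability. Cross-specificity is
the difference between the AUC against the matching disease's list and
against another disease's list; overall specificity is the competition
rank of the matching AUC among many decoy diseases' AUCs (ties share
the better rank).

## The synthetic-study generator

Real STRING + proteomics + CTD inputs are large, versioned, external
downloads, so the package carries a generator whose defaults define
its standard simulation conditions:

* 150 proteins; directed Erdős–Rényi background with edge probability
  0.02 (mean degree ≈ 3 in each direction, a sparse but mostly
  connected substrate);
* 4 planted cliques of 5–8 proteins each — fully mutually interacting
  complexes, every member reciprocally wired to 2 seeds, so complexes
  crowd the top of a naive ranking exactly the way consolidation is
  meant to counteract;
* 10 seed proteins (drawn outside the complexes) with synthetic
  p-values;
* 20 reference candidates, a fraction `planted_overlap_fraction`
  (default 0.8) wired 1–2 hops from the seeds, the rest uniform over
  the other non-seed proteins — so fraction 0 is an exact null whose
  expected precision is the chance level
  $n_{ref} / (n_{nodes} - n_{DP}) = 20/140$;
* 35% of seed-incident interactions pushed below confidence 900
  (`dp_lowscore_fraction`), emulating true interactions that raw
  filtering discards and only the +DP contextualization recovers.

Simulations evaluate precision at depth 30 for these 150-node studies
(roughly a fifth of the candidate pool, in the spirit of the
conventional top-100 of several thousand candidates; depth 100 would
cover nearly the whole pool and flatten every contrast). Benchmarks
in the test suite and the acceptance script use 100 independently
seeded studies.

What the generator does *not* emulate: scale-free degree
distributions, the size of real interactomes, biological correlation
between complex membership and disease annotation, and
identifier-mapping attrition. Passing the planted-signal benchmarks
therefore shows the algorithmic chain is correct and discriminating
under controlled structure — not that any particular precision level
will be attained on real cohorts.

## Numerical and design choices

* Confidence scores are held as integers 0–999; fractional input
  dialects are scaled by 1000 at parse time.
* Merged duplicate edges keep the maximum witness score (scores are
  unused downstream of filtering, so this is cosmetic).
* Convergence is declared on the L1 change of the probability vector;
  with $r = 0.7$ the iteration contracts by factor 0.3 per step and
  typically converges in ~20 iterations.
* All tie-breaks (clique ordering, rank ties, final ordering) are
  deterministic and lexicographic, making every pipeline output
  byte-reproducible.
* The identifier space is the interaction table's own (STRING protein
  IDs for real data); DP lists in gene symbols pass through a
  two-column alias table, and unmapped identifiers are reported, never
  dropped.

## Known limitations

* On the real STRING v10.5 file the published construction counts
  (353,643 edges / 6,391 proteins; 265 cliques / 3,569 proteins;
  21,051 edges / 3,109 nodes) depend on unstated details — the
  threshold reading, the minimum clique size, and a node arithmetic
  that does not internally reconcile (6391 − 3569 + 265 = 3087 ≠
  3109). `scripts/reproduce_string.R` sweeps these settings against
  the published figures and reports residual discrepancies instead of
  forcing agreement.
* The walk treats all surviving edges equally; confidence weighting
  beyond the threshold filter is out of scope.
* Hop distances ignore edge weights, as specified.
* Identifier mapping is a plain alias table; ambiguity resolution
  beyond first-match is the user's responsibility.
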