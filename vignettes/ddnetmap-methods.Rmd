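---
title: "ddnetmap: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ddnetmap: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddnetmap)
```

`ddnetmap` chains four analyses: questionnaire-based discounting-rate
estimation, seed-gene network propagation with a permutation-calibrated
proximity score, multiscale persistent-community hierarchy construction,
and hypergeometric trait enrichment. This vignette describes each model,
its assumptions and tunable parameters, the synthetic data the package
validates itself on, and the design decisions taken where more than one
reasonable convention exists.

## Discounting-rate estimation from the MCQ

A respondent choosing between an immediate amount $A_{imm}$ and a larger
delayed amount $A_{del}$ after $D$ days is assumed to discount
hyperbolically, $V = A/(1 + kD)$. Each item therefore has an *implied
indifference rate* $k^\ast = (A_{del}/A_{imm} - 1)/D$: a respondent with
$k < k^\ast$ should prefer the delayed option, one with $k > k^\ast$ the
immediate one. Scoring inverts this: the estimate $\hat k$ is the rate
whose predictions agree with the largest fraction of observed choices
(the *consistency*).

Decisions only change at the implied rates, so the candidate grid is the
set of geometric midpoints between consecutive sorted implied rates,
extended one step below the minimum and above the maximum
(`candidate_grid()`). Within each reward-magnitude bin the estimate is
the geometric mean of all maximally consistent candidates; the overall
$\hat k$ is the geometric mean of the per-bin estimates, and analyses
downstream use $\log_{10} \hat k$. Conventions adopted here, each of
which has live alternatives in the questionnaire literature:

* **Geometric (not arithmetic) averaging** across ties and bins: $k$ is
  a rate spanning three orders of magnitude, and all inference happens
  on the log scale.
* **Boundary ties count as consistent**: a choice at exact indifference
  is uninformative and should not penalize either direction.
* **Missing responses** leave the consistency denominator (no
  imputation), and profiles at the grid boundary (all-delayed /
  all-immediate) are flagged `floor_estimate` / `ceiling_estimate`.
* **QC defaults**: consistency ≥ 0.75, zero missing items, and a flag
  for all-identical response patterns. These are configurable
  (`qc_flags()`); they are conventional screening values, not
  universally agreed thresholds.

The default item bank (`mcq_item_bank()`) is a *synthetic* instrument:
nine implied-$k$ ranks from 1.6×10⁻⁴ to 0.25 per day in a geometric
ladder, crossed with three reward-magnitude bins. The same
(amount-ratio, delay) pairs are reused across bins, so the three bins
share an identical ladder — which makes noiseless on-grid choosers
exactly recoverable and keeps the recovery tests sharp. Any other bank
can be supplied as a CSV.

## Random-walk-with-restart propagation

The gene network is an undirected, weighted, simple graph. Its weighted
adjacency matrix is normalized column-wise into a transition matrix $W$
(each column divided by the node's weighted degree). Heat injected at
the seed set $Y_0$ (uniform mass $1/|S|$ per seed) diffuses with restart
parameter $\alpha$:

$$F = (I - \alpha W)^{-1}(1 - \alpha) Y_0 .$$

Because $W$ is column-stochastic, every term of the Neumann series
$(1-\alpha)\sum_m \alpha^m W^m Y_0$ has column sums preserved, so
$\sum F = \sum Y_0 = 1$ exactly — the "normalized adjacency" is read as
the random-walk normalization precisely because it conserves heat. The
package solves the linear system directly (sparse LU via `Matrix`) and
carries an independent fixed-point iteration
(`propagate_power_iteration()`) used as an oracle in the tests; the two
agree to below 1e-8 on randomized fixtures. $\alpha$ defaults to 0.5;
it is the fraction of heat that keeps diffusing per step, so small
$\alpha$ keeps heat at the seeds and $\alpha \to 1$ approaches the
walk's stationary distribution.

### Network Proximity Scores

Raw heat is dominated by degree, so each gene's observed heat is
compared with the heats it receives from 100 random seed sets matched
to the real seed set in size and degree distribution:

$$NPS_g = \frac{\log F_{g,S} - \langle \log F_{g,rand} \rangle}
               {\sigma(\log F_{g,rand})},$$

and genes with $NPS > 3$ (strict) form the proximal subnetwork. Choices
fixed here:

* **Log transform** uses the natural log; z-scores are base-invariant,
  the choice only affects reported intermediates.
* **$\sigma$ is the population standard deviation** (ddof = 0) over the
  null ensemble, read directly off the score's definition as the sd of
  that vector.
* **Degree matching** uses 10 equal-width bins in
  $\log_{10}(\text{degree}+1)$; bins with fewer than two members merge
  into the nearest occupied bin. Each null set replaces every seed with
  a uniform draw (without replacement within a set) from the seed's
  bin. Null sets may contain real seed genes — excluding them would
  bias the null degree distribution — but never reproduce the exact
  seed set.
* **Zero-heat genes** (unreachable from any seed placement) are
  excluded and flagged rather than floored with an epsilon, whose
  arbitrary magnitude would otherwise leak into the scores; genes with
  a degenerate (zero-spread) null are likewise flagged.
* **Seeds are scored too**; consumers can drop them downstream. The
  held-out calibration check (random matched sets scored against the
  ensemble pool to mean ≈ 0, sd ≈ 1) supports scoring all genes.

## Persistent-community hierarchy

The proximal subnetwork (selected genes plus seeds, induced edges) is
partitioned at each point of a resolution grid — by default ten steps up
to resolution 5, where higher resolution favours smaller communities.
The partitioner is seeded Leiden local moving on modularity (`igraph`);
the contract the package tests (modularity maximization on small
fixtures against exhaustive search, determinism under the seed,
disconnected components never sharing a block) is what is normative, not
the specific heuristic.

Blocks at consecutive resolutions are chained by greedy best Jaccard
match with threshold τ = 0.75 (ties to larger overlap, then smaller
block id); a chain alive for ≥ 5 consecutive steps becomes a community.
The community's gene set is taken at the chain's **first** (coarsest)
resolution — the scale at which the community emerges — and its
persistence is the chain length. Blocks smaller than 2 genes are never
chained: a singleton carries no modular structure, and admitting them
would pad the map with one-gene "communities".

Communities are organized by the containment index
$CI(v, w) = |v \cap w| / |v|$: an edge $w \to v$ (parent $w$) is added
when $CI(v, w) > 0.75$ **and** $|v| < |w|$. The strict size inequality
makes cycles impossible by construction; identical gene sets are merged
before edge building. Edges implied by longer directed paths are removed
(transitive reduction — idempotent and reachability-preserving, both
property-tested), and a synthetic root holding all mapped genes is added
when more than one top-level community remains. The similarity-network
preprocessing some community-detection tools apply before clustering is
deliberately *not* performed: the induced subnetwork is clustered
directly, avoiding an undocumented metric choice.

## Trait enrichment

Each (community, trait) pair is tested by the upper-tail hypergeometric
law, $P(X \ge a)$ for an overlap of $a$ — over-representation only, as
depletion is not of interest here. Odds ratios come from the 2×2 table
with a Haldane–Anscombe 0.5 added to every cell when any cell is zero,
keeping heatmap values finite. Benjamini–Hochberg correction is applied
across the full community × trait family in one pass, and
`significant` means $q < 0.05$.

The **universe** defaults to all genes of the loaded network (the space
the propagation ran over); restricting to mapped genes only
(`universe = "selected"`) is exposed as an option and recorded in the
manifest. The network universe is the more conservative choice for the
odds ratios — the same machinery also annotates communities with their
top term from an annotation GMT (`annotate_communities()`), ties broken
by overlap then name.

## What the synthetic data does and does not show

The generators produce: planted-partition (stochastic block model)
networks with uniform edge weights and optional per-block or block-pair
densities; seed and trait gene-sets placed into chosen blocks with a
ceiling rule on the requested fraction; and questionnaire profiles from
a known $\log_{10} k$ through a logistic choice rule (temperature 0 =
deterministic argmax, ties to "delayed" so noiseless output is
reproducible).

The packaged preset (`simulate_preset()`) fixes the study conditions the
acceptance checks run under: a 2000-gene network of 80 blocks
($p_{within} = 0.3$, $p_{between} = 0.002$), 16 seeds split 10/6 across
the first two blocks, six 30-gene trait sets with graded block overlap
(one a negative control), 40 respondents at noise temperature 1. The
network size matters scientifically: a gene's null heat distribution is
a mixture over whether a random seed lands near it, and only when the
seeded blocks are a small fraction of the network is that event rare
enough for z-scores to clear 3. At a few hundred genes the same code
ranks the planted block essentially perfectly (AUROC > 0.95) while few
genes pass the fixed threshold — the threshold's stringency is a
property of scale, not of the ranking.

Real functional networks differ from these conditions in ways the tests
cannot speak to: heavy-tailed degree distributions, weight distributions
encoding evidence quality, overlapping and nested pathway structure, and
seed lists contaminated by mapping artifacts. Passing the synthetic
checks shows the machinery is correct under its own assumptions, not
that the biological conclusions of any particular application are
robust.

## Numerical choices and degenerate inputs

* Direct solves are exact to solver precision; the fixed-point oracle
  iterates to max-norm 1e-12 and is guaranteed to converge for
  $\alpha < 1$.
* Heat conservation and the propagation fixtures are asserted to 1e-10;
  oracle agreement to 1e-8.
* Duplicate undirected edges keep the maximum weight (deterministic and
  order-independent); self-loops are dropped and counted; isolated
  nodes cannot exist (a gene exists only by incidence).
* Empty seed sets, empty universes, all-missing profiles, cyclic edge
  lists, and infeasible overlap requests raise classed errors
  (`ddnetmap_parameter_error`, `ddnetmap_format_error`) naming the
  offending input; stage failures in `run_all()` halt with the stage
  name.
* All randomness in a pipeline run derives from the single `rng_seed`
  by fixed integer offsets (kept inside 32-bit range); re-running a
  config reproduces byte-identical stage tables.

## Problem sizes in the test suite

The suite exercises: 50 random graphs (≤ 30 nodes, α ∈ {0.1, 0.5,
0.9}) for oracle equivalence; a 200-gene, 4-block network with 10 seeds
and 100 nulls for calibration and recovery; 500 noiseless simulated
respondents for rate recovery; exhaustive hypergeometric enumeration up
to a 12-gene universe; 1000 uniform-null replicates for FDR control;
and two full preset runs for byte-level determinism. These sizes were
chosen so each check is sensitive to the failure mode it targets while
the whole suite stays interactive.

## Known limitations

* One propagation variant (column-stochastic RWR) — symmetric-Laplacian
  and row-stochastic kernels are documented alternatives, not options.
* Persistence bookkeeping is greedy consecutive-resolution matching; a
  community that disappears at one grid point and reappears later
  starts a new chain.
* Gene identifiers are opaque case-sensitive strings; no symbol/ID
  mapping is attempted.
* The enrichment is set-based only; competitive gene-score enrichment
  is out of scope.
* The MCQ module fits a single hyperbolic functional; exponential,
  quasi-hyperbolic, and area-under-curve summaries are out of scope.
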