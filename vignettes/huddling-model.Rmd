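---
title: "The huddling model: rules, experiment design and statistical pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The huddling model: rules, experiment design and statistical pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarudango)
```

## The model

Japanese macaques huddle in cold weather, and the size of those huddles
("sarudango") varies enormously between sites — from pairs and triplets at
most locations to clusters of over a hundred animals on Shodoshima Island.
This package implements an individual-based model that asks how much of
that variation can emerge from two probabilistic local rules, without any
individual heterogeneity.

`group_size` identical agents live on a 16 x 16 toroidal grid of patches.
Agents are either *lone* (random-walking, one patch per tick, heading
resampled uniformly every tick) or *huddled* (stationary members of a
cluster). Lone agents sense conspecifics within a radius of 2 patches
(toroidal Euclidean distance). Each tick, every agent — processed once, in
a freshly shuffled order — takes one probabilistic decision:

* a lone agent that senses a candidate joins it with probability
  $$P_{join} = \frac{N_{ci}}{N_{cmax}}\cdot\frac{1}{T}\cdot\frac{1}{J},$$
  where $N_{ci}$ is the candidate's current size, $N_{cmax}$ the group
  size, $T \in \{1,\dots,10\}$ the temperature and $J \ge 1$ the joining
  threshold (higher = more selective);
* a huddled agent leaves its cluster of size $N_{ci}$ with probability
  $$P_{leave} = \frac{N_{cmax}-N_{ci}}{N_{cmax}}\cdot\frac{1}{L},$$
  where $L \ge 10$ is the leaving threshold (higher = more committed).

Large clusters are therefore more attractive and more retentive; the
full-group huddle is absorbing ($P_{leave} = 0$). A run ends when every
agent is huddled (`all_joined`) or after 20,000 ticks (`step_cap`).

## Design choices in the grey zones

The two formulas do not determine a complete simulator; the following
choices close the gaps. They are deliberate package decisions, fixed once:

* **Temperature domain.** $T = 0$ is rejected: the join rule divides by
  $T$, and the sweep design uses temperatures 1–10.
* **Nucleation.** Nothing says how the first huddle forms. Here a lone
  agent within sensing range is a size-1 candidate: a successful join on
  it creates a fresh 2-member cluster, anchored at the joiner's position.
  This lets $P_{join}$ with $N_{ci} = 1$ govern nucleation, and makes
  cluster formation harder in larger groups (the $1/N_{cmax}$ factor),
  matching the qualitative role of group size elsewhere in the model.
* **Candidate choice.** When several clusters or lone agents are in range,
  the candidate is the largest cluster represented (ties to the lowest
  cluster id), or the lowest-id lone agent when no cluster is in range.
  One candidate per tick keeps exactly one decision draw per agent.
* **Decision draws.** Every agent consumes exactly one decision draw per
  tick (plus the lone agent's heading draw), whether or not a candidate is
  in range. This makes the random stream a function of the tick structure
  only, which is what makes the two engines (below) comparable.
* **Cluster geometry.** Members are placed at equal angular spacing on a
  circle of radius `min(1, sensing_radius/2)` around the cluster anchor,
  re-spaced deterministically (members in ascending id order) after every
  membership change.
* **Dissolution.** A cluster reduced to one member dissolves and releases
  that member: a huddle of one is not a huddle. Recorded cluster sizes are
  therefore always at least 2.
* **Leavers** keep their position and resume the walk next tick; there is
  no repulsion step. Clusters never merge wholesale; membership changes
  one agent at a time.
* **Update order.** One shuffled pass per tick, each agent acting on the
  world as it currently stands mid-pass. A two-phase (simultaneous)
  update would be an alternative; the single pass matches the idiom of
  agent-based platforms and avoids conflict-resolution bookkeeping. The
  choice shifts the no-cluster fraction only marginally.

## Two engines, one trajectory

The per-tick semantics are defined by an exported, readable R stepper
(`init_world()`, `tick_world()`, `attempt_join()`, ...). Production runs
use a compiled engine (`run_simulation()`, Rcpp) that replays the same
rules on the same random stream: given equal seeds the two produce
bit-identical trajectories, which the test suite asserts directly. The
compiled engine adds two pure optimisations that cannot change results:
spatial binning for the neighbourhood scan (cell width at least the
sensing radius, 3 x 3 scan), and skipping the candidate search when the
decision draw already exceeds the join probability of the largest active
cluster (an upper bound on any candidate's join probability). Both engines
share one compiled `cos`/`sin` kernel, because trigonometric functions
from different compilation units may differ in the last bit, which would
break trajectory equality over long runs.

Every run's seed is `base_seed + ordinal` in its sweep, bound to the run
specification, so sweep tables are identical whatever the worker count,
and any single run can be replayed in isolation.

## The sweep experiment

`default_grid(N)` reproduces the published experiment design: temperatures
1–10, joining thresholds 1–8, 100 replicates, and leaving thresholds 10,
20, ..., 70 for a group of 70 (56,000 runs), or 10, 50, 90, ... truncated
at `min(N, 170)` for the other group sizes. Two published statements about
the design conflict (a joining-threshold range "to 10" versus totals that
require 1–8; a per-size run total that implies five leaving thresholds for
every size versus a rule that gives fewer for groups of 100–160). The
grids here follow the arithmetic that reproduces the 56,000-run total
exactly and remain fully overridable.

## The statistical stage

Both outcome variables are counts per run: the number of clusters at
termination (zero allowed) and the individuals per cluster (the mean of
that run's cluster sizes, rounded half-to-even to an integer; runs with no
cluster carry no such value and are dropped from this response). The
package fits negative-binomial GLMs with a log link (`MASS::glm.nb`),
reports per-term Wald statistics, theta with its standard error,
deviances, AIC and BIC; a Poisson family is available as a cross-check and
the test suite verifies the negative binomial converges to it when the
data are equidispersed. Collinearity is screened with variance inflation
factors computed from main-effects least-squares regressions; interactions
are off by default (they are collinear with the main effects on this
factorial design) but available behind a flag. Stepwise backward-forward
selection over the main effects (`MASS::stepAIC`, AIC or BIC) records a
trace of accepted steps. Group sizes 300 and 400 are excluded from the
regression stage by default: they produce clusters beyond the largest
huddle ever observed in the field (137), and the over-137 proportion per
group size is the package's screening diagnostic for that.

## Comparison with the empirical site lines

Four field sites provide cluster-size-versus-temperature lines built from
their values at the ends of the temperature scale (temperatures 1 and 10):
Arashiyama (3 down to 0 individuals per cluster), Katsuyama (constant
2.2), Takasakiyama (4.8 down to 2.8) and Shodoshima (30 down to 20). The
slope follows from the two anchors and the intercept from
$y = ax + b$ at the low anchor. Note one printed-source quirk: the
Takasakiyama line is sometimes quoted with intercept 4.8, which is its
value *at temperature 1*, not at 0; the anchors are authoritative here, so
the computed intercept is 5.02 while the slope matches the quoted -0.22.

For every (group size, joining threshold) combination the package fits an
ordinary least-squares line of per-run mean cluster size on temperature
(pooling leaving thresholds and replicates, excluding no-cluster runs),
then ranks all combinations against each site by the absolute differences
in intercept and in slope — two separate ascending rankings, averaged
(ties get average ranks; averaging the two rankings is what makes
non-integer mean ranks such as 1.5 possible). The best-ranked combination
is the model's closest match to that site.

## What the simulated data do and do not show

All inputs are generated by the simulator itself; there is no field data
in the package. The sweep emulates the published experiment's *design*
(its grids, replication and outputs), not the field system: agents are
homogeneous, space is featureless, and kinship, dominance and social
preference — all documented drivers of real huddling — are deliberately
absent. Passing tests therefore show that the rules are implemented
faithfully and reproducibly, not that the rules suffice to reproduce
field-scale huddling.

Under these rules as specified, sustained cluster growth requires the
product $T \times J$ to be small: a small cluster's per-member leave
hazard (up to $1/L$ per tick) outweighs its join inflow (at most
$N_{ci}/(N_{cmax} T J)$ per nearby lone agent per tick) except near the
cold, non-selective corner of the grid. Consequently most runs away from
that corner reach the 20,000-tick cap, a large share of runs end with no
cluster at the snapshot (tens of percent, versus the few percent reported
for the original experiment), and the regression stage recovers the
joining threshold's negative effect on cluster count but not every
published sign or magnitude. The package reports these quantities as
computed; the acceptance checks that depend on matching the original
system's scale are expected to flag the difference rather than hide it.
This sensitivity of aggregate outcomes to dissolution details is itself a
finding about the model family: the two printed formulas do not pin down
the published behaviour without additional, unstated stabilising
mechanics.

## Problem sizes and numerical notes

The packaged analyses scale the experiment down, keeping the full
factorial grids but fewer replicates: the bundled acceptance script uses 2
replicates per combination for group sizes 70–160 (2,880 runs),
plus single-replicate sweeps at thinned temperatures for the 300- and
400-agent screening diagnostic; the test suite uses 1–2 replicates. At
these sizes the no-cluster fraction carries a standard error well under
one percentage point and the GLM coefficient signs are stable across
seeds. Tolerances elsewhere are exact or near machine precision: the
probability formulas, grid arithmetic, line reconstruction and rank
arithmetic are deterministic, and seed-for-seed reproducibility is
asserted bitwise. Degenerate inputs are defined, not special-cased: a
zero step cap terminates with zero clusters; an empty pooled cluster list
yields proportion 0 with a warning; exactly collinear predictors report an
unbounded VIF rather than a number.
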