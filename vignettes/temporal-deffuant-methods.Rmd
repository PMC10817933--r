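---
title: "Bounded-confidence opinion dynamics on bursty temporal networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-confidence opinion dynamics on bursty temporal networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempdeffuant)
```

## The model

`tempdeffuant` simulates the Deffuant bounded-confidence opinion model in
which pairwise exchanges are gated not only by opinion similarity but also by
the *timing* of social contacts. A population of $N$ individuals carries
opinions $x_i \in [0,1]$, initially i.i.d. Uniform(0,1). Individuals are
embedded in a static social network; each social tie $(i,j)$ carries its own
renewal clock, and an opinion exchange can only be attempted when that tie
*activates*. An activation at time $t$ succeeds if

$$|x_i(t) - x_j(t)| < d$$

(strict inequality), in which case both individuals move symmetrically
towards each other:

$$x_i \leftarrow x_i + \mu\,(x_j - x_i), \qquad
  x_j \leftarrow x_j + \mu\,(x_i - x_j),$$

using the pre-update values on both lines. The confidence level $d \in (0,1]$
is the tolerance for dissimilar opinions; the influence parameter
$\mu \in [0,1]$ is the fraction of the gap closed per exchange. The update
conserves $x_i + x_j$ exactly and contracts the pair difference by the factor
$|1-2\mu|$; at the default $\mu = 0.5$ a successful pair collapses onto its
midpoint. $\mu$ affects the speed but not the attractor structure of the
dynamics, which is why it is fixed at 0.5 in the standard experiment design.

A *successful* exchange is defined as one that changes at least one opinion
at floating-point precision. This matters for termination: a fully converged
pair passes the $|x_i-x_j|<d$ gate forever, but its updates are no-ops. Under
the literal "gate passed" definition a consensus population would never be
recognised as stationary; under the definition used here, stationarity means
"no more updates are possible", covering both converged pairs and pairs
separated beyond $d$.

## Activation: renewal clocks and burstiness

Each tie activates according to a renewal process: after firing at $t$ it is
re-armed at $t + \Delta t$ with $\Delta t$ drawn independently from the
inter-event distribution. Two families are provided:

* **Exponential**, $P(\Delta t) = b\,e^{-b\Delta t}$, mean $1/b$ — the
  memoryless baseline. Driving the Deffuant dynamics with exponential clocks
  is statistically equivalent to the classical discrete-time model that
  activates one uniformly random edge per step
  (`run_static_baseline()`), and the package tests this equivalence.
* **Log-normal**, $\ln \Delta t \sim \mathcal N(\nu, \sigma^2)$, mean
  $e^{\nu+\sigma^2/2}$. The scale $\sigma$ interpolates from near-regular
  ticking ($\sigma \ll 1$, approaching a point mass at $e^\nu$) to heavy
  burstiness ($\sigma \gg 1$, nearly linear log-density like a power law):
  trains of rapid activations separated by very long silences.

Initial activation times are drawn from a normal distribution truncated to
positive values; the defaults (`init_mean` = the model's mean waiting time,
`init_sd = init_mean/4`) give a scale-matched start whose details are washed
out by the burn-in whenever a stationary regime exists. The burn-in default
used by the experiment runner is $10\,|E|$ discarded events, about ten
renewals per tie.

Events are delivered in global chronological order; simultaneous activations
are resolved deterministically by link id. Every tie owns an independent RNG
sub-stream derived by stable hashing of (master seed, link id), so a master
seed reproduces the identical event sequence bit for bit regardless of how
the queue is consumed, and replicates can be executed in any order.

### The heavy-tail regime and the horizon

For large $\sigma$ the log-normal becomes so heavy-tailed that its moments
are useless: at $\sigma = 20$, $\nu = 0$ the mean is $e^{200} \approx
7\times10^{86}$ and the second moment $e^{800}$ is not even representable in
double precision. The package flags such models with an overflow marker
(criterion: the second moment exceeds the double range) rather than
reporting an astronomically meaningless number.

Simulating this regime requires a finite **horizon** $T_{\max}$ (default
$10^6$ time units), with two explicit semantics on `build_schedule()`:

* `cap_mode = "truncate"` (default): waiting times are drawn from the law
  conditioned on $\Delta t \le T_{\max}$, by exact inverse-CDF sampling.
  Every tie remains a proper renewal clock with the finite truncated mean
  $e^{\nu+\sigma^2/2}\,\Phi\!\big(\tfrac{\ln T_{\max}-\nu-\sigma^2}{\sigma}\big)
  \big/ \Phi\!\big(\tfrac{\ln T_{\max}-\nu}{\sigma}\big)$
  (`interevent_mean(..., horizon, conditional = TRUE)`). At $\sigma = 20$,
  $T_{\max} = 10^6$ this is $\approx 2.1 \times 10^4$, and the corresponding
  lower partial moment is $\approx 1.9\times10^4$ — the scale at which the
  capped process actually operates.
* `cap_mode = "dormant"`: waiting times follow the unmodified law and a tie
  whose next activation falls beyond $T_{\max}$ is silenced forever. The
  stream is then finite: at $\sigma=20$ each tie delivers on average only
  $1/P(\Delta t > T_{\max}) \approx 4$ events in total, which starves the
  opinion dynamics (no group ever reaches the cluster-detection resolution).
  This mode is retained because it is the natural model of "ties that fall
  silent", but it is not the default.

The same $T_{\max}$ doubles as the **simulation horizon** of a run
(`max_time` of `run_temporal()`, applied by the experiment runner): no
activation later than $T_{\max}$ after the dynamics attach is processed, and
a run terminated this way is flagged `"horizon"`, distinctly from
window-rule convergence. Light-tailed configurations (exponential;
log-normal with $\sigma \lesssim 3$ at these scales) stabilise one to two
orders of magnitude before the horizon and never feel it; the heavy-tail
regime is terminated by it, frozen in a multi-cluster state. This is the
mechanism by which burstiness raises the number of surviving opinion
clusters: rapid bursts create local consensus early, while the long
silences starve the slow cluster-merging process of the activations it
would need before the horizon.

In the overflow regime the runner discards **no** burn-in: the truncated
stream's relaxation time is of the order of the horizon itself (only
$\sim 47$ renewals per tie fit into it), so there is no stationary regime a
transient could reach, and discarding $10\,|E|$ events would consume a fifth
of the entire simulation.

### Stopping rule

A run is declared stationary when a quiet window passes without a single
successful exchange. The window is `stop_window` = $N$ *consecutive
activations* by default (`stop_unit = "events"`), mirroring the
discrete-time reading in which one activation is one time step; a duration
window in continuous time units (`stop_unit = "time"`) is also provided
because the phrasing of stabilisation in terms of $\Delta t = N$ admits
either reading. For every quantity examined in this package's acceptance
checks the two conventions agree; the event window is far cheaper for slow
(bursty) clocks and is therefore the default. The stabilisation time
$T_f$ is reported as the continuous time of the last successful exchange,
with `events_to_stable` alongside so either convention can be compared.
`max_events` (default $10^8$) is a hard safety cap, reported distinctly.

## Social substrates

Three generators cover the spectrum from homogeneous to socially clustered:

* `generate_er(n, mean_degree)` — Erdős–Rényi, each pair linked with
  $p = \langle k\rangle/(n-1)$; the homogeneous reference.
* `generate_ws(n, k_nn, q)` — Watts–Strogatz: ring lattice over the $k_{nn}$
  nearest neighbours, each edge rewired with probability $q$ by redrawing
  its far endpoint. At $q=0$ the local clustering is the lattice closed form
  $3(k_{nn}-2)/(4(k_{nn}-1))$ (0.6 at $k_{nn}=6$); clustering decays as
  $\approx 0.6(1-q)^3$, so $q \approx 0.33$ reproduces $\langle cc \rangle
  \approx 0.177$, the value comparable to the strongly homophilous fitness
  networks. $q$ is a free parameter; no particular value is asserted.
* `generate_fitness(n, m, beta)` — growing attribute-fitness preferential
  attachment: each new node $J$ (trait $\theta_J \sim U(0,1)$) attaches to
  $m$ distinct existing nodes with probability $\propto k_i\,
  e^{-\beta|\theta_J-\theta_i|}$. $\beta = 0$ is pure preferential
  attachment (Barabási–Albert, $P(k) \propto k^{-3}$); increasing $\beta$
  trades hub formation for attribute homophily, raising triangles and
  community structure while leaving $\langle k \rangle = 2(m(m-1)/2 +
  m(n-m))/n$ fixed (5.988 at $n=1000$, $m=3$). Growth starts from a complete
  graph on the first $m$ nodes; targets are sampled without replacement with
  weights renormalised after each draw, which guarantees a simple graph.
  The degenerate all-zero-weight case (possible only at $m=1$) falls back to
  uniform attachment.

`rewire_to_configuration()` provides the degree-preserving null model:
repeated double-edge swaps $(a,b),(c,d) \to (a,d),(c,b)$ with random edge
orientation, rejecting proposals that would create self-loops or duplicate
ties, until `n_swaps` (default $10|E|$, a standard mixing heuristic)
proposals have been *accepted*. A proposal cap guards rigid graphs such as
the triangle, where no valid swap exists.

`compute_stats()` reports mean degree (exactly $2|E|/N$), mean local
clustering ($cc_i = 2e_i/(k_i(k_i-1))$ with $cc_i := 0$ for $k_i < 2$),
mean shortest-path betweenness (normalised by $(N-1)(N-2)/2$, endpoints
excluded), modularity of the partition found by Louvain-style greedy
modularity maximisation at resolution 1 (`community_method` selects the
algorithm; modularity values are method-dependent and reported as such),
degree assortativity (Pearson over edge endpoints, both orientations; `NA`
for regular graphs where it is undefined), and the degree distribution.
These standard statistics are computed by igraph.

## Opinion clusters

After stabilisation, opinions are sorted and split wherever a consecutive
gap is at least $\varepsilon = 10^{-4}$; in one dimension this equals
single-linkage clustering at threshold $\varepsilon$ (the package tests the
equivalence exhaustively against a brute-force union–find oracle). A group
counts as an opinion cluster only if it holds at least 1% of the population
(inclusive: size $\ge \lceil 0.01\,N\rceil$, the literal reading of "at
least 1%"); smaller groups — typically poorly connected individuals stuck
near their initial opinion — are reported as unclustered. A cluster's
position is the arithmetic mean of its members' opinions; since members
differ by less than $\varepsilon$ per sorted step, any representative is
equivalent at reporting precision. `cluster_profile()` relates relative
cluster size $\Omega = S_f/N$ to the offset $\Delta x = x_{\mathrm{cluster}}
- 0.5$ from the moderate opinion, with configurable binning (default 0.05)
for cross-run aggregation.

Note that the 1% rule needs $N$ large enough to bite: at $N = 100$ the
minimum size is 1 and every straggler counts as a cluster. The package's
own tests use $N \ge 200$.

## Experiment design

`run_sweep()` reproduces the replicated design: per cell (network spec ×
inter-event model × $d$), `n_networks` independent network samples
(default 15) × `n_runs` simulations with fresh opinion and activation seeds
(default 20), i.e. 300 replicates per cell at full scale. Standard errors
are pooled over all replicates (sample sd / $\sqrt m$). Network samples are
shared across cells of the same network spec, enabling paired comparisons
across $d$ and activation patterns; all seeds derive from the master seed by
stable hashing, so any single replicate can be reproduced in isolation and
execution order is irrelevant. Cells are checkpointed to CSV when a
checkpoint directory is given, making long sweeps resumable.

When comparing bursty activity against the memoryless baseline, the
exponential comparator is matched by mean: $b = 1/\langle\Delta t\rangle$
analytically for usable means, and $b = 1$/(conditional truncated mean
under $T_{\max}$) in the overflow regime — the only finite mean the capped
process has.

## Numerical choices

* Opinions are doubles; updates are convex combinations, so $[0,1]$ is
  invariant. The population sum drifts only by accumulated rounding
  ($<10^{-6}$ over $10^6$ events, asserted in tests).
* Equality of opinions (the no-op test for "successful") is exact
  floating-point equality; at $\mu=0.5$ merged pairs are bitwise equal, so
  quiescence detection is robust.
* Per-link RNG sub-streams are splitmix64 generators whose initial states
  are scattered by a double output-scramble of the hashed (seed, link id);
  waiting times use inverse-CDF sampling (so truncation changes only the
  uniform's range, not the stream alignment).
* The priority queue orders by (time, link id); re-arming happens at pop
  time, so each link has at most one pending event.
* Heavy sweeps cap replicates at `max_events` $= 2\times10^7$ events in the
  acceptance configurations; at that point the bursty $\sigma=2.7$ cells
  have long passed their last structural change and only rare straggler
  absorptions remain, so cluster counts are unaffected.

## What the generators emulate — and what they do not

The synthetic substrates and clocks capture: characteristic-degree random
mixing (ER), local social redundancy with short paths (WS), degree
heterogeneity with tunable attribute homophily (fitness), and the spectrum
from regular through Poissonian to bursty tie activation (log-normal
$\sigma$). They do **not** capture: circadian or weekly rhythms, correlated
(non-renewal) clocks, degree–activity correlations, co-evolution of ties
with opinions, directed or weighted ties, or group (one-to-many)
interactions. Passing tests therefore demonstrate correctness of the
mechanisms under these idealised conditions, not predictive validity for
any empirical communication dataset.

## Known limitations

* In the heavy-tail regime the final cluster count is sensitive to the
  horizon and to the unobservable details of the capped sampling law; the
  package fixes one explicit, documented convention (truncated law,
  $T_{\max} = 10^6$, no burn-in) rather than pretending the quantity is
  convention-free. Sensitivity to these choices is real and should be
  reported alongside any heavy-tail result.
* The stopping window can close while rare straggler-absorption events are
  still pending; stabilisation times are therefore defined by the window
  convention, not by literal global fixation (which for stragglers can take
  arbitrarily long).
* Modularity values depend on the community-detection method; only
  method-stated comparisons are meaningful.

## Problem sizes used by the test-suite

The package's tests run the full pipeline at $N = 1000$, $\langle k\rangle
= 20$ for the headline checks and at $N = 500$ (5 networks × 6 runs) for
the directional sweeps; these reduced replicate counts were chosen as the
smallest designs whose standard errors still separate the effects being
asserted.
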