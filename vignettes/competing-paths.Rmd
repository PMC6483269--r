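---
title: "Competing evolutionary paths: model, approximations and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing evolutionary paths: model, approximations and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evopaths)
```

## The model

A growing cell population lives on a finite simple directed graph.  Each
vertex is a cell state — a genotype, a spatial compartment, or a
combination — and each cell behaves independently: at vertex $x$ it
divides at rate $\alpha(x)$, dies at rate $\beta(x)$, and at rate
$\nu(x,y)$ divides while placing one daughter at vertex $y$, for every
edge $(x,y)$.  The growth rate of state $x$ is
$\lambda(x) = \alpha(x) - \beta(x)$.  The process starts with $z$ cells at
a designated *root* and we watch for the first cell at a designated
*target* (a sink).  Two questions drive the package: *when* does the
target population arise (the hitting time $T$), and *along which sequence
of states* (the seeding path)?

Standing assumptions, checked by `validate_graph()`:

* the root is a source, the target a sink, and the target is reachable;
* the root's growth rate $\lambda = \alpha - \beta$ is positive;
* every intermediate state is strictly less fit than the root,
  $\lambda(x) < \lambda$.

The last two are *model assumptions*, not structural requirements: the
simulator is exact without them, but the closed forms below are proved in
the regime where the root out-grows every intermediate and all transition
rates — mutation rates of $10^{-10}$–$10^{-5}$ per unit time, migration
or dissemination rates of similar magnitude — are small.  Violations are
therefore reported as warnings, structural defects as errors.

Transitions here occur *at division*, $(x) \to (x),(y)$, leaving the
parent in place.  The alternative convention $(x) \to (y)$ produces very
similar hitting times for small rates; only the division-coupled form is
implemented.

## Path weights

Everything is controlled by the weight of a root-to-target sequence
$p = (p_1, \dots, p_{l+1})$:

$$w(p) \;=\; \nu(p_1,p_2)\prod_{i=2}^{l}
   \frac{\nu(p_i,p_{i+1})}{\lambda - \lambda(p_i)},$$

the product of its transition rates divided by the fitness costs of its
internal states (empty product $=1$).  The total target weight is
$\phi_N = \sum_p w(p)$ over all simple root-to-target paths, and for any
non-target vertex the ratio $\Phi_x = \phi_x/(\lambda - \lambda(x))$
(with $\Phi_{\text{root}} = 1$) gives the asymptotic population
composition: almost surely
$e^{-\lambda t} Z_x(t) \to W\,\Phi_x$, where $W$ is a binomial–Erlang
mixture — the sum of $K \sim \mathrm{Binomial}(z, \lambda/\alpha)$
independent $\mathrm{Exponential}(\lambda/\alpha)$ variables — with mean
exactly $z$ and an atom $P(W=0) = (\beta/\alpha)^z$ at zero, the
probability the whole population dies out.  `sample_W()` draws from this
law; `estimate_scaled_sizes()` recovers $W$ and $\Phi_x$ from simulation.

Weights are computed and summed in log space throughout
(`log_sum_exp`), because application rates span $10^{-8}$ to $10^{-1}$
and linear products underflow long before their logs become inaccurate.

## Hitting time

For small target-seeding rates,

$$P(T > t) \;\approx\;
  \left(\frac{\lambda/\alpha}{1 + e^{\lambda t}\phi_N\alpha/\lambda^2}
        + \frac{\beta}{\alpha}\right)^{z},$$

which is the limiting centred law evaluated at $t - \mu$ with
$\mu = \tfrac1\lambda\log\!\big(\lambda^2/(\alpha\phi_N)\big)$ (the two
forms agree to machine precision; the identity is property-tested over
random parameter sets).  The $\beta/\alpha$ term is the footprint of
founding lineages that die out: letting $t \to \infty$,
$P(T < \infty) \approx 1 - (\beta/\alpha)^z$.

**Conditioning.**  Practitioners usually care about the law *given* the
target is reached.  With $s_1(t)$ the single-cell survival value, the $z$
founding lineages are independent, so the conditional survival is
$\big(s_1(t)^z - (\beta/\alpha)^z\big)/\big(1-(\beta/\alpha)^z\big)$.
For $z=1$ this collapses to the logistic
$1/(1+e^{\lambda(t-\mu)})$ — hence $\mu$ is the conditional median for a
single founder — and the density follows by differentiation.  This
construction is our own for $z > 1$ (an exact conditional form exists but
only the lineage-independence route is implemented here); it is validated
against simulation rather than against a printed formula.

**Median.**  `median_hitting_time()` returns $\mu$ for $z = 1$ and the
large-$z$ form $t_{1/2} \approx \tfrac1\lambda\log\!\big(\lambda/(z\phi_N)\big)$
otherwise, reporting which regime was used.  For moderate $z$ (say 2–20)
the large-$z$ shift $h(z) \sim \tfrac1\lambda\log(z\lambda/\alpha)$ is a
documented approximation — the exact shift interpolates between the two
regimes and is not implemented — so medians for small multi-cell starts
carry $O(1/\lambda)$ error.

## Which path wins

Conditional on the root population surviving, the probability that the
target is first seeded along $p$ is the normalised weight $w(p)/\phi_N$;
the probability of arriving along $p$ more than $t$ time units before any
competing path is

$$\frac{w(p)}{w(p) + e^{\lambda t}\sum_{q\neq p} w(q)},$$

a logistic decay in $t$ at rate $\lambda$ that reduces to the path
probability at $t=0$ (an exact identity in the implementation, also
property-tested).  Sets of paths are handled by summing normalised
weights.  This is how the package answers questions like "is resistance
more likely to cross a fitness valley than to take a direct mutational
route?" — the valley is preferred whenever its cost product stays below
the direct path's rate deficit.

## Cyclic graphs and walks

With back-transitions the graph acquires cycles.  The package keeps the
requirement that the root is a source and the target a sink, and:

* `rate_matrix_and_eigencheck()` builds the growth-and-transition matrix
  $A$ over non-target vertices ($a_{ii} = \lambda(i)$,
  $a_{ij} = \nu(j,i)$) and checks the condition under which the
  hitting-time results carry over: the largest real eigenvalue equals
  $\lambda$ and is simple.  For DAGs this always holds ($A$ is
  triangular in topological order); for cyclic graphs it holds when the
  cycle rates are small.  Tolerances: $|\lambda^* - \lambda| \le
  10^{-9}\max(1,|\lambda|)$ and eigenvalue gap $> 10^{-9}$, both
  configurable, since the exact condition must be judged in floating
  point.
* `enumerate_walks()` enumerates bounded-length walks (consecutive
  repeats are impossible as the graph has no self-loops), and
  `weight_table()` accepts a walk set, weighting each walk with repeated
  visits counted each time.  $\phi_N$ on a cyclic graph is approximated
  by the truncated walk-weight sum as the length bound grows; for small
  rates, cycle-containing walks contribute $O(\nu^2)$ relative to paths,
  so truncation converges quickly.  The exact eigenvector-based
  replacement for $\phi_N$ is not implemented — the truncated sum is the
  documented approximation.

## Extensions

**Random fitness effects.**  If a transition into $y$ yields growth rate
$\lambda_i(y)$ with probability $\pi_i$, replace $y$ by one vertex per
outcome, splitting incoming rates as $\nu\pi_i$ and copying outgoing
edges (`expand_fitness_distribution()`).  The mixture type requires
division *and* death rates per component, not just their difference: two
states with equal $\lambda$ but different turnover differ in extinction
probability and fluctuation size.  Mixture probabilities must sum to 1
within $10^{-12}$.

**Successful founders.**  $T$ waits for the first target cell, whose
progeny may die out.  To wait for the first *successful* founder instead,
multiply every target-incoming rate by the survival probability
$\lambda(N)/\alpha(N)$ (`successful_seeding_adjustment()`); all results
then apply unchanged.  The adjustment refuses targets with
$\lambda(N) \le 0$, for which no founding lineage survives.

## The simulator

`simulate_paths()` is an exact stochastic simulation (Rcpp core,
`src/ssa.cpp`).  The population is partitioned into *lineage classes* —
cells sharing the same vertex lineage, the sequence of distinct
consecutive states in their ancestry — so the seeding path is read off
the first target cell at no extra cost.  Each class contributes
`count × (α + β + Σν)` to the total rate; waiting times are exponential
in the total rate, and the class and event are chosen proportionally.
Division increments the class, death decrements it, and a transition
$x \to y$ leaves the source class untouched while incrementing the class
with lineage $q \oplus y$.  Every event changes exactly one class count
by $\pm 1$.  The cached total rate is refreshed from the per-class rates
every $2^{14}$ events to curb floating-point drift.

Bookkeeping choices:

* **Modes.** `stop_at_first_target` halts at the first target cell;
  `track_all_paths` runs to the horizon and records the first arrival
  time of every distinct target lineage, so per-path arrival times
  $T(p)$ and their minimum $T$ are both observable.
* **Censoring.**  A time horizon `t_max` is mandatory and a population
  cap (default $10^6$ cells) guards runaway growth; censored runs are
  labelled, never dropped.
* **Reproducibility.**  The master seed seeds R's generator, a per-run
  seed table is drawn from it, and each run re-seeds with its own entry:
  run $i$ of a large batch equals run $i$ of a small one, and different
  master seeds give unrelated batches.
* **Conditioning proxy.**  Conditional quantities discard runs whose
  whole population went extinct before the target was hit.  The theory
  conditions on the *root* population surviving; the two events coincide
  as rates tend to zero, and the proxy avoids the unobservable
  infinite-horizon survival event.

## Scenario builders

*Monotherapy with a drug sanctuary* (`build_monotherapy()`): four states,
two routes to compartmental resistance — mutate-then-migrate (weight
$\nu m/s$) and migrate-then-mutate ($\nu m/d$), with $s$ the resistance
cost and $d$ the drug's death-rate increment.  Mutation-first wins with
probability $d/(s+d)$, and the drug-switch rule compares sanctuary sizes
against $(1+s/d_B)/(1+s/d_A)$.

*Combination therapy with nested penetration* (`build_combination()`):
regions sanctuary / single-drug / double-drug with capacities $n_S$,
$n_D$, $n_{DD}$, four genotypes each; costs add on the death rate ($s$
per mutation, $d$ per unblocked drug; no epistasis).  Migration moves a
cell at rate $m$ split by destination capacity, e.g. sanctuary to
double-drug at $m\,n_{DD}/(n_D + n_{DD})$; back-migrations toward the
sanctuary are neglected, matching the acyclic analysis, so only the
sanctuary's *total* out-migration equals $m$ exactly.  The graph has 18
root-to-target paths, 6 direct and 12 stepwise, and
`combination_metrics()` reports both the $s \ll d$ limit forms — the
acceleration condition $(n_S+n_D)/n_{Tot} > s/m$, the worst-case region
ratio, the stepwise probability $[1 + s(n_{DD}+n_S)/(m n_D)]^{-1}$ — and
their exact-graph counterparts, so the user can see where the limit
breaks.  One parameter note: the scenario is conventionally quoted with
sanctuary growth rate $0.4$; the builder defaults to $\alpha = 0.7$,
$\beta = 0.3$ to realise it, since a growth rate cannot exceed the
division rate, and both are overridable.  The initial count is
$z = \gamma n_S$ with occupancy $\gamma \ll 1$.

*Chronic myeloid leukemia* (`cml_analysis()`): point mutation
($\nu_{pm} = 8\times10^{-8}$/day) races gene amplification
($\nu_{ga} = 8\times10^{-7}$/day); with equal lineage survival the
point-mutation-first probability is $1/11$.  If amplified lineages
survive less often, the survival-adjusted race tips to point mutations
once $\rho_{pm} > 10\,\rho_{ga}$; if resistance needs *two*
amplifications costing $s$ each, the amplification route becomes a
two-step path and the probability rises to $(1 + 8\times10^{-6}/s)^{-1}$.
Note two natural thresholds for "point mutations more likely" coexist —
$s > 8\times10^{-6}$ against even odds, $s > 8\times10^{-7}$ against the
single-step race's $1/11$ — and the function reports the probability
itself rather than asserting either cutoff.

*Bacterial multidrug resistance* (`mdr_order_probability()`,
`mdr_two_path_analysis()`): with equal mutation rates, the order of two
resistance mutations depends only on the intermediate strains' fitness
costs, $P(\text{drug 1 first}) = c_2/(c_1+c_2)$; relative growth rates
$0.88$ and $0.71$ give $0.29/0.41 \approx 0.71$.  The two-path hitting
law uses $\phi = 2\nu_R\nu_I/s$, and lineages differing only in mutation
rates have relative resistance probability
$\nu_R^{(1)}\nu_I^{(1)}/\nu_R^{(2)}\nu_I^{(2)}$ while
$\nu_R\nu_I e^{\lambda t}$ stays small; the implementation flags when
that limit form stops being valid instead of silently returning it.

## Numerical and interface choices

* Path enumeration delegates to a DFS over the graph and returns
  lexicographic order over vertex-id sequences, so indices are stable
  across platforms; the test suite checks it against an independent
  brute-force oracle on random DAGs.  A configurable cap guards
  combinatorial blow-up and fails loudly rather than truncating.
* Vertex ids are arbitrary labels (scenario graphs use meaningful names
  like `S.A`); the `1..N` convention is just the default of the example
  builders.
* Graph specs are versioned JSON, schema-checked field by field on load;
  unknown keys are rejected in strict mode.  CLI floating output is
  printed to 12 significant digits so regression comparisons are
  byte-stable, and CLI outputs are never overwritten without `--force`.
* Degenerate inputs fail explicitly: weights are undefined when an
  internal state is at least as fit as the root; the conditional law
  requires $\beta < \alpha$; the successful-seeding adjustment requires
  a viable target.

## What the synthetic benchmarks do and do not show

The tests and the acceptance script exercise the package on generated
systems: the two-path valley graph at moderate rates ($\nu = 0.1$), the
four-vertex chain with costly intermediates
($\alpha = 1$, $\beta = 0.4$, $\beta_{mid} = 1.3$, $\nu \le 0.1$),
random DAGs of up to 8 vertices with log-uniform rates in
$[10^{-3}, 10^{-1}]$, and the application graphs with literature-scale
rates.  Simulation sizes were chosen for tight-but-cheap inference:
250–1000 runs for distribution comparisons, $10^4$ for extinction
frequencies, 300 runs for scaled-size recovery at $t_f = 14.5$.  Two
calibration points worth knowing:

* at $\nu = 0.1$ the finite-rate seeding probability of the valley path
  sits about $0.05$ *below* its small-rate limit $5/9$ (measured at
  6000 runs: $0.512 \pm 0.008$); simulator-vs-theory tests therefore
  allow that systematic margin alongside 99% binomial bands, and the
  gap shrinks visibly when rates are scaled down;
* the hitting-time approximation's sup-distance from the empirical
  survival curve at 1000 runs drops from $\approx 0.036$ at $\nu = 0.1$
  to $\approx 0.022$ at $\nu = 0.05$ on the chain system.

These are branching-process benchmarks: no carrying capacity, no
cell–cell interaction, no time-varying rates, immortal exponential
growth.  Passing them says the implementation matches its own model and
approximations in their stated regime — not that the model captures any
particular biological system, where density dependence, epistasis,
back-mutation and rate heterogeneity may all matter.

## Known limitations

* Hitting-time results need small *target-seeding* rates; all
  application statements are limit approximations, and no error bounds
  are computed.
* The exact initial-size median shift and the exact conditional law for
  $z>1$ are replaced by the documented approximations above.
* Cyclic graphs: $\phi_N$ via truncated walk sums only; the path/walk
  *distribution* machinery requires the user to choose the walk set.
* The simulator is a plain SSA — no tau-leaping or rare-event
  acceleration — so regimes where the target is hit only after the
  population exceeds the cap (rates far below $10^{-8}$ with small
  caps) are out of reach; raise the cap or use the analytics there.
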