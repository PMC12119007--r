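---
title: "Optimizing the tuning parameters of a borrowing basket trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing the tuning parameters of a borrowing basket trial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basketopt)
```

## The design

A basket trial tests one therapy in $I$ strata of a single-arm phase II
study with a binary response endpoint: $r_i \sim \mathrm{Bin}(n_i, p_i)$,
with a conjugate $\mathrm{Beta}(a_i, b_i)$ prior on each response rate
(uniform $a_i = b_i = 1$ by default). Instead of testing each stratum on
its own posterior $\mathrm{Beta}(a_i + r_i,\, b_i + n_i - r_i)$, the
borrowing design pools posterior shape parameters across strata with
similarity weights:

$$p_i \mid \mathbf r \sim \mathrm{Beta}\Big(\textstyle\sum_j \omega_{ij}(a_j + r_j),\;
\sum_j \omega_{ij}(b_j + n_j - r_j)\Big),
\qquad \omega_{ij} = \mathbb 1(\tilde\omega_{ij}^\epsilon > \tau)\,
\tilde\omega_{ij}^\epsilon,$$

where $\tilde\omega_{ij} = 1 - \mathrm{JSD}(\mathrm{post}_i,
\mathrm{post}_j)$ is one minus the Jensen–Shannon divergence of the
unborrowed posteriors (natural logarithm, so
$\mathrm{JSD} \in [0, \log 2]$). Stratum $i$ is *detected* as active when
$P(p_i > p^*_i \mid \mathbf r) \ge \lambda$ under its borrowing posterior.
The design is fully described by the tuning vector
$\phi = (\lambda, \epsilon, \tau)$: the detection threshold, the weight
shape exponent, and the similarity cutoff.

Three conventions are worth stating because the formulas do not force
them:

* **Self-weight.** $\omega_{ii}$ is always 1. A literal reading of the
  threshold at $\tau = 1$ (a value the search grid contains) would give
  $\omega_{ii} = \mathbb 1(1 > 1) = 0$ and an undefined
  $\mathrm{Beta}(0,0)$ posterior; a stratum never discards its own data.
* **Strictness.** The weight cutoff is strict
  ($\tilde\omega^\epsilon > \tau$) and the detection rule is weak
  ($\ge \lambda$), exactly as the design is written.
* **Weight normalization.** A normalized weight variant (division by the
  largest unequal-response similarity) appears in discussions of the
  redundancy between $\epsilon$ and $\tau$; this package implements the
  primary, unnormalized definition throughout.

### Divergences and the extreme borrowing boundary

The Jensen–Shannon divergence of two beta posteriors has no closed form;
it is computed by adaptive quadrature on $(0,1)$ (absolute tolerance
1e-9, integrand defined as 0 where the numerator density vanishes; with
uniform priors all posterior shapes are $\ge 1$, so the integrands are
bounded and no endpoint singularities arise). The Hellinger distance is
offered as a drop-in alternative; for betas it reduces to a ratio of beta
functions and is evaluated in log space to avoid overflow.

Because $\tilde\omega_{ij}$ only depends on the per-stratum summaries
$(r_i, n_i, a_i, b_i)$, all pairwise similarities of a layout live in a
$(n_i{+}1) \times (n_j{+}1)$ table that is computed once and memoized for
the session. Exact enumeration over all
$\prod_i (n_i + 1)$ outcome vectors therefore costs one table lookup per
stratum pair plus one incomplete-beta tail per stratum — the enumeration
engine is vectorized across all outcomes at once.

Let $\tilde\omega^*$ be the largest similarity attainable by two strata
with *unequal* responder counts. For
$\epsilon > \epsilon_{\mathrm{extreme}}(\tau) =
\log(\tau)/\log(\tilde\omega^*)$ the weight matrix collapses to the
equal-responses indicator, and raising $\epsilon$ or $\tau$ further
changes nothing. For equal sample sizes this pairwise construction does
not depend on the stratum count, which is why
`extreme_borrowing_boundary()` takes a layout and a cutoff only.

## Operating characteristics

All performance measures are frequentist probabilities of the Bayesian
decision rule ("pragmatic Bayesianism"): outcomes are sampled from the
true binomial distributions of a *scenario* (a vector of true rates with
strata classified active where $p_i > p^*_i$), while detection uses the
borrowing posterior. `exact_oc()` enumerates the full outcome space and
weights decisions by product-binomial masses (refusing beyond a
configurable limit of $3 \times 10^6$ vectors, default); `mc_oc()` draws
$n_{MC}$ data sets (default 1000) and attaches Monte Carlo standard
errors $\sqrt{\hat r (1 - \hat r)/n_{MC}} \le 0.016$. The measures are
the per-stratum rejection rates (type-I error or power), the
experiment-wise power $P(\exists\, i \in R$ detected$)$, the family-wise
error rate $P(\exists\, i \in R^c$ detected$)$, and the expected number
of correct decisions. With no active strata EWP is defined as 0, and with
no inactive strata FWER is 0 — the measure of an empty union.

## The scenario sets

`build_all_scenario_sets()` constructs seven pre-specified sets spanning
3 to 20 strata, inactive rates 0.01–0.20, active rates 0.10–0.50 and
total sample sizes 72–480. Each set steps the number of active strata
from the global null upward with inactive strata listed first; the
four-stratum, $n = 20$ set adds the mixed "one in the middle"
$(0.4, 0.4, 0.3, 0.5)$ and "linear" $(0.15, 0.25, 0.35, 0.45)$
scenarios, ordered after the stepped ones. The target rate $p^*_i$ is set
to the set's inactive rate $p_0$ for every stratum: the study pre-specification does not
pin $p^*$ explicitly, and equating it with the null response rate is the
established convention for this design and makes "active"
$\iff p_i > p^*$. A consequence worth noting is that in the mixed
scenario all four strata count as active against $p^* = 0.15$. An
alternative — classifying mixed scenarios against a mid-point threshold —
was considered and rejected as it would break the equivalence between
activity and a false null.

## Utility functions

Twelve utilities combine the measures, all maximized over $\phi$
(defaults $\xi_1 = \xi_2 = 1$, $\xi_3 = 1000$, $\eta_1 = 0.05$,
$\eta_2 = 0.1$, $\eta_3 = 0.2$):

1. $u_{\mathrm{ewp}}(\phi, p_1, p_2)$: EWP under $p_1$ if
   $\mathrm{fwer}(p_2) < \eta_1$ (strict), else $-\xi_1\,\mathrm{fwer}(p_2)$;
2. $u_{\mathrm{ecd}}$: the same gate with ECD in the pass branch;
3. $u_{\mathrm{2ewp}}(\phi, p) = \mathrm{ewp} - (\xi_1 \mathrm{fwer} +
   \xi_2 (\mathrm{fwer} - \eta_2)^+)$;
4. $u_{\mathrm{2pow}}$: the stratum-wise analogue summing powers and
   two-level error penalties;
5. scenario-averaged versions $\sum_p w_p u_l(\phi, p)$ (uniform weights
   by default; the error scenario $p_2$ of families 1–2 is the set's
   global null);
6. penalized scenario-averaged versions returning
   $-\xi_3 \max_{p, j} \mathrm{toer}_j$ once the largest inactive-stratum
   error anywhere in the set reaches $\eta_3$.

The hinge indicator is $\mathbb 1(x > 0)$, so a rate exactly at $\eta_2$
incurs no second-level penalty, and $\mathrm{fwer} = \eta_1$ exactly
falls into the penalty branch (the gate is strictly $< \eta_1$). The
$\xi_3 \eta_3 > |\min \bar u_l|$ sanity condition is not enforced — it
cannot be verified before the utilities are evaluated.

One naming ambiguity in the surrounding literature (a "stratum-wise"
label attached to the family-wise symbol) is resolved by keeping both the
`2ewp` and `2pow` families in the registry, so either reading of the
algorithm-comparison test problems can be run.

`build_utility_objective()` compiles a utility into a fast
`function(phi)`: per evaluation the decision rule is applied once to the
pooled outcome space and reused across all scenarios of the set. When
enumeration is infeasible the Monte Carlo backend uses common random
numbers — the binomial draws are fixed per scenario when the objective is
built — so an optimization run sees a deterministic, seed-reproducible
objective rather than a freshly noisy one at each step.

## Optimizers

Eight configurations sit behind one interface with a shared evaluation
counter (every objective call, including invalid out-of-bounds
evaluations, counts against the budget of 1000 evaluations; trajectories
are recorded; ties keep the first optimum in evaluation order):

* **Bounded simulated annealing** (start temperatures 100, 10, 1) with
  proposals reflected into the box, and **unbounded simulated annealing**
  (start temperature 10) where out-of-bounds proposals receive an invalid
  $-\infty$ value and are never accepted. One evaluation per temperature
  step, geometric cooling. The cooling schedule and proposal law are left
  open by the study pre-specification; this package cools to $T_{final} =
  10^{-10}$ over the budget and decays the Gaussian proposal scale
  geometrically from 10% of each dimension's width to 2% of that. The
  combination was chosen once on the concave-quadratic rehearsal
  objective: with a fixed 10%-width proposal the $\epsilon$ dimension
  (width 25) cannot refine below ±0.05, and with temperature-coupled
  step sizes the walk freezes before it explores; explore-then-refine
  recovers the rehearsal optimum in effectively every seeded run.
* **Differential evolution**, canonical rand/1/bin (population 40,
  $F = 0.8$, crossover 0.5, greedy $\ge$ selection, clipping).
* **Grey wolf optimizer**, original linear-decay variant (pack 40,
  coefficient $a$ from 2 to 0); the later "improved" variant is not used.
* **COBYLA** backed by the nloptr implementation (parameter tolerance
  $10^{-6}$, value tolerance 0, box bounds as constraints), wrapped by
  the same counter; non-convergence is reported, never raised.
* **Grid search** over the pre-specified
  $10 \times 10 \times 10$ grid ($\lambda \in \{0.2, \ldots, 0.9, 0.99,
  0.999\}$, $\epsilon \in \{0, 0.5, 1, 1.5, 2, 5, 10, 15, 20, 25\}$,
  $\tau \in \{0, 0.1, \ldots, 0.8, 1\}$) — 1000 combinations, matching
  the budget.

Continuous algorithms search $\epsilon \in [0, 25]$: the boundary
analysis shows $\epsilon = 25$ already exceeds the extreme borrowing
boundary for the studied layouts, so nothing is lost by bounding the
hypercube. The unbounded annealer rejects an out-of-bounds start rather
than guessing a projection.

## The comparison study

**Part I** (`run_part1()`) runs all eight configurations on two test
problems — the scenario-averaged two-level family-wise utility and the
scenario-averaged ECD utility on one scenario set — repeating stochastic
algorithms $n_{runs} = 50$ times with seeds $1856, 1857, \ldots$ (the
pre-specification fixes the first seed; consecutive seeds for the remaining runs
are this package's choice). Reported measures: efficiency (evaluations,
wall time), internal consistency (mean/SD/normal-95%-CI/range of values
and parameter components, with the SD's own standard error from
`se_of_sd()`), and external reliability against the grid benchmark.
"Internal reliability" is named but not defined in the pre-specification; here it
is the fraction of runs within $10^{-4}$ of the per-problem best, and
"success" against the grid allows a $10^{-9}$ floating-point margin.
Selection: reliability $> 0.99$, then success rate $> 0.99$, then fastest.

**Part II** (`run_part2()`) optimizes all twelve utilities per scenario
set with the selected algorithm (seed 899), tabulates every measure for
every scenario at each optimum, and cross-evaluates every utility at
every optimum. Single-scenario utilities bind the "about half active"
scenario (2 of 3, 2 of 4, 4 of 8) with the global null as error scenario.
**Part III** (`run_part3()`) evaluates the same tables at the two
heuristic suggestions $(0.99, 2, 0)$ and $(0.99, 2, 0.5)$.
**Extras** (`run_extras()`) compare the Jensen–Shannon and Hellinger
variants (matched exact measures, timing reported) and trace the
two-stratum borrowing-inflation curves: one basket fixed at the null rate
0.2 while the neighbour's true rate sweeps 0.2–1.0.

## Problem sizes, reproducibility and limitations

The full pre-specified study (four-stratum exact enumeration inside
thousand-evaluation optimizations, repeated fifty times per algorithm) is
a cluster-scale computation. The package defaults therefore separate the
*protocol constants* (budget 1000, $n_{runs}$ 50, seeds 1856/899, start
$(0.2, 0.5, 0)$) from the *rehearsal scale* used in the test suite and
the acceptance script: a three-stratum layout with five patients per
stratum (216-point outcome space), budget 200 and $n_{runs} = 10$, which
exercises every code path of Parts I–III in minutes on one core. The
protocol scale remains reachable through `study_config()`.

Everything downstream of a seed is deterministic: exact enumeration is
reproducible bitwise, Monte Carlo and stochastic optimizers value-wise
under fixed seeds. What rehearsal-scale runs cannot show is the
*statistical* geometry of the full-scale utilities — with $n_i = 5$ the
discrete outcome space makes utilities piecewise constant in $\lambda$
over wide plateaus, so optimizer rankings at rehearsal scale are smoke
tests, not evidence about the full problems. Other known limitations:
binary endpoints only; equal priors across analysis stages; no
calibration of priors; single-stage designs (no interim analyses); and
Monte Carlo standard errors are the plain binomial ones, without
jackknife or bias correction.
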