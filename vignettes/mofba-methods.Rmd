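---
title: "Multi-objective flux balance analysis with NSGA-II: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective flux balance analysis with NSGA-II: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The constraint-based model

A metabolic network with $m$ metabolites and $n$ reactions is summarised
by its stoichiometric matrix $S \in \mathbb{R}^{m \times n}$: entry
$S_{ij}$ is the signed coefficient of metabolite $i$ in reaction $j$
(consumed negative, produced positive). Under the steady-state
assumption the flux vector $v \in \mathbb{R}^n$ satisfies $S v = 0$,
and each flux is confined to bounds $LB_j \le v_j \le UB_j$. Classical
flux balance analysis (FBA) picks one reaction of interest — a biomass
or bioproduct drain — and solves the linear program

$$\max_v \; v_\text{obj} \quad \text{s.t.} \quad S v = 0,\;
LB \le v \le UB.$$

`solve_fba()` implements exactly this. Fluxes are treated as
dimensionless rates (the case-study source tables carry no units).

When several bioproducts matter at once, the single objective becomes a
vector $\max_v (v_{b_1}, \dots, v_{b_k})$ over the same polytope. The
resulting problem has no single optimum but a Pareto frontier: the set
of feasible objective vectors not dominated by any other (domination
under maximisation: at least as good everywhere, strictly better
somewhere). A linear solver cannot enumerate this frontier; the package
approximates it with an evolutionary algorithm.

# The genotype: re-defining flux bounds

The search space is not the flux polytope itself but a family of
*sub-polytopes*. A configuration names two disjoint reaction sets: the
bioproducts $V_b$ (2 or 3 drains, the first being the *leading*
bioproduct) and a control set $V_M$ (typically the substrate
exchanges). The genotype holds one pair $(I_i, \Delta_i)$ per encoded
reaction, laid out $V_M$ block first, so its length is
$2(|V_M| + |V_b|)$. Decoding replaces the reaction's bounds by

$$LB_i^{new} = I_i, \qquad UB_i^{new} = (UB_i - I_i)\,\Delta_i + I_i,$$

with $I_i \in [LB_i, UB_i]$ and $\Delta_i \in [0, 1]$, which guarantees
$LB_i^{new} \le UB_i^{new}$. Decoding always starts from the *original*
bounds — repeated decoding has no hidden state. A knockout is the
special case $(I, \Delta) = (0, 0)$; the encoding therefore strictly
generalises knockout vectors. One worked example in the test-suite has
base bounds $(0, 10)$ throughout: $(I,\Delta) = (5, 0.50)$ gives
$(5, 7.5)$, $(2, 0.80)$ gives $(2, 8.4)$, and $(7.5, 0.10)$ gives
$(7.5, 7.75)$ — the formula, not any transcription of it, is
authoritative.

The fitness evaluation decodes a genotype, overrides the bounds, and
solves a *single-objective* FBA LP maximising the leading bioproduct.
The objective vector handed to the evolutionary engine is the flux of
every bioproduct read off that optimal solution. Two caveats follow
directly from this design:

* the leading component is an LP optimum and is unique; the non-leading
  components are read from one optimal vertex and are solver-dependent
  wherever alternate optima exist. The LP backend is deterministic, so
  results are reproducible, but a different pivoting rule would report
  different (equally optimal) non-leading fluxes. No lexicographic
  re-solve or flux-variability post-processing is applied.
* if the decoded bounds admit no steady state the LP is infeasible and
  the genotype is marked constraint-violating (next section).

# The NSGA-II engine

`nsga2_run()` is a self-contained generational NSGA-II for maximised
objectives: random initialisation inside the box, uniform random mating
pairs, simulated binary crossover (SBX), polynomial mutation, and
elitist $(\mu + \lambda)$ environmental selection by constrained
non-domination rank and crowding distance. Mating is *pure random
selection* (no binary tournament): selection pressure comes entirely
from the elitist truncation, with ranking and crowding driving it.

Default parameters follow the case-study protocol: population $N =
100$, evaluation budget 10,000 (the initial population counts), SBX
with $p_c = 1.0$ and $\eta_c = 20$, polynomial mutation with $\eta_m =
20$ and $p_m = 1/L$ for genotype length $L$ — for the 12-gene
case-study genotype that is $1/12 \approx 0.083$, the literal value the
protocol uses.

Two operator details deserve a note:

* **SBX child symmetry.** Per variable, the recombined (or copied) pair
  of child values is swapped between the two children with probability
  one half. Some implementations skip the swap on copied variables;
  because mating pairs are randomly ordered the two conventions are
  statistically equivalent at the population level, and the uniform
  swap makes the two children exchangeable — each child's expected
  value per variable is the parent midpoint, a property the test suite
  checks by Monte Carlo.
* **Crowding ties.** Truncation of the last front sorts by crowding
  distance with stable ties (input order), so runs are bit-reproducible
  under a fixed seed.

## Constraint handling

Feasibility-first (constrained) domination is used: a feasible solution
always beats an infeasible one regardless of objectives; among
infeasible solutions the smaller violation wins; among feasible ones
ordinary Pareto domination applies. Infeasible genotypes also receive a
large negative sentinel objective vector so they can never contaminate
a feasible front.

The violation magnitude is a genuine design choice. A binary flag
(feasible / infeasible) looks natural because an infeasible LP reports
no numbers — but it starves the search: on the case study a uniformly
random genotype is feasible with probability on the order of $10^{-4}$
(the encoded lower bounds usually exceed the attainable fluxes), and
with a binary flag an all-infeasible population is totally tied, so
elitist truncation with stable ties freezes the population and most
runs never reach feasibility at all. The package instead uses the LP's
own *Phase-1 infeasibility*: the minimum total artificial-variable mass
needed to satisfy $S v = 0$ under the decoded bounds, a deterministic
non-negative scalar that is zero exactly on feasible boxes. This
restores the graded feasibility ordering of standard constraint-domination
schemes and lets the population descend toward the feasible region
within a few generations. This is the package's reading of
"prefer feasible solutions" with a meaningful degree attached.

# The LP backend

FBA subproblems are solved by a bundled dense two-phase primal simplex
(C++): variables are shifted to $x = v - lb \ge 0$, finite upper bounds
become explicit slack rows, Phase 1 minimises artificial mass on the
equality rows, and Phase 2 optimises the objective. Bland's rule
(lowest eligible index enters, lowest basic index leaves) makes every
solve deterministic and cycle-free; the networks of interest are tiny
(tens of reactions), so a dense tableau is faster in practice than any
sparse machinery, and the evolutionary loop performs on the order of
$10^5$–$10^6$ solves per experiment. Numerical tolerances: pivot and
reduced-cost thresholds $10^{-9}$, Phase-1 feasibility threshold
$10^{-7}$ (scaled by the right-hand side), and a fixed steady-state
tolerance of $10^{-6}$ for `check_steady_state()`. Optimal vertices are
clipped into the box against roundoff. Lower bounds must be finite;
upper bounds may be infinite (the ratio test then detects
unboundedness, which the fitness function treats as a violation — it
cannot occur under the finite boxes of the encoding).

The test suite cross-checks this solver against two independent pure-R
references (`boot::simplex` and `pracma::linprog`) on the case-study
network and on random networks, verifying any reference vertex against
the constraints before trusting it.

# The case study

The built-in network is the heterotrophic (acetate-fed) glycolysis
module of *Chlamydomonas reinhardtii*: 18 reactions over 14
metabolites, with acetate, erythrose-4-phosphate and
xylulose-5-phosphate uptakes (`v1`, `v16`, `v17`) and protein,
carbohydrate and CO2 drains (`v10`, `v14`, `v18`) as the bioproducts of
interest. The canonical configuration C0 maximises
$(v_{10}, v_{14}, v_{18})$ with $V_M = \{v_1, v_{16}, v_{17}\}$; 36
further three-bioproduct configurations (C1–C36) swap the third
objective through the interior reactions. The third block's printed
source is an evident copy-paste repetition, so C25–C36 are
reconstructed by the symmetric pattern of the first two blocks and
flagged as such in the `generate_configurations()` output attribute.

**Reference bounds.** The package default caps the acetate uptake at
$UB(v_1) = 10$ and the pentose uptakes at $UB(v_{16}) = UB(v_{17}) =
0.3$, with $[0, 100]$ elsewhere. These are the bounds under which the
module's published reference optima hold (max $v_{10} = 10$, max
$v_{14} = 10.6$, with $v_{11} = 10.3$ at the carbohydrate optimum, all
reproduced to LP precision by the suite); an unconstrained uniform
$[0, 100]$ variant is available as `bounds = "uniform"`. Reversible
reactions keep $LB = 0$ in the fixture — every reference flux is
non-negative — but the parser records reversibility and accepts
negative lower bounds for other networks.

On this network the C0 Pareto frontier has a closed form: the acetate
cap fixes $v_{18} = 10$ and protein and carbohydrate trade off along
$v_{10} + v_{14} = 10.6$ for $v_{10} \in [0, 10]$. The distance from
this segment to the ideal point $(10, 10.6, 10)$ is minimised at
$v_{10} = 5$, giving the analytic floor $\sqrt{50} \approx 7.0711$ for
the quality indicator — a useful lower envelope for any evolutionary
result.

# Indicators and the experiment harness

* **Ideal point**: per bioproduct, the single-objective FBA maximum
  under base bounds (generally not jointly attainable).
* **Quality $Q$**: minimum Euclidean distance from a solution set to
  the ideal point; lower is better.
* **Diversity $D$**: number of distinct solutions, counted as
  connected components of the "all components within $10^{-6}$"
  relation in objective space. The tolerance is a package choice; the
  pooled counts it produces are consistent with objective-space
  uniqueness across replicates.

`run_experiment()` replicates the protocol (31 runs by default, one
seed per run), pools the feasible best-front points of all runs, and
reports the best $Q$ over the pool, the pooled non-dominated distinct
count, and per-run counts — the published per-configuration counts do
not state whether they are pooled or per-run, so both are emitted.
Likewise the best (not median) $Q$ over runs is reported, matching a
"best distances" reading. `compare_with_fba()` lays the results out
against the per-objective FBA qualities and attaches paired Wilcoxon
signed-rank p-values across configurations; replicate-dependent
quantities (p-values, front counts) are reported, never asserted
against, since they depend on the solver vertex and run set.

# Test oracles and synthetic data

`oracle_front()` is a deterministic $\varepsilon$-constraint sweep:
each objective in turn is maximised while the others are constrained to
a grid of lower bounds between their base bound and their
single-objective optimum; infeasible grid points are skipped and the
pooled non-dominated set is returned. Because each point is an LP
optimum, the sweep bounds the true frontier from inside up to grid
resolution; the suite uses it both on the case study (where the
analytic front is known) and on random networks.

`random_network_fixture()` generates connected chain-and-branch
networks with one uptake, at least two drains, and unit stoichiometry;
all lower bounds are zero so the zero flux vector is always feasible.
It emulates the topology class of small exchange/conversion modules —
linear pathways with branch points — and deliberately does *not*
emulate cofactor coupling, non-unit stoichiometry, reversibility with
negative flux, or thermodynamic constraints; passing property tests on
these fixtures therefore supports the solver and sorting machinery, not
biological realism of any particular model.

# Problem sizes and reproducibility

The suite runs the full case-study protocol once (31 runs × 10,000
evaluations, about 310,000 LP solves, under a minute on one core) and
keeps the remaining property tests at small sizes: 1,000 random
populations of up to 50 individuals for the sorting oracle, dozens of
random networks for the LP cross-checks, $10^4$-draw Monte Carlo checks
for operator symmetry. Every stochastic test fixes its seed; NSGA-II
runs are bit-reproducible given a seed, and experiment reports record
seeds, parameters and the LP backend identifier.

# Known limitations

* Non-leading objective values inherit LP degeneracy (see above);
  fronts are exact in the leading coordinate only up to the solver's
  vertex choice elsewhere.
* The dense simplex targets small modules; genome-scale models would
  need a sparse revised simplex or an external solver.
* The multi-objective model optimises bounds re-definitions, not flux
  distributions directly: the reported front is the image of the
  encoding's sub-polytopes, which covers the true frontier only insofar
  as bound tightening can steer the leading-objective optimum along it.
* No SBML/COBRA import: the plain-text reaction table is the canonical
  format.
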