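---
title: "The oncolattice model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oncolattice model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolattice)
```

# The model

`oncolattice` simulates the growth of a heterogeneous colony of healthy and
cancerous cells, together with tumor-induced angiogenesis, on a fixed 3D
lattice. It is a hybrid model operating on three scales:

* **Tissue scale (continuum).** Five molecular species — oxygen, glucose,
  TGF-$\alpha$, TNF-$\alpha$ and VEGF — are scalar fields over the lattice.
  Each evolves by an explicit finite-difference diffusion scheme on the
  26-neighbor Moore stencil,
  $$C(t+\Delta t) = C + \tfrac{D\,\Delta t}{\Delta S^2}\Big(\sum_{\mathrm{nb}} C_{\mathrm{nb}} - 26\,C\Big) - U + S\;(-W),$$
  with phenotype-dependent cellular uptake $U$, vessel-wall exchange
  $S = \tfrac{\Delta t}{\Delta S^2}\,2\pi R\,P_e\,(\rho - C)$ at perfused
  vessel sites, constant production of TGF-$\alpha$/TNF-$\alpha$ by tissue
  cells, a phenotype-graded VEGF source at cancer-cell sites, and
  first-order VEGF decay $W$. The cancer uptake schedule is
  $\beta_c / \{1, 2, 4, 6, 8\}$ across the phenotypes proliferation,
  migration, quiescence, hypoxia, necrosis; the VEGF production schedule is
  $\phi_c / \{1, 2, 4, 6, 8\}$ in the reverse order (necrotic and hypoxic
  cells secrete the most VEGF).

* **Cell scale (agents).** Each lattice site holds at most one tissue cell
  (healthy or cancerous), a permanent necrotic-debris marker, or up to four
  endothelial cells. Every macro step (1 hour) each active cell selects one
  phenotype from its type's repertoire — cancerous:
  {proliferation, migration, quiescence, hypoxia, necrosis}; healthy:
  {proliferation, migration, quiescence, apoptosis}; stalk:
  {quiescence, branch, sprout}; tip: {quiescence, branch, expansion}.
  Migration and daughter placement use a two-stage site selection: a
  candidate Moore site qualifies when, for any relevant nutrient
  (oxygen/glucose for tissue cells, VEGF for vessel cells),
  $\max C - \bar C > 3\sigma$ over its neighborhood; the pool of qualifying
  candidates (or all free candidates when none qualify) is then sampled
  with probability proportional to the summed neighborhood means. All cells
  propose moves simultaneously and contested sites are resolved in one
  batch: a cancerous claimant beats a healthy one, same-type ties are
  uniform, losers stay put.

* **Sub-cellular scale (signaling).** Each tissue cell runs an EGFR
  pathway (local TGF-$\alpha$ in, PLC-$\gamma$ out) and a TNF pathway
  (local TNF-$\alpha$ in, death signal out), both consuming their ligand
  from the local field. The pathways are not modeled mechanistically: the
  package defines their input/output contract and ships a surrogate: mass-action receptor binding
  $\dot r = k_{on} L (1-r) - k_{off} r$ with a saturating Hill readout
  $\dot y = k_{act}\, r^h/(K^h + r^h) - k_{dec}\, y$. The surrogate is
  monotone and saturating in sustained ligand, which is all the
  decision layer relies on. Pathway models are pluggable via
  `register_pathway()`; swapping in a mechanistic ODE system changes nothing
  elsewhere (this is exercised with a mock model in the test suite).

## Phenotype decisions: policies, reward, Q-learning

Ten policy rules link state variables to phenotype preferences (oxygen and
glucose thresholds, division budget, proliferation delay, hypoxia
duration, PLC-$\gamma$ relative to the population, neighbor crowding,
TNF-$\alpha$, VEGF, tip maturity $\psi$). Each rule contributes a smooth
reward term
$$RF_p(x) = \tanh\!\big((x - \mathrm{threshold}_p)/\mathrm{gradient}_p\big),$$
sign-adjusted so that positive means survival-favorable; the total reward
is the mean over the rules applicable to the cell type, hence always in
$(-1, 1)$.

For action *selection* each triggered rule shifts probability mass
multiplicatively: favored actions gain a factor $k$ (the bias strength,
default 4) and all other allowed actions lose the same factor. Two hard
constraints are encoded as zero weights: migration requires more than two
tissue Moore neighbors, and only type-allowed actions are considered. The
complementary down-weighting matters: with a flat residual prior a
well-nourished cell would still sample its death action a few percent of
the time per hour, and over hundreds of hours the colony would
stochastically self-destruct.

State–action values are learned online. Each macro step the engine
predicts $Q(s, a_k)$ for every allowed action (a three-kernel SVR
ensemble, below), samples an action proportionally to the shifted
non-negative $Q$ values times the policy-bias prior (train mode) or takes
the bias-masked argmax (test mode), advances the world, computes the
reward from the successor state, and applies
$$Q \leftarrow (1-\eta)\,Q + \eta\,[r + \gamma \max_{a'} Q(s', a')].$$
$\max_{a'} Q(s', a')$ uses the next macro step's predictions (a one-step
deferral; dead or quiescent cells contribute 0). Experiences with
$r > \theta$ enter a sliding FIFO window (capacity $d = 200$); the
ensemble is refit every 100 steps once at least 50 samples accumulated.
Before the first fit (cold start) actions are sampled from the policy
bias alone. By default only cancerous cells learn; healthy and vessel
cells follow the policy biases directly (configurable).

A plain proportional rule $P(a) = Q_a / \sum_i Q_i$ is ill-defined for
negative values, which learned $Q$ (derived from rewards in $(-1,1)$) can
take, and it permanently starves actions whose value ever reaches zero.
The sampler therefore shifts the values by their negative part and always
adds a small exploration floor ($\varepsilon = 0.05$) before normalizing;
well-separated non-negative values keep essentially their exact
proportions.

## Value-function approximation: SVR + NSGA-II

The regression dataset pairs (state vector, one-hot action) with the
continuous label $Q \in [-1, 1]$. Three $\varepsilon$-SVR kernels — RBF,
polynomial, sigmoid — are each tuned by an elitist non-dominated sorting
genetic algorithm (NSGA-II: fast non-dominated sorting, crowding distance,
binary tournament, SBX crossover, polynomial mutation; written in-package)
maximizing cross-validated (recall, precision, F-measure) over
$(C, \varepsilon, \gamma)$, with $C$ and $\gamma$ searched on a log scale.
Because the F-measure is a classification metric and the labels are
continuous, predictions are discretized by sign agreement (positive class
$Q \ge 0$) by default, or by $k$-bin agreement. One spec is taken from the
front by highest F-measure (ties by crowding distance), refitted on the
whole window, and the three kernels vote with weights equal to their
training F-measures; predictions are the weight-normalized average clipped
to $[-1, 1]$. A convexity argument guarantees the aggregate's error never
exceeds the worst member's at any point, which the tests confirm as a
MAPE inequality across twenty synthetic tasks.

## Angiogenesis and perfusion

Eight parent vessels span the lattice vertically: four arteries on the
mid-face lines and four veins on the vertical edges (the opposite
assignment is equally plausible; a geometry switch swaps them). When tumor-derived VEGF at a parent-vessel
wall exceeds the sprouting threshold, the wall site may launch a tip cell
(at most once per site — lateral inhibition; default rate 0.1/h per
eligible site). Tips advance up the VEGF field (expansion), leaving stalk
cells in their wake; after maturing for $\psi$ hours they branch with
raised probability; stalk cells occasionally sprout laterally. Sprouts
inherit their lineage side: arteriole from arteries, venule from veins.
A sprout becomes *perfused* when its connectivity component (segments
linked by Moore adjacency, roots linked to their own side) contains both
the arterial and the venous supernode — i.e., an arteriole has anastomosed
with a venule so blood can circulate. Only perfused segments exchange
nutrient with the tissue ($R = r_{cap}$ in the wall-exchange term) and
consume VEGF. Perfusion is recomputed from scratch each step, so severing
a connection reverts the path. Perfused segments stop remodeling
(flow-induced stabilization, the phalanx phenotype).

## Absorbing quiescence and death

Quiescence is absorbing: a cell that selects it (or whose proliferation
finds every Moore site occupied) never returns to an active phenotype.
It is read as barring a return to *activity*, not as immortality:
quiescent cells remain subject to the hard physiological limits — glucose
below the dead threshold, hypoxia beyond the endurance limit, or a
committed TNF death signal — which kill outright (apoptosis removal for
healthy cells, permanent necrotic debris for cancerous ones). A hypoxic
healthy cell additionally survives each hour only with probability
$1 - 0.3$; hypoxia-adapted cancer cells endure until the 48-hour limit.
This asymmetry is what lets the tumor front advance into regions its own
oxygen demand has made lethal to normal tissue.

# Parameters

All constants ship as config defaults in normalized concentration units
(arterial level $= 1$); they are implementation defaults chosen for
biological plausibility and internal consistency, not measured constants.
The key ones:

| parameter | default | units | rationale |
|---|---|---|---|
| lattice spacing $\Delta S$ | 20 | µm | one cell diameter |
| macro step | 1 | h | one decision per cell-hour |
| horizon | 504 | h | 21 days |
| $D$ (O$_2$/glucose, TGF/TNF, VEGF) | 400 / 100 / 200 | µm²/h | effective tissue-scale spread; sub-stepped to the 1/26 stability bound |
| $P_e$ | 5 | µm/h | wall exchange $\approx$ half-equilibration per hour at an arteriole |
| $r_{art}$, $r_{cap}$ | 6, 4 | µm | 12 µm arterioles, 8 µm capillaries |
| $\beta_c$ (O$_2$, glucose) | 0.4, 0.25 | 1/h | Warburg-scale excess over normal uptake |
| $\alpha_n$ (O$_2$, glucose) | 0.10, 0.05 | 1/h | demand placing the avascular interior at the hypoxic margin (Krogh-type diffusion limit) |
| $\phi_c$, $\omega$ | 0.05, 0.1 | a.u./h, 1/h | VEGF source/decay giving a screening length of a few sites |
| hypoxia threshold / endurance | 0.1 a.u. / 48 h | | tumor hypoxia persists for days; healthy cells die at 0.3/h when hypoxic |
| glucose dead/active | 0.05 / 0.2 | a.u. | three-band rule |
| seed radius / probabilities | 60 µm / 0.7 | | central seed sphere, tissue occupancy |
| $\psi$ (tip maturity) | 10 | h | sprout consolidation before branching |
| $\eta$, $\gamma$, $\theta$, $d$ | 0.5, 0.8, 0, 200 | | learning rate, discount, admission threshold, window |

The explicit scheme requires $D \Delta t/\Delta S^2 \le 1/26$;
`resolve_substep()` picks the minimal number of equal sub-steps per
macro step. The boundary condition is no-flux (a missing neighbor mirrors
the center value), chosen because the domain is a tissue block supplied by
its own vasculature; the convention is isolated in the stencil kernel so a
periodic variant could be swapped in. Negative concentrations from the
explicit update are clamped to zero and counted. Necrotic debris consumes
nutrient at $\beta_c/8$ as the discrete scheme is written; a config switch
(`agent$necrotic_uptake`) zeroes it.

Signaling is integrated once per macro step by fixed-step RK4 at
sub-minute resolution (refined automatically with the ligand level, which
sets the fastest rate); the surrogate is smooth and non-stiff, and the
fixed-step integrator vectorizes across thousands of cells where an
adaptive per-cell integrator would not. Agreement with an adaptive
reference integrator is verified in the test suite to $10^{-6}$.

# What the simulated data do and do not show

The synthetic world the generator produces emulates: nutrient-driven
competition between a 70%-seeded healthy tissue and a central tumor seed
(radius 60 µm, probability 0.7), hypoxia-triggered VEGF secretion,
sprouting angiogenesis with anastomosis-gated perfusion, and the
characteristic growth arc — near-exponential early growth, healthy
die-back around the hypoxic tumor, vascular rescue, and saturation when
space and supply run out. It does not emulate: deformable tissue
mechanics, blood-flow hemodynamics, interstitial pressure, immune
interactions, or mutation/heterogeneity within the cancer population; the
signaling layer is a behavioral surrogate, not a mechanistic reaction
network. Passing tests therefore certify the discrete scheme, the
decision engine and the validation machinery, not quantitative agreement
with any wet-lab measurement.

On growth-law validation: clinically fitted Gompertz parameters for human
tumors lie in $\alpha \in [0.005, 0.016]$ and $\beta \in [0.121, 0.390]$
(per hour). Jointly they imply a total growth ratio
$e^{\alpha/\beta} \le e^{0.016/0.121} \approx 1.14$ — months-scale tumors
barely grow over any 21-day window. A lattice-filling simulation
(ratio $\sim 10$–$100$) therefore cannot place both parameters inside
those ranges at once: the fitted $\alpha/\beta$ equals the log growth
ratio. The package reports the honestly fitted values and flags each
range separately; the reference parameter set $(n_0, \alpha, \beta) =
(100, 0.01, 0.3)$ used for the validation curves has the same tension, and
under noise only its ratio $\alpha/\beta$ is identifiable (the near-flat
curve leaves $\alpha$ and $\beta$ individually undetermined, which is why
the noisy-recovery tests use well-conditioned parameter sets).

# Numerical and design choices worth knowing

* **Determinism.** One master seed; every stochastic component draws from
  a purpose-labeled stream derived from it (`stream_seed()`), so a run is
  bit-reproducible from its resolved config echo.
* **Ties.** Argmax ties in test mode and same-type site contests are
  broken uniformly from the seeded stream.
* **Degenerate windows.** A constant-response window yields a constant
  predictor per kernel; an all-zero-weight ensemble falls back to a plain
  average at fit time and refuses to predict only if weights are zeroed
  afterwards.
* **Empty candidate pools.** All-zero selection weights fall back to
  uniform; a mover with no reachable site stays put; a blocked branch
  idles for the step (transient, unlike decision-selected quiescence).
* **Stopping.** A run ends at the horizon, or early only at a true fixed
  point (no free tissue site and no active cell), since transient fullness
  reopens through deaths.
* **Problem sizes.** The packaged analyses use a $20^3$ lattice over 504
  macro steps and five replicate seeds for the growth-curve studies, and
  small closed-form worlds (three-state decision process, $5^3$ diffusion
  block, bi-objective toy search) wherever an exact oracle exists.

# Session info

```{r}
sessionInfo()
```
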