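---
title: "Machine-guided transition path sampling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-guided transition path sampling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidedtps)
```

## The problem and the model

Rare molecular reorganization events — ion-pair formation, nucleation,
folding, dimer assembly — spend almost all simulation time waiting in
metastable states. The trajectory segments that actually cross between
two states A and B (transition paths, TPs) carry the mechanism, and the
committor $p_B(\mathbf{x})$, the probability that a trajectory launched
from configuration $\mathbf{x}$ with thermal velocities reaches B before
A, is the ideal reaction coordinate: it predicts trajectory fate in a
Markovian way.

`guidedtps` implements a closed learning loop around transition path
sampling (TPS):

1. **Sample.** Two-way shooting: pick a frame $\mathbf{X}_{SP}$ of the
   current TP, redraw Maxwell–Boltzmann velocities, propagate one trial
   forward and one backward in time until each commits to a state. If
   the two trials commit to different states they join into a new TP,
   accepted by a Metropolis rule.
2. **Learn.** Every trial trajectory is a Bernoulli observation: outcome
   $s_i = +1$ if it entered A first, $-1$ if B. With the committor
   modelled as $p_B = 1/(1+e^{-q(\mathbf{x}|\mathbf{w})})$, the negative
   log-likelihood of $k$ outcomes is
   $$l(\mathbf{w}|\theta) = \sum_{i=1}^k \log(1 + e^{s_i q(\mathbf{x}_i|\mathbf{w})}),$$
   minimized by full-batch Adam. For $N>2$ states the link generalizes
   to a softmax and the likelihood to a multinomial.
3. **Validate.** Before each shot the model's $p_B$ at the trial
   shooting point is recorded; for time-reversible Markovian dynamics a
   two-way shot yields a TP with probability $2p_B(1-p_B)$, so expected
   and generated TP counts over a sliding window of $k=100$ steps can be
   compared. The efficiency factor
   $\alpha_{\mathrm{eff}} = \min(1, (1 - n^{\mathrm{gen}}/n^{\mathrm{exp}})^2)$
   scales the learning rate ($\mathrm{lr} = \alpha_{\mathrm{eff}}
   \cdot 10^{-3}$, no training below $10^{-4}$): the model retrains only
   when its predictions fail, which protects against overfitting.
4. **Guide.** Shooting points are drawn from the Lorentzian selection
   density $p_{\mathrm{sel}}(\mathbf{x}|\chi) \propto 1/(q(\mathbf{x})^2 +
   \gamma^2)$, concentrating shots near the learned transition-state
   ensemble ($q=0$, where the reactive probability peaks at $1/2$) while
   $\gamma$ preserves exploration. The acceptance
   $p_{\mathrm{acc}} = \min(1, p_{\mathrm{sel}}(\mathbf{X}_{SP}|\chi')/
   p_{\mathrm{sel}}(\mathbf{X}_{SP}|\chi))$ keeps the chain unbiased;
   both densities are evaluated with the model frozen at move time,
   since the acceptance rule presumes a single selection density
   per move even though the model evolves between moves.
5. **Distill.** Permutation importance ranks the inputs; a $(N+1)$
   evolution strategy over expression trees searches for compact
   analytic expressions minimizing the same likelihood plus a complexity
   penalty $\lambda C$, and a Pareto front over (held-out loss,
   complexity) exposes the accuracy–simplicity trade-off.

## Study systems and their conditions

The built-in engines are deliberately minimal and treated as black
boxes, exactly as a molecular dynamics engine would be.

* `double_well_1d`: $U(x) = h(1-(x/x_0)^2)^2$ with $h = 4$, $x_0 = 1$.
  States are $x \le -0.9$ (A) and $x \ge 0.9$ (B). The default engine is
  overdamped Langevin (Euler–Maruyama) at $kT = 1$, friction 1, timestep
  $10^{-3}$: a $4\,kT$ barrier, high enough that shooting from a basin
  rarely produces a TP, low enough that trajectories commit in
  $\sim 10^2$–$10^3$ steps and a desk-scale run samples thousands of
  shots. The overdamped choice makes the exact committor available in
  closed form,
  $$p_B(x) = \frac{\int_a^x e^{U/kT}\,dy}{\int_a^b e^{U/kT}\,dy},$$
  (`analytic_committor_1d()`, quadrature via `stats::integrate` at
  relative tolerance $10^{-8}$; `analytic_committor_model()` caches it
  on a 513-point grid with monotone spline interpolation) so learned
  committors can be graded against an oracle.
* `two_channel_2d`: the same quartic profile in $x$ plus $c\,y^2$
  confinement and a Gaussian bump ($A = 3$, widths $0.5$) at the origin
  that forces crossings through two symmetric channels near
  $y \approx \pm 0.8$; run at $kT = 0.7$, where both channel barriers
  ($\approx 2.9$) are crossable but the central barrier ($\approx 5$) is
  not. This is the smallest system exercising multi-pathway clustering.
* Underdamped dynamics use velocity Verlet with per-step velocity
  randomization ($v \leftarrow e^{-\gamma\Delta t} v +
  \sqrt{(1-e^{-2\gamma\Delta t})kT/m}\,\xi$), the standard scheme for
  the named integrator contract; the suite checks equipartition of the
  stationary velocity distribution.

The backward trial of a two-way shot inverts momenta for underdamped
dynamics; for overdamped dynamics it is an independent forward
realization, valid by the time reversibility of overdamped equilibrium
dynamics. Velocities are fully redrawn at the shooting point (not
perturbed), which keeps the acceptance probability exact.
Uncommitted trials (a trajectory that exhausts `max_steps`, $10^6$ by
default) void the shot: the move counts as rejected and contributes no
training record; discarding is the disposal choice that cannot bias the
training set.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1 | Lorentzian exploration scale, in units of $q$; larger flattens selection toward uniform |
| `window` | 100 steps | validation window $k$ for expected/generated counts |
| `train_every` | 3 steps | gate cadence |
| `base_lr`, `lr_floor` | $10^{-3}$, $10^{-4}$ | learning-rate scaling of the gate |
| `train_epochs` | 5 | full-batch epochs per gated training event |
| `timestep` | $10^{-3}$ | reduced time units |
| `kT` | 1 | thermal energy; $\beta = 1/kT$ |

`train_epochs` deserves a note: production chains of $10^5$ steps can
afford one epoch per training event, but a desk-scale run of a few
thousand steps sees far fewer gate openings, so several epochs per event
are needed for the optimizer to actually reach the maximum-likelihood
solution within the shot budget. Five epochs per event is enough for the
1D study system and remains cheap.

The committor network is a pyramid: hidden widths decay geometrically
from the first block to the last with ratio
$f = (\mathrm{final}/\mathrm{input})^{1/(n_{\mathrm{blocks}}-1)}$, the
dropout schedule is $0.1 f^i$ when enabled, and the final layer is a
single linear neuron — the log-predictor. The toy systems use a small
`build_pyramid(16, 2, 8)` tanh network with zero dropout; residual and
self-normalizing variants of the production-scale architectures are out
of scope, the pyramid contract is what the package guarantees.
Transfer to a related system re-randomizes and retrains only that last
neuron (Adam at $2.5\times10^{-5}$, 20% held out, early stopping with
configurable patience — production patience of $10^3$ epochs is scaled
down to 200 in the defaults).

## Featurization

For point-cloud environments the package provides Behler-style symmetry
functions with a Fermi cutoff
$f_c(r) = [1+\exp(\alpha_c(r - r_{\mathrm{cut}} - 1/\sqrt{\alpha_c}))]^{-1}$
for $r \le r_{\mathrm{cut}}$ and 0 beyond. Two properties of these
definitions are implemented exactly as defined rather than "fixed":

* The $-1/\sqrt{\alpha_c}$ shift places the sigmoid midpoint beyond
  $r_{\mathrm{cut}}$, so $f_c$ has a small jump at the cutoff.
* The closed-form isotropic normalizer
  $V^{(2)}_{\mathrm{probe}} \approx 8\pi r_s^2\sqrt{2/\eta}$ is an
  approximation stated for small $\eta$; it does not coincide with the
  defining integral in general. `g2_normalizer_ratio()` reports the
  quadrature-to-closed-form ratio as a diagnostic, and a
  `method = "quadrature"` normalizer evaluates the defining integral,
  which is the normalization under which an ideal-gas cloud has unit
  mean by construction — the property-based test uses it for exactly
  that reason, and asserts nothing about the closed-form ratio.

The G5 pair normalizer uses
$V^{(5)} = 2^{1-\zeta} V^{(2)} (2\zeta-1)!!/\zeta!$ and the
$\langle N\rangle^2/2$ pair-count approximation, which is guaranteed
non-negative also below one expected atom. Angles are computed through a
clamped arccos for float safety; $\zeta$ is limited to even values up to
16 (the double factorial is evaluated iteratively). The rational
distance switch $(1-(r/R_0)^6)/(1-(r/R_0)^{12})$ is implemented in its
algebraically simplified form $1/(1+(r/R_0)^6)$, which removes the
removable singularity at $r = R_0$ (limit $1/2$) and is exact elsewhere.

## Symbolic distillation

Expression trees use protected operators: `log` of a nonpositive value,
division by $|d| \le 10^{-12}$ and invalid powers flag the record rather
than crash, and flagged records contribute a fixed finite penalty
($10^3$ per record) to the loss, so ill-defined expressions lose to
well-defined ones without producing infinities. Complexity counts every
operator node, including unary minus — the counting convention is not
universal, so it is fixed and documented here; under it the distilled
polymer-folding reference expression has $C = 7$. Constants are fitted
per candidate by BFGS from the current values (bounded random restarts
if the start is invalid), and the $(N+1)$ elitist selection makes the
best fitness monotone; because the search is seeded from the
closed-form best constant model ($q^* = \log(n_B/n_A)$), no result can
be less fit than that guard. Mutations are operator swaps, depth-limited
subtree replacement and constant perturbation/grafting; which random
structural changes to use is genuinely open, so the mutation kernel is
a package design choice. When held-out committor data are available the Pareto front is
drawn over validation loss; otherwise training loss is used. The knee is
the front point of maximal perpendicular distance to the endpoints'
chord after scaling both axes to $[0,1]$ — a suggestion, with the full
front always reported. The selection scale $\gamma$ is kept
constant per run; annealing it is a possible extension the package does
not take.

## What the synthetic generators emulate — and what they do not

`generate_logistic_records()` draws features and outcomes from a planted
committor through exactly the Bernoulli process the loss assumes, so
maximum-likelihood recovery of the planted parameters is a sharp test of
the estimator. `generate_shooting_table()` mimics an offline shooting
archive: points concentrated near the transition region, outcomes from
the analytic committor. `generate_planted_polylines()` plants two noisy
path bundles for clustering; `generate_point_cloud()` realizes the
ideal-gas reference of the symmetry-function normalizers.

What passing these tests does **not** show: the generators have
i.i.d. records, whereas real shooting outcomes from a TPS chain are
correlated through the chain (and the two outcomes of one two-way shot
are correlated for inertia-dominated dynamics — the likelihood
deliberately ignores this correlation, which is what licenses treating
each two-way shot as two records at the same features); the toy
potentials have none of the metastable intermediates, unassigned states
or feature noise of molecular systems. Conclusions about real systems
require the live validation loop, not the fixtures.

## Numerical and testing choices

* Problem sizes: the end-to-end committor-recovery run uses 5,000 MC
  steps on the 1D well ($\approx$ 10,000 training records); the
  detailed-balance check compares 500 decorrelated TPS path lengths
  (5,000 steps, every 10th — the chain holds a path over rejections, so
  consecutive steps are strongly correlated and a Kolmogorov–Smirnov
  comparison presumes approximately independent draws) against 500
  transitions excised from a single long equilibrium trajectory; the
  frozen-model self-consistency run uses 2,000 shots; symbolic-regression
  recovery uses 2,000 records, 200 generations, 4 offspring.
* The committor grid for oracle comparisons is the 9-point grid
  $x \in \{-0.8, -0.6, \dots, 0.8\}$, spanning committor values from
  $\approx 0.004$ to $\approx 0.996$.
* All randomness flows from explicit seeds; a master seed fans out to
  named sub-seeds (chain initialization, sampling, training) so modules
  can be re-run in isolation, and the compiled integrators draw from R's
  RNG so `set.seed()` governs everything.
* Degenerate inputs: empty clouds give $G^2 = G^5 = 0$; a constant
  feature column under min–max scaling maps to 0 with a warning; a zero
  expected TP count defines $\alpha_{\mathrm{eff}} = 1$ (maximal
  mismatch, logged); softening is refused when the model is
  uninformative ($p_B \approx 0.5$ at all probes).
* State softening replaces geometric states by committor iso-levels
  ($p_B \le 0.1$ / $\ge 0.9$ by default), which shortens TPs; softened
  states are evaluated on the R side in propagation chunks, geometric
  box states inside the compiled integrator.

## Known limitations

* The TPS backward trial for overdamped dynamics relies on time
  reversibility of equilibrium overdamped Langevin dynamics;
  non-equilibrium or irreversible engines would need a true backward
  propagator.
* DTW violates the triangle inequality; the clustering consumes the
  dissimilarity matrix as-is (average linkage by default — the linkage
  criterion and DTW step pattern are package defaults, not canonical).
* The multi-state (softmax) committor is implemented at the level of
  the link, loss and training; the sampling loop itself is two-state.
* Permutation importance splits credit between duplicated or strongly
  correlated inputs; rankings, not magnitudes, are what the distillation
  stage consumes.
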