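---
title: "Modelling competing homeostatic needs as diffusion on a shifting energy landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competing homeostatic needs as diffusion on a shifting energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(needscape)
```

## The model

A thirsty *and* hungry animal offered equally available water and food does
not dither between them, nor does it alternate trial by trial: it pursues one
goal persistently and switches at irregular, seemingly spontaneous moments.
`needscape` implements a minimal generative account of this behaviour.
A latent state $x \in \mathbb{R}^2$ — a coarse summary of need-related
neural population activity — diffuses over an energy landscape built from
three isotropic Gaussian wells (water, food, "other needs"):

$$U(x, t) = -\log\!\big(s\,T(t)\,\phi_w(x) + s\,H(t)\,\phi_f(x) + \phi_o(x)\big),$$

where $\phi_i$ is the bivariate normal density with centre $\mu_i$ and
covariance $\sigma^2 I$, $T(t)$ and $H(t)$ are the current thirst and hunger
magnitudes, and $s$ is a foraging weight scaling both reward needs relative
to the fixed "other" well. Raising a need deepens the matching well. The sign
convention (negative log of a positive mixture) is the one under which wells
are minima, barriers are positive, and the rate theory below is coherent; it
is fixed once here and used everywhere.

The state obeys overdamped Langevin dynamics, discretized by
Euler–Maruyama exactly as the model is defined — the discrete update *is*
the model, so no higher-order scheme is used:

$$x_{t+1} = x_t + \mathrm{d}t\, g\,(-\nabla U(x_t, t)) + \sqrt{\mathrm{d}t}\; n\, \mathcal N(0, I),$$

with gradient scale $g$, noise scale $n$ and step $\mathrm{d}t = 0.01$ s.
The plane is partitioned into three behavioural zones by the *unscaled*
densities (a maximum-likelihood rule; with a shared $\sigma^2$ this is a
nearest-centre rule). When a Go cue arrives, the zone containing $x$ is
emitted as the choice: water, food, or miss. A rewarded choice decrements
the matching need by a fixed reward size ($r_w = 0.006$, $r_f = 0.004$)
after a feedback delay $l$, and needs are clamped at zero. The delay default
is $l = 180$ s, the value in the model's published parameter list (the
surrounding text says "2 min"; we expose the parameter rather than silently
pick one reading).

Two things drive everything the package measures: the noise term makes
switching stochastic (larger $n$, more frequent switches), and the
need-scaled well depths tilt the switch rates as rewards are consumed.

## Closed-form theory

Between the two reward wells the model admits a two-state reduction. Escape
from a well is treated as a Kramers first-passage problem along the
inter-well axis, with friction $\gamma = 1$, thermal scale $K_bT = n^2$,
well frequency $\nu_A = 1/\sigma^2$ and transition-state frequency
$\nu_\ddagger = 2/\sigma^2$ (the saddle is approximated as twice as stiff as
a well, a fixed constant rather than a per-condition curvature):

$$\omega_{\mathrm{src}} \approx \frac{\sqrt{\nu_A \nu_\ddagger}}{2\pi\gamma}
\exp\!\left(-\frac{U^\ddagger - U^{\mathrm{src}}}{n^2}\right),$$

where $U^\ddagger$ and $U^{\mathrm{src}}$ are the $g$-scaled landscape
values at the saddle and the source-well minimum, located numerically on the
segment between the food and water centres (`barrier_heights()`). Solving
the two-state master equation with these rates gives the time-dependent
transition matrix (`transition_matrix()`), and equilibrium choice
probabilities come from zone-wise integrals of $e^{-g U(x)/n^2}$
(`boltzmann_choice_probs()`).

```{r theory}
geom <- well_geometry()
prm  <- default_params("behavior")
kramers_rates(1, 1, geom, prm)
transition_matrix(10, thirst = 1, hunger = 1, geom = geom, params = prm)
```

### Numerical choices

* **Stationary points.** The two well minima along the segment are its first
  and last *local* minima and the saddle is the maximum between them; each
  is refined to a $10^{-8}$ location tolerance (scalar path) or by bisection
  on the sign change of $\mathrm{d}m/\mathrm{d}\lambda$ (vectorized path
  used by the fitting engine). Local — not half-segment-global — minima
  matter: when one need is low its well is shallow, and the global minimum
  of that half-segment can sit on the far side of the saddle. If the wells
  have merged (one need near zero) the saddle coincides with the surviving
  extremum and the barrier is zero.
* **Quadrature.** Boltzmann integrals use a midpoint rule on cell centres
  over $[-25, 20] \times [-20, 20]$ ($\ge 5\sigma$ beyond every centre),
  default spacing 0.125, with an optional self-check that halving the
  spacing moves no probability by more than $10^{-4}$. Cell centres (not
  lattice points through $y = 0$) keep the water/food mirror symmetry exact,
  so $T = H$ gives exactly 0.5/0.5. The fitting engine uses spacing 0.25,
  which agrees with 0.125 to well under $10^{-4}$ per probability.
* **Zone ties.** Boundary ties resolve other-beats-reward (miss) and
  water-beats-food; measure zero, fixed for determinism.
* **Degenerate needs.** $T = H = 0$ is legal everywhere (only the "other"
  well remains); needs are clamped at zero after decrements so a reward
  delivered near satiation cannot invert a well.

## Fitting

`fit_landscape()` estimates $(g, n, s)$ from trial tables alone. Sessions
are reduced to three datasets: (i) consecutive rewarded choice pairs with no
miss between, scored by the transition matrix at their elapsed time and the
needs at the earlier reward; (ii) rewarded choices not adjacent to a miss,
scored by the two-zone equilibrium probability; (iii) near-satiation Go
trials (both behavioural needs $< 0.5$ — read as a conjunction, matching
"near satiation"), including misses, scored by the three-zone probability.
The loss is the sum of the three per-trial mean negative log-likelihoods.
Optimization is Adam at learning rate $0.1$ on $(\log g, \log n, \log s)$
(log-parameterization enforces positivity), with terms (ii) and (iii)
re-batched each epoch (default 1/50 of each set, floor 100 trials — at desk
scale the floor usually binds). The gradient is analytic throughout: the
pair term differentiates the rates with stationary-point locations held
fixed (exact, by the envelope theorem — including boundary-pinned locations
in degenerate geometries), and the Boltzmann terms differentiate the
quadrature weights; it matches central finite differences to $\sim 10^{-8}$
relative error. With stochastic batches the per-epoch improvement rarely
stays below the $10^{-6}$ tolerance for 50 straight epochs, so in practice
the epoch cap (default 400) ends the run; the trace is kept in the returned
object so convergence can be inspected.

The returned `needfit` object carries `coef()`, `predict()` (transition,
choice, and satiation probabilities), `simulate()` (forward sessions under
the fitted parameters), `summary()` and `plot()` (the optimization trace).
Residual methods are deliberately absent: the model is a generative
simulator scored through derived statistics, and no per-observation residual
is well defined.

## The synthetic assay

`generate_trial_schedule()` reproduces the task statistics: Go probability
0.67, inter-trial intervals uniform on $[2, 8]$ s plus a fixed 1.5 s
per-trial allowance (the maximum odour sampling time; the assay's trial-time
construction beyond its ITI distribution is not specified further, so the
allowance is fixed at the odour cap). `generate_dataset()` wraps the
simulator over (by default) 22 two-hour sessions — the size of the
behavioural dataset the model's published parameters were fitted to — with
initial needs drawn uniformly from $[0.8, 1.2]$, i.e. near 1 in units where
one water reward decrements thirst by $0.006$ (so a session collects roughly
the experimental number of rewards before satiation). Sessions end after 40
consecutive misses, the satiation criterion. It returns both the
experiment-format view (trial tables only) and a hidden ground-truth view
(trajectories, true needs, generating parameters) for recovery tests.

What the generator emulates: trial timing, need depletion with delayed
feedback, persistent bouts, stochastic switches, miss behaviour near
satiation. What it does not: lick kinematics, sensory errors early in
sessions, anticipatory or hysteretic need dynamics, inter-animal parameter
variability, or any feature of real neural recordings. Tests that pass on
generated data therefore validate the implementation and the model's
internal consistency, not the model's fidelity to real mice.

## Behavioural statistics

`behavioral_needs()` attaches the operational need measures: behavioural
thirst at a trial is the count of water rewards still to be collected in
that session, normalized by the dataset's median session total (hunger
analogously), and relative need is their normalized difference in
$[-1, 1]$ (undefined when both needs are zero; such trials are excluded
from need-conditioned analyses). One property of this definition deserves
emphasis: because it is computed from the session's own future outcomes, it
is mechanically correlated with upcoming choices even for need-blind
choice sequences. Null-hypothesis checks of the regression machinery must
therefore use exogenously assigned needs, and the package's tests do.

On top of the annotation sit the bout-persistence geometric fit
(`persistence_fit()`, MLE $\hat p = 1/\overline{\text{run length}}$ with
session-level bootstrap CIs — resampling sessions, the conservative level
for session-clustered data), the water-choice-versus-need regression with
5-percentile-bin MLE curves (`choice_probability_vs_need()`), per-choice
self-transition regressions with the fewer-than-10-remaining-rewards
exclusion applied to either reward type (`self_transition_regression()`),
the balanced-need Markov transition matrix (`transition_matrix_mle()`,
window $[-0.25, 0.25]$), switch probability versus inter-choice interval
with the theoretical overlay (`transition_vs_interval()`), an RBF-kernel
SVM comparison of needs versus previous choice as predictors of the
upcoming choice (`choice_predictor_comparison()`, cost 1, kernel width
scaled by total feature variance, 50% splits), kernel-density choice-time
analyses around stimulation epochs (`stim_choice_density()`, Scott's
bandwidth rule), and the goal-dimension analyses
(`goal_switch_analysis()`, `phase_portrait()`). The phase-portrait
transition zone defaults to half the distance from the midpoint to a well
projection (3.75 subspace units with the default geometry), and stay/switch
densities are resampled (default 1,000 draws) to a target switch fraction
so density comparisons are not biased by differing switch rates. All
statistics operate on plain session tables, so simulated and externally
recorded sessions flow through identical code paths.

## Perturbation experiments in silico

`simulate_opto_behavior()` models transient activation of thirst-sensing
neurons as a square wave added to $T(t)$ (default 10 s epochs, magnitude
18 — a detected-thirst magnitude about four times a daily water
restriction; needs enter the landscape logarithmically, so the gradient
effect is much tamer) in a hungry-only state ($H_0 = 0.5$,
$T_0 = 0.05$), with reward feedback off by default and the gradient scale
multiplied by 3.3, the published grid-search factor for the perturbation
analyses. `simulate_opto_prebehavior()` runs the same perturbation with no
trials at all ($T_0 = 0.8$, $H_0 = 2.25$; 25 epochs at 1-min spacing, 3
runs) and returns baseline-subtracted goal-dimension responses in 1-s bins
from $-10$ to $+20$ s around onset.

`simulate_forced_transition()` is the contrast class: noise reduced to
$n = 0.5$ (no spontaneous switches over a session), with transitions driven
by noise-free impulses at Poisson times. The magnitude question the model
statement leaves open — "sufficient to cross the saddle" — is resolved at
run time: each impulse carries the state along the goal dimension to a
configurable margin (default 1 unit) beyond the saddle projection, away
from the currently occupied well, so each impulse from within a well causes
exactly one switch. Phase portraits separate the two models cleanly:
diffusion switches launch from boundary-proximal positions, forced switches
from deep inside wells.

## Internal consistency, and its limits

The package ships an unusual negative result, established by its own
acceptance suite and worth understanding before trusting any one number.
The forward simulator and the closed-form theory are *both* faithful to
their published definitions, but they are not mutually consistent: the
discrete Langevin update has stationary density
$\propto e^{-2 g U/n^2}$, while the rate and equilibrium theory is built on
$K_bT = n^2$, i.e. $\propto e^{-g U/n^2}$, and its harmonic prefactor omits
the $g$-dependence of the landscape curvature. At the published parameters
the theory therefore under-predicts the simulator's switch rate by a factor
of $\approx 2.5$–4 (measured by first-passage Monte Carlo and by binned
zone-transition frequencies), and over-predicts miss-zone occupancy.
Consequences, all measured by the tests rather than asserted:

* simulated bout statistics under the published parameters are less
  persistent than the published behavioural values (geometric
  $\hat p \approx 0.21$ against 0.061; balanced-need repeat probability
  $\approx 0.78$–$0.81$ against $> 0.9$), while the need-to-choice
  regression slope *is* reproduced ($\approx 0.39$ against 0.426);
* fitting the theory-based likelihood to simulator output recovers $g$
  and $s$ but maps the noise scale to an effective
  $\hat n \approx 0.59\, n$ — the likelihood attributing the observed
  switching to a smaller temperature, exactly the fluctuation–dissipation
  factor at work;
* an effective noise of $\approx 1.66$ (with the published $g$ and $s$)
  makes the simulator reproduce all of the published behavioural statistics
  simultaneously, which suggests the parameter values were calibrated under
  a smaller effective temperature than the published update realizes.

The package keeps both components as defined — the simulator is the published
update, the theory is the published theory — and the acceptance suite reports
the disagreement honestly instead of re-scaling either side to force
agreement. Analyses that depend only on one side (all within-simulator
statistics; all within-theory predictions; parameter fits interpreted as
effective parameters) are unaffected.

## Known limitations

* The two-state theory ignores the miss zone entirely (pairs with
  intervening misses are excluded from fitting for the same reason); near
  satiation, where misses dominate, only the three-zone Boltzmann term
  carries information.
* The Kramers expressions assume deep wells; at the fitted parameters the
  inter-well barrier is below one thermal unit, so all rate-theory
  quantities are order-of-magnitude tools, not precise predictions — over
  and above the consistency issue described previously.
* Bootstrap CIs resample sessions; with few sessions (< 10) they are
  noticeably conservative.
* The fit treats trial pairs as independent (the behavioural Markov
  property); long-range dependencies, if present, are invisible to it.

## Problem sizes

Default test and verification scales, chosen so a laptop-class single CPU
completes the full suite comfortably: 22 sessions of 2 h for the
study-condition statistics; one 30,000 s fixed-need session for
theory-versus-simulation comparisons; 500 escape trajectories per condition
for first-passage rates; 300 Adam epochs for the recovery fit. All are
arguments, not constants.
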