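---
title: "Hierarchical motor adaptation: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical motor adaptation: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the task and its force environments, the two learning models and their
hierarchical extensions, the behavioral metrics and statistics, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the problem left them open.

## The task and its force environments

A planar reach from a start circle to a target 150 mm ahead (radius
7.5 mm), to be completed in roughly 400 ms. Coordinates are meters,
origin at the start, +y toward the target. Four force fields act on the
hand (`field_spec()`/`field_force()`):

* **VDCF** — velocity-dependent curl, `F = B1 [−ẏ, ẋ]`. Work-free,
  strongest mid-reach where speed peaks, negligible near the endpoint:
  it bends the path but does not induce target errors.
* **LIPF** — linearly increasing position-dependent field,
  `Fx = −K1 y`. Maximal at the target: it induces failures.
* **PSPF** — positively skewed position-dependent field,
  `Fx = −K2 (cos(π + 40y) + 1)/(π + 40y)⁵`, evaluated with `y` in meters
  and the argument in radians. Under this (literal) reading the printed
  gain `K2 = 20868` N/m produces order-1 N forces peaking before
  mid-reach and under 0.05 N at both the start and the target — a
  position-dependent field that does *not* induce target errors.
* **CPVF** — the LIPF term minus the VDCF term, with the printed minus
  sign kept verbatim even though it reverses the curl direction relative
  to the plain VDCF; a TE-inducing combination.

Two further elements define the task mechanics. The **endpoint lock**
(`endpoint_lock_spec()`), a stiff 500 N/m / 50 N s/m spring-damper,
engages permanently at the first sample where hand speed drops below
20 mm/s, anchoring at the position at engagement: it defines the movement
endpoint and forbids corrective sub-movements. The **partial error clamp**
(`channel_spec()`) is a one-dimensional spring-damper channel toward the
straight line, active only for y > 75 mm, so endpoint errors are
suppressed while the mid-reach lateral deviation stays free. The
experimental clamp is 800 N/m / 45 N s/m; the model simulations use their
own published constants (1500/100 for the point-mass model, 2500/1000 for
the arm model). All three parameter sets are plain configuration; none is
privileged.

## Behavioral metrics

`target_error()` is the signed x-deviation of the endpoint — the position
at the first sample where hand speed falls below 20 mm/s (the same rule
that triggers the lock; first-crossing semantics are used throughout
because the online device latches at first crossing). `lateral_deviation()`
is the signed x at the first crossing of y = 75 mm, linearly interpolated.
Trials whose reach distance is under 75 mm are invalid (LD undefined) and
excluded. `resample_x_at_y()` samples x on the 16 reporting positions from
7.5 to 150 mm. Epoch summaries use the six canonical windows (1st, 3rd–5th
and last-20 trials of each phase). Participant screening requires the
last-20 baseline |LD| mean below 4.5 mm (strict); the instability rule
flags a participant with at least three sign-crossing LD jumps above
20 mm over the last 100 washout trials *and* a last-20 LD mean beyond
3 group standard deviations. A "jump across the x-axis" is operationalized
as a consecutive-trial sign change with |ΔLD| > 20 mm, which the source
description leaves informal. Note a small-sample fact the tests respect:
a single outlier can exceed 3 in-group standard deviations only when the
group is larger than about 11 (the deviation is bounded by
(n−1)/√n) — the rule is meaningful at the reported group size of 14,
not in toy groups.

## The optimal feedback control model

The arm is a unit point mass whose actuated force is a first-order lag
(40 ms) on the motor command; the state is (position, velocity, actuated
force, 1), the trailing constant carrying target and feedforward terms.
The controller is a finite-horizon discrete LQR (10 ms steps, 400 ms
movement + 50 ms hold) for the *internal model* of the dynamics: the null
plant augmented with the predicted external force `F̂ = αD x̂`, where `D`
is the force matrix of the trained field and `α ∈ [0, 0.8]` is
internal-model knowledge. The skew field has no linear state
representation, so its prediction enters as a time-varying feedforward
along the nominal straight reach. Simulation is noise-free with a
certainty-equivalent (full, noiseless observation) estimator; errors arise
purely from model–plant mismatch. Past the policy horizon a stationary
hold regulator (converged Riccati iteration on the terminal stage cost)
keeps the hand at the target until the endpoint lock engages — without
it, the one-step terminal gain has no position authority and strongly
perturbed reaches run away instead of settling.

Stage costs: accuracy terms (position error to the aimed target, velocity,
actuated force) at and after the movement time, with weights calibrated
once so the null reach is straight, 150 mm, essentially complete at
400 ms, and ends inside the target; a control cost `uᵀRu` whose scale puts
the nominal reach's realized objective just below the 0.01 gate (below);
and a running path-regularization term — the same perpendicular projector
`Q_d` as the bias term, with constant weights — standing in for the arm
impedance the point mass lacks. Without that term the LQR has no
mid-reach lateral authority and the end-loaded field drives the mass off
the workspace. The flat variant is the hierarchical cost with the plan
pinned straight; the two variants therefore coincide exactly whenever no
failure occurs, which is itself one of the tested signatures.

**The hierarchical layer.** The plan is an aim direction at angle `φ`
(clockwise positive, degrees). It enters the cost twice: the printed
exponentially decaying bias term
`exp(-t/τ)(k_p pᵀQ_d p + k_v vᵀQ_d v)` (`k_p = k_v = 0.5`, `τ = 130` ms),
and a rotation of the terminal accuracy target to the aimed direction.
The second element is a design decision: the bias cost alone penalizes the
path but cannot move the *endpoint* (the terminal cost always pulls to the
unrotated target), so the update law would wind `φ` up indefinitely
without reducing the target error. Treating the plan as the aimed
movement direction — which is how the hierarchical layer is described —
gives the geometric response (≈ 2.6 mm of endpoint shift per degree) under
which the update `φ' = 0.95 φ − 0.85 θ` contracts in a few trials. `θ` is
the signed endpoint direction error (clockwise positive, so it shares the
sign of TE for this geometry).

**The cost gate.** On successful trials an active bias decays
(`φ' = 0.95 φ`) until the *motor cost of the generated reach* falls below
0.01, after which the decay stops permanently. The motor cost is the full
realized objective (state cost plus `uᵀRu`): in the null field an aimed
reach costs the same control effort as a straight one (it is just a
rotated reach), so a control-only cost cannot distinguish plan-aligned
reaching from reaching in conflict with the clamp, and the clamp
condition would not wash out. With the full objective, the clamp's
plan-vs-channel conflict keeps cost above threshold until the plan has
decayed, while in the free null field the cost drops once the
after-effect fades, freezing the bias while it is still several degrees
from zero — the persistent curved null trajectory. Frozen failures still
update the bias (with retention 1), which contracts it to just inside the
failure boundary; this attractor, not fine timing, sets the final
deviation.

**Learning schedule.** `α` rises 0 → 0.8 over the 155 adaptation trials as
`0.8·log(log i + 1)/log(log 155 + 1)` (natural logarithms; both bases give
monotone schedules). During washout `α` returns from 0.8 to 0 over 30
trials; de-adaptation is much faster than adaptation, so the decreasing
reading `0.8·(1 − log(log(i−155)+1)/log(log 30 + 1))` is used (the printed
de-adaptation formula increases over that window, contradicting the
accompanying text; the text is followed). From trial 186 on, `α = 0`.

## The V-shaped learning model

A two-joint planar arm (standard human segment parameters; shoulder at the
origin, reaching from (0, 350) to (0, 500) mm) driven by six muscles
(shoulder, elbow, and biarticular antagonist pairs) with constant moment
arms; muscle lengths are linear in joint angles, so the muscle-space error
is `E = λ − λ₀ = −A(q − q_des)`. Tension is feedforward command plus tonic
co-activation plus feedback: instantaneous viscoelasticity, a delayed
(60 ms) stretch reflex, and a co-contracting component proportional to the
mean absolute delayed error — the within-trial analog of the V-shaped
law, which also makes average tension an honest effort signal when
fighting a perturbation. Viscoelastic and reflex gains scale with each
muscle's drive: co-contraction buys impedance. This is essential, not
cosmetic: the V-shaped law raises activation for *both* error signs, and
if co-contraction bought no impedance the antagonist pumping would grow
without bound. Tensions are rectified at zero. Integration is
semi-implicit Euler at 1 ms; trials run 700 ms so perturbed reaches can
settle and the endpoint lock can engage.

**Learning.** Across trials,
`u'(t) = [u(t) + Δu(t + ϕ)]₊` with
`Δu = α_l [ε]₊ + β_l [−ε]₊ − γ_l` and `ε = E + g_d Ė`; the phase advance
`ϕ` equals the reflex delay (one shared constant). The increment is
smoothed over 100 ms before application: muscle activation is
band-limited, and unsmoothed increments interacting with the phase
advance build a backward-travelling oscillatory wave in the command that
pumps tension indefinitely. The printed law fixes no gain values; the
defaults (`α_l = 7000`, `β_l = 100`, `γ_l = 3.5` N per trial, `g_d =
0.08` s) were chosen once, jointly with the tension scale, so that
(i) learning converges within the session on all fields, (ii) washout is
complete to sub-millimeter lateral residuals in the flat model (the
deactivation-to-gain ratio `γ_l/α_l` is the learning deadzone, whose
hand-space image bounds the residual), and (iii) the deactivation —
which is the *only* mechanism that lowers commands — unlearns an adapted
field within the washout phase. The initial feedforward is the rigid-body
inverse dynamics of the desired motion distributed over antagonist pairs
by rectified assignment; the tonic co-activation is applied at execution
time rather than stored in the learned command, so deactivation cannot
erode the tension baseline against which the cost gate is scaled.

**The hierarchical layer.** The plan is the lateral deflection `dx` of the
via-point at 120 mm of a minimum-jerk desired trajectory, updated by
`dx' = 0.95 dx − 0.45 TE` on failures and decaying on successes with the
same structure and gating as the aim bias, with the gate at an average
muscle tension of 350 (the cost is the mean tension across the six
muscles over the movement). As with the aim bias, the deflection is a
change of planned movement *direction*: the plan's endpoint is shifted
laterally by the same `dx` as the via-point. A via-only bulge leaves the
desired endpoint fixed, cannot move the realized endpoint, and sends the
update law into windup until the inverse kinematics leaves the workspace.
The deflection saturates at 24 mm, which keeps plans reachable and —
because the plan-induced TE then cannot overshoot the decaying
after-effect — avoids spurious sign-flipped failures during early
washout. The tension scale (`t_coact = 327` N per muscle) places the
converged null reach just below the 350 gate while field fighting and
washout transients sit above it; the gate's placement relative to these
regimes is exactly what the threshold's original calibration — chosen to
produce experiment-like curved null trajectories — encodes.

## What the simulations do and do not show

Both models, in both variants, are run through the same schedule: 155
adaptation trials in the condition's field, then 150 washout trials in
the null field (or under the clamp for the clamp condition), with the
simulation field gains (point-mass model: curl 7 N s/m, end-loaded
120 N/m; arm model: curl 20 N s/m, end-loaded 120 N/m). The tested
contrasts are qualitative and differential, deterministic given the
configuration:

* flat variants: monotone LD decay, complete washout, no LD sign
  reversal — and failure to produce any persistent null-trajectory
  change;
* hierarchical variants: early LD sign reversal, fast monotone TE
  recovery into the target, a persistent final null LD above 2 mm, and
  clamp-driven restoration of the baseline path;
* on the curl field no failure ever occurs, the plan never activates, and
  the two variants coincide trial for trial.

Magnitudes (first-trial TE near −110 mm for the end-loaded field,
persistent LD of 2–3 mm, clamp washout under 1 mm) are in the range of
the reported group data, but only the signs, orderings and
threshold-crossings above are treated as claims; the models are
calibrated, not fitted.

## Synthetic data and parameter recovery

The generator (`gen_te_series()`, `gen_trajectory_dataset()`) is
phenomenological — fixture machinery, not a third model. Participants
draw an adaptation drive from the reported first-trial TE distribution
(112.6 ± 38.0 mm, n = 15, pushing −x); each trial's TE is drive plus the
latent deflection plus Gaussian noise, the deflection follows the
retention/sensitivity recursion, and washout flips the drive to the
after-effect scaled by the reported ratio (44.3/112.6). Trajectories are
a minimum-jerk forward profile (400 ± 50 ms over 150 mm) with a
two-basis lateral expansion solved so the measured TE and LD reproduce
the generated series; short-reach trials and an unstable participant can
be injected to exercise the exclusion and screening rules. The generator
reproduces the statistical structure the analysis assumes — first-trial
moments, recursion dynamics, exclusion edge cases — and nothing else: no
within-trial feedback corrections, no muscle-level structure, no
between-trial autocorrelation beyond the recursion. Passing tests on
generated data therefore validate the analysis plumbing, not any claim
about real reaching data. `fit_update_rule()` recovers (b, r) by least
squares on the linear recursion; recovery is exact on noiseless data and
accurate to better than 0.02 at 1 mm trial noise over 150 trials.

## Statistics

`t_one_sample_summary()` recomputes t statistics directly from printed
(mean, sd, n) triples — the three recomputable values match the printed
ones to their printed precision. `rm_anova_gg()` is the one-way
repeated-measures ANOVA with the Box/Greenhouse–Geisser epsilon (the
sample covariance estimator; the Huynh–Feldt variant is not offered
because only the former is used in the reporting being mirrored) and
partial eta squared; `tukey_pairwise()` uses the studentized range on the
within-participant error term. Degenerate inputs are defined: identical
conditions give F = 0; zero-variance summaries warn and return an
infinite statistic; missing cells are an error. Under null simulation all
implemented tests hold the nominal 5% level within [0.03, 0.07]; the
Greenhouse–Geisser correction is mildly conservative at small n, which is
why calibration is checked at the experiment's group size (n = 15).

## Numerical choices and limitations

Problem sizes were chosen so the whole test suite and the acceptance
script each run in a couple of minutes: 305-trial schedules, 10 ms control
steps for the point-mass model, 1 ms integration for the arm, 100-seed
recovery studies, 2000-replicate calibration. Known limitations: both
models are noise-free, so trial-to-trial variability, signal-dependent
noise, and stochastic policy effects are out of scope; the arm model's
muscle parameterization is a standard simplification (constant moment
arms, linear lengths); the clamp-condition contrast depends on the cost
gate's placement between the converged and fighting tension regimes, a
calibration the source itself describes as chosen to reproduce the
persistent null trajectory; and the failure boundary makes a few
late-adaptation endpoints graze the 7.5 mm radius by a fraction of a
millimeter, which the tests treat as inside-the-target behavior.
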