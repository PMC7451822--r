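---
title: "An actor-critic model of escape-avoidance learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An actor-critic model of escape-avoidance learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidrl)
```

## The task

A rat in an operant chamber undergoes 12 acquisition sessions of 25
trials. Each trial opens with a *danger period* (75-dB tone, maximum 72 s):
a lever press here — an **avoidance** — skips the shocks and starts the
inter-trial interval. Otherwise a *shock period* begins (footshocks at one
per 3.5 s, at most 20); a press — an **escape** — terminates it, with the
press's own timestep still carrying the shock it experienced. Either way a
fixed 180-s *ITI* follows under a safety signal (flashing light). Sessions
open with 60 s of *habituation* (chamber only) and close with a *homecage*
block representing the overnight interval: no tone, light, shock, or
lever, conventionally 500 timesteps.

Behavior is discretized to 12-s timesteps. Each frame carries five binary
stimulus indicators — danger signal (DS), safety signal (SS), shock (Sh),
chamber (chamb), homecage (home) — and a binary press indicator. A press
anywhere within a 12-s step counts as a press in that step; presses during
habituation are *anticipatory responses* (ARs) and presses during the ITI
are *inter-trial responses* (ITRs), recorded but without effect on phase
progression. At 12-s resolution the timings become exactly 5 habituation
steps, at most 6 danger steps, at most 6 shock steps (20 shocks × 3.5 s =
70 s spans six steps; the step and shock caps coincide, and whichever is
reached first ends the period), and 15 ITI steps; `task_config()` enforces
these second-count identities so any alternative discretization still
describes the same task. The shock bit of a step is 1 whenever at least
one scheduled shock falls inside it (`shocks_in_step()`).

## The model

The learner is an actor-critic over the 5-dimensional binary stimulus
vector $x_t$. The critic holds weights $v$ with state value
$V(x) = \sum_i v_i x_i$; the actor holds weights $m_{a,i}$ for the two
actions $a \in \{\mathrm{OTHER}, \mathrm{PRESS}\}$. Both are linear, so
overlapping stimuli (danger + chamber) sum — this matches the per-stimulus
layout of the fitted-weight output files. Action choice is a softmax over
propensities with a perseveration bonus on the previously emitted action:

$$P(a_t = a) \propto \exp\!\Big\{\mathrm{B}\big[\textstyle\sum_i m_{a,i}
x_{t,i} + P\,\mathbf{1}(a = a_{t-1})\big]\Big\}$$

Scaling the bonus by the exploitation parameter $\mathrm{B}$ makes
$\mathrm{B} = 0$ exactly uniform — a clean analytic anchor used by the
tests (negLLE $= T \ln 2$ over $T$ observed steps). Reinforcement is
per-timestep: $r_t = R_\mathrm{shock}\,x_{t,\mathrm{Sh}} +
R_\mathrm{press}\,\mathbf{1}(\text{press})$, both non-positive; one
$R_\mathrm{shock}$ per shock-bit step rather than per 0.5-s pulse, because
the data are binary per step. The TD error
$\delta_t = r_t + \gamma V(x_{t+1}) - V(x_t)$ (with $V \equiv 0$ past the
final frame) updates the critic for every active stimulus,
$v_i \mathrel{+}= \alpha\,\delta_t\,x_{t,i}$, and the actor for the chosen
action only, $m_{a_t,i} \mathrel{+}= \varepsilon\,\delta_t\,x_{t,i}$.
Update order per step: observe the frame, compute probabilities, take (or
read) the action, compute $r_t$ from the frame's shock bit and the action,
form $\delta_t$ against the next frame's stimuli, update, remember the
action.

The seven parameters and defaults where applicable:

| parameter | meaning | range |
|---|---|---|
| $\alpha$ | critic learning rate | $[0,1]$ |
| $\varepsilon$ | actor learning rate | $[0,1]$ |
| $\mathrm{B}$ | exploitation/exploration | $\ge 0$ |
| $R_\mathrm{shock}$ | subjective shock value | $\le 0$ |
| $R_\mathrm{press}$ | press effort cost | $\le 0$, fixed at $-0.05$ |
| $P$ | perseveration bonus | real |
| $\gamma$ | discount factor | $[0,1]$ |

$R_\mathrm{press}$ is held constant (the fitted model variant does not
search it), but it is an explicit, configurable setting
(`model_parameters()`, `grid_spec(r_press = )`) rather than a hard-coded
constant, since its published value is stated only as "held constant". The
previous action is *not* reset at session boundaries: 500 homecage steps
of forced `OTHER` intervene anyway, so by the first chamber frame of the
next session the distinction is immaterial; this was the simplest
convention.

Avoidance learning emerges without any positive reward: shocks drive
$V(\mathrm{Sh})$ and then, through $\gamma$-chaining, $V(\mathrm{DS})$
negative; a press in danger leads to the relatively safer ITI state, so
its TD error is positive and $m_{\mathrm{PRESS},\mathrm{DS}}$ grows —
escape is learned first, avoidance second, as in real acquisition curves.

## Likelihood and fitting

`neg_log_likelihood()` replays a dataset once: every chamber frame
contributes $-\log P(\text{observed action})$ under the current policy,
after which the agent is updated with the observed action. Homecage frames
drive updates (forced `OTHER`, $r = 0$) but are excluded from the sum by
default: no behavior was recorded in the homecage, and the files' zero
press bits there are placeholders, not observations. Because the original
convention is not documented, `include_homecage_ll = TRUE` is exposed
rather than guessed at.

Fitting is exhaustive grid search, faithful to the estimation procedure
the output format documents (per-parameter min/max/step columns):
`enumerate_grid()` lists the Cartesian product lexicographically in the
fixed order $\alpha, \varepsilon, \mathrm{B}, R_\mathrm{shock}, P,
\gamma$; `fit_grid()` evaluates negLLE at every point and keeps the first
minimum in enumeration order (a deterministic tie-break), then replays the
optimum to report the final M- and V-weights. Grid values are generated by
index ($\min + k\cdot\mathrm{step}$, rounded at the 12th decimal) so no
accumulation error creeps into the value sets and written parameter files
round-trip exactly. The published grid bounds are not in the text, so the
defaults are a deliberate desk-scale choice: $\alpha, \varepsilon \in
[0.05, 0.25]$ step $0.05$; $\mathrm{B} \in [1, 9]$ step 2;
$R_\mathrm{shock} \in [-3, -0.5]$ step $0.5$; $P \in [0, 1]$ step $0.25$;
$\gamma \in [0.5, 0.95]$ step $0.15$ — 15000 points, a few seconds per rat
with the compiled replay core.

Two independent routes guard the implementation: a pure-R replay built
from the exported agent primitives (`engine = "R"`) is tested for
equality against the compiled engine, and the batch grid scan is tested
against a stored per-point scan's argmin.

## Simulation and scoring

`simulate_run()` runs the generative loop: actions are sampled from the
softmax and *drive* the task's phase machine, so avoiders see short trials
and non-pressers see full shock periods. One code path scores both
simulated and empirical-format data (`score_frames()`): outcome per trial
(`A` if any danger-frame press, else `E` if any shock-frame press, else
`.`; a trial with both a danger press and shock frames is an error, since
an avoidance makes shocks impossible — a guard on the simulator/scorer
contract), ARs per session, ITRs per trial split into three one-minute
bins (ITI steps 1–5, 6–10, 11–15), and avoidance percentage per session.
`simulate_rat()` repeats this (conventionally 100 runs), deriving per-run
seeds from the master seed through R's RNG so runs are independent but
exactly reproducible. Simulated experiments include the homecage blocks
between sessions, matching the estimation design (configurable through
`task_config()`).

## Synthetic cohorts and parameter recovery

`make_cohort()` emulates a two-strain cohort at desk scale: 10 rats per
strain (the empirical design had 40 per strain; 10 keeps recovery studies
in minutes), each rat's true parameters drawn within one grid step of its
strain center and therefore exactly on the search grid. The centers are a
faster-acquiring strain (α = 0.15, ε = 0.15, B = 5, R_shock = −1.5,
P = 0.25, γ = 0.80) and a slower one with stronger shock aversion and
perseveration and a shorter horizon (α = 0.10, ε = 0.10, B = 3,
R_shock = −2.0, P = 0.50, γ = 0.65) — both behaviorally plausible
learners, chosen a priori as the cohort's study conditions. The truth
table is written in the parameter-listfile format so recovery doubles as
an I/O integration test. `recovery_fractions()` scores the fraction of
rats within a given number of grid steps of truth per parameter.

What the generator does *not* emulate: sensor noise, missed sessions,
drifting motivation, or any behavior outside the model class. Passing
recovery therefore demonstrates that the estimation machinery is correct
and that the parameters are identifiable from model-generated behavior at
this data size — not that the model captures every feature of real rats.

## Numerical choices and limitations

- Softmax terms are computed overflow-safely (max-subtraction in R;
  `log1p(exp(·))` softplus in the compiled core), so extreme
  $\mathrm{B}$ values degrade gracefully to 0/1 probabilities.
- negLLE is accumulated in double precision; the analytic
  $T \ln 2$ anchor is met to ~1e-13 relative error on full-length data.
- Degenerate inputs: an empty dataset has negLLE 0 with a fresh agent;
  `p(observed) = 0` can arise only from infinite propensities, which the
  validity checks reject.
- CSV round-trips are exact for parameters and grid columns (short
  decimals by construction); free-form doubles (weights, negLLE) round-trip
  through decimal text to ~1e-15 relative.
- The grid is exhaustive, not adaptive: cost is the product of the value
  counts, and fine grids get expensive; the compiled core handles ~5e7
  frame-updates per second on one CPU.
- Only the constant-press-cost model variant is implemented; eligibility
  traces, more than two actions, and hierarchical/Bayesian fitting are out
  of scope.

## Problem sizes used in the shipped checks

Unit tests run on down-scaled configurations (2–3 sessions, 3–10 trials,
20–30 homecage steps) that preserve the within-session timing structure.
The end-to-end checks use the full task (12 × 25, 500 homecage steps):
100-run simulations, a 729-point stored-scan comparison on three synthetic
rats, and a 20-rat recovery study on the default 15000-point grid — about
a minute of compute in total.
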