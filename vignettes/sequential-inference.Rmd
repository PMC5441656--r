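---
title: "Windowed sequential inference for probabilistic reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed sequential inference for probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqinfer)
```

## The model

The task has a hidden binary context $x_t \in \{1, 2\}$ (which stimulus
dimension is rewarded), a compound cue $y_t \in \{1, 2\}$, a binary action
$a_t$ and binary feedback $o_t$ (1 = gain). The agent's generative model is a
two-state hidden Markov model: the context repeats with probability $1 - r$
and reverses with probability $r$, and feedback is veridical with probability
$v$ (the cue validity): $P(o_t = 1 \mid x_t, a_t, y_t) = v$ when the action
is correct for the context/cue pair ($a = x$ for $y = 1$, $a = 3 - x$ for
$y = 2$) and $1 - v$ otherwise. Choices follow a softmax on the *predictive*
context belief with precision $\gamma$; for cue $y = 1$,
$P(a = i) \propto \exp\{\gamma\, P(x_t = i \mid o_{1:t-1})\}$, and the
complement for $y = 2$. $\gamma = 0$ is random choice.

A filtering agent (S1) maintains only $P(x_t \mid o_{1:t})$. The sequential
models S2–S5 instead maintain the joint posterior over a window of the $n$
most recent states,

$$P(x_{t-n+1}, \dots, x_t \mid o_{t-n+1}, \dots, o_t, x_{t-n}),$$

conditioned on a belief about the single state preceding the window. The
window needs $2^n$ sufficient statistics, which is why only short orders
(1–5) are practical — and the behavioural evidence this package is designed
to assess concerns precisely such short windows.

## Boundary semantics of the window

The windowed posterior is conditioned "on the last state preceding the
sequence", which leaves one genuine design choice open: *which* belief over
$x_{t-n}$ to condition on. `seqinfer` freezes it as the marginal of the
oldest in-window state at the moment that state is evicted, taken from the
previous trial's posterior joint. After eviction, the joint over the retained
states is rebuilt by re-multiplying, in order, each retained trial's stored
likelihood factor against the boundary-propagated prior, and the window is
then extended for the new trial.

This choice is deliberate and is what makes the model family behaviourally
interesting. The evicted-state marginal is a *one-step-smoothed* belief: it
already reflects outcomes that are then re-applied inside the rebuilt window.
Recent evidence is therefore weighed against an already-informed boundary,
which produces the two signature phenomena of the family (at $r = 0.05$,
$v = 0.8$):

* after a true reversal, the current-state belief of higher-order models
  crosses 0.5 at least as fast as filtering;
* a single misleading outcome inside a stable block moves the order-2 belief
  strictly less than the filtering belief.

The rejected alternative is the textbook fixed-lag smoothing recursion
(evict–extend–update without re-application). It is exact for
$P(x_{t-n+1:t} \mid o_{1:t})$, but its current-state marginal provably equals
the plain filter's, so all orders would make identical choices and the model
family would collapse. The implementation therefore does *not* use it; the
enumeration oracle in the test suite pins down the intended semantics
instead.

While the window is still filling ($t \le n$) the joint covers every state
so far, conditioned on a uniform belief over a notional $x_0$; inference is
then exact full-history smoothing, and the test suite checks this against
direct enumeration over all $2^t$ paths.

## Parameters, priors and defaults

| Parameter | Meaning | Support | Prior (MAP) |
|---|---|---|---|
| $r$ | subjective per-trial reversal probability | $[0,1]$ | Beta(1.1, 1.1) |
| $v$ | cue validity (veridical-feedback probability) | $[0,1]$ | Beta(1.1, 1.1) |
| $\gamma$ | softmax precision (inverse temperature) | $\ge 0$ | $\ln\gamma \sim N(1, 0.25)$ |
| $\varphi,\ \alpha_g,\ \alpha_l$ | delta-rule learning rates | $[0,1]$ | Beta(1.1, 1.1) |

$r$ is the *reversal* probability: the transition matrix has $1 - r$ on the
diagonal. Group-level summaries that describe a stable environment as having
a high value are on the complementary scale $1 - r$; all code in this package
uses the transition-matrix convention consistently.

The synthetic-data generator's default agent parameters are $r = 0.05$,
$v = 0.8$ — a mostly stable world with informative feedback, the same regime
used for the belief-trace simulations — and $\gamma = e \approx 2.72$, the
centre of the $\ln\gamma$ prior. The precision of a simulated agent is not
pinned down by the belief dynamics (beliefs are $\gamma$-free), so the prior
centre is the least arbitrary single value; it yields cohorts with roughly
75–80% correct choices, comparable to human performance on this task.

## The task generator

`generate_session()` emulates the experimental design: 128 trials in 4
sessions (one continuous run for modelling purposes — neither the latent
context, the agent's beliefs, nor the trigger window reset at session
boundaries), feedback veridical with probability 0.85, and
performance-triggered reversals: when the gain proportion over the 10 most
recent outcomes *strictly* exceeds 0.80 (i.e. at least 9 of 10), a reversal
is scheduled at a uniform lag of 1–3 trials. The trigger counts gains, not
correct responses, following the task description literally. On scheduling,
the trailing gain window is reset and further triggers are ignored while a
reversal is pending, so a single good run cannot cause two back-to-back
reversals; this reproduces the roughly even spacing of reversals in the
original design. Cues are i.i.d. uniform by default, with an exactly
balanced-per-session option; the initial context is a fair coin.

What the generator does *not* emulate: stimulus rendering, the young/old
category structure beyond its 1/2 coding, response times, and the 1–7 s
jittered intervals (irrelevant to choice modelling). Simulated "subjects" are
the models themselves with homogeneous parameters — passing recovery tests
therefore demonstrates internal consistency and identifiability of the
pipeline under the task's design, not that human subjects use these
strategies; real cohorts are heterogeneous in parameters and strategy, and
their data enter through `read_trials()`.

## Action-value baselines

Q1 updates only the chosen $(y, a)$ value toward the reward
($R \in \{0, 1\}$) with rate $\varphi$. The task makes $(y{=}1, a{=}1)$ and
$(y{=}2, a{=}2)$ logically equivalent bets, so Q2 and Q3 update all four
pairs per trial: the chosen pair and its logical twin move toward $R$, the
two mirrored pairs toward $1 - R$. Each pair uses its own prediction error
against its own target (the update pattern is not spelled out in the source
description; recomputing per-pair errors is the choice that keeps every
update a convex step, hence values in $[0, 1]$, and preserves within-cue
value sums of 1). Q3 applies $\alpha_g$ after gains and $\alpha_l$ after
losses to all four updates, since one feedback event has one valence. Values
initialise at the indifference point 0.5 and outcomes map to rewards as
$o = 1 \mapsto 1$, $o = 2 \mapsto 0$.

## Fitting and model comparison

MAP estimation maximises the log posterior with Nelder–Mead on transformed
coordinates (logit for rates, log for $\gamma$); the objective is evaluated
in natural space with no Jacobian correction — the transform is purely a
search mechanism, so the optimum is the natural-space MAP. Multi-start
(default 10 restarts: one canonical start, the rest drawn from the priors
under a fixed seed) with a relative objective tolerance of $10^{-6}$; fits
are deterministic given the seed. Exact evaluation on a rate's support
boundary returns $-\infty$ by contract; the optimizer never lands there
because the logit transform keeps the search interior.

Because precision trades off against the other parameters, the cohort-level
procedure is two-pass: fit everyone with $\gamma$ free, clamp $\gamma$ to the
group mean of the estimates (in natural space — the plain "group mean"
reading), and refit with one fewer free parameter. The per-subject BIC
comparison between passes is reported. Free-parameter counts after fixing:
2 for S1–S5 ($r, v$), 1 for Q1/Q2 ($\varphi$), 2 for Q3
($\alpha_g, \alpha_l$).

Model evidence per subject is summarised by
$\mathrm{BIC} = 2\,\mathrm{LL} - k \ln n$ (larger is better), and
$\mathrm{BIC}/2$ enters random-effects Bayesian model selection as the log
evidence. The group analysis is the variational Dirichlet scheme: iterate
responsibility and concentration updates to a $10^{-6}$ change, with a
uniform Dirichlet prior ($\alpha_0 = 1$ per model, the standard choice).
Exceedance probabilities use the exact Beta CDF for two models and
Monte-Carlo Dirichlet sampling otherwise (default $10^6$ draws, seeded).
Pseudo-R² is McFadden's measure against the coin-flip baseline
$n \ln 0.5$ — the standard choice for binary choice models.

Per-subject measures: $\Delta LL$ is the log-likelihood (not BIC) advantage
of the best of S2–S5 over S1 — after $\gamma$-fixing all S-models share $k$,
so the distinction is immaterial, but log-likelihood is the defining scale —
and $L$ is the order of the BIC-best sequential model, ties broken toward the
shorter window. Bayesian parameter averaging weights each model's $r$ and
$v$ estimates by the subject's posterior model probabilities; these are
computed as the softmax of the subject's $\mathrm{BIC}/2$ values under a
uniform model prior (the BMS responsibilities are also exposed, as an
alternative weighting).

## Numerical choices

Beliefs are kept in linear space with renormalisation after every operation:
with at most $2^5 = 32$ joint entries and likelihood factors bounded away
from 0 for interior $v$, there is no underflow risk in these parameter
ranges, and linear space keeps the recursion transparent. The boundary
belief is renormalised at every step. Joint indexing places the oldest state
in the most significant bit position (state 1 ↔ bit 0). Equality of the
recursion with the enumeration oracle is asserted to $10^{-10}$. Degenerate
inputs: $v = 0.5$ makes feedback uninformative (beliefs never move),
$r = 0.5$ erases history at every step, and $\gamma = 0$ yields the exact
chance log-likelihood $n \ln 0.5$ — all used as closed-form test anchors.

## Problem sizes in the test suite

The recovery experiments in the tests and acceptance script use 30-subject
cohorts at the task's 128-trial length (10 replicate cohorts per generating
model), 512-trial cohorts (3 replicates) for the saturated-selection check,
and 20 replicates of 512 trials for parameter recovery, with 3–5 optimizer
restarts in cohort settings where the warm-started second pass makes larger
restart counts redundant. These sizes were chosen to estimate the relevant
proportions and medians stably.

## Known limitations

* **Asymmetric identifiability.** An order-2 model can imitate filtering
  almost exactly by lowering its cue validity (double-counted evidence at
  reduced $v$ mimics single-counted evidence at the true $v$), while
  filtering cannot imitate a genuinely sequential agent. Model recovery for
  filtering-generated cohorts is therefore intrinsically harder than for
  sequential generators at 128 trials — visible in the recovery confusion
  matrix — though selection saturates with more trials. This mirrors the
  one-sided nature of the scientific question: evidence *for* sequential
  inference is diagnostic, evidence against it is weaker.
* The generative world model is itself Markovian; the package dissociates
  *inference strategies*, not non-Markovian environments.
* No perseverance/choice-kernel parameters, no hierarchical (empirical
  Bayes) fitting, and no continuous or more-than-binary state spaces.
* The Dirichlet exceedance Monte-Carlo error ($\approx 10^{-3}$ at the
  default draw count) is negligible for selection but visible if results
  are compared across seeds at more decimal places.
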