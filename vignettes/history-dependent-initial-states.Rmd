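---
title: "History-dependent initial states in evidence accumulation: model, likelihood, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{History-dependent initial states in evidence accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histddm)
library(ggplot2)
```

## The scientific problem

Two suboptimalities pervade two-alternative perceptual decisions in trained
animals: *history biases* (the previous trial's choice and outcome leak into
the current decision) and *lapses* (asymptotic errors that persist at the
easiest stimulus strengths). They are usually modeled as unrelated nuisance
processes. This package implements and tests a single mechanism that
produces both: an accumulation-to-bound decision process whose **initial
state** is updated from trial to trial by exponentially filtered
choice-outcome history. Large initial-state excursions do not merely shift
the psychometric function laterally; they also flatten its effective slope,
so pooling trials with heterogeneous initial states produces heavy-tailed
psychometric curves whose logistic fits report *apparent lapses* - errors
that look evidence-independent but are in fact deterministic consequences
of history.

The package provides, as testable code:

1. the history filter and its constrained variants (`history_params()`,
   `initial_state_sequence()`, `dbm_constrain()`);
2. the closed-form drift-diffusion choice probability and the pooling
   argument (`choice_prob_analytic()`, `pooled_psychometric()`);
3. a Fokker-Planck likelihood engine for pulsatile (Poisson clicks)
   evidence with sensory adaptation and sticky bounds
   (`fokker_planck_evolve()`, `choice_likelihood()`,
   `first_passage_density()`);
4. true-lapse mixtures (motor error, inattention, hybrid) and the joint
   choice/reaction-time likelihood with Wald non-decision times
   (`true_lapse_prob()`, `joint_choice_rt_likelihood()`);
5. maximum-likelihood fitting and per-trial BIC model comparison
   (`fit_mle()`, `bic_compare()`), psychometric analysis
   (`fit_psychometric()`, `modulation_metrics()`), and a closed-loop
   synthetic-session generator (`simulate_agent_session()`).

## Model

### Across trials: the history filter

Each choice-outcome pair $h \in \{Rw, Lw, Rl, Ll\}$ (right-win, left-win,
right-loss, left-loss) owns an exponential filter $i^h$ that decays by
$\beta^h \in [0,1)$ every trial and is incremented by $\eta^h$ when $h$ was
observed:

$$i^h(n) = \beta^h i^h(n-1) + \eta^h \, \mathbb{1}[o_{n-1} = h], \qquad
I(n) = \sum_h i^h(n).$$

$I(n)$ is the accumulator's starting value on trial $n$; positive values
favor the rightward bound. Violation trials (broken fixation: no choice, no
outcome) carry no update information; by default the state is *frozen*
across them (no decay, no increment), with a `violation_mode = "decay"`
alternative, since the data cannot distinguish the two readings.

Three parameterizations are supported. The side-constrained form used for
fitting ties the loss updates across sides ($\eta^{Rl} = \eta^{Ll}$,
$\beta^{Rl} = \beta^{Ll}$ - with a *common sign*, i.e. a side-independent
loss effect) and the win timescales ($\beta^{Rw} = \beta^{Lw}$), leaving 5
free history parameters. The `dbm` reduction (2 parameters) ties all decays
and all increment magnitudes with the sign set by the side the update
favors - the rewarded side: right-wins and left-losses both push toward
the rightward bound. This is the exponential-filter approximation of the
Dynamic Belief Model's Bayesian update under unsignaled prior switches.

### Within a trial: accumulation of clicks

Evidence arrives as two Poisson click trains. Accumulated evidence $x(t)$
obeys

$$dx = \lambda x\,dt + \left(\epsilon_R C_R \xi_R - \epsilon_L C_L \xi_L\right) dt
+ \sigma_a\, dW, \qquad x(0) = I(n),$$

frozen once $|x| \ge B$ (sticky bounds). Each click's magnitude $C$ is
depressed (or facilitated) by sensory adaptation, $C \mapsto \phi C$ at
each click with exponential recovery to 1 at timescale $\tau_\phi$; a
click's own jump applies *after* its magnitude is read (the ODE form makes
the jump a consequence of the click; a `jump = "before"` flag provides the
alternative). Adaptation starts fully recovered at stimulus onset
($C(0)=1$) and resets between trials. Per-click sensory noise is
multiplicative: $\xi \sim \mathcal{N}(1, \sigma_s^2)$, so a click of
adapted magnitude $C$ contributes mean $\pm C$ and variance $C^2\sigma_s^2$
- stated explicitly because implementations of this model family differ on
this point. In the fixed-duration task a rightward choice is reported when
$x(T) > \mathrm{bias}$ (ties split evenly, by symmetry); in the
reaction-time task the decision time is the bound-hitting time.

### True lapses and the mixture

On a fraction $\kappa$ of trials the choice bypasses accumulation:

* **motor** - rightward with fixed probability $\rho$ (history-independent);
* **inattention** - deterministically the side favored by the initial
  state relative to a criterion $\rho$ (so even evidence-independent
  choices inherit history);
* **hybrid** - a sigmoid $1/(1+e^{-m(I-\rho)})$ bridging the two; note
  $\rho$ is a probability for the motor variant but a criterion in
  initial-state units otherwise.

The trial's rightward probability is
$(1-\kappa) P_{\mathrm{acc}} + \kappa P_{\mathrm{lapse}}$.

### Reaction times

Non-decision times are Wald (Inverse-Gaussian) first-passage draws with
side-specific bounds $\omega_k$ and drifts $\nu_k$; the effective drift
declines linearly with trial number ($\alpha$) and increases after errors
($\gamma_o$), capturing the within-session slowing and post-error slowing
that appear only in RTs. The joint likelihood of an observed (choice, RT)
marginalizes the first-passage density of the observed choice over decision
times $\tau \le RT$, weighting by the NDT density of the residual
$RT - \tau$; on lapse trials the RT is an NDT draw alone. Accumulator mass
still unabsorbed at the evaluation horizon is treated as *censored* (it
contributes no density) rather than renormalized - the joint density then
integrates to $(1-\kappa)(1-\mathrm{survivor}) + \kappa$, which the tests
verify. In the reaction-time task the stimulus stops at the response, so
recorded click trains end at the RT and clicks after the decision time
never enter the likelihood.

## Numerical methods

**Fokker-Planck solver.** $P(x(t))$ lives on `n_bins` interior bins
spanning $(-B, B)$ plus two sticky absorbing states at $\pm B$. A
click-free transition step projects each source bin's step Gaussian
(mean $x + (\lambda x + \mu)\,dt$, variance $\sigma_a^2 dt$) onto linear
hat functions over the node set $\{-B, c_0, \dots, c_{n-1}, B\}$. Three
accuracy devices matter:

* *hat projection* preserves the distribution's mean exactly at any noise
  level, including sub-bin drift in the near-deterministic limit;
* the projection adds exactly $dx^2/6$ of variance per step, so the step
  Gaussian's variance is shrunk by that amount (second-moment matching);
* a *Brownian-bridge crossing correction* reallocates interior-to-interior
  mass to the bounds with probability
  $\exp\!\left(-2(B \mp x)(B \mp y)/\sigma_a^2 dt\right)$, removing the
  $O(\sqrt{dt})$ absorption bias of end-of-step monitoring.

Clicks are applied at the end of the step containing them, as
position-independent Gaussian "kicks" realized by one shared convolution
kernel; clicks sharing a step are applied sequentially in time order with
absorption checked in between (merging them into one Gaussian measurably
distorts absorption when $\sigma_s$ is large relative to $B$). Mass is
conserved to machine precision at every step. With the default single-trial
grid (201 bins, 2 ms) choice probabilities agree with the closed form to
well under $10^{-3}$ in click-free regimes and are stable to $<10^{-3}$
under refinement on click trials.

**Particle oracle.** An independent Euler-Maruyama simulator (1 ms steps,
Brownian-bridge barrier test between steps, clicks at step ends) provides
stochastic cross-checks of the grid solver and powers the synthetic-data
generator. For the *constant-drift* checks of the closed-form choice
probability the bridge correction makes the discretized simulation exact in
distribution up to double-crossing terms ($\sim e^{-4B^2/\sigma^2 dt}$,
negligible), so the oracle uses 10 ms steps there - strictly more accurate
per sample than a fine uncorrected step, and what makes million-path
comparisons affordable.

**Likelihood and fitting.** The Fokker-Planck propagator is linear, so for
fixed accumulator (and NDT) parameters one *adjoint* (backward) pass per
trial yields the trial's likelihood as a function of the initial state
over the whole grid; the forward and adjoint paths agree to machine
precision and both are exposed. `fit_mle()` exploits this: history and
lapse parameters - which only move $I(n)$ and the mixture - are optimized
in a fast inner loop (Nelder-Mead; multi-start with seeded jitter on the
first outer iteration, warm-started afterwards), while accumulator-level
parameters are profiled in an outer loop (Brent when one, Nelder-Mead when
several). Box bounds (defaults: $B \in (0.5, 10]$,
$\lambda \in [-5,5]\,s^{-1}$, $\beta \in [0, 0.999]$,
$\kappa \in [0, 0.5]$, variances capped at 25) are enforced by penalty.
Fitting uses a reduced grid (51 bins, 10 ms) whose parameter estimates on
synthetic benchmarks match the generative values well inside the $\pm 20\%$
recovery band; single-trial quantities default to the finer grid. The
4-parameter logistic psychometric fits ($\kappa_0, \kappa_1 \in [0,1]$)
maximize the Binomial likelihood by box-constrained quasi-Newton from five
deterministic starts including a logistic-regression warm start. Per-trial
BIC is $(k \ln N - 2 \ln L)/N$ over non-violation trials.

## The synthetic-data generator

`simulate_agent_session()` is a first-class module, not a fixture: it runs
the *same* generative model the likelihood describes, closed-loop (the
agent's realized choices and outcomes drive its own history filter). Tasks
emulated:

* **fixed-duration**: two Poisson streams summing to 40 Hz, rate ratios
  drawn from $\{39{:}1,\ 26{:}14,\ 23{:}17\}$ and their reciprocals,
  rewarded side and difficulty sampled independently, 0.5 s stimuli,
  reward to the side with more clicks;
* **reaction-time**: stimulus plays until the response; reward follows the
  greater generative *rate*; RT = bound-hitting time + Wald NDT; recorded
  clicks truncate at the RT; the first 50 trials of real sessions are
  dropped by the QC stage, mirroring warm-up effects.

The task family's descriptions fix the stimulus statistics but not the
agent's generative constants, so defaults were chosen once to land in the reported
behavioral regime and then left alone: accumulator
$\sigma_a^2 = 1,\ \sigma_s^2 = 1.5,\ B = 3,\ \phi = 0.8,\ \tau_\phi = 50$
ms, history $\eta^{Rw} = -\eta^{Lw} = 0.8$, $\eta^{Rl} = -\eta^{Ll} = -0.3$
(win-stay / lose-shift), $\beta^w = 0.7$, $\beta^l = 0.5$, motor lapses at
$\kappa = 0.05$. This yields $\approx 0.78$ accuracy and
$P(\text{repeat}\,|\,\text{win}) \approx 0.58$ in fixed-duration sessions,
the regime typical of trained rat cohorts on this task family
($\approx 0.79$ accuracy with a clear win-stay tendency). The
reaction-time agent uses stronger updates ($\eta^w = \pm 1.2$,
$\eta^l = \mp 0.5$), consistent with the clearer history signatures seen
with reaction-time reports ($\approx 0.75$ accuracy; we obtain
$\approx 0.73$ and a robust error-vs-correct RT gap of $\approx 20$ ms). NDT defaults
($\omega = 2, \nu = 10$: mean 200 ms, SD 45 ms) are typical rodent
non-decision latencies.

What the generator does *not* emulate: violation-rate dynamics, satiation
or other session-boundary nonstationarities beyond the NDT trial-number
drift, and changepoint structure across sessions. Passing tests therefore
certify internal consistency of simulator and likelihood, oracle-level
numerical correctness, and recoverability under the model's own
assumptions - not robustness to the un-modeled features of real data.

## What the benchmarks check

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R`) covers, at desk scale:

* closed-form choice probabilities against $10^6$-path simulation on a
  $5\times5$ (drift, initial state) grid, each cell within 3 Monte-Carlo
  SE;
* the Fokker-Planck engine against particle simulation (choice
  probabilities and passage-time quantiles) and against the two-boundary
  constant-drift first-passage series within $10^{-3}$ sup-norm;
* the lapse-free logistic reduction at $I = 0$ (fitted lapses
  $< 10^{-3}$);
* apparent-lapse emergence (pooled fitted lapse rate $\approx 0$ at
  $\eta = 0$, non-decreasing in $|\eta|$) and threshold/lapse-rate
  comodulation across a 20-agent cohort. The $\eta$ grid spans
  $[0, 0.45]$ with $B = 1$: within the regime where initial states do not
  saturate at the bounds, which is where the theory's pooling argument -
  and the 4-parameter logistic description itself - is meaningful;
* parameter recovery on 20,000-trial synthetic sessions
  ($\eta^{Rw}, \eta^{Lw}, \beta^w, B, \kappa$ within $\pm20\%$ or 0.05
  absolute in $\ge 8/10$ seeds);
* per-trial BIC preferring history-dependent initial states on
  $\ge 9/10$ history-generated rats and rejecting them on $\ge 9/10$
  history-free rats;
* the three reaction-time signatures: faster errors than corrects, faster
  responses to history-consistent stimuli after wins, and repetition bias
  concentrated in the fastest RT quantiles (vanishing gap without history
  updates);
* normalization: the joint choice-RT density integrates to 1 within
  $10^{-3}$ on a fixture trial, and Fokker-Planck mass balance holds to
  $10^{-10}$.

Problem sizes (trials per synthetic rat, particle counts, grid
resolutions) are the package's benchmark choices: large enough for the
stated tolerances to be meaningful, small enough to run on a laptop.

## Worked example

```{r example, eval = FALSE}
cfg <- task_config(n_trials = 5000)
sim <- simulate_agent_session(cfg, default_agent(cfg), seed = 3)

# history-conditioned psychometrics
hp <- history_psychometric(sim$session)
hp$modulation
autoplot(hp)

# fit the accumulator model with and without history-dependent
# initial states, compare by per-trial BIC
spec_h <- model_spec(free = c("eta_Rw", "eta_Lw", "beta_w", "bound", "kappa"),
                     fixed = c(eta_loss = -0.3, beta_loss = 0.5, rho = 0.5))
fit_h <- fit_mle(sim$session, spec_h, grid = fp_grid(51, 0.01), seed = 1)
spec_0 <- model_spec(with_hist = FALSE, free = c("kappa", "rho"))
fit_0 <- fit_mle(sim$session, spec_0, grid = fp_grid(51, 0.01), seed = 1)
bic_compare(fit_h, fit_0)
```

## Known limitations

* Constant bounds only: collapsing-bound policies and urgency signals are
  out of scope, as is across-trial drift-rate variability (whose RT
  signature - slow errors - is the opposite of the initial-state
  signature this model captures).
* The inner/outer fitting split assumes the accumulator-level free set is
  small (1-3 parameters); profiling many accumulator parameters at once
  falls back to Nelder-Mead and is slow.
* The stimulus-strength axis for psychometrics is the click-count
  difference (fixed-duration) or a smoothed log count ratio (reaction
  time); the underlying generative rates of real sessions are not part of
  the session format, so rate-based axes must be supplied externally.
* `fit_mle()` fits one parameter set per session table; hierarchical
  (shared-across-subject) structure and Bayesian posteriors are not
  implemented.
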