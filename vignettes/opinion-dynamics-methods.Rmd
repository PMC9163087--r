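---
title: "Models and methods: echo chambers and the random dynamical nudge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: echo chambers and the random dynamical nudge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnudge)
```

`rdnudge` simulates two agent-based models in which echo chambers — clusters
of agents who interact almost exclusively with like-minded peers, producing a
bimodal opinion distribution — emerge from the interaction rules alone, and
implements the *random dynamical nudge* (RDN): a stochastic per-agent input
built from randomly sampled peer opinions, intended to prevent echo chambers
from forming or to dissolve existing ones. This vignette documents the
models, every tunable that matters, the numerical choices, and what the
simulations do and do not establish.

## The activity-driven model

Each of `N` agents carries an unbounded opinion $x_i(t)$ whose sign is a
stance and whose magnitude is conviction. Opinions evolve by explicit Euler
integration of

$$\dot x_i \;=\; -x_i \;+\; K \sum_{j} A_{ij}(t)\,\tanh(\alpha x_j)\;+\;D\,\mathcal R_i,$$

where $A_{ij}(t) = 1$ records an input from agent $j$ to agent $i$ during the
current step, $K$ is the social interaction strength, $\alpha$ the
*controversialness* of the issue (the gain of the saturating influence: for
large $\alpha$ even mild opinions push with near-maximal force), and
$D\,\mathcal R_i$ the optional nudge.

The temporal network is activity-driven. Each agent has a fixed activity
$a_i \in [\varepsilon, 1]$ drawn once per run from the truncated power law
$F(a) \propto a^{-\gamma}$ (defaults $\gamma = 2.1$, $\varepsilon = 10^{-2}$),
sampled by inverse transform (`sample_activities()`); most agents are rarely
active, a few are very active, mirroring the skew of posting rates on
social platforms. At each Euler step an agent activates with probability
$a_i$ and contacts `m` distinct partners drawn without replacement with
homophilic weights

$$p_{ij} \;\propto\; |x_i - x_j|^{-\beta},$$

each contacted partner contributing a $j \to i$ input; with probability `r`
the contact is reciprocal and $i \to j$ is recorded too. With probability
`p_opp` an activation flips the sign of $\beta$, making the agent
preferentially contact *opposed* peers.

Key defaults follow the study conditions: `N = 1000`, `m = 10`, `K = 3`,
`alpha = 3`, `beta = 3`, `r = 0.5`, `T = 10`, `dt = 0.01`.

### Choices the equations do not fix

* **Activation semantics.** `activation_mode = "per_step"` (probability
  $a_i$ per Euler step) is the default; the alternative reading
  `"rate_times_dt"` (probability $a_i\,\mathrm dt$) is provided. At these
  parameters the rate reading generates so few interactions on $t \in [0,30]$
  that the decay term sends every opinion to zero; the per-step reading
  polarizes on that timescale, which is the regime the model is meant to
  exhibit, so it is the default.
* **Distance floor `delta`.** The weights $|x_i-x_j|^{-\beta}$ diverge as
  opinions coincide. With a floor of essentially zero the kernel degenerates:
  inside an opinion cluster the single nearest neighbour receives
  $10^{9}$-fold more weight than a peer $0.1$ away, so contacts collapse onto
  a handful of hubs and most agents are starved of input. The default
  `delta = 0.1` — 10% of the initial opinion scale — treats smaller
  differences as socially indistinguishable, so contact weight is shared
  within a cluster while the power-law decay still governs meaningful
  distances. The floor is a config field; setting it very small restores the
  winner-take-all behaviour.
* **Initial opinions** are uniform on $[-1, 1]$: symmetric around the
  neutral consensus and matching the scale on which the confidence and
  homophily parameters are quoted.
* **Stability guard.** The run aborts with a diagnostic if any $|x_i|$
  exceeds $10^6$; instability should surface, not overflow silently.
* **Trajectory stride.** Opinions are recorded every 0.1 time units to bound
  output size; metrics evaluated "at time t" use the nearest recorded
  snapshot.

## The nudge family

`nudge_config()` selects the form of $\mathcal R_i$. The reference form is
CLT-scaled:

$$\mathcal R_i \;=\; \sqrt n\,\bigl(\langle X_n\rangle_i - \langle X\rangle\bigr),$$

each agent's own fresh sample mean of `n` opinions against the exact
population mean, scaled so its spread approaches the population spread of
opinions independently of `n`. Variants drop the scaling, replace the
population mean by a second sample, compare two single opinions, or show a
single signed opinion; `shared_sample_mean` makes one draw per step shown
identically to everyone (the control that fails: a shared pull acts like a
single central influencer), and `wiener` is per-agent Brownian noise (an
external-noise baseline that is not a feedback mechanism). Sampling is
without replacement within one draw, excludes the receiving agent's own
opinion by default, and is independent across agents and steps. The
population mean is recomputed exactly every step. For `single_opinion` the
tabulated "±" sign is read as a fresh equal-probability sign per draw;
`sign_mode = "positive"` gives the unsigned reading. In the
sample-against-sample variant the single opinion and the sample mean are
independent draws; either reading of whether $X_1$ belongs to the sample is
zero-mean, and the package uses the independent one. The Wiener process is
per-agent and independent — consistent with the finding that only *unique*
per-agent inputs depolarize. The nudge enters the Euler update multiplied by
`dt` like every other term; an Euler–Maruyama $\sqrt{\mathrm dt}$ scaling was
evaluated and rejected because the CLT-scaled noise amplitude tracks the
opinion spread, making that scaling self-amplifying to overflow within a few
time units.

## The selective social-influence model

The second model is message-based. `N` agents sit on a directed follow graph
with exactly `E` edges. One agent per time step is selected uniformly; it
sees a screen of the `m` most recent messages posted or reposted by accounts
it follows, moves toward the mean of *concordant* messages — those with
$|x_i - x_j| < \epsilon$, strictly — by a fraction `mu`, posts (probability
$1-p$) or reposts a concordant message (probability $p$, the repost carrying
the original opinion value), and with probability `q` rewires one follow edge
away from a discordant message's poster to a uniformly chosen new account.
Defaults are the study conditions: `N = 100`, `E = 400`, `m = 10`,
`eps_conf = 0.5`, `mu = 0.5`, `p = 0.5`, `q = 0.5`, 5000 steps.

Decisions worth knowing:

* **Decay-free update map.** The per-activation map is
  $x_i \leftarrow x_i + \mathrm{dt}_{sel}(\mu\,\overline{\Delta x} + D\mathcal R_i)$
  without a $-x_i$ term. With the decay term at unit step size every
  self-consistent cluster contracts to zero, which contradicts the
  persistent nonzero chambers this model is known to produce;
  `include_decay = TRUE` gives the literal continuous-time form.
* **Empty concordant set.** The social normalization is undefined when no
  screen message is concordant; the opinion is then left unchanged by the
  social term.
* **Nudge ordering.** The selected agent receives its nudge *before* the
  concordance test: in the underlying differential form the indicator
  evaluates the nudge-influenced opinion. The nudge therefore also acts when
  the screen is entirely discordant. This ordering is what allows the nudge
  to bridge otherwise-discordant clusters at all.
* **Recency and ties.** Screen recency is global posting order, newest
  first; the board is pre-seeded with one message per agent so early screens
  are not empty.
* **Runaway detection.** A run is flagged unstable and truncated when any
  single update changes an opinion by more than `instability_jump` (default
  1) within a trailing `instability_window` (default 10 steps). Single jumps
  that large occur only once the opinion spread has self-amplified — the
  cluster-variance balance
  $\sigma^2 \approx D^2\sigma_{pop}^2 / (1-(1-\mu)^2)$ crosses the
  $\epsilon/2$ cohesion limit near $D \approx \mu/2$ — so the detector flags
  genuine runaway rather than benign nudge jitter.

## Polarization metrics

`peak_distance()` implements the peak-distance statistic $\Lambda_x$: split
opinions at zero, histogram each side with bin width
$w = \min\bigl(\tfrac{\max x_R - \min x_R}{\log_2 n + 1},\; 2\,\mathrm{IQR}\,n^{-1/3}\bigr)$
(Sturges vs Freedman–Diaconis, computed on the subset itself — `n` is the
subset size, the standard usage of both rules), and return the distance
between the two maximal-density bin centers. Ties break toward zero, which
under-reports polarization; if either side holds under 1% of agents the
distribution is one-sided and $\Lambda_x$ is flagged undefined rather than
zero, so radicalized runs are not mistaken for depolarized ones.

`count_peaks()` counts local maxima of a Gaussian kernel density estimate
whose topographic prominence exceeds 10% of the maximum density. The
bandwidth defaults to the Sheather–Jones plug-in (Silverman fallback):
range- or IQR-based bandwidths are inflated by the heavy conviction tails of
the activity model and demonstrably smooth away a genuinely bimodal bulk
(camps at $\pm 0.5$ with a two-fold central dip count as one peak at the
histogram-rule bandwidth). Both the bandwidth and the prominence threshold
are arguments.

`classify_state()` operationalizes the three end states: *radicalized* when
at least 90% of agents share one sign and the median magnitude exceeds 0.5,
*polarized* when there are at least two peaks and a defined peak distance
above 0.5, otherwise *consensus*. `nn_mean_opinion()` (interaction-weighted
mean opinion of the agents one heard from) and `in_degree_summary()` expose
the network-level echo-chamber diagnostics.

## Experiments

`experiment_spec()` + `run_experiment()` execute Cartesian parameter sweeps
crossed with replicate seeds; per-run seeds derive deterministically from
the master seed, sweep-point index and replicate index via a fixed modular
hash, so a result table is reproducible row by row. `preset()` encodes the
figure-level protocols (prevention from the start, homophily flipping,
Wiener baseline, shared-versus-unique nudges, delayed on/off windows,
robustness grids, the selective-model grid) at desk scale: presets default
to 3–5 replicate seeds where the original protocols used up to 20 trials;
`n_seeds` raises them. The tests and the acceptance script use `N = 1000`,
`T = 10`–`20` activity runs and 5000-step selective runs — the published
study conditions — with 5–10 seeds per condition.

## What the simulations show — and what they do not

Within this implementation, at the study conditions: homophilic
activity-driven runs form two symmetric opinion camps with a central dip and
classify as polarized, non-homophilic runs radicalize to a single stance,
the activity sweep never produces more than two peaks, and the CLT-scaled
nudge at $D = 3$ reliably merges the two peaks into one both when applied
from the start and when switched on at $t = 10$. In the selective model the
defaults produce two (sometimes three) chambers, a specific instance flips
to a single peak under the $D = 0.2$, $n = 1$ nudge, delayed nudging merges
chambers only slowly and in a minority of seeds, and $D \ge 0.3$ runs
dissolve into an unstable smear.

Two behaviours fall short of the motivating account. First, after nudging,
the per-side histogram argmax tends to move *outward* even as the two peaks
merge: the depolarized bulk is broader than the pre-nudge camps are far
apart (camps sit at roughly $\pm 0.5$–$0.8$ here), so $\Lambda_x$ often
rises where the peak count falls; depolarization in this package is
therefore best read from `count_peaks()`/`classify_state()`, with
$\Lambda_x$ as a secondary measure. Second, the selective-model nudge at
$D = 0.2$ prevents chamber formation in only a minority of seeds rather
than most; the per-update displacement the printed parameters allow
(stationary deviation about 0.13) is small against the bounded-confidence
radius, and the acceptance suite records this gap honestly rather than
retuning the conditions.

These are simulations of deliberately minimal models. Agents exchange a
single scalar opinion with no content, expertise weighting, or
platform-algorithmic mediation; activities are static; the synthetic
networks have no community structure beyond what the dynamics create.
Passing tests establish internal consistency with the model definitions and
the qualitative phenomena above — not that a deployed intervention on a real
platform would behave comparably.
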