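# rdnudge

Agent-based opinion dynamics for studying **echo chambers** and a family of
**random dynamical nudge (RDN)** interventions that aim to prevent or
dissolve them.

On polarizing issues, social-media users preferentially interact with
like-minded peers, and opinion distributions split into two camps with a
depleted middle. `rdnudge` implements two minimal models in which this
happens endogenously, plus the intervention and the metrics needed to
evaluate it:

* **Activity-driven model** — `N` agents with power-law activities
  `F(a) ∝ a^(-γ)` on `[ε, 1]` form a temporal interaction network with
  homophilic contact probabilities `p_ij ∝ |x_i − x_j|^(−β)`; opinions follow

  ```
  dx_i/dt = −x_i + K Σ_j A_ij(t) tanh(α x_j) + D·R_i
  ```

  with interaction strength `K`, controversialness `α`, reciprocity `r`, and
  an optional nudge `D·R_i`. Homophily (`β > 0`) polarizes the population
  into two camps; indiscriminate mixing (`β = 0`) radicalizes it onto a
  single stance.

* **Selective social-influence model** — agents on a directed follow graph
  exchange messages; one agent per step sees a screen of its followees'
  `m` most recent messages, moves toward the mean of *concordant* messages
  (those within a bounded-confidence radius `ε`), reposts or posts, and may
  rewire away from discordant posters. Echo chambers emerge from influence
  plus unfollowing.

* **The RDN** — each agent receives its own stochastic input built from
  randomly sampled peer opinions; the reference form is the CLT-scaled
  `R_i = √n (⟨X_n⟩_i − ⟨X⟩)`, with simpler variants (unscaled, sample vs
  sample, pair difference, single opinion, a shared-mean control, and a
  Wiener-process baseline) available via `nudge_config()`.

* **Metrics** — peak distance `Λx` (distance between the maximal-density
  histogram bins on either side of zero, with the min(Sturges,
  Freedman–Diaconis) bin rule), prominence-based peak counting on a kernel
  density estimate, nearest-neighbour mean opinion, in-degree summaries,
  and a consensus/polarized/radicalized end-state classifier.

* **Experiment runner** — `preset()` + `run_experiment()` rerun the
  figure-level protocols (prevention, delayed on/off depolarization,
  robustness sweeps over `D × α × K × β`, the selective-model grid) as
  seeded sweeps returning tidy tibbles, with CSV/JSON outputs and a thin
  CLI at `exec/rdnudge`.

## Worked example

A homophilic activity-driven run at the standard conditions polarizes; the
same run with a CLT-scaled nudge of strength `D = 3` ends unimodal:

```r
library(rdnudge)

run <- run_activity_model(activity_config(seed = 1))
run
#> <activity_run> N=1000 T=10 beta=3 K=3 alpha=3 nudge=none D=0 seed=1
#>   final state: polarized
glance(run)
#> # A tibble: 1 × 14
#>   lambda_x n_peaks state     one_sided mean_opinion sd_opinion     N     T  beta
#>      <dbl>   <int> <chr>     <lgl>            <dbl>      <dbl> <int> <dbl> <dbl>
#> 1    0.937       2 polarized FALSE           -0.190       3.02  1000    10     3

nudged <- run_activity_model(
  activity_config(seed = 1),
  nudge_config("clt_scaled", D = 3, n = 30)
)
glance(nudged)
#> # A tibble: 1 × 14
#>   lambda_x n_peaks state     one_sided mean_opinion sd_opinion     N     T  beta
#>      <dbl>   <int> <chr>     <lgl>            <dbl>      <dbl> <int> <dbl> <dbl>
#> 1     1.28       1 consensus FALSE           -0.233       3.01  1000    10     3
```

`n_peaks` drops from 2 to 1: the two opinion camps (peak distance
`Λx ≈ 0.9`) merge into a single broad distribution around the neutral
consensus. `tidy(run)` returns the long trajectory (`t`, `agent`,
`opinion`); `autoplot(run)` draws it; `plot_nn_mean(run)` shows the
echo-chamber diagnostic (opinion vs interaction-weighted neighbour opinion)
when the interaction log is recorded.

The selective model at its published defaults forms two chambers:

```r
run <- run_selective_model(selective_config(seed = 3))
run
#> <selective_run> N=100 E=400 steps=5000 nudge=none D=0 seed=3
#>   final peaks: 2
glance(run)
#> # A tibble: 1 × 15
#>   lambda_x n_peaks state     one_sided mean_opinion sd_opinion     N     E steps
#>      <dbl>   <int> <chr>     <lgl>            <dbl>      <dbl> <int> <int> <int>
#> 1     1.02       2 polarized FALSE          -0.0375      0.453   100   400  5000
```

Figure-level protocols run as presets:

```r
spec <- preset("fig3_delayed_rdn")   # nudge on only for t in [10, 20]
results <- run_experiment(spec, master_seed = 1)
write_experiment_outputs(results, "out/fig3")
```

or from the shell:

```sh
exec/rdnudge run --model selective --preset fig6_selective --seed 1 --out out/fig6
# out/fig6/: results.csv, manifest.json, summary.json
```

Saved trajectories (`write_trajectory()`) can be re-analysed without
rerunning the simulation:

```sh
exec/rdnudge metrics --trajectory my_run.csv --out my_run_metrics.json
```

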