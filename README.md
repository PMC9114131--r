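# chembias

Bias-corrected molecular property prediction with graph neural networks.

## The problem

Experimental chemistry datasets are not uniform samples of chemical space:
cost, drug-likeness heuristics, lab specialization and publication decisions
all skew which molecules get measured. A regressor trained on such data
minimizes error under the *biased* sampling distribution and can perform
poorly on the chemical space it will actually be applied to. `chembias` is a
workbench for simulating this situation and evaluating two corrections from
causal inference, for anyone studying covariate shift in molecular machine
learning.

Given a biased training set `D_train = {(G_i, y_i)}` of molecular graphs with
scalar properties and an unlabeled uniform sample `D_test`, the package
trains a message-passing neural network `f` (bond-type-conditioned messages
`m_v = ReLU(Σ_{u∈N(v)} W_{σ(u,v)} h_u)`, GRU state updates, set2set readout)
with three estimators:

* **Baseline** — minimize `(1/N) Σ ℓ(y_i, f(G_i))`, `ℓ` the squared loss.
* **IPS** — fit a propensity classifier `π(G) ≈ Pr(G ∈ D_train)` by
  separating the two sets (target values never used), then minimize the
  inverse-weighted objective `o^IPS = (1/N) Σ ℓ(y_i, f(G_i)) / π(G_i)`.
* **CFR** — a shared feature extractor `f_F`, a label predictor `f_L` on the
  labeled domain, a Wasserstein distance between the domains' embedding
  clouds, and a weight head `f_W` giving closed-form importance weights
  `w_i = 1 + exp(φ^(1−d_i) − φ^(d_i))`; trained by alternating minimization
  of `o^property + α·o^IPM` (extractor + predictor) and `o^domain` (weight
  head). The deliverable predictor is `f_L ∘ f_F`.

Selection bias is simulated by four scenarios preferring molecules with fewer
atoms, fewer single bonds, a higher gap-like auxiliary property, or a higher
target value. Inclusion chances are sigmoids of the scenario indicator with
the gain calibrated by bisection so the average inclusion probability is 10%;
the unbiased test set is a uniform 10% split; trials are repeated for paired
t-testing (`**` p < 0.01, `*` p < 0.05). Evaluation is test-set MAE, plus
indicator-binned MAE and train/test density diagnostics.

Everything runs on synthetic molecular-like graph populations generated by
the package (no downloads); a SMILES CSV loader is included for real data.

## Worked example

```r
library(chembias)

ds <- default_benchmark(seed = 0)        # 3,000 synthetic molecules
cfg <- experiment_config(
  target   = "target_size_linked",
  scenario = scenario_config(1, n_trials = 10),   # fewer atoms preferred
  methods  = c("baseline", "ips", "cfr"),
  mpnn     = mpnn_config(n_layers = 2, hidden_dim = 8, s2s_steps = 1),
  train    = train_config(initial_lr = 3e-3, max_epochs = 100),
  alpha    = 10, base_seed = 101)
rep <- run_experiment(ds, cfg)
print(rep)
```

```
<eval_report: scenario 1, target 'target_size_linked', 10 trial(s)>
  baseline  MAE 4.6868 +/- 0.2727
  ips       MAE 3.6759 +/- 0.5280 **
  cfr       MAE 4.4628 +/- 0.5166
```

Reading the output: each row is the mean ± sd of the test-set MAE over the 10
biased-sampling trials. Under the small-molecule-preferring scenario the
propensity-weighted regressor (IPS) cuts the error by about 22% relative to
the uncorrected baseline, significant at p < 0.01 in the paired test (`**`);
its gains sit almost entirely in the large-molecule bins that training
underrepresents (`rep$binned_mae`, `rep$densities`). The end-to-end CFR
estimator improves the mean but not significantly at this problem size — on
some splits its shared representation collapses outside the training region
(see the package vignette for the diagnosis; a CFR fit's `domain_accuracy`
near 0.5 flags such runs).

A command-line wrapper (`inst/cli/chembias`) exposes `synth`, `sample` and
`run` subcommands over the same functions.

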