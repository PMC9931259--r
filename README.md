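# healthgen

Conditional generation of clinical time series with informative
missingness, in R.

## The problem

ICU time series are irregularly sampled, and *when* something is measured
is itself a signal: missingness in electronic health records is
missing-not-at-random and often as predictive as the values. Sharing such
data is hard, and the cohorts that are available underrepresent many
patient groups. This package is for researchers who want to (a) synthesize
EHR-like cohorts whose feature trajectories *and* missingness masks are
jointly realistic, (b) control the demographic and label composition of the
synthetic cohort, and (c) evaluate generators the way that matters — by how
well models trained on the synthetic data perform on real data.

## The model

Each patient is $(x_{1:T}, m_{1:T}, s, y)$: a $T \times D$ standardized
feature matrix with zeros at missing cells, the binary observation mask,
static category codes, and binary intervention labels. The generator is a
conditional dynamical variational autoencoder with a static latent
$v \sim \mathcal N(0, I)$ and a latent sequence $z_{1:T}$:

* masks, one-shot: $p_{\theta_m}(m_{1:T} \mid v, s, y) = \prod_{t,d}
  \mathrm{Bernoulli}(m_{t,d};\ \mu_{t,d}(v, s, y))$
* features, dynamical: $h_t = e_h(x_{t-1}, h_{t-1}, v)$,
  $\ z_t \sim p_{\theta_z}(z_t \mid z_{t-1}, h_t)$,
  $\ x_t \sim \mathcal N\!\big(\mu_{\theta_x}(z_t, h_t, v, s, y),\
  \mathrm{diag}\,\sigma^2_{\theta_x}\big)$

Inference uses a bidirectional summarizer for $q(v \mid x, m, s, y)$, an
anti-causal recurrence $g_t$, and an autoregressive posterior
$q(z_t \mid z_{t-1}, g_t)$. Training maximizes an ELBO whose feature
reconstruction term is masked to observed cells, so the objective is
exactly independent of values at missing cells. Conditioning is
concatenation of one-hot statics and labels; dropping the static block
gives generation unconditional in demographics.

Evaluation is Train-on-Synthetic-Test-on-Real (TSTR): a GRU-D classifier
(trainable exponential decay of missing inputs toward empirical means, and
of the hidden state with time-since-measurement) is trained once on real
and once on synthetic data, both scored on the same real test set; the gap
between the two AUROCs measures generator faithfulness. Bootstrap
resampling gives 95% intervals; one-sided Mann-Whitney U tests compare
arms. A latent nearest-neighbour audit (cosine distance on the flattened
posterior means of $v$ and $z_{1:T}$) screens for memorization.

There is no deep-learning framework dependency: the package carries a small
reverse-mode autodiff engine over batched matrix operations, verified
against finite differences in the test suite.

## Worked example

Simulate an event-stream cohort with a strong intervention effect and
label-dependent missingness, preprocess onto the 25-step clinical grid,
fit the generator, synthesize a mirror cohort, and evaluate by TSTR:

```r
library(healthgen)

cfg <- sim_config(n_patients = 300, n_features = 3, label_effect = c(3, 0, 0))
sim <- simulate_cohort(cfg, grid_spec(), seed = 1)
co  <- preprocess_cohort(sim$streams, grid_spec(),
                         feature_names = c("hr", "map", "spo2"),
                         static_vocab  = sim_static_vocab(cfg),
                         label_names   = "vent")
co
#> <hg_cohort> 300 patients, D = 3 features, M = 2 statics, L = 1 labels (real)
#> grid: 4 steps/hour, 6 h obs + 2 h gap + 4 h prediction (T = 25)

sp  <- split_cohort(co, c(0.7, 0.15, 0.15), task_index = 1, seed = 2)
mod <- healthgen(sp$train, arch = healthgen_arch(dim_v = 8, dim_z = 8,
                                                 dim_h = 16, dim_g = 16,
                                                 decoder_hidden = 32),
                 epochs = 60, learning_rate = 2e-3, seed = 3)
mod
#> Conditional dynamical VAE for clinical time series
#>   features D = 3, sequence length T = 25
#>   latents: dim_v = 8, dim_z = 8 (flattened 208)
#>   conditioning width C = 5 (with statics, 1 label)
#>   trained 60 epochs: ELBO -435.522 -> -54.779

synth <- simulate(mod, seed = 4, template = sp$train)
rep <- tstr(synth, sp, task_index = 1,
            grud_args = list(hidden_dim = 16, epochs = 10), seeds = 0:1)
rep
#> TSTR report (task 1)
#>   real-trained  e     = 1.000  [1.000, 1.000]
#>   synth-trained e-hat = 1.000  [1.000, 1.000]
#>   gap e - e-hat = 0.000;  p(real > synth) = 1.0000

aud <- audit_report(synth, sp$train, mod, n_queries = 3, k = 3, seed = 5)
#> minimum latent NN distance: 0.032 (memorization flag: FALSE)
```

Reading the numbers: the ELBO rises from −435.5 to −54.8 per patient over
training; a classifier trained only on the synthetic cohort matches the
real-trained classifier on held-out real patients (gap 0.000) — on this
simulated task the generator transfers the full downstream signal — and no
synthetic patient sits on top of a training patient in latent space
(minimum cosine distance 0.032, so the cohort is not a copy).

Other entry points: `generate_cohort()` for exact (s, y) composition
control, `augment_cohort()` to top minority groups up to the majority
count, `per_group_report()` for per-subgroup AUROCs and the fairness gap,
`elbo()` for objective diagnostics, `save_cohort()`/`load_cohort()` for
bit-exact cohort directories, and `run_pipeline()` (or the
`inst/exec/healthgen` script) to chain everything under one seed from a
YAML config.

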