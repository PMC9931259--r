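---
title: "Conditional generation of clinical time series with informative missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional generation of clinical time series with informative missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multivariate ICU time series are irregularly sampled, and *when* a variable
is measured is itself informative: clinicians order measurements in response
to a patient's state, so the missingness pattern is missing-not-at-random
(MNAR) and often carries as much predictive signal as the values. A useful
generator of synthetic electronic-health-record (EHR) cohorts therefore has
to synthesize three things jointly: the feature trajectories, their
missingness masks, and their dependence on static patient descriptors
(demographics, insurance) and on intervention labels.

This package implements such a generator — a conditional dynamical
variational autoencoder — together with the full apparatus needed to judge
it: a fixed-grid preprocessing pipeline for irregular event streams, a
simulator with known ground truth, a GRU-D downstream classifier, the
train-on-synthetic-test-on-real (TSTR) protocol with bootstrap uncertainty
and Mann-Whitney significance tests, conditional generation and
minority-group augmentation workflows, and a latent nearest-neighbour
memorization audit.

## Data representation

Each patient is a tuple $(x_{1:T}, m_{1:T}, s, y)$: a $T \times D$ matrix of
standardized feature values with zeros at missing cells, the binary
$T \times D$ mask $m$ ($m_{t,d} = 1$ iff the cell was observed), integer
static-category codes $s$ (1-based, following R convention), and binary
intervention labels $y$.

Preprocessing converts irregular event streams to this form:

* **Grid.** Points sit at $k/f$ hours, $k = 0, \dots$, with $f$ steps per
  hour and an inclusive endpoint, so the observation block has
  $T = f \cdot \text{obs} + 1$ rows — 25 at the defaults (4/hour, 6 h).
  This inclusive-endpoint convention is the only one consistent with a
  25-step, 6-hour observation window at 4 steps/hour.
* **Assignment.** Each event goes to its nearest grid point (window of
  ± half a step, left-closed/right-open). When several events of one feature
  compete for a window, the one closest in time wins; the later one wins an
  exact tie. Which summary to record per window (mean, last, nearest) is a
  genuinely open choice; *nearest* is used and isolated behind
  `resample_to_grid()` so it can be swapped.
* **Labels.** The span is split into observation (6 h), gap (2 h) and
  prediction (4 h) windows; a label is positive iff the intervention is
  active at some point of the open-start prediction window. The gap prevents
  label information from leaking out of the tail of the observation window.
* **Standardization.** Per-feature mean and *population* (divide-by-$n$)
  standard deviation over observed cells only, pooled over patients and
  time, with the sd floored at $10^{-6}$; missing cells become exactly 0
  after centering. Any consistent sd convention passes the refit property
  (refitting on the standardized output gives mean 0, sd 1); divide-by-$n$
  was chosen once.
* **Decay inputs.** The downstream classifier wants the time since each
  feature was last observed: $\delta_{1,d} = 0$ and
  $\delta_{t,d} = \Delta + \delta_{t-1,d}[m_{t-1,d} = 0]$ with grid step
  $\Delta = 1/f$ — the counter resets on observation, following the standard
  GRU-D convention.

## The generative model

A static latent $v \in \mathbb{R}^{d_v}$ (prior $\mathcal{N}(0, I)$)
captures time-invariant patient state. Conditioning is implemented by
concatenating one-hot-encoded statics $s$ and labels $y$ into a vector $c$;
either block can be dropped (dropping $s$ gives generation that is
unconditional in the demographics).

* **Masks.** The whole mask sheet is decoded in one feedforward step, not as
  a dynamical process: $p(m_{1:T} \mid v, s, y) = \prod_{t,d}
  \text{Bernoulli}(m_{t,d}; \mu_{t,d}(v, c))$. Probabilities are smoothly
  clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$.
* **Features.** A deterministic forward recurrence
  $h_t = e_h(x_{t-1}, h_{t-1}, v)$ ($h_0 = 0$) carries history; a learned
  Gaussian transition prior $p(z_t \mid z_{t-1}, h_t)$ drives a latent
  sequence; the decoder emits
  $p(x_t \mid z_t, h_t, v, s, y) = \mathcal{N}(\mu_\theta, \text{diag}\,
  \sigma^2_\theta)$.
* The two channels are generated independently given $(v, s, y)$: gradients
  of the mask reconstruction term with respect to the feature decoder are
  identically zero (a property the test suite checks literally).

Inference mirrors this: a bidirectional GRU summarizer over $[x_t, m_t]$,
pooled and joined with $c$, parameterizes $q(v \mid x, m, s, y)$; an
anti-causal recurrence $g_t = e_g(x_t, h_t, g_{t+1}, v)$ feeds an
autoregressive Gaussian posterior $q(z_t \mid z_{t-1}, g_t)$.

The ELBO has four per-patient terms: mask reconstruction over the full
sheet, feature reconstruction **masked to observed cells**, and closed-form
KL penalties for $v$ (against $\mathcal{N}(0,I)$) and for each $z_t$
(posterior against transition prior, inside a Monte-Carlo average over
sampled $z$ paths). Masking the feature term means the objective is exactly
invariant to the values stored at missing cells; `elbo()` additionally
multiplies $x$ by $m$ before any network consumes it, making that invariance
bit-exact by construction rather than an input-hygiene assumption.

### Sampling

Ancestral sampling: draw $v \sim \mathcal{N}(0, I)$, sample the mask sheet,
draw $z_0 \sim \mathcal{N}(0, I)$ (sampling rather than fixing $z_0 = 0$ at
generation time), then for $t = 1..T$ sample $z_t$ from the transition
prior, $x_t$ from the decoder, and advance $h$. Two conventions are our own
choices where the sampling procedure is silent:

* the generated $x_t$ is zeroed at generated-missing cells, so synthetic
  records satisfy the same container invariant as preprocessed real records
  and are drop-in substitutes for the downstream classifier;
* the recurrence $e_h$ consumes the mask-zeroed $x_t$, because during
  training $h$ only ever sees zero-imputed inputs — feeding it the raw
  Gaussian draw would put generation off the training distribution.

During ELBO evaluation the $t = 1$ conditioning uses $z_0 = 0$ in both the
posterior and prior heads; $z_0$ is only sampled at generation. Generated
feature values are not clipped to any range; users standardizing by heavy
tails should be aware synthetic values can stray outside the observed range.

### Numerical choices

Standard deviations are parameterized as softplus plus a floor
($10^{-3}$); mask probabilities are clamped as above; optimization is Adam
(default learning rate $10^{-3}$ here exposed via `learning_rate`), with
global gradient-norm clipping at 10; `n_mc = 1` Monte-Carlo draw per step is
the usual VAE practice, exposed for tests. Network bodies are single-layer
GRU-style cells and two-layer feedforward heads behind
`healthgen_arch()` — deliberately swappable, since nothing in the model's
definition pins the cell internals. The forward recurrence $e_h$ is shared
between the generative and inference passes. Training, sampling and
encoding are deterministic given their seeds; the gradient engine is a
small reverse-mode tape over batched matrix operations whose every
operation is verified against central finite differences in the tests.

## The simulator

Real ICU data cannot ship with the package, so every downstream claim is
tested on a simulator with known ground truth (`simulate_cohort()`). Per
patient: statics from configurable category probabilities (supporting
minority groups such as 0.9/0.1), a task label
$y \sim \text{Bernoulli}(p)$, a patient effect
$a \sim \mathcal{N}(\mu_s, \sigma_a^2)$, a latent AR(1) trajectory
$u_t = \rho u_{t-1} + a + \epsilon_t$, feature values
$u_t + y \cdot \beta_d$, and an emission (observation) probability
$\text{logit}^{-1}(\alpha_d + \gamma y + \kappa |value|)$ — so missingness
is genuinely MNAR and label-dependent. Positive patients get one
intervention interval placed uniformly inside the prediction window.

The AR(1)-plus-patient-effect process is the simplest one exhibiting the two
correlation structures of real EHR data — values correlated over time, and
missingness patterns correlated with state — while keeping closed-form
moments for tests. Labels are drawn first and injected into both the signal
and the missingness so the TSTR target is recoverable by construction;
other causal orderings would leave nothing to verify against.

Defaults (600 patients in the TSTR experiments, 200 for optimization-sanity
checks; $\rho = 0.5$, $\sigma_a = 0.5$, noise sd 0.3, base observation
logit 1, label effect 3 on feature 1, label-missingness coefficient 1,
positive rate 0.3) were chosen once as a regime where the Bayes-style
reference statistic — the mean observed feature-1 value, whose AUROC
`ground_truth_auroc_bound()` estimates by Monte Carlo — exceeds 0.9, i.e. a
strong but not trivial downstream task. What passing tests on this
simulator shows is that the whole pipeline recovers known structure at
desk scale; it does not show clinical realism of any specific vital sign,
nor performance on credentialed ICU data, which require the real cohort and
far larger models (the reference uses $D = 104$ features, latent sizes 32,
and an 832-dimensional flattened latent, which this package reproduces as
dimensional constants but not as a trained artifact).

## Evaluation

**GRU-D.** The downstream classifier consumes $(x, m, \delta)$ directly.
Two trainable exponential decays implement its clinical priors: a missing
input decays from its last observed value toward the feature's empirical
training mean, $\hat x_{t,d} = m_{t,d} x_{t,d} + (1 - m_{t,d})
(\gamma_{t,d}\, x^{last}_d + (1-\gamma_{t,d})\, \bar x_d)$ with
$\gamma = \exp(-\max(0, w_d \delta_{t,d} + b_d))$; and the hidden state is
damped elementwise by $\exp(-\max(0, W\delta_t + b))$ before each update.
Beyond the decays the cell is a standard gated recurrent unit taking
$[\hat x_t, m_t]$; empirical means fall back to 0 (the standardized prior
mean) for never-observed features. Decay rates are initialized slightly
positive so the rectifier starts in its active region.

**TSTR.** Two classifiers with identical architecture and training
procedure: $E$ trained on real training data, $\hat E$ on the synthetic
cohort; both scored on the *same* real test set, $e = E(D_{test})$,
$\hat e = \hat E(D_{test})$. The gap $e - \hat e$ is the headline measure
of generator faithfulness — distributional similarity proxies are
deliberately not computed. Each arm repeats over five random
initializations (configurable) and keeps the best by validation AUROC —
real validation data for $E$; a held-out slice of the synthetic cohort for
$\hat E$, since selecting on the real test set would leak. Uncertainty: 30
bootstrap resamples of the test patients give a 95% percentile interval of
the AUROC; one-sided Mann-Whitney U tests (exact for small tie-free
samples, normal approximation with tie correction otherwise) compare
bootstrap distributions between arms. Per-subgroup reports drop categories
lacking a positive test case, and summarize disparity as the max-minus-min
per-category AUROC — a declared substitute for a fairness metric whose
exact form is not public.

**Conditional generation and augmentation.** `generate_cohort()` honours an
exact requested (s, y) contingency (integer equality, tested);
`composition_mirror()` reproduces a template's empirical joint.
`augment_cohort()` tops up every category of a chosen static variable to
the majority category's count, copying each category's own label balance
(rounded) — the group's deficit, not the global balance, is what
augmentation targets. Masks are binarized by sampling, not by thresholding
at 0.5, because thresholding would distort marginal missingness rates.

**Memorization audit.** Each patient maps to a deterministic flattened
latent — the posterior mean of $v$ concatenated with the $T$ posterior
means of $z_t$ propagated through their own means ($d_v + T d_z$
dimensions; 832 at the defaults). Queries are randomly sampled synthetic
patients; the 3 cosine-nearest training latents are reported with distances
and side-by-side trajectory plots. Each record is encoded with its *own*
(s, y). The audit is report-only (minimum distance, table, figures) with no
pass/fail cutoff, because nearest-neighbour distance is a qualitative
screen, not a privacy guarantee; no differential-privacy accounting is
attempted.

## Problem sizes and reproducibility

The shipped experiments run on one CPU: simulated cohorts of 120–600
patients, $D = 2$–5 features, latent sizes 8, hidden sizes 16–32, 80
training epochs for the generator and 10–15 for the classifier; these sizes
were chosen as the smallest at which every pipeline property is comfortably
measurable. All entry points take explicit seeds, and `run_pipeline()`
derives per-stage seeds from one global seed by a fixed counter scheme, so
whole runs reproduce byte-identically while stages remain individually
re-runnable. Splitting is stratified on a single designated task label —
the protocol trains and evaluates per task, and joint multi-label
stratification is underdetermined — with largest-remainder allocation per
stratum, which bounds the positive-rate difference between splits by one
record's worth.

## Known limitations

* Cohorts are held in memory; the design targets method study, not
  hundred-thousand-patient extracts.
* The generator's conditional fidelity is only as good as the ELBO fit;
  with very small cohorts the mask decoder's rates converge well before the
  conditional feature distribution does.
* No FHIR/OMOP ingestion, no unit harmonization, no variable-length
  sequences: event streams are assumed cleaned to the documented schema.
* The memorization audit is qualitative; absence of near-duplicates in
  latent space is evidence against verbatim copying, not a privacy proof.
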