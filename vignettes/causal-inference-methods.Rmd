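---
title: "Causal-inference models of audiovisual distance perception: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal-inference models of audiovisual distance perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avdistci)
```

## The problem

When an observer sees and hears an event — here, a musician playing an organ
somewhere along a 10-m room diagonal — the visual and auditory signals each
carry an estimate of the event's distance. Whether and how the two estimates
interact is governed, under the Bayesian causal-inference account, by an
inference over the *causal structure*: did both signals come from one physical
source (`C = 1`) or from two (`C = 2`)? This package implements a
non-generative version of that account for distance perception, scores it
against three classical rival models on trial-level slider-response tables,
and derives causal-inference sensory weights and interaction windows. A
synthetic observer generates response tables with the statistical structure
the analysis assumes, because the original human responses for this paradigm
are not publicly deposited.

"Non-generative" means no free parameters are fitted to the response data.
Every model component is predicted numerically from quantities measured
elsewhere in the experiment: the unimodal conditions supply the sensation
distributions, and the rate of identical visual/auditory answers supplies the
causal posterior. This avoids both overfitting and the computational cost of
maximum-likelihood generative fits.

## The model

**Sensations.** Reports to a unimodal stimulus at distance $d$ are taken as
draws from the sensation distribution $N(\mu_i(d), \sigma_i^2(d))$,
$i \in \{A, V\}$, with independent noise across modalities. The pipeline
estimates each $(\mu_i, \sigma_i^2)$ as the sample mean and unbiased sample
variance of the pooled unimodal reports at that distance
(`compute_unimodal_profiles()`).

**Common cause (`C = 1`).** The fused estimate is the inverse-variance
weighted (maximum-likelihood) combination
$$\hat s_{C=1} = \frac{x_A/\sigma_A^2 + x_V/\sigma_V^2}
                       {1/\sigma_A^2 + 1/\sigma_V^2},
\qquad
\sigma_{C=1}^2 = \frac{\sigma_A^2 \sigma_V^2}{\sigma_A^2 + \sigma_V^2},$$
shared by both modality reports (`integrate_common()`). Its variance never
exceeds either unimodal variance.

**Separate causes (`C = 2`).** Each report keeps its own unimodal mean and
variance unchanged (`segregate()`).

**Causal posterior.** Because participants are instructed to give identical
answers when they perceive a single source, $p(C=1)$ for a stimulus pair is
observed directly as the pair's matching rate — the proportion of bimodal
trials whose two reports match (`estimate_p_common()`).

**Resolution strategies.** With $0 < p(C{=}1) < 1$ the final percept can be
formed three ways, all implemented as closed-form predicted response
distributions:

* *model selection* — take the estimate of the more probable structure
  (`resolve_model_selection()`);
* *model averaging* — the posterior-weighted linear average of the two means,
  and (as a working hypothesis, in the absence of a better prediction) the
  same weighted average of the two variances (`resolve_model_averaging()`);
* *probability matching* — per trial the response follows one structure with
  probability equal to its posterior, so the predicted response distribution
  is a two-component Gaussian mixture weighted by the posterior
  (`resolve_probability_matching()`). The mixture is the analytic expectation
  of the per-trial sampling process; the per-trial draw itself exists only in
  the simulator.

**Rival models.** Sensory dominance (the lower-variance cue is used for both
reports), mandatory integration (fusion on every trial) and no interaction
(segregation on every trial) complete the six-model set.

**Sensory weights.** Under causal inference the weight of modality $j$ on the
auditory estimate blends the segregated weights (self-weight 1 when causes
are separate) with the MLE weights (when causes are common):
$$w_A = p(C{=}2) + p(C{=}1)\frac{\sigma_V^2}{\sigma_A^2+\sigma_V^2},
\qquad
w_V = p(C{=}1)\frac{\sigma_A^2}{\sigma_A^2+\sigma_V^2}.$$
They sum to 1 by construction, and the self-weight can never fall below
$p(C{=}2)$. Visual-estimate weights use the symmetric exchange of the two
formulas (only the auditory case is usually written out). The *interaction
window* at a given auditory distance is the span of visual distances where
$w_V > 0.5$ strictly.

## Goodness of fit

Continuous predictions are compared with count data on the response scale:
`discretize()` integrates each predicted density over ten unit bins centred
at 1..10 m (`[c-0.5, c+0.5)`, tails absorbed into the extreme bins, so the
vector sums to one; a response at exactly 0 falls into bin 1). Predicted
probabilities are scaled by the trials per pair into expected counts, and
observed counts are regressed on predicted counts by simple OLS
(`fit_model()`); the statistic is $r^2$. No complexity correction is applied:
all six models have the same number of parameters and none is fitted.
`compare_models()` runs this for the six models over the scopes "All" (both
report modalities in one pooled regression), "All (A)", "All (V)", and one
scope per subject. With the full layout each modality scope contains
10 bins x 50 pairs x 6 subjects = 3000 cells.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `variance_floor` | 1e-4 | m^2 | replaces a zero sample variance (all repeats identical); the formulas divide by variances |
| `match_rule` | `"bin"` | — | two reports "match" when they fall in the same 1-m bin; `"exact"` requires float equality |
| `centers` | `1:10` | m | response-count grid |
| `tau` (simulator) | 2 | m | width of the generative similarity kernel |
| `sigma2_v` (simulator) | 0.25 | m^2 | constant visual sensation variance (sd 0.5 m) |
| `sigma2_a` (simulator) | `(0.8 + 0.18 d)^2` | m^2 | auditory sensation variance growing with distance |

The default match rule is the binned one because responses come from a
continuous slider: participants aiming to repeat a value will land within the
same metre bin far more reliably than on the same float. Exact equality is
kept as an option (and is what the recovery tests use, since the simulator's
fused reports are exactly equal).

## Design choices at genuinely open points

* **Tie at `p(C=1) = 0.5`.** The selection rule is stated with strict
  inequalities both ways, leaving the tie undefined; it resolves here to the
  separate-cause estimate — the conservative default of no interaction.
* **Tie at equal variances in sensory dominance.** Resolved to the visual
  profile: vision is the more reliable modality throughout this paradigm.
* **Averaged variance under model averaging.** The linear average of the two
  structures' variances is a stated hypothesis, not a derived law; the
  mixture variance (which adds the spread of the component means) is a
  plausible alternative that is deliberately not substituted — the averaged
  form is what the strategy predicts here, and the mixture form already
  exists separately as the probability-matching predictor.
* **Counts, not rates.** Observed counts are regressed on predicted counts;
  with a constant trial count per pair the two are proportional, so $r^2$ is
  unchanged.
* **One pooled regression for "All".** The "All" scope regresses both
  modalities' cells in a single OLS rather than averaging two per-modality
  regressions; the per-modality scopes are also reported, so both readings
  are available.
* **Window interpolation.** Reported interaction-window widths are finer than
  the 2-m visual grid, implying sub-grid reading; windows here are measured
  by linear interpolation of $w_V$ between grid points at the 0.5 crossing,
  with runs touching the grid edge truncated at the edge, and the widest run
  reported if several exist. Boundary equality ($w_V = 0.5$) is outside the
  window.
* **Per-subject scopes re-estimate everything.** In subject scopes the
  profiles and posteriors come from that subject's data only, matching the
  idea that each subject's model is predicted from their own unimodal
  behaviour.

## The synthetic observer

`simulate_experiment()` generates the full layout: 5 visual x 6 reps, 10
auditory x 6 reps, and 50 bimodal pairs x 6 reps for each of 6 subjects,
with responses clipped to the [0, 10] slider. Per bimodal trial the observer
draws sensations $x_A, x_V$, perceives a common cause with probability
$\exp(-(x_V - x_A)^2 / 2\tau^2)$, draws $\zeta \sim U[0,1]$, and (under the
default probability-matching strategy) reports the fused value on both
sliders when $\zeta < p$ and the raw sensations otherwise. Alternative
response strategies (averaging, selection, dominance, mandatory, none) are
available for model-identifiability checks.

Two points deserve emphasis. First, the analysis pipeline has no generative
causal model — the similarity kernel and its width $\tau$ are simulator
inventions, quarantined there, and never consulted by the estimators; the
closed-form kernel mean (available because a Gaussian kernel of a Gaussian
difference integrates analytically) is used only as ground truth in recovery
tests. Second, the noise defaults are a calibration, not a reproduction: the
visual sd of 0.5 m and auditory sd of $0.8 + 0.18d$ m were chosen once so
that simulated unimodal mean absolute errors land near the magnitudes this
paradigm reports (roughly 0.3–0.4 m visual, 1.2–1.5 m auditory), and they are
not revisited.

What the simulator does *not* emulate: response biases and spatial priors
(the observer is unbiased by construction), learning or order effects,
response latency, subject heterogeneity (all subjects share one parameter
set; only their noise streams differ), and any stimulus-level acoustics or
optics. Passing recovery tests therefore demonstrates the pipeline's
correctness on data satisfying its own assumptions — not that human data
satisfy them.

## Numerical choices

* Slider clipping makes the observed unimodal moments those of a *censored*
  normal; recovery tests compare against censored moments obtained by
  numeric integration rather than against the latent $\mu, \sigma^2$.
* Each subject draws from its own seeded substream, so a subject's rows are
  invariant to how many subjects are simulated and the whole table is
  bit-reproducible under a fixed seed.
* Recovery of per-pair matching rates is checked against a Monte-Carlo
  re-enactment of the generative process with a simultaneous (Bonferroni)
  binomial band across the 50 pairs, so the family-wise error of the check
  is controlled at 5%.
* Degenerate inputs fail loudly: non-positive variances, missing unimodal
  levels, pairs without posteriors, and constant predictors (whose $r^2$ is
  defined as 0) all raise errors or warnings rather than propagating NaNs.
* Test and example problem sizes: property sweeps use 1e5 random inputs;
  Monte-Carlo equivalence uses 1e5 draws per tested pair; recovery uses the
  full design at 60 repetitions and model-identification uses 10 independent
  seeds at 60 repetitions, sizes at which binomial and chi-square bounds are
  tight enough to be informative.

## Worked example

```{r example, eval = FALSE}
cfg <- observer_config(seed = 20161213L)
dat <- simulate_experiment(cfg)
fits <- compare_models(dat)
format_fit_table(fits)

prof <- compute_unimodal_profiles(dat)
post <- estimate_posteriors(dat)
surf <- weight_surface(prof, post, target = "auditory")
interaction_windows(surf)
plot_weight_surface(surf)
```

The `analysis/` directory runs exactly this sequence as three numbered
drivers (`01_simulate.R`, `02_fit.R`, `03_weights.R`) writing their tables
under `results/`.

## Known limitations

* The matching-rate estimator of $p(C=1)$ is upward-biased under the binned
  match rule when segregated responses happen to share a bin; the exact rule
  removes this at the cost of fragility on data where instructed-identical
  answers are not float-identical.
* The averaged-variance hypothesis of model averaging is untested against
  alternatives here, by design.
* Interaction-window bounds depend on the interpolation rule; with a 2-m
  visual grid the rule can shift window edges by up to a bin.
* $r^2$ comparisons are descriptive; no inferential ordering of models is
  attempted (and with six models of equal complexity none is needed for the
  ranking itself).
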