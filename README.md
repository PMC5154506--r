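# avdistci

Bayesian causal-inference modelling of audiovisual distance perception,
without generative fitting.

When an observer both sees and hears an event at some distance, the percept
depends on an inference over causal structure: one physical source (`C = 1`)
or two (`C = 2`). `avdistci` implements the non-generative form of this
account for distance judgements on a 0–10 m slider and everything needed to
test it against trial-level response tables:

* **Model predictors** — maximum-likelihood (inverse-variance) cue
  integration for a common cause; segregation for separate causes; the
  causal posterior observed as the rate of matching visual/auditory answers;
  and three strategies for resolving an uncertain structure — *model
  selection* (take the more probable structure), *model averaging*
  (posterior-weighted means and variances), *probability matching* (a
  posterior-weighted Gaussian mixture). Three rivals without causal
  inference: sensory dominance, mandatory integration, no interaction.
* **Goodness of fit** — each model's predicted response distributions are
  discretized onto ten 1-m response bins, scaled to expected counts, and
  scored against observed counts by OLS (`r²`), pooled, per modality and per
  subject.
* **Sensory weights** — for an auditory estimate,
  `w_A = p(C=2) + p(C=1) · σ²_V / (σ²_A + σ²_V)` and
  `w_V = p(C=1) · σ²_A / (σ²_A + σ²_V)`; weight surfaces over the stimulus
  grid and the *interaction windows* where the visual weight exceeds 0.5.
* **Synthetic observer** — a seeded generator of unimodal + bimodal response
  tables (Gaussian sensation noise, similarity-kernel causal perception,
  configurable resolution strategy) for testing every pipeline stage,
  because the paradigm's human responses are not publicly deposited.

See `vignettes/causal-inference-methods.Rmd` for the model, assumptions and
design choices.

## Worked example

The `analysis/` drivers run the whole pipeline on a simulated
probability-matching observer (full layout: 50 audiovisual pairs, 6
repetitions, 6 subjects):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit.R
Rscript analysis/03_weights.R
```

`02_fit.R` prints the goodness-of-fit table (abridged here):

```
                 model   All All (A) All (V)    s1    s2    s3
1     SensoryDominance 0.436   0.103   0.852 0.317 0.426 0.423
2 MandatoryIntegration 0.323   0.117   0.558 0.209 0.302 0.272
3        NoInteraction 0.671   0.346   0.852 0.588 0.635 0.578
4    CausalInferencePM 0.731   0.516   0.850 0.585 0.726 0.659
5    CausalInferenceMA 0.666   0.350   0.851 0.547 0.647 0.571
6    CausalInferenceMS 0.691   0.447   0.847 0.576 0.695 0.649

best model (All): CausalInferencePM
```

Causal inference resolved with probability matching explains the simulated
data best overall — as it should, since that is the strategy the synthetic
observer used; the no-interaction model follows, because large stimulus
discrepancies make separate causes the common percept. `03_weights.R` prints
the interaction windows on the auditory estimate, e.g.

```
   auditory_distance window_lo window_hi width
3                  3      1.47      4.67 3.191
4                  4      1.99      5.18 3.188
5                  5      4.05      7.14 3.095
```

a mobile window of roughly 1–4 m centred near the auditory stimulus, within
which vision dominates the auditory distance estimate; outside it the
auditory estimate is essentially unaffected.

In code, the same pipeline is four calls:

```r
library(avdistci)
dat  <- simulate_experiment(observer_config(seed = 20161213L))
fits <- compare_models(dat)                      # six models x all scopes
surf <- weight_surface(compute_unimodal_profiles(dat),
                       estimate_posteriors(dat)) # per-pair w_A, w_V
interaction_windows(surf)                        # windows where w_V > 0.5
```

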