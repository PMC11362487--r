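# entropySI

Bayesian measurement of **latent speech intelligibility** from
listener-transcription **entropy scores**.

When a panel of listeners orthographically transcribes a speaker's
spontaneous sentences, the transcriptions of each word can be aggregated
into a normalized Shannon entropy

$$H_{wsib} = \frac{-\sum_{k=1}^{K} p_k \log_2 p_k}{\log_2 J} \in [0,1],$$

where $J$ listeners produced $K$ distinct transcription types with
proportions $p_k$: 0 means perfect agreement (a fully intelligible
word), 1 means every listener heard something different. Entropy scores
are bounded, noisy measurements of an unobservable speaker trait,
clustered within sentences, speakers and listener blocks, and prone to
outliers and heteroscedasticity. `entropySI` implements the full
analysis chain for such data:

* **Entropy aggregation** — aligned listener x word grids (with `[B]`
  blank and `[X]` unidentifiable-speech markers) to tidy word-level
  entropy tables. Each `[X]` counts as its own transcription type;
  blanks share one type by default.
* **Synthetic study generator** — emulates a two-group design (16
  normal-hearing and 16 cochlear-implanted children, 10 sentences each,
  5 blocks of 21 listeners and 64 sentences) with a full generative
  model down to raw transcription grids, so the pipeline is testable
  although the motivating dataset is private.
* **Twelve model variants** — six normal linear mixed models and six
  beta-proportion GLLAMMs (beta distribution parameterized by mean
  $\mu$ and dispersion $M$), crossing a robust per-speaker outcome
  scale with three fixed-effect structures. The beta family ties the
  expected entropy to a speaker's latent potential intelligibility
  $SI_i$ through the negative inverse-logit link
  $\mu = \mathrm{logit}^{-1}(a_b - SI_i)$, with the structural equation
  $SI_i = \alpha + \alpha_{HS[i]} + \beta_{A,HS[i]}(A_i-\bar A) + e_i + u_i$.
  Fitting is by MCMC (JAGS), 4 chains x 4000 iterations with 2000
  warmup by default, fully seeded.
* **Chain diagnostics** — rank-normalized split $\widehat R$ (1.05
  cutoff), bulk/tail effective sample sizes, trace/rank/ACF/density
  plot data.
* **Model comparison** — DIC, WAIC and PSIS-LOO with standard errors,
  differences to the best model with difference SEs, complexity
  penalties, $e^{-\Delta/2}$ evidence weights, and Pareto-$\hat k$
  influential-observation flags (0.7 threshold).
* **Latent inference** — per-speaker posteriors of $SI_i$, rankings
  with 95% HPDIs, speaker and group contrasts (significance = HPDI
  excludes zero), and posterior-predictive checks including the share
  of predictive mass outside $[0,1]$.

## Worked example

The five-listener grid shipped with the package (five Belgian-Dutch
word positions, including a blank and two unidentifiable tokens):

```r
library(entropySI)
grid_entropies(example_grid())[, c("word", "entropy", "n_types")]
#>   word   entropy n_types
#> 1    1 0.0000000       1
#> 2    2 0.3109175       2
#> 3    3 0.6554588       3
#> 4    4 0.8277294       4
#> 5    5 1.0000000       5
```

Word 1 (`de` x5) was understood by everyone; word 2 splits 4:1
(`jongen` vs `hond`); in word 4 the single blank acts as one more
response type (counts 2,1,1,1); in word 5 the two `[X]` tokens are
distinct types, so all five transcriptions differ and the entropy is
exactly 1.

A small end-to-end run on synthetic data — simulate, fit the robust
beta GLLAMM (model 10) and the robust normal LMM (model 4), and compare:

```r
sim <- simulate_dataset(design_config(n_speakers_per_group = 8,
                                      sentences_per_speaker = 3,
                                      words_range = c(5, 5),
                                      words_mean = 5, words_sd = 0.1,
                                      n_blocks = 4),
                        true_params(M = 1), seed = 201)
f10 <- fit_model(10, sim$data, chains = 2, iterations = 1000, warmup = 500, seed = 1)
f4  <- fit_model(4,  sim$data, chains = 2, iterations = 1000, warmup = 500, seed = 1)
compare_models(list(score_model(f10), score_model(f4)))[,
  c("model_id", "family", "waic", "psis", "d_waic", "weight_waic", "n_high_pareto_k")]
#>   model_id family       waic       psis   d_waic   weight_waic n_high_pareto_k
#> 1       10   beta -604.89294 -602.81802   0.0000  1.000000e+00               1
#> 2        4 normal   36.16057   42.57177 641.0535 6.266123e-140               7
```

With boundary-heavy scores (dispersion $M = 1$) the beta GLLAMM beats
the normal LMM by ~640 WAIC points and carries essentially all the
evidence weight; the misspecified normal fit flags 7 influential
observations (Pareto $\hat k > 0.7$) against the beta fit's 1, and
`posterior_predictive(f4)` puts 27.9% of its predictive mass outside
the physically possible $[0,1]$ range (for `f10` that share is exactly
0).

The numbered scripts in `analysis/` run the full narrative on the
emulated study: `01_simulate.R` (design + latent truth + entropy
scores + raw grids), `02_entropy.R` (grids to scores),
`03_fit_models.R` (all 12 variants, diagnostics, comparison table),
`04_latent_inference.R` (speaker ranking, speaker and group
contrasts), `05_pipeline_demo.R` (one-config `run_pipeline()` with a
provenance manifest). Tables land in `results/`.

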