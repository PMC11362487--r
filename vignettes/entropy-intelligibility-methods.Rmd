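---
title: "Measuring latent speech intelligibility from transcription entropy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring latent speech intelligibility from transcription entropy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropySI)
```

## The measurement problem

When a speaker's spontaneous speech is transcribed orthographically by a
panel of listeners, agreement among the transcriptions carries
information about how intelligible the speaker is: a word every
listener writes down identically was fully understood, while a word
that every listener renders differently was not understood at all.
`entropySI` turns aligned listener transcriptions into word-level
agreement scores and models those scores with Bayesian hierarchical
models in which a speaker-level latent trait — *potential
intelligibility* — drives the expected agreement.

The motivating design is a two-group child-speech study: 16
normal-hearing (NH) children and 16 hearing-impaired children with
cochlear implants (HI/CI), each contributing 10 spontaneous sentences,
with sentences and listeners organized into 5 experimental blocks of 21
listeners and 64 sentences. That dataset is not publicly available, so
the package ships a synthetic-data generator that emulates the design;
every analysis in this vignette and in `analysis/` runs on synthetic
data.

## Entropy scores

For one word position transcribed by $J$ listeners, let $K$ be the
number of distinct transcription types and $p_k$ the proportion of
transcriptions in type $k$. The score is the normalized Shannon
entropy

$$H = \frac{-\sum_{k=1}^{K} p_k \log_2 p_k}{\log_2 J} \in [0, 1],$$

0 when all listeners agree and 1 when all $J$ transcriptions are
distinct. Two marker tokens need conventions:

* `[X]` (unidentifiable speech) — every `[X]` is its own type. Two
  listeners who both failed to identify a word did not agree on a
  word; the worked example shipped with the package (five listeners,
  five words) prints an entropy of exactly 1 for a column containing
  two `[X]` among five distinct renderings, which forces this rule.
* `[B]` (blank) — all blanks form **one** shared type by default:
  "nothing heard here" is treated as a common response category. This
  is the conservative reading; `blank_distinct = TRUE` switches to
  pairwise-distinct blanks.

Type equality is exact string match after trimming and (default-on)
case folding; no stemming or edit distance, because the scores
aggregate orthographic transcriptions verbatim. Entropies are kept at
full float precision; `round4 = TRUE` in `write_entropy_table()`
matches 4-decimal display. $J$ is taken per grid rather than fixed at
21, so small worked examples are first-class. Absent cells in a grid
file are read as blanks; a whole missing row is a malformed grid.

```{r}
grid_entropies(example_grid())[, c("word", "entropy", "n_types")]
```

## The synthetic study generator

`design_config()` encodes the emulated design. Speaker ages are drawn
from truncated normals matching the two groups' published summaries
(NH: mean 86.3, SD 9.0 months on [68, 104]; HI/CI: mean 86.3, SD 6.7 on
[78, 98]); only these summaries are known, so the truncated normal is a
modeling choice. Words per sentence come from a discretized truncated
normal on [3, 11] targeting mean 7.1 and SD 1.1. Because 32 speakers
times 10 sentences cannot be split into 5 blocks of 64 sentences with
every speaker confined to one block (64 is not a multiple of 10),
blocks are filled sequentially: every block holds exactly 64 sentences,
each sentence belongs to exactly one block, both groups appear in every
block, and a boundary speaker may span two blocks. The original
allocation scheme is not recoverable from the published description;
this rule is the package's own.

The generative model mirrors the fitted one. Latent potential
intelligibility of speaker $i$ is

$$SI_i = \alpha + \alpha_{HS[i]} + \beta_{A,HS[i]}(A_i - \bar A) + e_i + u_i,
\qquad u_i = \tfrac1S \sum_s u_{si},$$

with $\bar A$ the minimum age in the sample, $e_i \sim N(0, sd_e)$,
$u_{si} \sim N(0, sd_u)$, and block effects $a_b \sim N(m_b, s_b)$.
Word-level scores are beta-proportion draws
$H \sim \mathrm{BetaProp}(\mu, M)$ with
$\mu = \mathrm{logit}^{-1}(a_b - SI_{si})$ — the *negative* link makes
higher intelligibility produce lower entropy — or, for the normal
family, unclamped Gaussian draws around the direct-link predictor.
Default generative parameters mirror the magnitudes a full-structure
fit reports on data of this kind: $\alpha = 0.01$, group intercepts
$(0.21, 0.23)$, age slopes $(0.10, 0.06)$ per month, $sd_e = 0.3$,
$sd_u = 0.2$, $s_b = 0.2$, $M = 5$. `simulate_grids()` additionally
maps $\mu$ to raw listener behaviour (correct transcription with
probability $q = 1 - \mu$; errors are a shared confusion word with
probability `confusion`, else `[X]`), linking the latent model all the
way back to grids.

What the generator does **not** emulate: real orthographic variation
(words are synthetic strings), listener-level covariates, alignment
errors, and any dependence of word difficulty on sentence position.
Passing tests therefore demonstrate that the pipeline recovers what it
assumes, not that the model is correct for any particular real corpus.

## The twelve models

Six normal linear mixed models and six beta-proportion GLLAMMs cross
the *robust* feature (per-speaker outcome scale $\sigma_i$ or $M_i$
versus one shared scale) with three fixed-effect structures (intercept
only; group intercepts plus a common age slope; group intercepts plus
group slopes). The beta-proportion distribution is the beta
parameterized by mean and dispersion, shapes $(\mu M, (1-\mu)M)$. All
models keep the redundant global $\alpha$: it sets the latent scale,
and with the priors below the overparameterization is harmless.

Priors (the scales are introspectable from the model code emitted by
`build_model()`): outcome scales $\sigma_i, M_i \sim \mathrm{Exp}(r)$
with $r \sim \mathrm{Exp}(2)$; $e_i \sim N(m_e, s_e)$,
$m_e \sim N(0, 0.05)$, $s_e \sim \mathrm{Exp}(2)$; likewise for block
effects; $u_{si} \sim N(0, s_u)$, $s_u \sim \mathrm{Exp}(2)$;
$\alpha \sim N(0, 0.05)$; $\alpha_{HS} \sim N(0, 0.2)$ (normal family)
or $N(0, 0.3)$ (beta family); slopes $\sim N(0, 0.1)$. The speaker
subscripts sometimes written on the random-effect hyperparameters are
read as shared hypers of the speaker-effect distribution — one mean and
scale per speaker would be unidentifiable. No prior is conventionally
printed for $u_{si}$; the $N(0, s_u)$, $s_u \sim \mathrm{Exp}(2)$
choice matches the scale conventions of the other effects.

Two structural choices deserve emphasis. First, sentence effects enter
the likelihood per observation (as $u_{si}$ in $SI_{si}$); the
*reported* $SI_i$ uses their average $u_i$. If $u_{si}$ appeared only
through its average, the sentence effects would be unidentifiable and
the average vacuous. Second, entropy scores contain exact 0s and 1s
that a beta likelihood cannot support, so the outcome is compressed
once, for **all twelve models**, by $y' = (y(n-1) + 0.5)/n$ — keeping
every model on the identical outcome vector so information criteria
remain comparable (an $\varepsilon$-clamp is available as an
alternative). The comparison functions enforce outcome identity with a
fingerprint check.

## Estimation

Models are fit by MCMC with JAGS through `rjags`. The reference
protocol is 4 chains of 4000 iterations with the first 2000 as warmup
(adaptation plus burn-in), retaining 8000 draws; per-chain RNG seeds
are derived from one master seed, so a refit reproduces the draws
exactly, and chain initial values are drawn around the priors so the
chains start dispersed.

Gibbs/slice sampling mixes poorly on two features of this posterior:
the scale-versus-effects funnel of the sentence effects, and the ridge
between a group intercept (defined at the *minimum* sample age) and its
age slope. Both are addressed by exact reparameterizations that leave
the model unchanged: random effects are sampled non-centered
($e_i = m_e + s_e z_i$ with $z_i \sim N(0,1)$), and each
intercept/slope pair is sampled as (intercept at the group's mean
centered age, slope) with the conditional prior
$\alpha^c_{HS} \mid \beta \sim N(\beta \bar a_g, 0.3^2)$, whose implied
marginals are exactly the stated priors. In sampler checks on
well-specified synthetic data these changes moved the worst
effective sample sizes from single digits to the hundreds per 1500
retained draws.

Because single-site samplers need more iterations per effective draw
than gradient-based ones, the scaled-down simulation studies in the
test suite run 2 chains of 5500 iterations (500 warmup) for the
full-structure recovery study, roughly 2 × 600–4000 elsewhere, and long
cheap chains (2 × 15000) for the conjugate normal variants, sized so
the whole suite completes in well under half an hour on one CPU; the
analysis scripts use 2 × 1500 for the twelve-model sweep and state the
reference protocol in their headers. JAGS reports no divergence diagnostics;
chain quality is assessed wholly through the statistics below.

## Chain quality

`diagnose()` computes rank-normalized split $\widehat R$ (the maximum
of the bulk and folded variants) with the conventional 1.05 flag
cutoff, plus bulk and tail effective sample sizes from the combined
split-chain autocorrelation with Geyer's initial positive and monotone
sequence corrections. The implementation was checked against an
independent reference implementation to $10^{-6}$ on shared draws, and
against closed forms (iid and AR(1) chains). Degenerate (constant)
parameters report NaN with a flag; antithetic chains whose raw ESS
exceeds the draw count are capped at the total and flagged. The plain
Gelman–Rubin split statistic is available behind
`rank_normalized = FALSE`. Trace, rank-histogram, ACF and density data
are exported as tidy tables by `plot_data()`, keeping plotting out of
the core.

## Model comparison

`score_model()` evaluates the pointwise log-likelihood of every
retained draw on the shared transformed outcome and computes:

* **WAIC** $= -2\sum_i(\mathrm{lppd}_i - p_i)$ with
  $p_i = \mathrm{Var}_s(\ell_{si})$, SE
  $\sqrt{n\,\mathrm{Var}_i(\cdot)}$;
* **PSIS-LOO**: per observation, raw importance ratios
  $\propto e^{-\ell_{si}}$; the largest
  $M = \lceil\min(0.2S, 3\sqrt S)\rceil$ ratios are replaced by
  expected order statistics of a generalized Pareto distribution fitted
  to the tail exceedances by the Zhang–Stephens posterior-mean
  estimator (with the standard weak shape regularization), truncated at
  the raw maximum. The tail shape $\hat k$ is reported per observation
  and observations with $\hat k > 0.7$ (the established reliability
  cutoff, configurable) are flagged as influential;
* **DIC** $= \hat D + 2 p_{DIC}$ with
  $p_{DIC} = \bar D - \hat D$ evaluated at the posterior mean.

When the pointwise log-likelihood is constant across draws, PSIS
reduces exactly to WAIC. `compare_models()` reports differences to the
best model with paired difference SEs, penalties, Pareto-k flag counts,
and $e^{-\Delta/2}$ evidence weights normalized per criterion (WAIC and
PSIS separately). Negative penalties are reported with a warning, not
clamped.

## Latent inference

For beta-family fits, `extract_si()` assembles $SI_i$ draw by draw from
the structural components (fixed effects as the variant specifies,
$e_i$, and the speaker's average sentence effect); block effects are
not part of the trait. Speakers are ranked by posterior mean, most
intelligible first, ties broken by speaker id for determinism. HPDIs
are the shortest interval containing the requested mass, computed by a
sliding window over the sorted draws — correct for the unimodal
posteriors these models produce, and checked against exhaustive window
search. Contrasts (speaker pairs, $\alpha_{HS[2]} - \alpha_{HS[1]}$,
and slope gaps where the variant has them) are computed on the draw
scale; "significant" is interval exclusion of zero, not a frequentist
test. `posterior_predictive()` pushes draws through the likelihood and
reports the share of predictive mass outside $[0, 1]$ — structurally
zero for the beta family, and the normal family's physical-consistency
failure mode on boundary-heavy scores.

## Numerical choices and degenerate inputs

* `inverse_logit` is computed overflow-safely; fitted means are clamped
  to $[10^{-12}, 1 - 10^{-12}]$ before the beta log-density.
* `word_entropy` requires $J \ge 2$ ($\log_2 J = 0$ otherwise); the
  error names the word position and sentence when raised from a grid.
* The GPD fitter needs at least 5 positive exceedances and declines to
  smooth (returning NaN $\hat k$, uniform weights) when the tail is
  degenerate; `psis_loo()` warns below 100 draws.
* `hpdi` uses $\lceil pn \rceil$-sample windows; 50+ draws are
  recommended.
* Empty grid files parse to empty lists; zero prior-predictive draws
  return an empty matrix; an empty diagnostics subset returns an empty
  report.

## Pipeline

`run_pipeline()` drives simulate → fit → diagnose → compare →
rank/contrast from one config (an R list or YAML file), writing each
stage's tables, a seed and config-hash manifest with per-artifact md5s,
and recording stage failures while skipping downstream stages. Its
gate status is nonzero when any parameter failed the $\widehat R$
cutoff. The numbered scripts in `analysis/` present the same workflow
as a narrative, at sizes chosen for a single-CPU session.

## Limitations

Construct validity of the latent trait is out of scope: the package
quantifies agreement-driven intelligibility under the stated model, not
whether transcription agreement measures "intelligibility" in a deeper
sense. The entropy aggregation assumes aligned grids as input;
automatic alignment of free transcriptions is deliberately not
implemented. Parameter-recovery results are conditional on the
generator's assumptions (truncated-normal ages, synthetic vocabularies,
independent sentence effects); they bound what the pipeline can claim
about real data. Bayes factors, refit cross-validation and stacking
weights are intentionally absent from the comparison module.
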