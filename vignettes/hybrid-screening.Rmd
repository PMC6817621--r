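---
title: "Hybrid text-plus-questionnaire screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid text-plus-questionnaire screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textprior)
```

## The measurement problem

Screening for PTSD in large samples usually relies on short item-based
questionnaires, because structured clinical interviews are expensive. A
person's free-text account of their trauma carries complementary
information, and this package implements one way of using it: an automated
text score serves as an *informative prior* for the latent severity that
the questionnaire measures. Three estimation routes coexist:

1. **Questionnaire only.** A unidimensional 2PL item response model with
   fixed, previously calibrated item parameters; the trait is the EAP under
   a standard normal prior.
2. **Text only.** A product-score (naive-Bayes-style) classifier of the
   narrative, thresholded on its log-ratio score.
3. **Combination.** The standardized text score enters a latent regression
   whose fitted line defines a normal prior for each person's trait; the
   posterior combines that prior with the 2PL likelihood.

## The 2PL stage

For item $i$ with discrimination $\alpha_i > 0$ and difficulty $\beta_i$,

$$P(X_{ni}=1 \mid \theta_n) =
  \frac{\exp[\alpha_i(\theta_n-\beta_i)]}{1+\exp[\alpha_i(\theta_n-\beta_i)]}.$$

No $D = 1.7$ scaling constant is used; the scale is the logit scale on
which the shipped bank was calibrated. The Rasch model is the special case
$\alpha_i \equiv 1$ and flows through the same code path. Item information
is $\alpha_i^2 P(1-P)$, maximal at $\theta=\beta_i$; test information is
its sum over administered items.

The shipped bank (`ncsr_bank()`) contains the 21 DSM-IV PTSD symptom items
of the NCS-R screening section with parameters calibrated by marginal
maximum likelihood on $n=880$; this package deliberately performs **no
item calibration** — parameters are consumed as known constants, as in the
screening application the package supports. Their standard errors and
per-item criterion validity correlations are carried as metadata.

### EAP quadrature

`eap_estimate()` integrates on an equally spaced grid, by default 121
points spaced $0.1$ on $[-6,6]$ — ample for a standard normal prior, where
the omitted tails hold about $2\times10^{-9}$ of the mass. When a caller
supplies a prior located or scaled so that $[-6,6]$ would cover less than
$99.999\%$ of its mass (an informative text prior with variance
$\sigma^2=3.57$ easily does), the grid is widened automatically at the
same spacing (and refined to a tenth of the prior SD for very tight
priors) so coverage always holds; an *explicitly* supplied grid that
misses prior mass raises an error instead of silently truncating the
posterior. Probabilities inside the log-likelihood are clamped to
$[10^{-12}, 1-10^{-12}]$; missing responses (items not administered) are
skipped. Prior-only estimation (zero items) is legal and returns the prior
moments, which the routing machinery uses as its $m=0$ conceptual anchor.

## The text stage

Preprocessing lowercases, expands common contractions, discards tokens
containing digits and punctuation-only strings, removes a small stop list
(`default_stoplist()`, configurable), and Porter-stems the remainder; the
stemmer is implemented in full in `R/porter.R` and checked against the
algorithm's canonical worked examples. The product score model assigns
each class the score

$$S_c = P(C_c)\prod_{w}\left[\frac{n_{cw}+a}{\mathrm{len}(C_c)}\right]^{x_w},$$

with smoothing constant $a=0.5$ added to every keyword count. Scoring is
performed entirely in the log domain; a brute-force product oracle in the
test suite confirms the equivalence on small vocabularies. Three
conventions, each configurable, deserve note:

* **Token multiplicity.** Occurrences count with multiplicity
  (multinomial style), matching the definition of the counts $n_{cw}$ as
  numbers of occurrences. Whether the original screening system scored
  types or tokens is not documented; multiplicity is the default and the
  flag to change it is the vocabulary itself (collapse a document to
  unique stems before scoring).
* **Tie rule.** A document whose log-ratio equals the threshold $b$
  (default 0) is assigned to class 2, the literal "else" branch of the
  decision rule.
* **Priors.** Class priors default to training-document proportions and
  may be fixed externally, e.g. to a known population prevalence.
* **Standardization.** Text scores are z-scored *within the analyzed
  cohort* with the $n-1$ SD. The alternative — standardizing against the
  training corpus — is available by applying the training moments
  manually; the cohort convention was chosen because the downstream
  latent regression is itself fit on the cohort.

The published list of 1,000 discriminative unigrams is not reproduced in
any public source, so the vocabulary is an input; by default `psm()` uses
the union of observed stems. The 20 published example stems (10 per class)
seed the synthetic generator's vocabulary.

## The combination stage

The latent regression $\theta_n = b_0 + b_1 y_n + \varepsilon_n$,
$\varepsilon_n \sim N(0,\sigma^2)$, turns a standardized text score into
the prior $\theta_n \mid y_n \sim N(b_0+b_1y_n, \sigma^2)$.
`fit_latent_regression()` samples the joint posterior with item parameters
fixed:

* random-walk Metropolis for each $\theta_n$, proposal SD tuned during
  burn-in toward a 30–50% acceptance rate (batches of 50 iterations,
  multiplicative adaptation, frozen after burn-in so the post-burn-in
  chain is a genuine Markov chain);
* conjugate Gibbs draws for $(b_0,b_1)$ under independent $N(0,100)$
  priors and for $\sigma^2$ under an inverse-gamma$(0.01, 0.01)$ prior —
  weakly informative defaults mirroring common practice for this model
  class, both configurable.

Defaults are 5,000 iterations with 1,000 burn-in, two chains, and a
split-chain $\widehat R$ diagnostic; runs are bit-reproducible given a
seed (chain $c$ uses `seed + c - 1`). Per-person Monte Carlo standard
errors come from batch means. A `fix_coefficients` mode holds
$(b_0,b_1,\sigma^2)$ at given values, which the test suite uses to verify
the trait sampler against the deterministic quadrature of `hybrid_eap()`
— the two-stage path that scores persons with plugged-in posterior-mean
coefficients and is also what the routing curves use for speed. With
$b_0=0$, $b_1=0$, $\sigma^2=1$ the hybrid posterior reproduces the
questionnaire-only posterior exactly (same grid, same engine).

## Routing and the SE curve

Items are ranked once by information at the diagnostic cutoff
$\theta=-0.15$ (the value carried over from the $n=880$ calibration;
`rank_items()`, ties broken by bank order), and administered cumulatively
in that order. `se_curve()` traces the cohort-mean standard error against
test length $m$, with and without the text prior, and `items_saved()`
applies the discrete crossing rule: the saving is $M - m^\*$, where
$m^\*$ is the smallest $m$ at which the with-prior curve reaches the
full-length without-prior level (no interpolation).

The SE measure required a genuine design decision. The curves this
analysis emulates start near 1.6 (without prior) and 1.4 (with prior) at
$m=1$ and end near 0.68 and 0.65 at $m=21$ — values consistent with the
large-sample information-based standard error
$1/\sqrt{\pi_0 + I_m(\hat\theta)}$, where the prior precision $\pi_0$ is
$1/\sigma^2$ with the text prior and $0$ without (the questionnaire alone
carrying the measurement), and *not* with an exact posterior SD: under a
standard normal prior a posterior SD can never exceed 1, and with a text
prior of variance $\sigma^2 = 3.57 > 1$ the posterior-SD ordering of the
two curves actually inverts, since posterior spread reflects prior
precision but not how well the prior is centered. `se_curve()` therefore
defaults to `se_measure = "information"`, evaluating $I_m$ for both
curves at a common reference estimate of each person's trait (the
full-questionnaire EAP) — interim estimates at very short test lengths
are too noisy to anchor the information function and would make the
curves incomparable. The exact posterior SD remains available as
`se_measure = "posterior_sd"` and is the quantity used in the
precision-ordering tests (a variance-0.5, identically centered prior
tightens every pattern's posterior).

## Standard setting

Three methods locate a cutoff between diagnosed-positive and
diagnosed-negative latent score distributions, and their arithmetic mean
is the operating cutoff:

1. midpoint of the two group medians;
2. contrasting groups: logistic regression of membership on score, cutoff
   where the fitted probability is 50%, i.e. $-a/b$. The source
   formulation ("$y^* = a + bx$, given $y^* = 0.5$") literally reads as
   $x = (0.5-a)/b$ on the linear predictor; the probability-0.5 reading is
   the standard contrasting-groups method and is the one implemented;
3. Bayes discriminant under zero-one loss with normal class densities:
   the boundary solving $P_1\phi(x;\mu_1,\sigma_1)=P_2\phi(x;\mu_2,\sigma_2)$.
   With unequal variances the quadratic has two roots; the root between
   the group means is returned (it is the operating boundary in the
   overlap region), else the root nearest their midpoint.

Degenerate inputs fail loudly: empty groups, complete separation
(detected from fitted probabilities), zero within-group variance,
non-finite cutoffs entering the average.

Classification against the cutoff is boundary-inclusive
($\hat\theta \ge$ cutoff is positive; configurable), and the five
screening metrics follow their confusion-table definitions, with
zero-denominator metrics flagged undefined rather than fabricated.

## The synthetic cohort generator

Because the motivating study's raw data (99 respondents; 34 positive) are
not deposited, every stage is exercised on synthetic cohorts
(`cohort_spec()`, `simulate_study()`) built to the same statistical
structure:

* labels Bernoulli with prevalence $34/99$;
* standardized text scores as class-shifted normals, class gap 2 SD
  pre-standardization — a separation at which a text-only classifier
  plateaus in the mid-0.8 accuracy range typical of narrative-based PTSD
  screening;
* traits from the latent regression with defaults
  $b_0=-0.41$, $b_1=1.44$, $\sigma^2=3.57$;
* item responses as independent Bernoulli draws from the 2PL under the
  shipped bank;
* narratives as class-conditional unigram multinomials over a 100-stem
  vocabulary seeded with the 20 published class-typical stems plus
  neutral fillers (all Porter fixed points), document length Poisson with
  mean 150 tokens. The keyword tilt is log-linear with strength
  `text_effect`, fixed at 0.6 after a one-off calibration giving held-out
  product-score accuracy near 0.83 and a correlation of about 0.95
  between the generating score and the recovered one. When the cohort's
  own `y` is passed to `gen_narratives()`, the tilt follows each person's
  score, making the chain *narratives → PSM → standardization → latent
  regression* generatively coherent; labels-only generation is available
  for pure classifier experiments (`text_effect = 0` yields chance-level
  accuracy on balanced classes).

What the generator does **not** emulate: real lexical diversity, syntax,
narrative length–severity dependence, respondent faking, or any coupling
between symptom endorsement and word choice beyond the single latent
score. Consequently, passing tests demonstrate the *estimators'* internal
correctness and calibration under the assumed model, not clinical
performance. In particular, trait-based classification accuracy on
synthetic cohorts sits far below the high-0.9 values reported for real
cohorts: with residual variance 3.57 the simulated label–trait coupling
is much looser than in the motivating sample, and no choice of seed
changes that. This is a property of the stated simulation conditions and
is left as is.

## Problem sizes and runtime choices

The test suite and the acceptance script scale their simulations to
desk-size problems chosen as the package's own defaults: parameter
recovery on cohorts of $n=200$ with the full 5,000-iteration two-chain
sampler; sampler-versus-quadrature agreement on 20 persons at fixed
coefficients; null-slope coverage over 20 replicates of $n=60$ with
shortened chains; standard-setting symmetry at $2\times10^4$ scores;
EAP-versus-oracle agreement on the full 21-item bank against a
Riemann-sum oracle on a 10-times finer grid (tolerance $10^{-4}$).

## Known limitations

* Item parameters are trusted as fixed; parameter uncertainty (the SE
  columns of the bank) is not propagated into trait posteriors.
* The latent regression assumes homoscedastic normal residuals; heavy
  tails or a nonlinear text–trait link would miscalibrate the prior.
* The routing plan is fixed at the cutoff, not adapted per person after
  interim responses.
* Multidimensional symptom structure (separate B/C/D domains) is out of
  scope; the trait is unidimensional by construction.
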