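---
title: "Methods: forecasting county opioid mortality from language and history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting county opioid mortality from language and history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The forecasting problem

`trop` forecasts the next year's opioid-related death rate for each U.S.
county from (a) the county's own rate history and (b) yearly county-level
social-media topic loadings, optionally augmented with seven
socio-economic covariates. Writing $Y_t$ for a county's death rate (per
100,000 persons) in year $t$ and $X_t$ for its reduced $D$-dimensional
language vector, the model is an autoregressive map

$$f(Y_t; X_t,\; Y_{t-1}; X_{t-1},\; \dots,\; Y_{t-n}; X_{t-n}) + \epsilon = Y_{t+1},$$

with $n$ the history length (3 by default, one time-step per calendar
year). Because county death rates trended upward over the period this
kind of panel covers, the series is non-stationary; we difference once
and model the *change* $P_t$, reconstructing the level forecast as
$\hat Y_{t+1} = Y_t + \hat P_t$. A single integration step is all a
seven-year panel can afford: each difference costs one year of usable
history.

The train/test split is temporal: training windows target years up to the
split year (2015 in the canonical seven-year layout), test windows target
the final two years. With seven years and history 3 there is exactly one
training window per county (inputs = changes 2011→2012, 2012→2013,
2013→2014; target = change 2014→2015), and the window slides forward one
step for each test year. Nothing a test prediction depends on — the
topic-reduction basis, model parameters, hyperparameters — is computed
from years at or after the target year.

## Preprocessing

**Age adjustment.** Some sources suppress small-county age-adjusted
rates, so the package reconstructs an age-adjusted rate from the crude
rate: within each year, the crude rate is regressed (OLS, intercept
included) on the county's population counts in three age terciles, and
the county's adjusted rate is its residual plus that year's cross-county
mean crude rate. Under this convention ("standard" mode) the adjustment
is exactly a no-op when every county shares an age structure, and the
yearly mean rate is preserved to machine precision. The source formula
can also be read with the residual *subtracted* (leaving fitted + mean);
that "literal" mode is retained for audits, but it inflates or deflates
every county toward the regression surface and breaks the no-op
property, which is why it is not the default.

**Activity filtering.** Counties need at least 100 users with 30+ tweets
over the whole span to be retained; a county-year that fails the
criterion only has its topic vector flagged unobserved.

**Imputation.** Unobserved topic-years are replaced by the unweighted
cross-county mean of that year's observed vectors; counties with more
than two unobserved years are dropped. Imputed cells are usable as model
input (windows must be complete), but the lagged association analysis
excludes counties imputed in either tested year (`observed_only = TRUE`):
a mean-imputed cell manufactures a jump between the county's own loading
and the yearly mean that can be an order of magnitude larger than a real
yearly change, and such artifacts would dominate a change-on-change
regression.

**Topic reduction.** The $K$-dimensional loadings (2000 in the canonical
setting) are compressed to $D = 20$ non-negative dimensions by NMF fit
only on training years. Because no suitable NMF implementation ships with
the package's dependency set, the factorization is implemented here:
deterministic NNDSVD initialization, Lee–Seung multiplicative updates on
the Frobenius objective, at most 500 iterations, stopping when the
relative error improvement falls below 1e-4. New county-years are
transformed against the frozen components by non-negative least squares
(accelerated projected gradient on the normal equations, tolerance 1e-9).
Zero vectors map to zero coefficients; outputs are non-negative by
construction and deterministic given a fitted reducer.

**Feature sequences.** Each county-year becomes a vector
(outcome; $D$ topic features; optionally 7 SES variables), so the
per-step input dimension is 1, 21, or 28. The outcome is always
differenced inside window construction. Topic/SES covariates are
differenced too by default — the association framing of the science is
about yearly *changes* in language — but a flag carries levels instead,
since the regression formulation is agnostic.

## Models

**Transformer (TrOP).** One encoder layer sized for short sequences:
a learned affine projection lifts the input to the model width, fixed
sinusoidal positional encodings are added, then multi-head
self-attention (scaled dot-product, $h = 3$ heads) and a feed-forward
block (hidden 128, ReLU), each with a residual connection followed by
layer normalization (post-residual placement, as in the original
architecture), dropout 0.20 on the sublayer outputs during training
only. The last position's representation feeds an affine head that emits
the scalar predicted change. Width rule: 21 features with 3 heads is
divisible, but sinusoidal encodings need an even width, so the model
width is the smallest even multiple of $h$ strictly above the input
dimension (21→24, 28→30, 1→6); per-head width is then 8 for the
canonical multivariate setting. All forward/backward passes are
hand-written, batched over windows, and the analytic gradients are
verified against central finite differences (relative error < 1e-5) in
the test suite.

**Recurrent network.** GRU cells by default (LSTM available),
bidirectional with the two directions' hidden states concatenated at
each step, pooled across time by additive neural attention whose weights
are softmax-normalized (they sum to 1 by construction), then an affine
head. Hidden size 32 by default; the hyperparameter search grid maps
"hidden size" to this width, and for the transformer to the feed-forward
width.

**Ridge autoregressor.** L2-regularized linear regression on the
flattened window, trained by deterministic gradient descent with
momentum on the centered problem; the intercept is unpenalized and
recovered analytically. The fixed point equals the closed-form ridge
estimate, and the suite checks agreement to 1e-4 on random window sets.

**Heuristic baselines.** last(1) repeats the final observed level
(zero predicted change); mean(k) predicts the mean of the last $k$
levels (default $k = 4$).

**Training.** Minibatch AdamW (decoupled weight decay) on the MSE of the
predicted change; default learning rate 1e-3, weight decay 1e-4, batch
size 64. Counties are split 80/20 into fit/dev by a seeded partition
(a by-year dev split is impossible with so few years); early stopping on
dev MSE with patience 25 within at most 500 epochs (the package-level
checks use 300, which the optimizer rarely exhausts), returning the
dev-best parameters. Hyperparameter search, when requested, is seeded
random sampling over the documented spaces (learning rate log-uniform
5e-5–5e-3, weight decay 0–1, dropout 0.10–0.50 in steps of 0.05, hidden
size 1–16 step 2 univariate / 32–256 step 16 multivariate), 25 trials by
default, selected on dev MSE.

## Evaluation

Forecast levels are reconstructed from each window's anchor and scored
by MAE (deaths per 100,000) and MAPE (percent, the mean of per-window
absolute percentage errors; windows with a zero truth level are excluded
from MAPE with a logged count — real rates are strictly positive, so
this only matters for synthetic edge cases). Model pairs are compared by
a classical two-sided paired t-test on per-window absolute errors, with
a degenerate-case signal instead of a p-value when the differences have
zero variance. Per-year breakdowns carry t-interval 95% confidence
bounds on the MAE; a sweep driver retrains at each history length.

## Lagged association analysis

For each topic, the county-level future outcome change is regressed on
the prior topic change (both z-scored) with the prior-year outcome level
as an additional standardized covariate, by OLS across counties; the
topic term's coefficient is the standardized association $\beta$ with a
two-sided p-value, and p-values are Benjamini–Hochberg adjusted across
topics within each target year. The full pre-reduction topic set is
tested (the reduced components can be tested via the same function on a
reduced panel). The prior-year *level* covariate follows the analysis
text; a `covariate = "change"` flag implements the alternative reading
(adjusting for the prior outcome change) without guessing intent.
Constant topic changes are flagged degenerate and skipped rather than
producing unstable fits.

## The synthetic panel generator

Every stage is exercisable without any real data through
`generate_panel()`, whose defaults are fixed study conditions, not
tuning knobs:

* **Outcome.** Initial rates uniform on 5–40 per 100k; yearly change =
  per-county drift (mean 1.0, SD 0.5 per 100k — most counties trend
  upward) + AR(1) persistence 0.25 + the language signal + Gaussian
  noise (SD 1.0). Levels are floored at zero.
* **Language.** Non-negative topic loadings random-walk around county
  preferences. Preferences have low non-negative rank (ten latent
  "styles" shared across topics) plus small idiosyncratic noise — topic
  loadings estimated from text are strongly correlated across topics,
  which is exactly what makes a 2000→20 NMF compression faithful; an
  i.i.d. full-rank preference structure would make any 20-dimensional
  summary discard the change signal and would misrepresent the data the
  pipeline assumes. Eight signal topics drift with twice the nuisance
  SD, keeping the planted directions among the dominant ones.
* **Signal.** The next-year outcome change receives
  `language_effect` (default 0.5 per 100k per SD) for each signal
  topic's lagged change, scaled by that topic's generation SD, so the
  ground-truth raw coefficient per topic is `language_effect / sd_k` and
  a correctly specified linear model can recover it exactly on a
  noise-free panel (checked to 1e-2 in the suite).
* **Demographics.** Time-constant age terciles tied to a latent county
  factor add a county-level offset (2 per 100k per SD of elderly share)
  to the crude rate — constant over time, so differencing removes it and
  the within-year regression can remove it cross-sectionally. The seven
  SES covariates derive from the same latent factor.
* **Missingness.** Topic-years are masked unobserved at rate 0.01 and at
  most two per county, mirroring a small number of affected counties per
  year.

One master seed feeds labelled substreams (latent factor, population,
topics, outcome, SES, missingness), so toggling SES generation does not
perturb the topic draws. `generate_null_panel()` sets the language
effect to zero for false-discovery and calibration checks.

What the generator does **not** emulate: real tweet text or user-level
aggregation, spatial correlation between neighboring counties,
reporting suppression correlated with population, distribution shifts in
the outcome process between training and test years, and
heavier-than-Gaussian innovation tails. Passing the directional checks
on these panels therefore shows that the pipeline recovers the kind of
structure it posits, not that real panels contain that structure.

## Problem sizes and numerical choices in the checks

The package-level directional checks run 300 counties × 7 years × 200
topics over eleven seeds (plus ten null seeds), sizes at which a full
train-evaluate cycle of all models completes in seconds per seed while
keeping the test-year window count (600) large enough for stable MAE
medians. Equation-level checks use closed-form oracles at tiny sizes and
tolerances of 1e-10 to 1e-12; stochastic calibration checks use 1000
simulated repeats with three-sigma Monte-Carlo margins. Ridge gradient
descent stops at gradient norm 1e-10; the NMF stopping rule and NNLS
tolerances are as above. Ties in BH adjustment need no tie-break (the
step-up minimum is well-defined); attention softmaxes subtract the row
maximum for numerical stability.

## Known limitations

* A single transformer layer and fixed sinusoidal positions are
  appropriate for sequences of length ≤ 6; the configuration allows more
  layers but nothing here is tuned for long sequences.
* The ridge model treats the flattened window as exchangeable features;
  it has no county fixed effects, so between-county drift differences
  act as irreducible noise for all models.
* Mean-imputation of missing topic-years is faithful to the documented
  procedure but known to distort change-based analyses; the association
  module works around it, the forecasting module inherits it.
* MAPE is undefined at zero truth levels and asymmetric by construction;
  MAE in deaths per 100k is the primary comparison metric.
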