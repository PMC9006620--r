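---
title: "Spatial regression for field trials: models, estimators and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial regression for field trials: models, estimators and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
set.seed(1)
```

```{r}
library(fieldspat)
```

# The problem

Agricultural field trials measure an outcome $A$ (say, yield) and regressors
$B_1, \dots, B_p$ (microbiome features, soil covariates, treatments) on plots
laid out on a grid. Fertility gradients, border effects and locally varying
soil make nearby plots more alike than distant ones. Regression methods that
assume independent errors then misbehave in two distinct ways:

1. **Inference**: standard errors are too small, so null effects are declared
   significant far more often than the nominal level, whenever both outcome
   and a regressor carry spatial structure (spatial confounding).
2. **Selection** (high-dimensional case): penalized regression preferentially
   selects spatially smooth regressors when the outcome is spatially
   structured — a bias we call the *red shift* — and cross-validated
   performance estimates become optimistic because training and held-out plots
   are spatially correlated.

`fieldspat` provides a simulator with known ground truth, estimators that
account for the spatial correlation (iterative GLS and a GLS elastic net), and
evaluation tools (blocked cross-validation, mean-centered $R^2$, Moran's $I$)
to quantify both failure modes and their remedies.

# The data-generating model

All simulated variables live on a $G \times G$ unit-spaced grid and follow

$$ V = f(x, y) + \varepsilon, \qquad \varepsilon \sim N(0, \Sigma), $$

with four structure types:

| structure  | mean $f(x,y)$                         | covariance $\Sigma$ |
|------------|----------------------------------------|---------------------|
| `none`     | $0$                                    | $\sigma^2 I$        |
| `linear`   | $\gamma_1 x + \gamma_2 y$              | $\sigma^2 I$        |
| `edge`     | $\beta_e \, d_{edge}(x,y)$             | $\sigma^2 I$        |
| `gaussCor` | $0$                                    | Gaussian-decay      |

where $d_{edge}(x, y) = \min(x, y, G{+}1{-}x, G{+}1{-}y)$ is the distance to
the field border (1 on the border rows) and the Gaussian-decay covariance is

$$ \Sigma_{ij} = \sigma^2 \left[ \tau \, 1\{i = j\}
   + (1 - \tau) \exp\!\big( -(d_{ij} / r)^2 \big) \right], $$

with range $r$, nugget $\tau \in [0, 1]$ and Euclidean distance $d_{ij}$.
Defaults are $\sigma^2 = 1$, $r = 7.5$, $\tau = 0.25$. Unspecified gradient
coefficients are drawn per variable: $\gamma \sim U[-0.5, 0.5]^2$ and
$\beta_e \sim N(0, 50)$.

```{r}
d <- simulate_observational(p = 50, n = 100, G = 15,
                            outcome_spec = "gaussCor",
                            regressor_spec = "gaussCor",
                            beta_sd = 0.5, seed = 7)
plot_field(d)
str(sim_truth(d)[c("beta", "spatial_flags")])
```

Half of the regressors (by default) carry the spatial structure; within the
spatial and non-spatial groups separately, 20% have nonzero coefficients drawn
from $N(0, \beta_{sd}^2)$. An unbiased selector should therefore pick
spatially structured features about half the time.

`simulate_checkerboard()` generates the experimental counterpart: an
$18 \times 18$ field split into square subplots treated in a checkerboard
pattern. Subplot side 6 produces 5 treated vs 4 control subplots, the
configuration in which the treatment is spatially confounded with
border/center position; sides 9 and 3 are exactly balanced.

# Estimators

## Iterative GLS

`fit_gls()` alternates (i) restricted maximum-likelihood estimation of
$(\sigma^2, r, \tau)$ from the current residuals and (ii) weighted least
squares on outcome and design premultiplied by $\hat\Sigma^{-1/2}$, until the
mean squared change in fitted values drops below $10^{-6}$. Because the mean
coefficients are profiled inside the REML objective, the alternation is
self-consistent after two passes; the loop structure and tolerance are kept as
the defining contract. `wald_test()` provides the per-coefficient test on
$n - p - 1$ degrees of freedom.

Numerical design of the covariance step (`fit_cov_params()`):

* the likelihood is profiled analytically over $\sigma^2$ and the mean
  coefficients, leaving a 2-D optimization over $(\log r, \mathrm{logit}\,\tau)$;
* the surface is flat and often multimodal, so a $3 \times 3$ grid of starts
  ($r \in \{2, 7.5, 15\}$, $\tau \in \{0.1, 0.5, 0.9\}$) is evaluated and
  Nelder–Mead is run from the best three;
* range and nugget from a single field are strongly correlated and highly
  variable — wide spread of $(\hat r, \hat\tau)$ across replicates is expected
  and does not harm the downstream regression, which only needs a reasonable
  whitening.

```{r}
fit <- fit_gls(d, regressors = paste0("B_", 1:5))
glance(fit)
```

## GLS elastic net

For $p \gg n$, `fit_pengls()` embeds the same whitening idea in the elastic
net: starting from $\Sigma = I$ (so the first pass is the plain elastic net),
it alternates a penalized fit on whitened data — with the whitened intercept
direction left unpenalized — and REML covariance re-estimation from the
residuals, stopping when the mean squared change in predictions falls below
$2.5 \times 10^{-4}$. Whitening removes the red shift: with spatial
correlation absorbed by $\hat\Sigma$, smooth and rough regressors compete on
equal terms.

The penalty is tuned by `tune_lambda()` along a 100-value log-spaced path with
the one-standard-error rule on cross-validated mean-centered $R^2$ (largest
$\lambda$ within one SE of the best). A full alternating fit for every
(fold, $\lambda$) pair would be prohibitively slow, so per fold the covariance
is estimated once, from a full alternating fit at a reference $\lambda$ (the
plain elastic net's one-SE choice), and the whole path is then evaluated with
that whitening fixed. The final model is refit by full alternation at the
selected $\lambda$.

Two comparators are provided: `fit_en()` (plain elastic net) and
`fit_en_eigen()` (elastic net augmented with Moran eigenvectors — spatial
filtering: eigenvectors of the doubly-centered proximity matrix
$\exp(-d/\bar d)$ above 25% of the leading eigenvalue absorb smooth spatial
patterns; they are excluded from the selected set and from predictions).

```{r}
folds <- random_folds(nrow(d), 5, seed = 2)
tl <- tune_lambda(d, folds, method = "en")
en <- fit_en(d, tl$lambda)
selection_metrics(en$selected, d)
```

# Evaluation

* `r_squared_centered()` centers observed and predicted values by their own
  means before computing $R^2$, so baseline offsets between fields do not
  count; the statistic can be negative.
* `random_folds()` vs `blocked_folds()` (k-means on coordinates): blocked CV
  breaks the spatial correlation between training and held-out plots, removing
  the optimism of random CV under spatial structure.
* `morans_i()` uses inverse-distance weights (not row-standardized); the
  *conditional* form measures residual autocorrelation given the model's
  coefficient-only predictions. `adjusted_morans_i()` adds the null
  expectation $1/(n-1)$ so values are comparable across sample sizes.
* `simulate_test_set()` draws matched test data with the same true
  coefficients, either with redrawn spatial structure (`"spatial"`, a nearby
  field) or with none (`"none"`, an unrelated field).

# Monte-Carlo studies

The `run_*()` functions reproduce the benchmark designs at configurable scale:
`run_univariate_observational()` (type-I error / power of OLS vs GLS),
`run_univariate_checkerboard()` (treatment tests with and without row/column
dummies), `run_lowdim()` ($R^2$ measures and residual Moran's $I$ for OLS/GLS)
and `run_highdim()` (selection metrics for the elastic-net variants).
Replicate seeds derive deterministically from a master seed, so studies are
reproducible, independent of method subsets, and extendable: increasing `reps`
leaves earlier replicates unchanged. Results come back as tidy tibbles
(one row per replicate/method/metric) ready for `summarize_study()` or
`autoplot()`.

Desk-scale defaults (100–1000 replicates for univariate studies, 50 for the
penalized ones) run in minutes on a single core; the studies are sequential by
design so that results never depend on a parallel backend.

```{r}
res <- run_univariate_observational(reps = 20, methods = c("ols", "gls"),
                                    outcome_structures = c("none", "linear"),
                                    regressor_structures = "linear",
                                    settings = "null", master_seed = 99)
summarize_study(res)
```

# Limitations

* The covariance model is isotropic Gaussian decay; anisotropy, nonstationary
  range or non-Gaussian noise are out of scope.
* Predictions deliberately exclude spatial terms (no kriging): the target is
  the transferable regressor–outcome relation, not interpolation of the
  training field.
* The Wald test does not account for the estimation of the covariance
  parameters, which is mildly anti-conservative in principle; the type-I
  studies quantify the practical effect.
* Moran's $I$ with inverse-distance weights has no finite-sample variance
  correction here; use the expectation-adjusted form for comparisons across
  sample sizes.
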